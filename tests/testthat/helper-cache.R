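# Heavy simulations shared between test files are computed once per test
# run and memoized here (testthat sources helpers into one session).
.sim_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .sim_cache)) {
    assign(name, force(expr), envir = .sim_cache)
  }
  get(name, envir = .sim_cache)
}
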