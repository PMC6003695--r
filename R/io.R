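#' Read and write spike and weight tables
#'
#' Plain tab-separated interchange for the two tables the simulator emits:
#' spike event tables (`time_ms`, `neuron_id`, plus any annotation columns
#' such as `phase` and `trial`) and sparse weight tables (`pre`, `post`,
#' `weight`). Files written by one session can be re-read and fed to every
#' analysis function.
#'
#' @param x a spikes or weights tibble.
#' @param path file path (`.tsv`).
#' @return the read functions return a tibble; the write functions return
#'   `x` invisibly.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' write_spikes(tibble::tibble(time_ms = c(1, 2), neuron_id = c(5L, 3L)), f)
#' read_spikes(f)
#' @export
write_spikes <- function(x, path) {
  stopifnot(all(c("time_ms", "neuron_id") %in% names(x)))
  utils::write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(x)
}

#' @rdname write_spikes
#' @export
read_spikes <- function(path) {
  out <- tibble::as_tibble(utils::read.delim(path, sep = "\t"))
  stopifnot(all(c("time_ms", "neuron_id") %in% names(out)))
  out
}

#' @rdname write_spikes
#' @export
write_weights <- function(x, path) {
  stopifnot(all(c("pre", "post", "weight") %in% names(x)))
  utils::write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(x)
}

#' @rdname write_spikes
#' @export
read_weights <- function(path) {
  out <- tibble::as_tibble(utils::read.delim(path, sep = "\t"))
  stopifnot(all(c("pre", "post", "weight") %in% names(out)))
  out
}
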