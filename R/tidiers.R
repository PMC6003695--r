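#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a replay-shift test
#'
#' @param x a [shift_test()] result.
#' @param ... unused.
#' @return `tidy()`: one row per phase with the sample mean and size;
#'   `glance()`: a one-row tibble with the shift summary and KS test.
#' @export
tidy.sorn_shift <- function(x, ...) {
  tibble::tibble(phase = c("before", "after"),
                 mean_rho = c(x$mean_before, x$mean_after),
                 n_trials = c(x$n_before, x$n_after))
}

#' @rdname tidy.sorn_shift
#' @export
glance.sorn_shift <- function(x, ...) {
  tibble::tibble(delta_mean = x$delta_mean,
                 ks_statistic = x$ks_statistic,
                 p_value = x$p_value,
                 n_before = x$n_before, n_after = x$n_after)
}

#' Tidy an experiment
#'
#' @param x a [run_experiment()] result.
#' @param ... unused.
#' @return `tidy()`: the annotated spike table; `glance()`: a one-row
#'   summary (simulated time, spike counts, final connection fraction,
#'   mean E-to-E weight).
#' @export
tidy.sorn_experiment <- function(x, ...) x$spikes

#' @rdname tidy.sorn_experiment
#' @export
glance.sorn_experiment <- function(x, ...) {
  n_e <- sum(x$net$neurons$is_exc)
  tibble::tibble(
    variant = x$protocol$variant,
    t_total_s = x$net$time_ms / 1000,
    n_spikes = nrow(x$spikes),
    cf = connection_fraction(x$net),
    mean_ee_weight = mean(x$net$synapses$weight[x$net$synapses$class == "EE"])
  )
}
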