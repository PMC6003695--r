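#' Spike raster plot
#'
#' @param spikes spike tibble (`time_ms`, `neuron_id`); cluster members can
#'   be highlighted by passing `clusters`.
#' @param clusters optional [build_clusters()] result; members are coloured
#'   by cluster label.
#' @param window optional length-2 time window, ms.
#' @return a ggplot.
#' @export
plot_raster <- function(spikes, clusters = NULL, window = NULL) {
  if (!is.null(window)) {
    spikes <- spikes[spikes$time_ms >= window[1] & spikes$time_ms <= window[2], ]
  }
  p <- ggplot2::ggplot(spikes, ggplot2::aes(.data$time_ms, .data$neuron_id))
  if (is.null(clusters)) {
    p <- p + ggplot2::geom_point(shape = ".", alpha = 0.6)
  } else {
    sp <- dplyr::left_join(spikes,
                           clusters[c("neuron_id", "label")], by = "neuron_id")
    p <- ggplot2::ggplot(sp, ggplot2::aes(.data$time_ms, .data$neuron_id,
                                          colour = .data$label)) +
      ggplot2::geom_point(shape = ".", alpha = 0.8) +
      ggplot2::labs(colour = "cluster")
  }
  p + ggplot2::labs(x = "time (ms)", y = "neuron") + ggplot2::theme_minimal()
}

#' Per-second network trace plot
#'
#' Connection fraction, population rates and (when clusters were supplied
#' to the simulation) adjacent-cluster forward/backward weights over time.
#'
#' @param trace the `trace` tibble of [simulate_network()] /
#'   [run_experiment()].
#' @param what one of `"cf"`, `"rates"`, `"weights"`.
#' @return a ggplot.
#' @export
plot_trace <- function(trace, what = c("cf", "rates", "weights")) {
  what <- match.arg(what)
  t_s <- trace$time_ms / 1000
  if (what == "cf") {
    return(ggplot2::ggplot(trace, ggplot2::aes(t_s, .data$cf)) +
             ggplot2::geom_line() +
             ggplot2::labs(x = "time (s)", y = "E-E connection fraction") +
             ggplot2::theme_minimal())
  }
  if (what == "rates") {
    df <- tidyr::pivot_longer(trace[c("time_ms", "rate_exc", "rate_inh")],
                              -"time_ms", names_to = "population",
                              values_to = "rate")
    return(ggplot2::ggplot(df, ggplot2::aes(.data$time_ms / 1000, .data$rate,
                                            colour = .data$population)) +
             ggplot2::geom_line() +
             ggplot2::labs(x = "time (s)", y = "mean rate (Hz)") +
             ggplot2::theme_minimal())
  }
  df <- tidyr::pivot_longer(trace[c("time_ms", "fwd_weight", "bwd_weight")],
                            -"time_ms", names_to = "direction",
                            values_to = "weight")
  ggplot2::ggplot(df, ggplot2::aes(.data$time_ms / 1000, .data$weight,
                                   colour = .data$direction)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "mean adjacent-cluster weight") +
    ggplot2::theme_minimal()
}

#' Replay-score distribution plot
#'
#' Cumulative distributions of trial Spearman scores before and after
#' training.
#'
#' @param scores_before,scores_after [replay_scores()] tables.
#' @return a ggplot.
#' @export
plot_replay_shift <- function(scores_before, scores_after) {
  df <- dplyr::bind_rows(
    dplyr::mutate(scores_before, when = "before"),
    dplyr::mutate(scores_after, when = "after"))
  df <- df[!is.na(df$rho), ]
  ggplot2::ggplot(df, ggplot2::aes(.data$rho, colour = .data$when,
                                   linetype = .data$when)) +
    ggplot2::stat_ecdf() +
    ggplot2::labs(x = "Spearman correlation", y = "cumulative fraction") +
    ggplot2::theme_minimal()
}

#' Transition-matrix heatmap
#'
#' @param mat a matrix from [transition_probabilities()] (or a difference
#'   of two such matrices).
#' @return a ggplot.
#' @export
plot_transition_matrix <- function(mat) {
  df <- tibble::as_tibble(as.table(mat), .name_repair = "minimal")
  names(df) <- c("from", "to", "p")
  ggplot2::ggplot(df, ggplot2::aes(.data$to, .data$from, fill = .data$p)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_discrete(limits = rev(rownames(mat))) +
    ggplot2::labs(x = "next cluster", y = "current cluster", fill = "P") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot methods
#'
#' `autoplot()` on an experiment shows the cluster raster of the test and
#' training phases; on a shift test the cumulative score distributions.
#'
#' @param object a `sorn_experiment`.
#' @param ... passed on.
#' @return a ggplot.
#' @export
autoplot.sorn_experiment <- function(object, ...) {
  plot_raster(object$spikes[!is.na(object$spikes$trial), ],
              clusters = object$clusters, ...)
}
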