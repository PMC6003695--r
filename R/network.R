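#' Place neurons uniformly on the cortical sheet
#'
#' Neuron positions are drawn independently and uniformly on the rectangular
#' grid. Excitatory neurons get ids `1..n_exc`, inhibitory neurons
#' `n_exc+1..n_exc+n_inh`.
#'
#' @param n_exc,n_inh positive neuron counts (`n_inh` may be 0).
#' @param geometry list with `width` and `height` in \eqn{\mu m}.
#' @return A tibble with columns `id`, `x`, `y`, `is_exc`.
#' @examples
#' place_neurons(10, 2, list(width = 2500, height = 1000))
#' @export
place_neurons <- function(n_exc, n_inh,
                          geometry = sorn_params()$geometry) {
  if (n_exc <= 0 || n_inh < 0) {
    stop("n_exc must be positive and n_inh non-negative")
  }
  n <- n_exc + n_inh
  tibble::tibble(
    id = seq_len(n),
    x = stats::runif(n, 0, geometry$width),
    y = stats::runif(n, 0, geometry$height),
    is_exc = c(rep(TRUE, n_exc), rep(FALSE, n_inh))
  )
}

#' Distance-dependent connection kernel
#'
#' Relative (unnormalized) probability that two neurons at distance `d` are
#' connected: a Gaussian kernel with mean 0 and standard deviation
#' `sigma_c` = 200 \eqn{\mu m}. Used as sampling weight both for the initial
#' fixed connectivity and for structural growth of excitatory synapses.
#'
#' @param d distance in \eqn{\mu m} (vectorized, must be non-negative).
#' @param sigma_c kernel standard deviation in \eqn{\mu m}.
#' @return `exp(-d^2 / (2 sigma_c^2))`, in (0, 1].
#' @examples
#' connection_probability(c(0, 200, 600))
#' @export
connection_probability <- function(d, sigma_c = 200) {
  if (any(d < 0)) stop("distances must be non-negative")
  exp(-d^2 / (2 * sigma_c^2))
}

#' Boundary correction factor for synaptic normalization
#'
#' The mass of a unit 2D Gaussian of width `sigma_c` centred at a neuron's
#' position that falls inside the grid rectangle. Neurons near the boundary
#' have fewer potential partners under the distance-dependent kernel; scaling
#' each neuron's normalization target by this factor prevents boundary
#' neurons from concentrating the same total weight on fewer synapses (which
#' otherwise seeds activity waves starting at the corners).
#'
#' The integral is separable and evaluated exactly as a product of 1D
#' Gaussian CDF differences.
#'
#' @param x,y position(s) inside the grid, \eqn{\mu m} (vectorized).
#' @param geometry list with `width`, `height`.
#' @param sigma_c Gaussian width in \eqn{\mu m}.
#' @return factor(s) in (0, 1]; 0.25 in the corner limit, approaching 1 deep
#'   in the interior.
#' @examples
#' boundary_factor(1250, 500, list(width = 2500, height = 1000))
#' @export
boundary_factor <- function(x, y, geometry = sorn_params()$geometry,
                            sigma_c = 200) {
  if (any(x < 0 | x > geometry$width | y < 0 | y > geometry$height)) {
    stop("position outside grid")
  }
  fx <- stats::pnorm((geometry$width - x) / sigma_c) - stats::pnorm(-x / sigma_c)
  fy <- stats::pnorm((geometry$height - y) / sigma_c) - stats::pnorm(-y / sigma_c)
  fx * fy
}

# Weighted sampling of k items without replacement, prob proportional to w
# (Efraimidis-Spirakis exponential-key method; avoids O(n*k) sample()).
weighted_sample_noreplace <- function(n, k, w) {
  if (k > n) stop("requested more edges than available pairs")
  if (k == 0) return(integer(0))
  keys <- stats::rexp(n) / w
  order(keys)[seq_len(k)]
}

# Sample `k` directed edges from pre-population `pre_ids` to post-population
# `post_ids` (self-edges excluded) with probability proportional to the
# distance kernel. Returns a tibble pre/post.
sample_distance_edges <- function(pre_ids, post_ids, neurons, k, sigma_c) {
  pairs <- expand.grid(pre = pre_ids, post = post_ids)
  pairs <- pairs[pairs$pre != pairs$post, , drop = FALSE]
  d <- sqrt((neurons$x[pairs$pre] - neurons$x[pairs$post])^2 +
            (neurons$y[pairs$pre] - neurons$y[pairs$post])^2)
  idx <- weighted_sample_noreplace(nrow(pairs), k,
                                   connection_probability(d, sigma_c))
  tibble::tibble(pre = pairs$pre[idx], post = pairs$post[idx])
}

#' Initial fixed connectivity
#'
#' Realizes the non-plastic connection classes by distance-weighted sampling:
#' a fraction 0.1 of all ordered E-to-I and I-to-E pairs and 0.5 of ordered
#' I-to-I pairs, with per-pair probability proportional to
#' [connection_probability()]. Recurrent excitatory (EE) synapses start
#' absent; they are grown by structural plasticity. Initial weights are 0.15
#' (EI) and 0.4 (IE, II); each class is then normalized once so that every
#' neuron's summed incoming weight per class matches its boundary-corrected
#' target (the same rule applied continually to EE synapses).
#'
#' @param neurons neuron table from [place_neurons()].
#' @param params a [sorn_params()] object.
#' @return A tibble with columns `pre`, `post`, `weight`, `class`
#'   (factor EE/EI/IE/II) and `delay` (ms).
#' @export
init_fixed_connectivity <- function(neurons, params = sorn_params()) {
  cc <- params$connectivity
  e_ids <- neurons$id[neurons$is_exc]
  i_ids <- neurons$id[!neurons$is_exc]
  n_e <- length(e_ids); n_i <- length(i_ids)

  mk <- function(pre_ids, post_ids, frac, w, class, delay) {
    n_pairs <- length(pre_ids) * length(post_ids) -
      length(intersect(pre_ids, post_ids))
    k <- round(frac * length(pre_ids) * length(post_ids))
    if (length(pre_ids) == 0 || length(post_ids) == 0 || k == 0) {
      return(tibble::tibble(pre = integer(0), post = integer(0),
                            weight = numeric(0), class = character(0),
                            delay = numeric(0)))
    }
    if (k > n_pairs) stop("connection fraction unreachable for class ", class)
    edges <- sample_distance_edges(pre_ids, post_ids, neurons, k, cc$sigma_c)
    tibble::tibble(pre = edges$pre, post = edges$post, weight = w,
                   class = class, delay = delay)
  }

  syn <- dplyr::bind_rows(
    mk(e_ids, i_ids, cc$cf_ei, cc$w_ei, "EI", cc$delay_ei),
    mk(i_ids, e_ids, cc$cf_ie, cc$w_ie, "IE", cc$delay_ie),
    mk(i_ids, i_ids, cc$cf_ii, cc$w_ii, "II", cc$delay_ii)
  )
  if (nrow(syn) > 0) {
    bf <- boundary_factor(neurons$x, neurons$y, params$geometry, cc$sigma_c)
    targets <- c(EI = cc$cf_ei * n_e * cc$w_ei,
                 IE = cc$cf_ie * n_i * cc$w_ie,
                 II = cc$cf_ii * n_i * cc$w_ii)
    syn <- syn |>
      dplyr::group_by(.data$class, .data$post) |>
      dplyr::mutate(weight = .data$weight *
                      targets[.data$class[1]] * bf[.data$post[1]] /
                      sum(.data$weight)) |>
      dplyr::ungroup()
  }
  syn$class <- factor(syn$class, levels = c("EE", "EI", "IE", "II"))
  syn
}

#' Build a LIF-SORN network instance
#'
#' Assembles a ready-to-simulate network: uniformly placed neurons, the fixed
#' distance-dependent EI/IE/II connectivity, an initially empty recurrent
#' excitatory synapse table, resting membrane state, and the per-neuron
#' synaptic-normalization targets (boundary-corrected).
#'
#' At full size the model has `n_exc = 1000` excitatory and
#' `n_inh = 0.2 * n_exc = 200` inhibitory neurons on a 2500 x 1000
#' \eqn{\mu m} sheet. For reduced test networks use [make_mini_network()],
#' which also rescales the structural-growth rate.
#'
#' @param n_exc,n_inh neuron counts.
#' @param params a [sorn_params()] object.
#' @param seed optional integer; if given, seeds R's RNG for placement and
#'   wiring so the instance is reproducible.
#' @return An object of class `sorn_network`: a list with elements `params`,
#'   `neurons` (tibble), `synapses` (tibble; the EE class grows during
#'   simulation), `state` (membrane and plasticity state vectors),
#'   `w_total` (per-excitatory-neuron normalization target) and `time_ms`.
#' @examples
#' net <- sorn_network(n_exc = 50, n_inh = 10, seed = 1)
#' net
#' @export
sorn_network <- function(n_exc = 1000, n_inh = round(0.2 * n_exc),
                         params = sorn_params(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  neurons <- place_neurons(n_exc, n_inh, params$geometry)
  synapses <- init_fixed_connectivity(neurons, params)
  n <- n_exc + n_inh
  nv <- params$neuron
  state <- list(
    V = rep(nv$E_L, n),
    V_T = ifelse(neurons$is_exc, nv$V_T_E_init, nv$V_T_I),
    g_e = rep(0, n), g_i = rep(0, n), g_ext = rep(0, n),
    refrac = rep(0L, n),
    u = rep(params$stp$U, n_exc),
    x = rep(1, n_exc),
    last_arr = rep(-1e18, n_exc),
    last_post = rep(-1e18, n_exc)
  )
  bf <- boundary_factor(neurons$x[seq_len(n_exc)], neurons$y[seq_len(n_exc)],
                        params$geometry, params$connectivity$sigma_c)
  w_total <- params$sn$cf_target * n_exc * params$sn$mean_strength * bf
  structure(
    list(params = params, neurons = neurons, synapses = synapses,
         state = state, w_total = w_total, time_ms = 0),
    class = "sorn_network"
  )
}

#' @export
print.sorn_network <- function(x, ...) {
  ne <- sum(x$neurons$is_exc); ni <- sum(!x$neurons$is_exc)
  cat("<sorn_network> ", ne, " excitatory + ", ni, " inhibitory neurons on ",
      x$params$geometry$width, " x ", x$params$geometry$height, " um\n",
      sep = "")
  cnt <- table(x$synapses$class)
  cat("  synapses:", paste(names(cnt), cnt, collapse = ", "), "\n")
  cat("  simulated time:", x$time_ms / 1000, "s\n")
  invisible(x)
}

#' E-to-E connection fraction
#'
#' Realized recurrent excitatory synapses divided by the number of possible
#' ordered excitatory pairs.
#'
#' @param net a `sorn_network`.
#' @return a single number in \[0, 1\].
#' @export
connection_fraction <- function(net) {
  n_e <- sum(net$neurons$is_exc)
  sum(net$synapses$class == "EE") / (n_e * (n_e - 1))
}
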