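#' Stimulus blocks
#'
#' Constructors for the three external-drive types, each describing one
#' timed block of input. A protocol phase is a tibble of such blocks
#' (combine with `dplyr::bind_rows()`).
#'
#' * `stim_sweep()`: a spot of peak rate `r_max` moving linearly from
#'   `x_start` to `x_goal`; the duration is the path length divided by the
#'   sweep speed `v_spot` (437.5 ms for the default geometry at 4
#'   \eqn{\mu m}/ms).
#' * `stim_cue()`: the same spot held fixed at one position for `t_cue`
#'   (100 ms).
#' * `stim_bar()`: a bar spanning `x_start` to `x_goal`, flashed for
#'   `t_cue`; its cross-section equals the spot's profile, with distance
#'   measured to the bar segment.
#'
#' The rate field seen by an excitatory neuron at position `x` is the
#' super-Gaussian bump `r_max * exp(-(d/alpha)^beta)` (`alpha` = 150
#' \eqn{\mu m}, `beta` = 4) around the instantaneous spot centre `u(t)` (or
#' around the bar segment), and 0 outside the block's time interval. Each
#' neuron receives `n_input` independent Poisson trains at that rate,
#' entering the external conductance with jump `w_ff` per input spike.
#'
#' @param t0 block onset, ms.
#' @param x_start,x_goal 2-vectors, \eqn{\mu m}.
#' @param at cue position, 2-vector.
#' @param params a [sorn_params()] object supplying stimulus defaults.
#' @return one-row tibble with columns `type`, `t0`, `t_end`, `x0`, `y0`,
#'   `x1`, `y1`, `r_max`, `alpha`, `beta`.
#' @examples
#' stim_sweep(0)
#' stim_cue(1000, at = c(375, 500))
#' @export
stim_sweep <- function(t0, x_start = NULL, x_goal = NULL,
                       params = sorn_params()) {
  s <- params$stimulus
  if (is.null(x_start)) x_start <- s$x_start
  if (is.null(x_goal)) x_goal <- s$x_goal
  len <- sqrt(sum((x_goal - x_start)^2))
  tibble::tibble(type = "sweep", t0 = t0, t_end = t0 + len / s$v_spot,
                 x0 = x_start[1], y0 = x_start[2],
                 x1 = x_goal[1], y1 = x_goal[2],
                 r_max = s$r_max, alpha = s$alpha, beta = s$beta)
}

#' @rdname stim_sweep
#' @export
stim_cue <- function(t0, at = NULL, params = sorn_params()) {
  s <- params$stimulus
  if (is.null(at)) at <- s$x_start
  tibble::tibble(type = "cue", t0 = t0, t_end = t0 + s$t_cue,
                 x0 = at[1], y0 = at[2], x1 = at[1], y1 = at[2],
                 r_max = s$r_max, alpha = s$alpha, beta = s$beta)
}

#' @rdname stim_sweep
#' @export
stim_bar <- function(t0, x_start = NULL, x_goal = NULL,
                     params = sorn_params()) {
  s <- params$stimulus
  if (is.null(x_start)) x_start <- s$x_start
  if (is.null(x_goal)) x_goal <- s$x_goal
  tibble::tibble(type = "bar", t0 = t0, t_end = t0 + s$t_cue,
                 x0 = x_start[1], y0 = x_start[2],
                 x1 = x_goal[1], y1 = x_goal[2],
                 r_max = s$r_max, alpha = s$alpha, beta = s$beta)
}

#' Spot trajectory
#'
#' Position of the stimulus centre at time `t` within a block: linear
#' interpolation from the block's start to its goal point over its duration
#' (constant for a cue).
#'
#' @param t time(s), ms; must lie within the block interval.
#' @param block one-row stimulus tibble from [stim_sweep()] or [stim_cue()].
#' @return matrix with columns `x`, `y` (\eqn{\mu m}).
#' @export
spot_position <- function(t, block) {
  if (any(t < block$t0 | t > block$t_end)) {
    stop("t outside the stimulus interval")
  }
  frac <- if (block$t_end > block$t0) (t - block$t0) / (block$t_end - block$t0) else 0
  cbind(x = block$x0 + (block$x1 - block$x0) * frac,
        y = block$y0 + (block$y1 - block$y0) * frac)
}

#' Stimulus rate field
#'
#' Input-train rate (Hz) for a neuron at position (`x`, `y`) at time `t`
#' under a stimulus block: `r_max * exp(-(d/alpha)^beta)` with `d` the
#' distance to the instantaneous spot centre (sweep, cue) or to the bar
#' segment (perpendicular distance inside the span, endpoint distance
#' beyond); 0 Hz outside the block's time window.
#'
#' @param x,y neuron position(s), \eqn{\mu m}.
#' @param t time, ms (scalar).
#' @param block one-row stimulus tibble.
#' @return rate(s), Hz.
#' @examples
#' b <- stim_cue(0, at = c(375, 500))
#' stimulus_rate(375, 500, 50, b)          # on-centre: 50 Hz
#' stimulus_rate(375 + 150, 500, 50, b)    # at alpha: 50/e Hz
#' @export
stimulus_rate <- function(x, y, t, block) {
  if (t < block$t0 || t > block$t_end) return(rep(0, length(x)))
  if (block$type == "bar") {
    d <- dist_point_segment(x, y, block$x0, block$y0, block$x1, block$y1)
  } else {
    u <- spot_position(t, block)
    d <- sqrt((x - unname(u[1, 1]))^2 + (y - unname(u[1, 2]))^2)
  }
  block$r_max * exp(-(d / block$alpha)^block$beta)
}

# distance from points to a segment (vectorized over points)
dist_point_segment <- function(px, py, ax, ay, bx, by) {
  vx <- bx - ax; vy <- by - ay
  len2 <- vx^2 + vy^2
  if (len2 == 0) return(sqrt((px - ax)^2 + (py - ay)^2))
  tt <- pmin(1, pmax(0, ((px - ax) * vx + (py - ay) * vy) / len2))
  sqrt((px - ax - tt * vx)^2 + (py - ay - tt * vy)^2)
}

#' Generate external input spike counts
#'
#' Per-neuron, per-step Poisson counts for the superposition of `n_input`
#' independent Poisson trains at the block's rate field: each count has mean
#' `n_input * r(x, t) * dt / 1000`. The simulation engine draws these
#' internally; this R-level generator exists so the input statistics can be
#' inspected and tested in isolation.
#'
#' @param neurons neuron table (excitatory rows receive input).
#' @param blocks stimulus-block tibble.
#' @param t_start,t_end window, ms.
#' @param n_input number of superposed trains per neuron.
#' @param dt step, ms.
#' @return tibble `step`, `time_ms`, `neuron_id`, `count` (zero counts are
#'   omitted).
#' @export
generate_input_spikes <- function(neurons, blocks, t_start, t_end,
                                  n_input = sorn_params()$stimulus$n_input,
                                  dt = sorn_params()$neuron$dt) {
  exc <- neurons[neurons$is_exc, ]
  steps <- seq(t_start, t_end - dt / 2, by = dt)
  out <- vector("list", length(steps))
  for (i in seq_along(steps)) {
    tt <- steps[i]
    rate <- rep(0, nrow(exc))
    for (b in seq_len(nrow(blocks))) {
      rate <- rate + stimulus_rate(exc$x, exc$y, tt, blocks[b, ])
    }
    k <- stats::rpois(nrow(exc), n_input * rate * dt / 1000)
    nz <- which(k > 0)
    if (length(nz)) {
      out[[i]] <- tibble::tibble(step = i, time_ms = tt,
                                 neuron_id = exc$id[nz], count = k[nz])
    }
  }
  dplyr::bind_rows(out)
}
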