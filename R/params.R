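#' Model parameters
#'
#' Builds the full parameter set of the LIF-SORN: membrane and synapse
#' constants, connectivity geometry, the five plasticity mechanisms, the
#' moving-spot stimulus and the recording clusters. Defaults correspond to a
#' model of a small patch of layer 5 rodent cortex; every value can be
#' overridden either here or from a YAML config file via [read_sorn_config()].
#'
#' Units throughout: time in ms, space in \eqn{\mu m}, potentials in mV,
#' rates in Hz, conductances and synaptic weights dimensionless.
#'
#' @param ... named overrides of nested defaults, e.g.
#'   `sorn_params(neuron = list(sigma_noise = 0), ip = list(eta = 0.2))`.
#'   Unknown names are an error.
#'
#' @return An object of class `sorn_params`: a named nested list with
#'   components `geometry`, `neuron`, `connectivity`, `stp`, `stdp`, `sn`,
#'   `sp`, `ip`, `stimulus` and `clusters`.
#'
#' @details
#' The main groups are:
#' \describe{
#'   \item{neuron}{Leaky integrate-and-fire membrane with conductance-based
#'     synapses: resting potential `E_L` (-60), membrane time constant `tau`
#'     (20 ms), excitatory/inhibitory reversal potentials `E_e` (0) and `E_i`
#'     (-80), synaptic time constants `tau_e` (3 ms) and `tau_i` (5 ms),
#'     membrane-noise standard deviation `sigma_noise` (16 mV, the stationary
#'     SD of the free membrane potential), class-specific reset and threshold
#'     potentials, an absolute refractory period `t_refrac` (5 ms) and the
#'     simulation step `dt` (0.1 ms).}
#'   \item{connectivity}{Distance-dependent wiring on the sheet with a
#'     Gaussian kernel of SD `sigma_c` (200 um); fixed connection fractions
#'     0.1 (E-to-I and I-to-E) and 0.5 (I-to-I); fixed weights 0.15 (E-to-I)
#'     and 0.4 (I-to-E, I-to-I); axonal delays 3/1/2/2 ms for EE/EI/IE/II.}
#'   \item{stp}{Short-term facilitation/depression of all outgoing E-to-E
#'     efficacy: increment `U` (0.04), facilitation and depression time
#'     constants `tau_f` (2000 ms) and `tau_d` (500 ms).}
#'   \item{stdp}{Asymmetric exponential window, nearest-neighbour pairing:
#'     amplitudes `A_plus` (4.8e-2) and `A_minus` (-2.4e-2), time constants
#'     `tau_plus` (15 ms) and `tau_minus` (30 ms).}
#'   \item{sn}{Synaptic normalization once per `interval` (1000 ms): each
#'     excitatory neuron's summed incoming E-to-E weight is rescaled to
#'     `cf_target * N_E * mean_strength * boundary_factor`, with
#'     `mean_strength` 0.8 and the boundary factor of [boundary_factor()].}
#'   \item{sp}{Structural plasticity once per second: the number of new
#'     E-to-E synapses is Gaussian with mean and SD `growth_mean` and
#'     `growth_sd` (both 6000 per second at full size), inserted at
#'     `init_weight` (1e-3) on distance-weighted non-existing ordered pairs;
#'     synapses with weight strictly below `prune_threshold` (1e-4) are
#'     removed.}
#'   \item{ip}{Intrinsic plasticity: every step the excitatory threshold
#'     moves by `eta * (N_spikes - r_target * dt)`, with `eta` 0.1 mV and
#'     target rate `r_target` 3 Hz.}
#'   \item{stimulus}{Moving-spot drive: peak input rate `r_max` (50 Hz),
#'     spot scale `alpha` (150 um), shape `beta` (4), `n_input` (100)
#'     Poisson trains per neuron, feed-forward weight `w_ff` (0.04), sweep
#'     speed `v_spot` (4 um/ms), cue flash duration `t_cue` (100 ms), and
#'     the sweep start/end points `x_start` (375, 500) and `x_goal`
#'     (2125, 500).}
#' }
#'
#' @examples
#' p <- sorn_params()
#' p$ip$r_target
#' q <- sorn_params(neuron = list(sigma_noise = 0))
#' @export
sorn_params <- function(...) {
  p <- list(
    geometry = list(width = 2500, height = 1000),
    neuron = list(
      E_L = -60, tau = 20, E_e = 0, E_i = -80,
      tau_e = 3, tau_i = 5, sigma_noise = 16,
      V_reset_E = -70, V_reset_I = -60,
      V_T_I = -48, V_T_E_init = -48,
      t_refrac = 5, dt = 0.1
    ),
    connectivity = list(
      sigma_c = 200,
      cf_ei = 0.1, cf_ie = 0.1, cf_ii = 0.5,
      w_ei = 0.15, w_ie = 0.4, w_ii = 0.4,
      delay_ee = 3, delay_ei = 1, delay_ie = 2, delay_ii = 2
    ),
    stp  = list(U = 0.04, tau_f = 2000, tau_d = 500),
    stdp = list(A_plus = 4.8e-2, A_minus = -2.4e-2,
                tau_plus = 15, tau_minus = 30),
    sn   = list(cf_target = 0.1, mean_strength = 0.8, interval = 1000),
    sp   = list(growth_mean = 6000, growth_sd = 6000,
                init_weight = 1e-3, prune_threshold = 1e-4, interval = 1000),
    ip   = list(eta = 0.1, r_target = 3),
    stimulus = list(
      r_max = 50, alpha = 150, beta = 4,
      n_input = 100, w_ff = 0.04,
      v_spot = 4, t_cue = 100,
      x_start = c(375, 500), x_goal = c(2125, 500)
    ),
    clusters = list(n_clu = 8, r_clu = 100)
  )
  p <- modify_params(p, list(...))
  structure(p, class = "sorn_params")
}

# recursive override with name checking
modify_params <- function(base, over, path = "") {
  if (length(over) == 0) return(base)
  nm <- names(over)
  if (is.null(nm) || any(nm == "")) {
    stop("parameter overrides must be named (at ", if (nzchar(path)) path else "top level", ")")
  }
  for (k in nm) {
    if (!k %in% names(base)) {
      stop("unknown parameter: ", paste0(path, k))
    }
    if (is.list(base[[k]]) && is.list(over[[k]])) {
      base[[k]] <- modify_params(base[[k]], over[[k]], paste0(path, k, "$"))
    } else {
      base[[k]] <- over[[k]]
    }
  }
  base
}

#' @export
print.sorn_params <- function(x, ...) {
  cat("<sorn_params>\n")
  for (g in names(x)) {
    v <- x[[g]]
    fmt <- vapply(names(v), function(k) {
      paste0(k, "=", paste(format(v[[k]], digits = 4), collapse = ","))
    }, character(1))
    cat(" ", g, ": ", paste(fmt, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Read or write a model configuration file
#'
#' Configurations are YAML files whose structure mirrors [sorn_params()];
#' only the values to be overridden need to be present.
#'
#' @param path file path of the YAML config.
#' @return `read_sorn_config()` returns a `sorn_params` object;
#'   `write_sorn_config()` writes `params` to `path` and returns it
#'   invisibly.
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' write_sorn_config(sorn_params(ip = list(r_target = 5)), f)
#' read_sorn_config(f)$ip$r_target
#' @export
read_sorn_config <- function(path) {
  over <- yaml::read_yaml(path)
  # YAML represents the 2-vectors as lists; flatten numerics
  over <- rapply(over, function(v) unlist(v), classes = "list", how = "replace")
  do.call(sorn_params, over)
}

#' @rdname read_sorn_config
#' @param params a `sorn_params` object.
#' @export
write_sorn_config <- function(params, path) {
  stopifnot(inherits(params, "sorn_params"))
  yaml::write_yaml(unclass(params), path)
  invisible(params)
}
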