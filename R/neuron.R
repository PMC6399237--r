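#' Single-neuron parameters
#'
#' Parameters of the single-compartment conductance-based model: leak,
#' spike-generating sodium and potassium currents, and (for excitatory
#' neurons) a slow adaptation current gated by \code{z} that reverses at
#' \code{V_K}.  Defaults are the values used throughout the network model.
#'
#' @param population \code{"E"} or \code{"I"}.  Only excitatory neurons have
#'   an adaptation current; \code{g_adapt} is forced to 0 for \code{"I"}.
#' @param C_m Membrane capacitance (uF/cm^2).
#' @param g_L,V_L Leak conductance (mS/cm^2) and reversal (mV).
#' @param g_Na,V_Na Sodium maximal conductance and reversal.
#' @param g_K,V_K Potassium maximal conductance and reversal.
#' @param g_adapt Adaptation conductance (mS/cm^2), E only.
#' @param tau_adapt Adaptation time constant (ms).
#' @return Object of class \code{"neuron_params"}.
#' @export
neuron_params <- function(population = c("E", "I"), C_m = 1, g_L = 0.1,
                          V_L = -65, g_Na = 100, V_Na = 55, g_K = 40,
                          V_K = -80, g_adapt = 0.5, tau_adapt = 60) {
  population <- match.arg(population)
  if (population == "I") g_adapt <- 0
  stopifnot(C_m > 0, g_L >= 0, g_Na >= 0, g_K >= 0, g_adapt >= 0,
            tau_adapt > 0)
  structure(list(population = population, C_m = C_m, g_L = g_L, V_L = V_L,
                 g_Na = g_Na, V_Na = V_Na, g_K = g_K, V_K = V_K,
                 g_adapt = g_adapt, tau_adapt = tau_adapt),
            class = "neuron_params")
}

#' Voltage-dependent gating rates
#'
#' Opening and closing rates \eqn{\alpha_x(V)}, \eqn{\beta_x(V)} for the
#' instantaneous sodium activation \code{m}, sodium inactivation \code{h} and
#' potassium activation \code{n}, in 1/ms.  The kinetics are pluggable; both
#' populations use the same set.
#'
#' The default \code{"hh_cortical"} set is the shifted Hodgkin-Huxley rate
#' functions of the Shriki-Hansel-Sompolinsky cortical neuron, the model
#' whose conductance values (\eqn{g_{Na} = 100}, \eqn{g_K = 40} mS/cm^2) and
#' adaptation gate this network inherits; with those conductances it has a
#' stable resting state near the leak reversal.  The alternative
#' \code{"wang_buzsaki"} set is the fast-spiking interneuron kinetics of
#' Wang & Buzsaki (1996) with temperature factor \eqn{\phi = 5} on \code{h}
#' and \code{n}; note that combined with \eqn{g_{Na} = 100} it yields a
#' spontaneously spiking cell.  Removable singularities of \eqn{\alpha_m}
#' and \eqn{\alpha_n} are evaluated by their limits.
#'
#' @param V Membrane potential (mV), vectorized.
#' @param kinetics Which rate-function set to use.
#' @return data.frame with columns \code{alpha_m}, \code{beta_m},
#'   \code{alpha_h}, \code{beta_h}, \code{alpha_n}, \code{beta_n}.
#' @export
gating_rates <- function(V, kinetics = c("hh_cortical", "wang_buzsaki")) {
  stopifnot(all(is.finite(V)))
  kinetics <- match.arg(kinetics)
  lin_exp <- function(x, s) {         # x / (1 - exp(-x/s)), limit s at x = 0
    out <- x / (1 - exp(-x / s))
    out[abs(x) < 1e-7] <- s
    out
  }
  if (kinetics == "hh_cortical") {
    data.frame(
      alpha_m = 0.1 * lin_exp(V + 30, 10),
      beta_m  = 4 * exp(-(V + 55) / 18),
      alpha_h = 0.07 * exp(-(V + 44) / 20),
      beta_h  = 1 / (exp(-0.1 * (V + 14)) + 1),
      alpha_n = 0.01 * lin_exp(V + 34, 10),
      beta_n  = 0.125 * exp(-(V + 44) / 80))
  } else {
    phi <- 5
    data.frame(
      alpha_m = 0.1 * lin_exp(V + 35, 10),
      beta_m  = 4 * exp(-(V + 60) / 18),
      alpha_h = phi * 0.07 * exp(-(V + 58) / 20),
      beta_h  = phi / (exp(-0.1 * (V + 28)) + 1),
      alpha_n = phi * 0.01 * lin_exp(V + 34, 10),
      beta_n  = phi * 0.125 * exp(-(V + 44) / 80))
  }
}

#' Steady-state sodium activation
#'
#' The sodium activation is taken as instantaneous,
#' \eqn{m_\infty(V) = \alpha_m/(\alpha_m + \beta_m)}; the sodium current is
#' \eqn{g_{Na} m_\infty^3 h (V - V_{Na})}.
#'
#' @param V Membrane potential (mV), vectorized.
#' @inheritParams gating_rates
#' @return Activation in (0, 1).
#' @export
m_inf <- function(V, kinetics = c("hh_cortical", "wang_buzsaki")) {
  r <- gating_rates(V, kinetics)
  r$alpha_m / (r$alpha_m + r$beta_m)
}

#' Steady-state adaptation gate
#'
#' Logistic steady state of the adaptation gating variable,
#' \eqn{z_\infty(V) = 1/(1 + \exp(-0.7(V + 30)))}: midpoint -30 mV,
#' slope 0.7/mV.
#'
#' @param V Membrane potential (mV), vectorized.
#' @return Steady-state value in (0, 1).
#' @export
z_inf <- function(V) 1 / (1 + exp(-0.7 * (V + 30)))

#' Right-hand side of the single-neuron dynamics
#'
#' Time derivatives of membrane potential and gating variables:
#' \deqn{C_m dV/dt = -I_L - I_{Na} - I_K - I_{adapt} + I_{syn}}
#' with \eqn{I_{Na} = g_{Na} m_\infty^3 h (V - V_{Na})},
#' \eqn{I_K = g_K n^4 (V - V_K)},
#' \eqn{I_{adapt} = g_{adapt} z (V - V_K)}, and first-order kinetics for
#' \code{h}, \code{n} (rates from [gating_rates()]) and \code{z}
#' (relaxation to [z_inf()] with time constant \code{tau_adapt}).
#'
#' @param state List or numeric vector with elements \code{V}, \code{h},
#'   \code{n}, \code{z}.
#' @param I_syn Total synaptic (plus any injected) current density
#'   (uA/cm^2), positive = depolarizing.
#' @param params A [neuron_params()] object.
#' @inheritParams gating_rates
#' @return Named numeric vector \code{dV}, \code{dh}, \code{dn}, \code{dz}
#'   (mV/ms and 1/ms).
#' @export
membrane_derivative <- function(state, I_syn, params,
                                kinetics = c("hh_cortical", "wang_buzsaki")) {
  state <- as.list(state)
  V <- state$V; h <- state$h; n <- state$n; z <- state$z
  if (!all(is.finite(c(V, h, n, z, I_syn))))
    stop("non-finite neuron state: integration blow-up", call. = FALSE)
  p <- params
  r <- gating_rates(V, kinetics)
  m <- r$alpha_m / (r$alpha_m + r$beta_m)
  I_L <- p$g_L * (V - p$V_L)
  I_Na <- p$g_Na * m^3 * h * (V - p$V_Na)
  I_K <- p$g_K * n^4 * (V - p$V_K)
  I_adapt <- p$g_adapt * z * (V - p$V_K)
  c(dV = (-I_L - I_Na - I_K - I_adapt + I_syn) / p$C_m,
    dh = r$alpha_h * (1 - h) - r$beta_h * h,
    dn = r$alpha_n * (1 - n) - r$beta_n * n,
    dz = (z_inf(V) - z) / p$tau_adapt)
}

# Steady-state gating values at a voltage, used for initial conditions.
gating_steady_state <- function(V, kinetics = "hh_cortical") {
  r <- gating_rates(V, kinetics)
  list(h = r$alpha_h / (r$alpha_h + r$beta_h),
       n = r$alpha_n / (r$alpha_n + r$beta_n),
       z = z_inf(V))
}

#' Simulate one isolated neuron with injected current
#'
#' Runs the network integrator for a single neuron with all synaptic and
#' background inputs disabled and a constant injected current.  Used for
#' f-I curves and step-size convergence checks.
#'
#' @param params A [neuron_params()] object.
#' @param I_ext Injected current density (uA/cm^2).
#' @param t_total Duration (ms).
#' @param dt Time step (ms).
#' @param V0 Initial membrane potential (mV); gates start at steady state.
#' @inheritParams gating_rates
#' @return List with \code{spikes} (spike times, ms) and \code{V_end}.
#' @export
simulate_single_neuron <- function(params, I_ext, t_total = 1000, dt = 0.05,
                                   V0 = params$V_L,
                                   kinetics = c("hh_cortical", "wang_buzsaki")) {
  kinetics <- match.arg(kinetics)
  sim <- simulate_network_cpp(
    n_E = if (params$population == "E") 1L else 0L,
    n_I = if (params$population == "I") 1L else 0L,
    src_ptr = c(0L, 0L), tgt_idx = integer(0),
    jump = matrix(0, 2, 2), tau_syn = 3, rho = 0.5,
    V_rev_E = 0, V_rev_I = -75,
    par_E = unlist(params[c("C_m", "g_L", "V_L", "g_Na", "V_Na", "g_K",
                            "V_K", "g_adapt", "tau_adapt")]),
    par_I = unlist(params[c("C_m", "g_L", "V_L", "g_Na", "V_Na", "g_K",
                            "V_K", "g_adapt", "tau_adapt")]),
    gb_mean = c(0, 0), gb_amp = c(0, 0), gff_bar = c(0, 0),
    R_tot = 0, eta_sigma = 0, I_ext = I_ext,
    dt = dt, t_total = t_total, t_record = 0,
    V0 = V0, seed = 1, noise_on = FALSE,
    kinetics = match(kinetics, c("hh_cortical", "wang_buzsaki")))
  list(spikes = sim$spike_t, V_end = sim$V_end)
}
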