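#' Recurrent synapse parameters
#'
#' Unscaled coupling strengths \eqn{G_{AB}} (ms mS/cm^2; first index is the
#' postsynaptic population) together with the synaptic time constant and the
#' conductance/current mixing fraction.  In a network with mean in-degree K
#' the per-synapse strength is scaled as \eqn{\bar g_{AB} = G_{AB}/\sqrt K};
#' each presynaptic spike adds \eqn{\bar g_{AB}/\tau_{syn}} to the synaptic
#' conductance, which then decays exponentially, so the time integral of one
#' unitary conductance transient is exactly \eqn{\bar g_{AB}}.
#'
#' The driving force of each synapse is a mixture
#' \eqn{\rho (V - V_B) + (1 - \rho)(V_L - V_B)}: \code{rho = 1} is a pure
#' conductance synapse, \code{rho = 0} a current synapse with driving force
#' frozen at the leak reversal.  The default is \code{rho = 0}: the membrane
#' conductance load of the strong inhibitory synapses otherwise shunts the
#' neuronal gain and with it the disynaptic self-coupling that reciprocal
#' connections create, muting the phenomena this model exists to study (see
#' the methods vignette for the sensitivity analysis).
#'
#' @param G_EE,G_IE,G_EI,G_II Unscaled couplings (ms mS/cm^2).
#' @param tau_syn Synaptic time constant (ms).
#' @param rho Conductance/current mixing fraction in \[0, 1\].
#' @param V_rev_E,V_rev_I Excitatory and inhibitory synaptic reversal
#'   potentials (mV); the excitatory reversal is shared by the feedforward
#'   and background inputs.
#' @return Object of class \code{"synapse_params"}.
#' @export
synapse_params <- function(G_EE = 0.15, G_IE = 0.45, G_EI = 2.0, G_II = 3.0,
                           tau_syn = 3, rho = 0,
                           V_rev_E = 0, V_rev_I = -75) {
  stopifnot(tau_syn > 0, rho >= 0, rho <= 1,
            G_EE >= 0, G_IE >= 0, G_EI >= 0, G_II >= 0)
  structure(list(G_EE = G_EE, G_IE = G_IE, G_EI = G_EI, G_II = G_II,
                 tau_syn = tau_syn, rho = rho,
                 V_rev_E = V_rev_E, V_rev_I = V_rev_I),
            class = "synapse_params")
}

#' Background input parameters
#'
#' Stochastic drive standing in for input from other cortical areas: a
#' conductance \eqn{g_b = \bar g_b K (R_b + \sqrt{R_b/K}\,\eta(t))} at the
#' excitatory reversal, where \eqn{\eta} is Ornstein-Uhlenbeck noise with
#' correlation time \eqn{\tau_{syn}} and stationary autocorrelation
#' \eqn{e^{-|\Delta t|/\tau_{syn}}/(2\tau_{syn})} (unit-integral kernel).
#' Negative instantaneous conductances are clipped to zero.
#'
#' @param g_bar_E,g_bar_I Background conductance scale \eqn{\bar g_b^A}
#'   per population (mS/cm^2 per unit rate in 1/ms).
#' @param R_b_E,R_b_I Background rates (Hz).
#' @return Object of class \code{"background_params"}.
#' @export
background_params <- function(g_bar_E = 0.012, g_bar_I = 0.012,
                              R_b_E = 5, R_b_I = 5) {
  stopifnot(g_bar_E >= 0, g_bar_I >= 0, R_b_E >= 0, R_b_I >= 0)
  structure(list(g_bar_E = g_bar_E, g_bar_I = g_bar_I,
                 R_b_E = R_b_E, R_b_I = R_b_I),
            class = "background_params")
}

#' Feedforward (layer 4) input parameters
#'
#' The feedforward drive summarizes on average \eqn{K^{ff}_A} orientation-
#' selective layer-4 afferents per neuron as a filtered stochastic rate.
#' Its strength is scaled as \eqn{\bar g^{ff}_A = G^{ff}_A / (c^{ff}_A
#' \sqrt K)} with \eqn{c^{ff}_A = K^{ff}_A / K}.  The response amplitude at
#' contrast C is \eqn{R_1^{ff}(C) = R_1^{ff} \log_{10}(C + 1)}.
#'
#' @param G_ff_E,G_ff_I Unscaled feedforward strengths (ms mS/cm^2).
#' @param K_ff_E,K_ff_I Mean numbers of feedforward inputs.
#' @param R0 Baseline layer-4 rate without stimulus (Hz).
#' @param R1 Layer-4 response amplitude parameter (Hz).
#' @param tuning_strength Layer-4 tuning strength \eqn{\xi_A} (same for
#'   both populations by default).
#' @return Object of class \code{"feedforward_params"}.
#' @export
feedforward_params <- function(G_ff_E = 0.0286, G_ff_I = 0.0162,
                               K_ff_E = 100, K_ff_I = 800,
                               R0 = 2, R1 = 20, tuning_strength = 0.8) {
  stopifnot(G_ff_E >= 0, G_ff_I >= 0, K_ff_E > 0, K_ff_I > 0,
            R0 >= 0, R1 >= 0, tuning_strength >= 0)
  structure(list(G_ff_E = G_ff_E, G_ff_I = G_ff_I,
                 K_ff_E = K_ff_E, K_ff_I = K_ff_I,
                 R0 = R0, R1 = R1, tuning_strength = tuning_strength),
            class = "feedforward_params")
}

#' Quenched disorder of the feedforward input
#'
#' Per-neuron frozen random parameters of the feedforward drive: a standard
#' normal \eqn{x_i} (quenched fluctuation of the untuned component), a
#' Rayleigh-distributed tuned-modulation amplitude \eqn{z_{1,i}} (density
#' \eqn{z e^{-z^2/2}}) and a preferred orientation \eqn{\Delta_i} uniform
#' on \[0, pi).  Drawn once per network and reused across trials,
#' orientations and reciprocity sweeps.
#'
#' @param N_E,N_I Population sizes.
#' @param seed Integer seed.
#' @return Object of class \code{"disorder"}: list with vectors \code{x},
#'   \code{z1}, \code{delta} of length \code{N_E + N_I} (E first) and
#'   \code{population}.
#' @export
draw_disorder <- function(N_E, N_I, seed = 1) {
  N <- N_E + N_I
  local_seed(seed)
  structure(list(x = rnorm(N),
                 z1 = sqrt(-2 * log(runif(N))),
                 delta = runif(N, 0, pi),
                 population = rep(c("E", "I"), c(N_E, N_I))),
            class = "disorder")
}

#' Total feedforward rate per neuron
#'
#' Summed layer-4 input rate for stimulus orientation \code{theta} at
#' contrast C: an untuned component of order \eqn{c_{ff} K} plus a quenched
#' component of order \eqn{\sqrt{c_{ff} K}} modulated as
#' \eqn{\cos 2(\theta - \Delta_i)},
#' \deqn{R_{tot,i} = c_{ff}K (R_0 + R_1(C)) + \sqrt{c_{ff}K}\,(x_i +
#'   R_1(C) (x_i + \xi z_{1,i} \cos 2(\theta - \Delta_i))),}
#' clipped at zero.  At C = 0 the amplitude \eqn{R_1(C) = R_1
#' \log_{10}(C+1)} vanishes and the rate loses its orientation dependence.
#'
#' @param theta Stimulus orientation (radians, \[0, pi)).
#' @param disorder A [draw_disorder()] object.
#' @param ff A [feedforward_params()] object.
#' @param K Mean recurrent in-degree (sets \eqn{c_{ff} = K_{ff}/K}).
#' @param contrast Stimulus contrast C (>= 0).
#' @return Numeric vector of per-neuron rates (Hz, >= 0).
#' @export
feedforward_rate <- function(theta, disorder, ff, K, contrast = 100) {
  stopifnot(inherits(disorder, "disorder"), inherits(ff, "feedforward_params"),
            theta >= 0, theta < pi, contrast >= 0)
  R1C <- ff$R1 * log10(contrast + 1)
  cK <- ifelse(disorder$population == "E", ff$K_ff_E, ff$K_ff_I)  # c_ff * K
  tuned <- disorder$x + R1C * (disorder$x + ff$tuning_strength * disorder$z1 *
                                 cos(2 * (theta - disorder$delta)))
  pmax(cK * (ff$R0 + R1C) + sqrt(cK) * tuned, 0)
}

#' One exact step of the Ornstein-Uhlenbeck noise
#'
#' Advances OU noise by \code{dt} using the exact discretization
#' \eqn{\eta \leftarrow \eta e^{-dt/\tau} + \sigma\sqrt{1 - e^{-2dt/\tau}}
#' N(0,1)}, which preserves the stationary law \eqn{N(0, \sigma^2)} for any
#' step size.  The stationary autocorrelation is
#' \eqn{\sigma^2 e^{-|\Delta t|/\tau}}; the network uses
#' \eqn{\sigma = 1/\sqrt{2\tau_{syn}}} so the autocorrelation is the
#' unit-integral kernel \eqn{e^{-|\Delta t|/\tau_{syn}}/(2\tau_{syn})}.
#'
#' @param eta Current noise value(s).
#' @param dt Time step (ms), > 0.
#' @param tau Correlation time (ms).
#' @param sigma Stationary standard deviation.
#' @return Updated noise value(s), same length as \code{eta}.
#' @export
ou_step <- function(eta, dt, tau = 3, sigma = 1 / sqrt(2 * tau)) {
  stopifnot(dt > 0, tau > 0, sigma >= 0)
  d <- exp(-dt / tau)
  eta * d + sigma * sqrt(1 - d^2) * rnorm(length(eta))
}

#' Exponential synaptic conductance: decay and spike jumps
#'
#' One step of the single-exponential synapse: the conductance decays by
#' \eqn{e^{-dt/\tau_{syn}}} and each presynaptic spike adds
#' \eqn{\bar g/\tau_{syn}}, so a single spike produces a transient with
#' time integral exactly \eqn{\bar g}.
#'
#' @param g Current conductance(s) (mS/cm^2), >= 0.
#' @param dt Elapsed time (ms).
#' @param n_spikes Number of presynaptic spikes in the step (vectorized).
#' @param g_bar Scaled synaptic strength \eqn{\bar g} (ms mS/cm^2).
#' @param tau_syn Synaptic time constant (ms).
#' @return Updated conductance(s).
#' @export
synapse_decay_jump <- function(g, dt, n_spikes = 0, g_bar = 0, tau_syn = 3) {
  stopifnot(all(g >= 0), dt >= 0, tau_syn > 0)
  g * exp(-dt / tau_syn) + (g_bar / tau_syn) * n_spikes
}

#' Recurrent synaptic current
#'
#' Current density produced by the excitatory and inhibitory recurrent
#' conductances with the mixed driving force,
#' \deqn{I = -\sum_B g^{AB} (\rho (V - V_B) + (1-\rho)(V_L - V_B)).}
#'
#' @param V Membrane potential (mV).
#' @param g_E,g_I Excitatory / inhibitory synaptic conductances (mS/cm^2).
#' @param sp A [synapse_params()] object.
#' @param V_L Leak reversal used for the current-based fraction (mV).
#' @return Current density (uA/cm^2), positive = depolarizing.
#' @export
recurrent_current <- function(V, g_E, g_I, sp, V_L = -65) {
  stopifnot(inherits(sp, "synapse_params"))
  drive <- function(V_rev)
    sp$rho * (V - V_rev) + (1 - sp$rho) * (V_L - V_rev)
  -(g_E * drive(sp$V_rev_E) + g_I * drive(sp$V_rev_I))
}

#' Background conductance trace
#'
#' Simulates the background conductance
#' \eqn{g_b(t) = \bar g_b K (R_b + \sqrt{R_b/K}\,\eta(t))} over \code{n}
#' steps with OU noise \eqn{\eta}, clipping negative excursions at zero.
#' Long-run mean \eqn{\bar g_b K R_b} (rates in 1/ms).
#'
#' @param n Number of steps.
#' @param dt Time step (ms).
#' @param bp A [background_params()] object.
#' @param K Mean recurrent in-degree.
#' @param population \code{"E"} or \code{"I"}.
#' @param tau_syn Noise correlation time (ms).
#' @return Numeric vector of conductances (mS/cm^2), length \code{n}.
#' @export
background_conductance <- function(n, dt, bp, K, population = "E",
                                   tau_syn = 3) {
  stopifnot(inherits(bp, "background_params"), n >= 1, K > 0)
  g_bar <- if (population == "E") bp$g_bar_E else bp$g_bar_I
  R_b <- (if (population == "E") bp$R_b_E else bp$R_b_I) / 1000  # 1/ms
  sigma <- 1 / sqrt(2 * tau_syn)
  eta <- rnorm(1, 0, sigma)
  out <- numeric(n)
  for (i in seq_len(n)) {
    eta <- ou_step(eta, dt, tau_syn, sigma)
    out[i] <- max(g_bar * K * (R_b + sqrt(R_b / K) * eta), 0)
  }
  out
}

#' Feedforward conductance from a rate trace
#'
#' Causally filters an input rate (plus optional square-root shot noise)
#' with the unit-integral exponential kernel
#' \eqn{e^{-t/\tau_{syn}}/\tau_{syn}}:
#' \eqn{g(t) = \bar g_{ff} \int^t (R(t') + \sqrt{R(t')}\eta(t'))
#' e^{-(t-t')/\tau_{syn}} dt' / \tau_{syn}}.  For a constant rate the
#' conductance relaxes exponentially (time constant \eqn{\tau_{syn}}) to
#' \eqn{\bar g_{ff} R}.
#'
#' @param R Rate trace (Hz), one value per step.
#' @param dt Time step (ms).
#' @param g_ff_bar Scaled feedforward strength \eqn{\bar g_{ff}}.
#' @param tau_syn Filter time constant (ms).
#' @param noise Add OU-modulated square-root noise to the rate.
#' @param g0 Initial conductance; defaults to the mean-rate fixed point.
#' @return Conductance trace (mS/cm^2), same length as \code{R}.
#' @export
feedforward_conductance <- function(R, dt, g_ff_bar, tau_syn = 3,
                                    noise = FALSE, g0 = NULL) {
  stopifnot(all(R >= 0), dt > 0, tau_syn > 0)
  R_ms <- R / 1000
  d <- exp(-dt / tau_syn)
  sigma <- 1 / sqrt(2 * tau_syn)
  g <- if (is.null(g0)) g_ff_bar * R_ms[1] else g0
  eta <- if (noise) rnorm(1, 0, sigma) else 0
  out <- numeric(length(R))
  for (i in seq_along(R)) {
    if (noise) eta <- ou_step(eta, dt, tau_syn, sigma)
    drive <- max(R_ms[i] + sqrt(R_ms[i]) * eta, 0)
    g <- g * d + (1 - d) * g_ff_bar * drive
    out[i] <- g
  }
  out
}
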