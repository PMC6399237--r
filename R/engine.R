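#' Simulation run configuration
#'
#' Bundles everything one simulation campaign needs: topology, neuron and
#' input parameters, integration settings, stimulus protocol and the root
#' seed.  The root seed deterministically derives separate child streams
#' for the quenched disorder, the connectivity blocks and the per-trial
#' noise/initial conditions, so that reciprocity sweeps compare matched
#' realizations (only the swept block changes).
#'
#' The default problem size (2 x 2000 neurons, K = 100) is a desk-scale
#' profile of the full model that preserves the \eqn{G/\sqrt K} coupling
#' structure and the feedforward ratios \eqn{c_{ff} = K_{ff}/K}; the
#' disynaptic self-coupling integral \eqn{pK\xi (G/\sqrt K)^2 = p\xi G^2}
#' is independent of K, so the reciprocity effects survive the reduction.
#'
#' @param topology A [topology_config()].  Default: 2 x 2000 neurons,
#'   K = 100, chance-level reciprocity.
#' @param neuron_E,neuron_I [neuron_params()] per population.
#' @param synapse A [synapse_params()].
#' @param background A [background_params()].
#' @param feedforward A [feedforward_params()].  The default feedforward
#'   in-degrees are scaled to keep \code{K_ff/K} at the full-model values
#'   (100/500 and 800/500).
#' @param dt Integration step (ms).
#' @param t_transient Discarded settling time per trial (ms).
#' @param t_measure Recorded time per trial (ms).
#' @param orientations Stimulus orientations (radians, in \[0, pi)).
#' @param contrast Stimulus contrast C.
#' @param n_trials Default number of repeat trials for Fano-factor runs.
#' @param seed Root seed (integer).
#' @param kinetics Gating kinetics set, see [gating_rates()].
#' @return Object of class \code{"run_config"}.
#' @export
run_config <- function(topology = NULL,
                       neuron_E = neuron_params("E"),
                       neuron_I = neuron_params("I"),
                       synapse = synapse_params(),
                       background = background_params(),
                       feedforward = NULL,
                       dt = 0.05, t_transient = 1000, t_measure = 10000,
                       orientations = seq(0, pi, length.out = 13)[1:12],
                       contrast = 100, n_trials = 20, seed = 1,
                       kinetics = c("hh_cortical", "wang_buzsaki")) {
  kinetics <- match.arg(kinetics)
  if (is.null(topology))
    topology <- topology_config(2000, 2000, 100, seed = seed)
  if (is.null(feedforward)) {
    scale <- topology$K / 500   # keep c_ff = K_ff / K at full-model values
    feedforward <- feedforward_params(K_ff_E = 100 * scale,
                                      K_ff_I = 800 * scale)
  }
  stopifnot(inherits(topology, "topology_config"),
            inherits(neuron_E, "neuron_params"),
            inherits(neuron_I, "neuron_params"),
            inherits(synapse, "synapse_params"),
            inherits(background, "background_params"),
            inherits(feedforward, "feedforward_params"),
            dt > 0, t_transient >= 0, t_measure > 0, contrast >= 0,
            n_trials >= 1, all(orientations >= 0 & orientations < pi))
  structure(list(topology = topology, neuron_E = neuron_E,
                 neuron_I = neuron_I, synapse = synapse,
                 background = background, feedforward = feedforward,
                 dt = dt, t_transient = t_transient, t_measure = t_measure,
                 orientations = orientations, contrast = contrast,
                 n_trials = as.integer(n_trials), seed = as.integer(seed),
                 kinetics = kinetics),
            class = "run_config")
}

#' Spike data container
#'
#' Per-neuron ordered spike times for one trial, with population labels and
#' trial metadata.
#'
#' @param times List of numeric vectors: strictly increasing spike times
#'   (ms) in \[0, duration\], one vector per neuron.
#' @param population Character vector of population labels ("E"/"I"), one
#'   per neuron (recycled if scalar).
#' @param duration Trial duration (ms).
#' @param theta Stimulus orientation (radians) or NA.
#' @param seed Trial seed or NA.
#' @return Object of class \code{"spike_data"}.
#' @export
spike_data <- function(times, population, duration, theta = NA_real_,
                       seed = NA_integer_) {
  stopifnot(is.list(times), duration > 0)
  population <- rep_len(population, length(times))
  for (t in times)
    if (length(t) && (is.unsorted(t, strictly = TRUE) || t[1] < 0 ||
                      t[length(t)] > duration))
      stop("spike times must be strictly increasing within [0, duration]",
           call. = FALSE)
  structure(list(times = times, population = population,
                 duration = duration, theta = theta, seed = seed),
            class = "spike_data")
}

#' @method print spike_data
#' @export
print.spike_data <- function(x, ...) {
  ns <- vapply(x$times, length, 1L)
  cat(sprintf("Spike data: %d neurons, %.0f ms, %d spikes\n",
              length(x$times), x$duration, sum(ns)))
  for (p in unique(x$population)) {
    sel <- x$population == p
    cat(sprintf("  %s: %d neurons, mean rate %.2f Hz\n", p, sum(sel),
                mean(ns[sel]) / x$duration * 1000))
  }
  invisible(x)
}

#' Firing rates of a spike_data object
#'
#' @param spikes A [spike_data()] object.
#' @return Numeric vector of per-neuron mean rates (Hz).
#' @export
firing_rates <- function(spikes) {
  stopifnot(inherits(spikes, "spike_data"))
  vapply(spikes$times, length, 1L) / spikes$duration * 1000
}

#' Flatten connectivity to the simulator's adjacency layout
#'
#' Converts the four sparse blocks into a single source-indexed adjacency
#' (CSR over presynaptic neurons, global 0-based neuron ids, excitatory
#' population first).  Done once per connectivity and reused across trials.
#'
#' @param C A \code{"connectivity"} object.
#' @return Object of class \code{"prepared_network"}.
#' @export
prepare_network <- function(C) {
  stopifnot(inherits(C, "connectivity"))
  N_E <- nrow(C$EE); N_I <- nrow(C$II); N <- N_E + N_I
  col_of <- function(M) rep.int(seq_len(ncol(M)), diff(M@p))
  src <- c(col_of(C$EE), col_of(C$IE),              # E sources
           col_of(C$EI) + N_E, col_of(C$II) + N_E)  # I sources
  tgt <- c(C$EE@i + 1L, C$IE@i + 1L + N_E, C$EI@i + 1L, C$II@i + 1L + N_E)
  ord <- order(src)
  structure(list(n_E = N_E, n_I = N_I,
                 src_ptr = c(0L, cumsum(tabulate(src, N))),
                 tgt_idx = tgt[ord] - 1L),
            class = "prepared_network")
}

# Scaled per-spike conductance jumps, jump[post, pre] = (G/sqrt(K))/tau_syn
jump_matrix <- function(sp, K) {
  matrix(c(sp$G_EE, sp$G_IE, sp$G_EI, sp$G_II), 2, 2) / sqrt(K) / sp$tau_syn
}

neuron_par_vec <- function(np)
  unlist(np[c("C_m", "g_L", "V_L", "g_Na", "V_Na", "g_K", "V_K",
              "g_adapt", "tau_adapt")], use.names = FALSE)

#' Run one network trial
#'
#' Integrates the full network for \code{t_transient + t_measure} ms at one
#' stimulus orientation and returns the spikes emitted during the
#' measurement window.  Deterministic given (config, connectivity,
#' disorder, trial_seed).  Initial membrane potentials are drawn uniformly
#' in \[V_L, V_L + 10\] mV from the trial seed; gates start at their steady
#' state for that voltage.
#'
#' @param config A [run_config()].
#' @param connectivity A \code{"connectivity"} object (generated from
#'   \code{config$topology} when NULL).
#' @param disorder A [draw_disorder()] object (derived from the root seed
#'   when NULL).
#' @param theta Stimulus orientation (radians).
#' @param trial_seed Integer seed for this trial's noise and initial
#'   conditions; derived from the root seed when NULL.
#' @param prepared Optional [prepare_network()] result to reuse.
#' @param noise_on Enable the stochastic background/feedforward noise.
#' @param t_measure,t_transient Override the config durations (ms).
#' @return A [spike_data()] object (times relative to measurement onset).
#' @export
run_trial <- function(config, connectivity = NULL, disorder = NULL,
                      theta = 0, trial_seed = NULL, prepared = NULL,
                      noise_on = TRUE, t_measure = NULL, t_transient = NULL) {
  stopifnot(inherits(config, "run_config"))
  top <- config$topology
  if (is.null(connectivity) && is.null(prepared))
    connectivity <- generate_connectivity(top)
  if (is.null(prepared)) prepared <- prepare_network(connectivity)
  stopifnot(prepared$n_E == top$N_E, prepared$n_I == top$N_I)
  if (is.null(disorder))
    disorder <- draw_disorder(top$N_E, top$N_I,
                              derive_seeds(config$seed, 1L, "disorder"))
  if (is.null(trial_seed))
    trial_seed <- derive_seeds(config$seed, 1L, "trial")
  if (is.null(t_measure)) t_measure <- config$t_measure
  if (is.null(t_transient)) t_transient <- config$t_transient

  N <- top$N_E + top$N_I
  K <- top$K
  sp <- config$synapse
  bp <- config$background
  ff <- config$feedforward

  R_tot <- feedforward_rate(theta, disorder, ff, K, config$contrast) / 1000
  gff_bar <- c(ff$G_ff_E / (ff$K_ff_E / K) / sqrt(K),
               ff$G_ff_I / (ff$K_ff_I / K) / sqrt(K))
  gb_mean <- c(bp$g_bar_E * K * bp$R_b_E, bp$g_bar_I * K * bp$R_b_I) / 1000
  gb_amp <- c(bp$g_bar_E * K * sqrt(bp$R_b_E / 1000 / K),
              bp$g_bar_I * K * sqrt(bp$R_b_I / 1000 / K))

  local_seed(trial_seed)
  V_L <- c(rep(config$neuron_E$V_L, top$N_E), rep(config$neuron_I$V_L, top$N_I))
  V0 <- V_L + runif(N, 0, 10)

  sim <- simulate_network_cpp(
    n_E = top$N_E, n_I = top$N_I,
    src_ptr = prepared$src_ptr, tgt_idx = prepared$tgt_idx,
    jump = jump_matrix(sp, K), tau_syn = sp$tau_syn, rho = sp$rho,
    V_rev_E = sp$V_rev_E, V_rev_I = sp$V_rev_I,
    par_E = neuron_par_vec(config$neuron_E),
    par_I = neuron_par_vec(config$neuron_I),
    gb_mean = gb_mean, gb_amp = gb_amp, gff_bar = gff_bar,
    R_tot = R_tot, eta_sigma = 1 / sqrt(2 * sp$tau_syn),
    I_ext = 0, dt = config$dt,
    t_total = t_transient + t_measure, t_record = t_transient,
    V0 = V0, seed = trial_seed, noise_on = noise_on,
    kinetics = match(config$kinetics, c("hh_cortical", "wang_buzsaki")))

  times <- split(sim$spike_t, factor(sim$spike_id, levels = 0:(N - 1)))
  spike_data(times = unname(times),
             population = rep(c("E", "I"), c(top$N_E, top$N_I)),
             duration = t_measure, theta = theta, seed = trial_seed)
}

#' Orientation tuning experiment
#'
#' Runs one trial per stimulus orientation with the same connectivity and
#' quenched disorder and returns the per-neuron tuning curves (mean rate
#' over the measurement window at each orientation).
#'
#' @inheritParams run_trial
#' @param orientations Stimulus orientations; default from the config.
#' @return Object of class \code{"tuning_curves"}: list with
#'   \code{orientations}, \code{rates} (N x n_orientations matrix, Hz) and
#'   \code{population}.
#' @export
run_tuning_experiment <- function(config, connectivity = NULL,
                                  disorder = NULL, orientations = NULL,
                                  t_measure = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(orientations)) orientations <- config$orientations
  stopifnot(length(orientations) >= 4)
  top <- config$topology
  if (is.null(connectivity)) connectivity <- generate_connectivity(top)
  prepared <- prepare_network(connectivity)
  if (is.null(disorder))
    disorder <- draw_disorder(top$N_E, top$N_I,
                              derive_seeds(config$seed, 1L, "disorder"))
  seeds <- derive_seeds(config$seed, length(orientations), "tuning")
  rates <- vapply(seq_along(orientations), function(k) {
    sd_k <- run_trial(config, disorder = disorder, theta = orientations[k],
                      trial_seed = seeds[k], prepared = prepared,
                      t_measure = t_measure)
    firing_rates(sd_k)
  }, numeric(top$N_E + top$N_I))
  structure(list(orientations = orientations, rates = rates,
                 population = rep(c("E", "I"), c(top$N_E, top$N_I))),
            class = "tuning_curves")
}

#' Trial-repeat experiment for Fano factors
#'
#' Repeats the same stimulus \code{n_trials} times with fixed connectivity
#' and quenched disorder while varying the initial conditions and the
#' background/feedforward noise realization per trial, and counts spikes
#' per neuron in the full measurement window of each trial.
#'
#' @inheritParams run_trial
#' @param n_trials Number of repeats (>= 2); default from the config.
#' @param frozen_noise Reuse the identical trial seed for every repeat
#'   (deterministic repeats; Fano factor 0 for every neuron).
#' @return Integer matrix, neurons x trials, of spike counts.  The
#'   counting window equals \code{t_measure} (one window per trial).
#' @export
run_fano_experiment <- function(config, connectivity = NULL, disorder = NULL,
                                theta = 0, n_trials = NULL,
                                frozen_noise = FALSE, t_measure = NULL,
                                t_transient = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(n_trials)) n_trials <- config$n_trials
  stopifnot(n_trials >= 2)
  top <- config$topology
  if (is.null(connectivity)) connectivity <- generate_connectivity(top)
  prepared <- prepare_network(connectivity)
  if (is.null(disorder))
    disorder <- draw_disorder(top$N_E, top$N_I,
                              derive_seeds(config$seed, 1L, "disorder"))
  seeds <- derive_seeds(config$seed, n_trials, "fano")
  if (frozen_noise) seeds <- rep(seeds[1L], n_trials)
  vapply(seq_len(n_trials), function(k) {
    sd_k <- run_trial(config, disorder = disorder, theta = theta,
                      trial_seed = seeds[k], prepared = prepared,
                      t_measure = t_measure, t_transient = t_transient)
    vapply(sd_k$times, length, 1L)
  }, integer(top$N_E + top$N_I))
}

#' Reciprocity sweep
#'
#' Regenerates the connectivity for each reciprocity value \code{p} of one
#' connection class -- with matched block seeds, so the non-swept blocks
#' and all input sample paths are bit-identical across p -- and collects
#' spike statistics (and optionally Fano factors) at each p.
#'
#' @inheritParams run_trial
#' @param p_values Reciprocity values in \[0, 1\].
#' @param class Which connection class to sweep: \code{"II"}, \code{"EE"}
#'   or \code{"EI"}.
#' @param n_fano_trials Repeat-trial count for Fano factors (0 = skip).
#' @param max_lag AC lag range (ms).
#' @param fano_t_measure,fano_t_transient Durations for the repeat trials
#'   (ms); defaults 2000 / 500.
#' @return Object of class \code{"reciprocity_sweep"}: list with
#'   \code{p_values}, \code{class}, \code{summaries} (one [stats_summary()]
#'   per p) and \code{summary}, a data.frame of population means vs p.
#' @export
run_reciprocity_sweep <- function(config, p_values, class = c("II", "EE", "EI"),
                                  theta = 0, n_fano_trials = 0,
                                  max_lag = 200, fano_t_measure = 2000,
                                  fano_t_transient = 500) {
  stopifnot(inherits(config, "run_config"),
            all(p_values >= 0 & p_values <= 1))
  class <- match.arg(class)
  top <- config$topology
  disorder <- draw_disorder(top$N_E, top$N_I,
                            derive_seeds(config$seed, 1L, "disorder"))
  trial_seed <- derive_seeds(config$seed, 1L, "trial")
  summaries <- vector("list", length(p_values))
  for (k in seq_along(p_values)) {
    top_k <- top
    top_k[[paste0("p_", class)]] <- p_values[k]
    C_k <- generate_connectivity(top_k)
    cfg_k <- config
    cfg_k$topology <- top_k
    sd_k <- run_trial(cfg_k, connectivity = C_k, disorder = disorder,
                      theta = theta, trial_seed = trial_seed)
    counts <- NULL
    if (n_fano_trials >= 2)
      counts <- run_fano_experiment(cfg_k, connectivity = C_k,
                                    disorder = disorder, theta = theta,
                                    n_trials = n_fano_trials,
                                    t_measure = fano_t_measure,
                                    t_transient = fano_t_transient)
    summaries[[k]] <- stats_summary(sd_k, counts = counts, max_lag = max_lag)
  }
  tab <- do.call(rbind, lapply(seq_along(p_values), function(k)
    cbind(p = p_values[k], summaries[[k]]$population)))
  structure(list(p_values = p_values, class = class,
                 summaries = summaries, summary = tab),
            class = "reciprocity_sweep")
}

#' @method print reciprocity_sweep
#' @export
print.reciprocity_sweep <- function(x, ...) {
  cat(sprintf("Reciprocity sweep over p_%s\n", x$class))
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}
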