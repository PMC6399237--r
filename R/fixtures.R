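#' Synthetic spike trains with planted statistical structure
#'
#' Point-process generators whose statistics are known in closed form or by
#' construction, used as independent oracles for the spike-train statistics
#' suite (they never touch the network simulator):
#' \describe{
#'   \item{poisson}{Homogeneous Poisson: CV = 1, FF = 1, flat AC, zero
#'     serial correlations.}
#'   \item{gamma-renewal}{Renewal train with gamma ISIs of shape \code{k}:
#'     CV = \eqn{1/\sqrt k}, FF tends to \eqn{CV^2} over long windows.}
#'   \item{markov-ISI}{Non-renewal train whose ISIs follow a
#'     Gaussian-copula AR(1): first-order serial correlation approximately
#'     \code{rho1}, geometric decay of higher orders
#'     (see [generate_correlated_isis()]).}
#'   \item{periodic}{Deterministic clock with period \code{period}: CV,
#'     CV2 and FF over commensurate windows are all 0.}
#'   \item{rate-modulated}{Locally regular train whose instantaneous rate
#'     is slowly modulated, \eqn{r(t) = r_0(1 + m\sin(2\pi t/P))}; spikes
#'     fire at unit crossings of the integrated rate.  Its CV is inflated
#'     by the modulation while CV2 stays near 0.}
#' }
#'
#' @param family One of \code{"poisson"}, \code{"gamma-renewal"},
#'   \code{"markov-ISI"}, \code{"periodic"}, \code{"rate-modulated"}.
#' @param rate Mean firing rate (Hz).
#' @param duration Train duration (ms).
#' @param seed Integer seed; generation is reproducible.
#' @param shape Gamma shape \code{k} (gamma-renewal).
#' @param rho1 Latent AR(1) coefficient (markov-ISI), |rho1| < 1.
#' @param period Clock period (ms, periodic).
#' @param mod_depth,mod_period Modulation depth in \[0, 1) and period (ms)
#'   of the rate-modulated family.
#' @return A single-neuron [spike_data()] object.
#' @export
generate_train <- function(family = c("poisson", "gamma-renewal",
                                      "markov-ISI", "periodic",
                                      "rate-modulated"),
                           rate = 10, duration = 10000, seed = 1,
                           shape = 4, rho1 = 0.5, period = 100,
                           mod_depth = 0.5, mod_period = 1000) {
  family <- match.arg(family)
  stopifnot(duration > 0, rate >= 0)
  r_ms <- rate / 1000
  times <- switch(family,
    "poisson" = {
      local_seed(seed)
      n_max <- max(20, ceiling(r_ms * duration + 6 * sqrt(r_ms * duration)))
      t <- cumsum(rexp(n_max, r_ms))
      while (length(t) && max(t) < duration)
        t <- c(t, max(t) + cumsum(rexp(n_max, r_ms)))
      t[t < duration]
    },
    "gamma-renewal" = {
      stopifnot(shape > 0)
      local_seed(seed)
      n_max <- max(20, ceiling(r_ms * duration + 6 * sqrt(r_ms * duration)))
      t <- cumsum(rgamma(n_max, shape = shape, rate = shape * r_ms))
      while (length(t) && max(t) < duration)
        t <- c(t, max(t) +
                 cumsum(rgamma(n_max, shape = shape, rate = shape * r_ms)))
      t[t < duration]
    },
    "markov-ISI" = {
      n <- ceiling(r_ms * duration * 1.5) + 20
      isis <- generate_correlated_isis(n, rate = rate, rho1 = rho1,
                                       seed = seed)
      t <- cumsum(isis)
      t[t < duration]
    },
    "periodic" = {
      stopifnot(period > 0)
      t <- seq(period, duration, by = period)
      t[t < duration]
    },
    "rate-modulated" = {
      stopifnot(mod_depth >= 0, mod_depth < 1, mod_period > 0)
      # unit crossings of the integrated rate: locally regular, slowly
      # modulated; phase computed on a fine grid
      dt <- min(0.1, mod_period / 1000)
      tt <- seq(0, duration, by = dt)
      phase <- cumsum(r_ms * (1 + mod_depth * sin(2 * pi * tt / mod_period))) * dt
      tt[diff(floor(c(0, phase))) >= 1]
    })
  spike_data(times = list(times), population = "E", duration = duration,
             seed = seed)
}

#' Serially correlated inter-spike intervals (Gaussian-copula AR(1))
#'
#' Generates ISIs with a prescribed marginal and tunable first-order serial
#' correlation: a latent standard-normal AR(1) sequence with coefficient
#' \code{rho1} is mapped through its CDF onto the quantile function of the
#' marginal.  Rank correlations are invariant under the monotone map, so
#' the ISI serial rank correlation of order i is that of the latent AR(1),
#' \eqn{(6/\pi)\arcsin(\rho_1^i/2) \approx \rho_1^i}: geometric decay with
#' monotone control by \code{rho1}, marginal exactly preserved.
#'
#' @param n Number of intervals.
#' @param rate Mean rate (Hz); the marginal ISI mean is \code{1000/rate} ms.
#' @param rho1 Latent AR(1) coefficient, |rho1| < 1.
#' @param marginal \code{"exponential"} or \code{"gamma"}.
#' @param shape Gamma shape (marginal = "gamma").
#' @param seed Integer seed.
#' @return Numeric vector of \code{n} positive ISIs (ms).
#' @export
generate_correlated_isis <- function(n, rate = 10, rho1 = 0,
                                     marginal = c("exponential", "gamma"),
                                     shape = 4, seed = 1) {
  marginal <- match.arg(marginal)
  stopifnot(n >= 2, abs(rho1) < 1, rate > 0)
  local_seed(seed)
  z <- numeric(n)
  z[1] <- rnorm(1)
  innov_sd <- sqrt(1 - rho1^2)
  eps <- rnorm(n - 1, sd = innov_sd)
  for (i in 2:n) z[i] <- rho1 * z[i - 1] + eps[i - 1]
  u <- stats::pnorm(z)
  u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
  r_ms <- rate / 1000
  switch(marginal,
         exponential = stats::qexp(u, rate = r_ms),
         gamma = stats::qgamma(u, shape = shape, rate = shape * r_ms))
}

#' Small network fixture for end-to-end tests
#'
#' A 2 x 200 neuron, K = 20 network with the standard coupling structure,
#' sized so that a full trial (transient plus measurement) runs in seconds.
#' Couplings keep the \eqn{G/\sqrt K} scaling of the full model.
#'
#' @param seed Root seed.
#' @return List with \code{topology} (a [topology_config()]) and
#'   \code{config} (a [run_config()]).
#' @export
tiny_network_fixture <- function(seed = 42) {
  top <- topology_config(N_E = 200, N_I = 200, K = 20, seed = seed)
  cfg <- run_config(topology = top, t_transient = 300, t_measure = 1000,
                    n_trials = 3, seed = seed)
  list(topology = top, config = cfg)
}
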