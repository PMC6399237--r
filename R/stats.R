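#' Orientation selectivity index
#'
#' Circular-variance-style selectivity of a tuning curve:
#' \deqn{OSI = |\sum_k r(\theta_k) e^{2i\theta_k}| / \sum_k r(\theta_k).}
#' 0 for a flat curve, 1 for a response confined to a single orientation.
#' Invariant under uniform rescaling of the rates and global rotation of the
#' stimulus orientations.
#'
#' @param rates Nonnegative firing rates, one per orientation, or a matrix
#'   with one row per neuron and one column per orientation.
#' @param orientations Stimulus orientations in radians, in \[0, pi).
#' @return OSI in \[0, 1\] (vector for matrix input).  An all-zero tuning
#'   curve has no defined preferred orientation: \code{NA} is returned with
#'   a warning, not 0.
#' @export
osi <- function(rates, orientations) {
  if (is.matrix(rates)) {
    stopifnot(ncol(rates) == length(orientations))
    return(apply(rates, 1L, osi, orientations = orientations))
  }
  stopifnot(length(rates) == length(orientations), length(rates) >= 3,
            all(rates >= 0))
  tot <- sum(rates)
  if (tot <= 0) {
    warning("all-zero tuning curve: OSI undefined")
    return(NA_real_)
  }
  Mod(sum(rates * exp(2i * orientations))) / tot
}

#' Fano factor of trial spike counts
#'
#' Ratio of the across-trial variance to the across-trial mean of the spike
#' count, with the variance taken as a plain average of squared deviations
#' (divide by the number of trials, not n-1; see Details).
#'
#' The plain-average convention mirrors the defining expression
#' \eqn{FF = \langle (N_k - \bar N)^2 \rangle_k / \bar N}; set
#' \code{unbiased = TRUE} for the n-1 sample-variance convention.
#'
#' @param counts Integer vector of per-trial spike counts for one neuron, or
#'   a matrix with one row per neuron and one column per trial.
#' @param unbiased Use the n-1 variance convention (default FALSE).
#' @return Fano factor (vector for matrix input).  A zero mean count leaves
#'   the ratio undefined: \code{NA} with a warning.
#' @export
fano_factor <- function(counts, unbiased = FALSE) {
  if (is.matrix(counts)) {
    stopifnot(ncol(counts) >= 2)
    return(apply(counts, 1L, fano_factor, unbiased = unbiased))
  }
  stopifnot(length(counts) >= 2)
  m <- mean(counts)
  if (m <= 0) {
    warning("zero mean spike count: Fano factor undefined")
    return(NA_real_)
  }
  v <- mean((counts - m)^2)
  if (unbiased) v <- v * length(counts) / (length(counts) - 1)
  v / m
}

#' Coefficient of variation of inter-spike intervals
#'
#' Standard deviation over mean of the ISIs, with the plain-average variance
#' convention (divide by n).
#'
#' @param isis Positive inter-spike intervals (ms).
#' @return CV (dimensionless).
#' @export
cv_isi <- function(isis) {
  stopifnot(length(isis) >= 2, all(isis > 0))
  m <- mean(isis)
  sqrt(mean((isis - m)^2)) / m
}

#' Local coefficient of variation (CV2)
#'
#' Average over adjacent ISI pairs of
#' \eqn{2|\Delta t_{i+1} - \Delta t_i| / (\Delta t_{i+1} + \Delta t_i)}.
#' Bounded in \[0, 2\]; unlike the CV it is insensitive to slow firing-rate
#' modulation because each term only compares neighbouring intervals.
#'
#' @param isis Positive inter-spike intervals (ms).
#' @return CV2 in \[0, 2\].
#' @export
cv2_isi <- function(isis) {
  stopifnot(length(isis) >= 2, all(isis > 0))
  a <- isis[-length(isis)]
  b <- isis[-1L]
  mean(2 * abs(b - a) / (b + a))
}

#' Serial rank correlations of inter-spike intervals
#'
#' Spearman-type serial correlation of order i: every ISI is replaced by its
#' rank among all ISIs of the train (average ranks on ties), and SRC_i is
#' the Pearson correlation between the ranks of interval pairs separated by
#' i - 1 intervals, \eqn{(ISI_k, ISI_{k-i})}.
#'
#' @param isis Positive inter-spike intervals (ms).
#' @param max_order Largest order m; requires \code{length(isis) > m + 1}.
#' @return Numeric vector \code{SRC_1 .. SRC_m}, each in \[-1, 1\].
#' @export
serial_rank_correlations <- function(isis, max_order = 20) {
  n <- length(isis)
  stopifnot(max_order >= 1, n > max_order + 1)
  r <- rank(isis, ties.method = "average")
  vapply(seq_len(max_order), function(i) {
    a <- r[seq_len(n - i)]
    b <- r[seq_len(n - i) + i]
    if (sd(a) == 0 || sd(b) == 0) return(0)
    cor(a, b)
  }, numeric(1))
}

#' Predicted Fano factor from CV and serial rank correlations
#'
#' For a stationary renewal process the count Fano factor over long windows
#' equals \eqn{CV^2}; serial ISI correlations modify it to
#' \eqn{FF = CV^2 (1 + 2\sum_i SRC_i)}.  Positive serial correlations
#' increase FF, negative ones reduce it.  Used to cross-check the direct
#' trial-count estimator on long single trains.
#'
#' @param cv ISI coefficient of variation.
#' @param src Vector of serial rank correlations \code{SRC_1..m}; use
#'   \code{numeric(0)} (or all zeros) for a renewal process.
#' @return Predicted Fano factor.
#' @export
ff_from_cv_src <- function(cv, src = numeric(0)) {
  stopifnot(cv >= 0)
  cv^2 * (1 + 2 * sum(src))
}

#' Spike-train autocorrelation function
#'
#' Bins each spike train at \code{bin} ms, estimates for every neuron the
#' lagged bin-count product \eqn{\langle N(t) N(t+\tau)\rangle_t / \Delta
#' t^2} (units Hz^2), removes the zero-lag peak, and averages over the
#' population.  With this normalization the AC of each neuron converges at
#' long lags to its squared mean rate; the population asymptote is the
#' population mean of \eqn{r_i^2}.
#'
#' @param spikes A [spike_data()] object, or a list of spike-time vectors
#'   (ms in \[0, duration\]).
#' @param duration Train duration (ms); taken from \code{spikes} when it is
#'   a \code{spike_data} object.
#' @param bin Bin width (ms), default 1.
#' @param max_lag Largest lag (ms).
#' @param population Optional subset: compute over neurons of this
#'   population only (\code{"E"} or \code{"I"}).
#' @return Object of class \code{"ac_function"}: list with \code{lag} (ms),
#'   \code{ac} (Hz^2), \code{asymptote} (population mean squared rate,
#'   Hz^2), \code{rate_mean} (Hz), \code{n_neurons},
#'   \code{normalization = "rate_squared"}.
#' @export
spike_autocorrelation <- function(spikes, duration = NULL, bin = 1,
                                  max_lag = 200, population = NULL) {
  if (inherits(spikes, "spike_data")) {
    if (is.null(duration)) duration <- spikes$duration
    trains <- spikes$times
    if (!is.null(population)) trains <- trains[spikes$population == population]
  } else trains <- spikes
  stopifnot(!is.null(duration), duration > max_lag, bin > 0)
  n_bins <- floor(duration / bin)
  n_lag <- floor(max_lag / bin)
  dt_s <- bin / 1000
  S <- numeric(n_lag)
  rates <- numeric(length(trains))
  for (ni in seq_along(trains)) {
    t <- trains[[ni]]
    rates[ni] <- 1000 * length(t) / duration
    if (length(t) < 2) next
    b <- floor(t / bin)
    hi <- findInterval(t + max_lag + bin, t)  # over-collect, filter on bin diff
    cnt <- hi - seq_along(t)
    if (sum(cnt) == 0) next
    from <- rep.int(seq_along(t), cnt)
    d <- b[from + sequence(cnt)] - b[from]
    d <- d[d >= 1 & d <= n_lag]
    if (length(d)) S <- S + tabulate(d, n_lag)
  }
  # per-lag normalization: number of bin pairs at that lag, per neuron
  ac <- S / (length(trains) * (n_bins - seq_len(n_lag))) / dt_s^2
  structure(list(lag = seq_len(n_lag) * bin, ac = ac,
                 asymptote = mean(rates^2), rate_mean = mean(rates),
                 n_neurons = length(trains),
                 normalization = "rate_squared"),
            class = "ac_function")
}

#' Convert an AC function to the mean-activity normalization
#'
#' Rescales an [spike_autocorrelation()] estimate so that its long-lag
#' asymptote is the population mean rate instead of the mean squared rate
#' (division by the mean rate), the convention used for display.
#'
#' @param ac An \code{"ac_function"} object with
#'   \code{normalization = "rate_squared"}.
#' @return An \code{"ac_function"} with \code{normalization = "rate"}.
#' @export
ac_normalize_rate <- function(ac) {
  stopifnot(inherits(ac, "ac_function"), ac$normalization == "rate_squared")
  ac$ac <- ac$ac / ac$rate_mean
  ac$asymptote <- ac$asymptote / ac$rate_mean
  ac$normalization <- "rate"
  ac
}

#' Decorrelation time of an autocorrelation function
#'
#' Characteristic decay time of the AC toward its asymptote.  The excess
#' \eqn{AC(\tau) -} asymptote (optionally smoothed by a centered moving
#' average, which suppresses collective-oscillation ripples) is examined
#' from the lag of largest magnitude; the fit window is the contiguous run
#' of lags over which the excess keeps that sign and stays above
#' \code{frac} times its peak magnitude.  The default \code{"semilog"}
#' method regresses \eqn{\log |excess|} on lag and returns
#' \eqn{-1/\mathrm{slope}}, the decay time constant of an exponential
#' relaxation (the sign of the departure does not matter: a refractory
#' trough recovering from below and a positive tail decaying from above are
#' both relaxations toward the asymptote).  The \code{"loglog"} variant
#' regresses \eqn{\log |excess|} on \eqn{\log} lag and returns minus that
#' slope (a power-law exponent, not a time), kept for comparison with
#' slope-based readouts.
#'
#' @param ac An \code{"ac_function"} object.
#' @param asymptote Long-lag asymptote; defaults to \code{ac$asymptote}.
#' @param method \code{"semilog"} (default) or \code{"loglog"}.
#' @param frac Fit window extends while the excess magnitude exceeds
#'   \code{frac} times its peak (default 0.05).
#' @param min_points Minimum number of lags in the window.
#' @param smooth Odd width (in lags) of a centered moving average applied
#'   before fitting; 1 (default) fits the raw excess.
#' @return List with \code{tau_dec} (ms; for \code{"loglog"} the
#'   dimensionless slope magnitude), \code{window} (lags used),
#'   \code{method}, \code{sign} (sign of the fitted departure).  A flat or
#'   non-decaying excess leaves the decay undefined: \code{tau_dec = NA}
#'   with a warning.
#' @export
decorrelation_time <- function(ac, asymptote = NULL,
                               method = c("semilog", "loglog"),
                               frac = 0.05, min_points = 5, smooth = 1) {
  stopifnot(inherits(ac, "ac_function"), smooth >= 1, smooth %% 2 == 1)
  method <- match.arg(method)
  if (is.null(asymptote)) asymptote <- ac$asymptote
  ex <- ac$ac - asymptote
  lag <- ac$lag
  if (smooth > 1) {
    ex <- as.numeric(stats::filter(ex, rep(1 / smooth, smooth), sides = 2))
    keep <- !is.na(ex)
    ex <- ex[keep]
    lag <- lag[keep]
  }
  i0 <- which.max(abs(ex))
  s <- sign(ex[i0])
  if (s == 0 || abs(ex[i0]) < .Machine$double.eps * max(abs(asymptote), 1)) {
    warning("AC shows no departure from its asymptote: ",
            "decorrelation time undefined")
    return(list(tau_dec = NA_real_, window = integer(0), method = method,
                sign = 0))
  }
  ok <- sign(ex) == s & abs(ex) > frac * abs(ex[i0])
  n_end <- i0 + which(!ok[seq(i0, length(ex))])[1] - 2L
  if (is.na(n_end)) n_end <- length(ex)
  w <- seq(i0, n_end)
  if (length(w) < min_points) {
    warning("fewer than ", min_points, " usable lags: ",
            "decorrelation time undefined")
    return(list(tau_dec = NA_real_, window = integer(0), method = method,
                sign = s))
  }
  x <- if (method == "semilog") lag[w] else log(lag[w])
  slope <- coef(lm(log(abs(ex[w])) ~ x))[[2]]
  if (slope >= 0) {
    warning("non-decaying AC excess: decorrelation time undefined")
    return(list(tau_dec = NA_real_, window = lag[w], method = method,
                sign = s))
  }
  tau <- if (method == "semilog") -1 / slope else -slope
  list(tau_dec = tau, window = lag[w], method = method, sign = s)
}

#' Per-neuron and population spike-train statistics
#'
#' Computes for every neuron its mean rate, ISI CV and CV2 (neurons need at
#' least \code{min_isis} ISIs to contribute), optionally the Fano factor
#' from a trial-count matrix, and per population the averaged
#' autocorrelation function with its decorrelation time.
#'
#' @param spikes A [spike_data()] object (one long trial).
#' @param counts Optional N x n_trials count matrix from
#'   [run_fano_experiment()].
#' @param max_lag Largest AC lag (ms).
#' @param src_order Serial-rank-correlation order for per-neuron SRCs
#'   (0 to skip).
#' @param min_isis Minimum ISI count for CV/CV2/SRC.
#' @param ac_smooth Smoothing width for [decorrelation_time()].
#' @return Object of class \code{"stats_summary"}: list with
#'   \code{per_neuron} (data.frame), \code{population} (data.frame of
#'   population means incl. \code{tau_dec}), \code{ac} (list of
#'   \code{"ac_function"} per population), \code{src} (matrix or NULL).
#' @export
stats_summary <- function(spikes, counts = NULL, max_lag = 200,
                          src_order = 0, min_isis = 5, ac_smooth = 1) {
  stopifnot(inherits(spikes, "spike_data"))
  n <- length(spikes$times)
  rate <- vapply(spikes$times, length, 1L) / spikes$duration * 1000
  cv <- cv2 <- rep(NA_real_, n)
  src <- if (src_order > 0) matrix(NA_real_, n, src_order) else NULL
  for (i in seq_len(n)) {
    isis <- diff(spikes$times[[i]])
    if (length(isis) >= min_isis && all(isis > 0)) {
      cv[i] <- cv_isi(isis)
      cv2[i] <- cv2_isi(isis)
      if (src_order > 0 && length(isis) > src_order + 1)
        src[i, ] <- serial_rank_correlations(isis, src_order)
    }
  }
  per_neuron <- data.frame(neuron = seq_len(n),
                           population = spikes$population,
                           rate = rate, cv = cv, cv2 = cv2)
  if (!is.null(counts))
    per_neuron$ff <- suppressWarnings(fano_factor(counts))
  pops <- unique(spikes$population)
  ac <- lapply(setNames(pops, pops), function(p)
    spike_autocorrelation(spikes, max_lag = max_lag, population = p))
  pop_stats <- do.call(rbind, lapply(pops, function(p) {
    sel <- spikes$population == p
    td <- suppressWarnings(decorrelation_time(ac[[p]], smooth = ac_smooth))
    data.frame(population = p,
               rate = mean(rate[sel]),
               cv = mean(cv[sel], na.rm = TRUE),
               cv2 = mean(cv2[sel], na.rm = TRUE),
               ff = if (!is.null(counts))
                 mean(per_neuron$ff[sel], na.rm = TRUE) else NA_real_,
               tau_dec = td$tau_dec)
  }))
  structure(list(per_neuron = per_neuron, population = pop_stats,
                 ac = ac, src = src),
            class = "stats_summary")
}

#' @method print stats_summary
#' @export
print.stats_summary <- function(x, ...) {
  cat("Spike-train statistics (", nrow(x$per_neuron), " neurons)\n", sep = "")
  print(x$population, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Spike counts in consecutive windows
#'
#' Splits a single long spike train into consecutive windows of equal
#' length and counts spikes per window; used to estimate the Fano factor
#' from one train.
#'
#' @param times Spike times (ms).
#' @param duration Train duration (ms).
#' @param window Window length (ms).
#' @return Integer vector of counts, one per complete window.
#' @export
windowed_counts <- function(times, duration, window) {
  n_win <- floor(duration / window)
  stopifnot(n_win >= 1)
  t <- times[times < n_win * window]
  tabulate(floor(t / window) + 1L, n_win)
}
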