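#' Topology configuration for a two-population recurrent network
#'
#' Describes the random connectivity of an excitatory/inhibitory network in
#' which every neuron receives on average \code{K} recurrent inputs from each
#' population, while the probability that a connection is reciprocated is
#' controlled separately for each connection class.  With reciprocity
#' parameter \code{p = 0} the four blocks are independent Erdos-Renyi graphs;
#' \code{p > 0} adds bidirectional (reciprocal) dyads in excess of chance
#' without changing the in-degree distributions.
#'
#' For a within-population block with connection probability \eqn{q = K/N},
#' an unordered neuron pair is made bidirectional with probability
#' \eqn{pq + (1-p)q^2} and unidirectional (each direction) with probability
#' \eqn{(1-p)q(1-q)}.  Each neuron then receives \eqn{K} inputs on average,
#' about \eqn{pK} of them reciprocated when \eqn{p \gg K/N}, versus
#' \eqn{K^2/N} by chance.  For the cross-population class with
#' \eqn{N_E \neq N_I} the bidirectional probability generalises to
#' \eqn{p\sqrt{q_1 q_2} + (1-p)q_1 q_2} so that both marginal connection
#' probabilities are preserved (it reduces to the within-population rule when
#' \eqn{N_E = N_I}).
#'
#' @param N_E,N_I Number of excitatory / inhibitory neurons (each >= 2).
#' @param K Target mean recurrent in-degree per input class;
#'   must satisfy \code{K <= min(N_E, N_I)}.
#' @param p_EE,p_II,p_EI Reciprocity parameters in \[0, 1\] for
#'   excitatory-excitatory, inhibitory-inhibitory and cross-population
#'   connections.  Default 0 (chance-level reciprocity, independent ER).
#' @param seed Integer root seed.  Each connection class draws from its own
#'   child stream, so changing e.g. \code{p_II} leaves the EE block
#'   bit-identical -- this is what makes matched sweeps over p possible.
#' @return An object of class \code{"topology_config"}.
#' @seealso [generate_connectivity()], [dyad_state_probs()]
#' @export
topology_config <- function(N_E, N_I, K, p_EE = 0, p_II = 0, p_EI = 0,
                            seed = 1L) {
  cfg <- list(N_E = as.integer(N_E), N_I = as.integer(N_I), K = K,
              p_EE = p_EE, p_II = p_II, p_EI = p_EI, seed = as.integer(seed))
  validate_topology_config(cfg)
  class(cfg) <- "topology_config"
  cfg
}

validate_topology_config <- function(cfg) {
  stopifnot(cfg$N_E >= 2, cfg$N_I >= 2, cfg$K > 0)
  if (cfg$K > min(cfg$N_E, cfg$N_I))
    stop("K must not exceed min(N_E, N_I)", call. = FALSE)
  for (nm in c("p_EE", "p_II", "p_EI")) {
    p <- cfg[[nm]]
    if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1)
      stop(sprintf("%s must be a single number in [0, 1]", nm), call. = FALSE)
  }
  # every dyad-state probability must be a valid probability
  dyad_state_probs(cfg$K / cfg$N_E, cfg$K / cfg$N_E, cfg$p_EE)
  dyad_state_probs(cfg$K / cfg$N_I, cfg$K / cfg$N_I, cfg$p_II)
  dyad_state_probs(cfg$K / cfg$N_E, cfg$K / cfg$N_I, cfg$p_EI)
  invisible(cfg)
}

#' Dyad-state probabilities of the reciprocity-controlled wiring rule
#'
#' Probability of each state of an unordered neuron pair (dyad) under the
#' generator: bidirectionally connected, unidirectional in either direction,
#' or unconnected.  \code{q1} is the marginal probability of the first
#' direction, \code{q2} of the second; within one population
#' \code{q1 = q2 = K/N}.
#'
#' @param q1,q2 Marginal connection probabilities of the two directions.
#' @param p Reciprocity parameter in \[0, 1\].
#' @return Named numeric vector with entries \code{bidir}, \code{uni_12},
#'   \code{uni_21}, \code{none}, summing to one.
#' @export
dyad_state_probs <- function(q1, q2, p) {
  stopifnot(q1 >= 0, q1 <= 1, q2 >= 0, q2 <= 1, p >= 0, p <= 1)
  p_bi <- p * sqrt(q1 * q2) + (1 - p) * q1 * q2
  u12 <- q1 - p_bi
  u21 <- q2 - p_bi
  none <- 1 - q1 - q2 + p_bi
  out <- c(bidir = p_bi, uni_12 = u12, uni_21 = u21, none = none)
  if (any(out < -1e-12))
    stop("invalid dyad-state probabilities for this (p, K, N) combination: ",
         paste(sprintf("%s = %.4g", names(out), out), collapse = ", "),
         call. = FALSE)
  pmax(out, 0)
}

#' Generate a reciprocity-controlled random connectivity matrix
#'
#' Draws the four directed connectivity blocks (EE, EI, IE, II) by sampling
#' every unordered neuron pair once from the four-state dyad distribution of
#' [dyad_state_probs()].  Entry \code{(i, j)} of block \code{AB} is 1 when
#' neuron \code{j} of population B projects to neuron \code{i} of population
#' A.  Self-connections are excluded.
#'
#' Each block uses its own RNG child stream derived from \code{cfg$seed} and,
#' within a block, the same underlying uniform draws are classified against
#' p-dependent thresholds; realizations at different \code{p} for the same
#' seed are therefore maximally coupled, which is what matched reciprocity
#' sweeps rely on.
#'
#' @param cfg A [topology_config()].
#' @return Object of class \code{"connectivity"}: list with sparse logical
#'   blocks \code{EE}, \code{EI}, \code{IE}, \code{II} and the generating
#'   \code{config}.
#' @export
generate_connectivity <- function(cfg) {
  stopifnot(inherits(cfg, "topology_config"))
  validate_topology_config(cfg)
  seeds <- derive_seeds(cfg$seed, 3L, "topology")
  EE <- sample_within_block(cfg$N_E, cfg$K / cfg$N_E, cfg$p_EE, seeds[1L])
  II <- sample_within_block(cfg$N_I, cfg$K / cfg$N_I, cfg$p_II, seeds[2L])
  cross <- sample_cross_block(cfg$N_E, cfg$N_I, cfg$K, cfg$p_EI, seeds[3L])
  out <- list(EE = EE, EI = cross$EI, IE = cross$IE, II = II, config = cfg)
  class(out) <- "connectivity"
  out
}

# Sample one within-population block of N neurons, connection prob q,
# reciprocity p.  Iterates over columns j, drawing the dyads (i < j) for that
# column; returns a sparse pattern matrix with [i, j] = 1 iff j -> i.
sample_within_block <- function(N, q, p, seed) {
  pr <- dyad_state_probs(q, q, p)
  t_bi <- pr[["bidir"]]
  t_u1 <- t_bi + pr[["uni_12"]]
  t_u2 <- t_u1 + pr[["uni_21"]]
  rows <- vector("list", N)
  cols <- vector("list", N)
  local_seed(seed)
  for (j in 2:N) {
    u <- runif(j - 1L)
    bi <- which(u < t_bi)
    u1 <- which(u >= t_bi & u < t_u1)   # i -> j
    u2 <- which(u >= t_u1 & u < t_u2)   # j -> i
    # edge a -> b stored at [b, a]
    rows[[j]] <- c(bi, rep(j, length(bi)), u2, rep(j, length(u1)))
    cols[[j]] <- c(rep(j, length(bi)), bi, rep(j, length(u2)), u1)
  }
  Matrix::sparseMatrix(i = unlist(rows), j = unlist(cols), dims = c(N, N),
                       repr = "C")
}

# Sample the E<->I cross-population dyads.  q1 = P(e -> i) = K/N_E,
# q2 = P(i -> e) = K/N_I.  Returns the two blocks: EI (N_E x N_I, [e, i] = 1
# iff i -> e) and IE (N_I x N_E, [i, e] = 1 iff e -> i).
sample_cross_block <- function(N_E, N_I, K, p, seed) {
  pr <- dyad_state_probs(K / N_E, K / N_I, p)
  t_bi <- pr[["bidir"]]
  t_u1 <- t_bi + pr[["uni_12"]]       # e -> i only
  t_u2 <- t_u1 + pr[["uni_21"]]       # i -> e only
  ei_r <- vector("list", N_I); ei_c <- vector("list", N_I)
  ie_r <- vector("list", N_I); ie_c <- vector("list", N_I)
  local_seed(seed)
  for (j in seq_len(N_I)) {
    u <- runif(N_E)
    bi <- which(u < t_bi)
    e2i <- which(u >= t_bi & u < t_u1)
    i2e <- which(u >= t_u1 & u < t_u2)
    ei_r[[j]] <- c(bi, i2e); ei_c[[j]] <- rep(j, length(bi) + length(i2e))
    ie_r[[j]] <- rep(j, length(bi) + length(e2i)); ie_c[[j]] <- c(bi, e2i)
  }
  list(EI = Matrix::sparseMatrix(i = unlist(ei_r), j = unlist(ei_c),
                                 dims = c(N_E, N_I), repr = "C"),
       IE = Matrix::sparseMatrix(i = unlist(ie_r), j = unlist(ie_c),
                                 dims = c(N_I, N_E), repr = "C"))
}

#' Exhaustive dyad census of a connectivity matrix
#'
#' Counts, for each connection class, the number of bidirectional dyads,
#' unidirectional dyads and unconnected dyads.  Used to validate the wiring
#' probabilities of [generate_connectivity()].
#'
#' @param C A \code{"connectivity"} object.
#' @return data.frame with one row per class (\code{EE}, \code{II},
#'   \code{EI}) and columns \code{n_bidirectional}, \code{n_unidirectional},
#'   \code{n_unconnected}, \code{n_dyads}.
#' @export
count_motifs <- function(C) {
  stopifnot(inherits(C, "connectivity"))
  within <- function(M) {
    N <- nrow(M)
    n_edges <- Matrix::nnzero(M)
    n_bi <- Matrix::nnzero(M & Matrix::t(M)) / 2
    n_uni <- n_edges - 2 * n_bi
    n_dyads <- N * (N - 1) / 2
    c(n_bi, n_uni, n_dyads - n_bi - n_uni, n_dyads)
  }
  B1 <- C$EI                 # [e, i]: i -> e
  B2 <- Matrix::t(C$IE)      # [e, i]: e -> i
  n_bi <- Matrix::nnzero(B1 & B2)
  n_uni <- Matrix::nnzero(B1) + Matrix::nnzero(B2) - 2 * n_bi
  n_dyads <- nrow(B1) * ncol(B1)
  m <- rbind(EE = within(C$EE), II = within(C$II),
             EI = c(n_bi, n_uni, n_dyads - n_bi - n_uni, n_dyads))
  data.frame(pair = rownames(m), n_bidirectional = m[, 1],
             n_unidirectional = m[, 2], n_unconnected = m[, 3],
             n_dyads = m[, 4], row.names = NULL)
}

#' In-degrees by presynaptic population
#'
#' @param C A \code{"connectivity"} object.
#' @return data.frame with columns \code{population} (of the receiving
#'   neuron), \code{indeg_E}, \code{indeg_I}.
#' @export
in_degrees <- function(C) {
  stopifnot(inherits(C, "connectivity"))
  data.frame(
    population = rep(c("E", "I"), c(nrow(C$EE), nrow(C$II))),
    indeg_E = c(Matrix::rowSums(C$EE), Matrix::rowSums(C$IE)),
    indeg_I = c(Matrix::rowSums(C$EI), Matrix::rowSums(C$II)))
}

#' Integral of the effective self-coupling induced by excess reciprocity
#'
#' A neuron taking part in reciprocated dyads receives delayed feedback from
#' its own spikes through disynaptic loops: a spike adds \eqn{J/\sqrt{K}} to
#' each of its targets, eliciting on average \eqn{\xi J/\sqrt{K}} extra
#' spikes per target, of which about \eqn{pK} project back.  The time
#' integral of this effective self-coupling is \eqn{pK\xi J^2} for
#' within-population reciprocity and \eqn{-pK\xi J_{EI}J_{IE}} for the
#' cross-population loop (negative: one leg is inhibitory).
#'
#' @param p Reciprocity parameter in \[0, 1\].
#' @param K Mean recurrent in-degree.
#' @param gain_E,gain_I Average neuronal gains \eqn{\xi_E}, \eqn{\xi_I}
#'   (extra spikes per unit of integrated synaptic input), >= 0.
#' @param J Named list or vector of scaled coupling strengths
#'   \eqn{\bar g_{AB} = G_{AB}/\sqrt K} with entries \code{J_EE},
#'   \code{J_IE}, \code{J_EI}, \code{J_II}.
#' @return Named numeric vector: \code{EE} (self-coupling of E neurons via
#'   EE loops), \code{II}, and \code{EI_on_E} / \code{EI_on_I} (negative
#'   cross-population loop for each population).
#' @export
effective_self_coupling <- function(p, K, gain_E, gain_I, J) {
  stopifnot(p >= 0, p <= 1, K > 0, gain_E >= 0, gain_I >= 0)
  J <- as.list(J)
  stopifnot(all(c("J_EE", "J_IE", "J_EI", "J_II") %in% names(J)))
  c(EE = p * K * gain_E * J$J_EE^2,
    II = p * K * gain_I * J$J_II^2,
    EI_on_E = -p * K * gain_I * J$J_EI * J$J_IE,
    EI_on_I = -p * K * gain_E * J$J_EI * J$J_IE)
}

#' @method print connectivity
#' @export
print.connectivity <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Connectivity: N_E = %d, N_I = %d, K = %g\n",
              cfg$N_E, cfg$N_I, cfg$K))
  cat(sprintf("reciprocity p_EE = %g, p_II = %g, p_EI = %g (seed %d)\n",
              cfg$p_EE, cfg$p_II, cfg$p_EI, cfg$seed))
  m <- count_motifs(x)
  print(m, ...)
  invisible(x)
}

# Derive child seeds from a root seed without disturbing the caller's RNG.
# Distinct stream names give unrelated child sequences for the same root.
derive_seeds <- function(seed, n, stream = "") {
  ch <- utf8ToInt(stream)
  off <- sum(ch * seq_along(ch))
  local_seed((seed * 7919 + off * 104729) %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}

# set.seed scoped to the calling function's frame
local_seed <- function(seed, env = parent.frame()) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    do.call(on.exit, list(call("assign", ".Random.seed", old, globalenv()),
                          add = TRUE), envir = env)
  }
  set.seed(seed)
}
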