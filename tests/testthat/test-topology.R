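test_that("config validation rejects invalid parameter combinations", {
  expect_error(topology_config(100, 100, 200), "K must not exceed")
  expect_error(topology_config(100, 100, 20, p_EE = 1.2), "p_EE")
  expect_error(topology_config(100, 100, 20, p_II = -0.1), "p_II")
  # cross-population dyad probabilities can go negative when q1 != q2:
  # P(bidir) = p*sqrt(q1 q2) can exceed the smaller marginal
  expect_error(topology_config(2000, 40, 20, p_EI = 1),
               "invalid dyad-state")
})

test_that("dyad-state probabilities follow the wiring rule and sum to one", {
  q <- 0.1
  for (p in c(0, 0.3, 1)) {
    pr <- dyad_state_probs(q, q, p)
    expect_equal(sum(pr), 1)
    expect_equal(pr[["bidir"]], p * q + (1 - p) * q^2)
    expect_equal(pr[["uni_12"]], (1 - p) * q * (1 - q))
  }
  # p = 0 is the independent ER case
  expect_equal(unname(dyad_state_probs(q, q, 0)),
               c(q^2, q * (1 - q), q * (1 - q), (1 - q)^2))
  # p = 1: no unidirectional dyads within a population
  expect_equal(dyad_state_probs(q, q, 1)[["uni_12"]], 0)
})

test_that("p = 1 makes within-population blocks exactly symmetric", {
  C <- generate_connectivity(topology_config(300, 300, 30, p_EE = 1,
                                             p_II = 1, seed = 5))
  expect_identical(as(C$EE, "generalMatrix"),
                   as(Matrix::t(C$EE), "generalMatrix"))
  expect_true(all(Matrix::diag(C$EE) == 0))
  m <- count_motifs(C)
  expect_equal(m$n_unidirectional[m$pair == "EE"], 0)
  expect_equal(m$n_unidirectional[m$pair == "II"], 0)
})

test_that("motif census is exact on hand-built connectivity", {
  blk <- function(i, j, nr, nc)
    Matrix::sparseMatrix(i = i, j = j, dims = c(nr, nc), repr = "C")
  # 2 E neurons connected reciprocally; 1 I neuron untouched
  C <- structure(list(EE = blk(c(1, 2), c(2, 1), 2, 2),
                      EI = blk(integer(0), integer(0), 2, 1),
                      IE = blk(integer(0), integer(0), 1, 2),
                      II = blk(integer(0), integer(0), 1, 1),
                      config = NULL),
                 class = "connectivity")
  m <- count_motifs(C)
  expect_equal(m$n_bidirectional, c(1, 0, 0))
  expect_equal(m$n_unidirectional, c(0, 0, 0))
  expect_equal(m$n_unconnected, c(0, 0, 2))
  expect_equal(m$n_dyads, c(1, 0, 2))
})

test_that("empirical dyad frequencies and in-degrees match the rule", {
  # ER block at p = 0: bidirectional fraction ~ (K/N)^2 (within 3 SE over
  # pooled realizations)
  N <- 200; K <- 20; q <- K / N
  n_real <- 30
  n_bi <- 0
  for (s in seq_len(n_real)) {
    C <- generate_connectivity(topology_config(N, N, K, seed = s))
    n_bi <- n_bi + count_motifs(C)$n_bidirectional[1]
  }
  n_dyads <- n_real * N * (N - 1) / 2
  p_bi <- dyad_state_probs(q, q, 0)[["bidir"]]
  se <- sqrt(p_bi * (1 - p_bi) / n_dyads)
  expect_lt(abs(n_bi / n_dyads - p_bi), 3 * se)

  # in-degree mean invariant under p
  for (p in c(0, 0.5, 1)) {
    C <- generate_connectivity(topology_config(500, 500, 50, p_II = p,
                                               seed = 2))
    d <- in_degrees(C)
    expect_equal(mean(d$indeg_I[d$population == "I"]), 50, tolerance = 0.07)
    expect_equal(mean(d$indeg_E[d$population == "I"]), 50, tolerance = 0.07)
  }
})

test_that("reciprocity raises bidirectional partners to pK + (1-p)K^2/N", {
  N <- 500; K <- 50; p <- 0.6
  C <- generate_connectivity(topology_config(N, N, K, p_II = p, seed = 9))
  S <- C$II & Matrix::t(C$II)
  expected <- p * K + (1 - p) * K^2 / N
  expect_equal(mean(Matrix::rowSums(S)), expected, tolerance = 0.1)
})

test_that("changing one block's reciprocity leaves the other streams intact", {
  a <- generate_connectivity(topology_config(300, 300, 30, p_II = 0, seed = 4))
  b <- generate_connectivity(topology_config(300, 300, 30, p_II = 0.8, seed = 4))
  expect_identical(a$EE, b$EE)
  expect_identical(a$EI, b$EI)
  expect_identical(a$IE, b$IE)
  expect_false(identical(a$II, b$II))
  # reproducibility
  a2 <- generate_connectivity(topology_config(300, 300, 30, p_II = 0, seed = 4))
  expect_identical(a$II, a2$II)
})

test_that("effective self-coupling integrals follow pK xi J^2 with loop signs", {
  J <- list(J_EE = 0.15 / sqrt(500), J_IE = 0.45 / sqrt(500),
            J_EI = 2 / sqrt(500), J_II = 3 / sqrt(500))
  out <- effective_self_coupling(0.5, 500, gain_E = 1, gain_I = 1, J)
  expect_equal(out[["II"]], 0.5 * 500 * (3 / sqrt(500))^2)  # = 4.5
  expect_equal(out[["II"]], 4.5)
  expect_equal(out[["EE"]], 0.5 * 500 * J$J_EE^2)
  expect_equal(out[["EI_on_E"]], -0.5 * 500 * J$J_EI * J$J_IE)
  expect_true(out[["EE"]] > 0 && out[["II"]] > 0)
  expect_true(out[["EI_on_E"]] < 0 && out[["EI_on_I"]] < 0)
  expect_equal(unname(effective_self_coupling(0, 500, 1, 1, J)), rep(0, 4))
  # gains weight the loop: doubling gain_I doubles II and EI_on_E
  out2 <- effective_self_coupling(0.5, 500, gain_E = 1, gain_I = 2, J)
  expect_equal(out2[["II"]], 2 * out[["II"]])
  expect_equal(out2[["EI_on_E"]], 2 * out[["EI_on_E"]])
})
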