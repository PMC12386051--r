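test_that("galton measure carries the covariance prefactor", {
  ls <- light_switch()
  pc <- maxent_distribution(ls$space)
  expect_equal(measure_value(cs_galton(ls, pc, "ON", "ON")), 0.25)

  # independence: identical rows give zero covariance
  m <- transition_model(matrix(rep(c(0.1, 0.2, 0.3, 0.4), each = 4), 4))
  expect_equal(measure_value(cs_galton(m, maxent_distribution(m$space),
                                       "s1", "s2")), 0)

  # equals the indicator covariance on random systems
  set.seed(91)
  for (rep in 1:5) {
    m <- random_tpm(5)
    pc <- random_pc(m$space)
    expect_equal(measure_value(cs_galton(m, pc, "s2", "s4")),
                 oracle_galton_cov(m, pc, 2, 4), tolerance = 1e-12)
  }
})

test_that("eells and suppes are the primitive differences", {
  ls <- light_switch()
  pc <- maxent_distribution(ls$space)
  expect_equal(measure_value(cs_eells(ls, pc, "ON", "ON")), 1)

  r <- c(0.2, 0.5, 0.3)
  m <- transition_model(matrix(r, 3, 3, byrow = TRUE))
  expect_equal(measure_value(cs_eells(m, maxent_distribution(m$space),
                                      "s1", "s2")), 0)
  expect_equal(measure_value(cs_suppes(m, maxent_distribution(m$space),
                                       "s1", "s2")), 0)

  # deterministic unique cause in a 4-state system: suppes = 1 - 1/4
  m4 <- transition_model(rbind(c(1, 0, 0, 0), c(0, 1, 0, 0),
                               c(0, 0, 1, 0), c(0, 0, 0, 1)))
  expect_equal(measure_value(cs_suppes(m4, maxent_distribution(m4$space),
                                       "s1", "s1")), 0.75)

  # sign agreement between suppes and effect information
  set.seed(101)
  for (rep in 1:10) {
    m <- random_tpm(5)
    pc <- maxent_distribution(m$space)
    s <- measure_value(cs_suppes(m, pc, "s1", "s3"))
    ei <- measure_value(effect_information(m, pc, "s1", "s3"))
    expect_equal(sign(s), sign(ei))
  }
})

test_that("cheng causal power handles its degenerate denominator", {
  ls <- light_switch()
  pc <- maxent_distribution(ls$space)
  expect_equal(measure_value(cs_cheng(ls, pc, "ON", "ON")), 1)

  # s = 1 forces cheng = 1 whatever the (positive) necessity
  m <- transition_model(rbind(c(0, 1, 0), c(0.2, 0.5, 0.3), c(1, 0, 0)))
  expect_equal(measure_value(cs_cheng(m, maxent_distribution(m$space),
                                      "s1", "s2")), 1)

  # v = 0 (effect certain without the cause) is undefined, not zero
  m0 <- transition_model(rbind(c(0.5, 0.5), c(0, 1)))
  r <- cs_cheng(m0, maxent_distribution(m0$space), "s1", "s2")
  expect_false(r$defined)
  expect_true(is.na(measure_value(r)))
})

test_that("good's weight of evidence covers its limit cases", {
  # v = 1 - s makes the odds ratio 1, zero evidence
  m <- transition_model(rbind(c(0.3, 0.7), c(0.3, 0.7)))
  pc <- maxent_distribution(m$space)
  expect_equal(measure_value(cs_good(m, pc, "s1", "s1")), 0)

  # s = 0.5, v = 1: one bit of evidence
  m2 <- transition_model(rbind(c(0.5, 0.5), c(0, 1)))
  expect_equal(measure_value(cs_good(m2, maxent_distribution(m2$space),
                                     "s1", "s1")), 1)

  # s = 1, v = 1: infinite evidence, flagged but defined
  ls <- light_switch()
  r <- cs_good(ls, maxent_distribution(ls$space), "ON", "ON")
  expect_identical(measure_value(r), Inf)
  expect_true(r$defined)
})

test_that("lewis relative-risk drop matches its closed forms", {
  # v = 1: value 1 for any positive sufficiency
  m2 <- transition_model(rbind(c(0.5, 0.5), c(0, 1)))
  expect_equal(measure_value(cs_lewis(m2, maxent_distribution(m2$space),
                                      "s1", "s1")), 1)
  # s = 1 - v: value 0
  m <- transition_model(rbind(c(0.3, 0.7), c(0.3, 0.7)))
  expect_equal(measure_value(cs_lewis(m, maxent_distribution(m$space),
                                      "s1", "s1")), 0)
  # equals 1 - P(e|C\c)/P(e|c) on random systems
  set.seed(111)
  for (rep in 1:5) {
    m <- random_tpm(5)
    pc <- random_pc(m$space)
    cf <- oracle_counterfactual(m, pc, 2)
    expect_equal(measure_value(cs_lewis(m, pc, "s2", "s5")),
                 1 - cf[5] / m$matrix[2, 5], tolerance = 1e-12)
  }
})

test_that("pearl's PN, PS, PNS are exact aliases of lewis, cheng, eells", {
  set.seed(121)
  for (rep in 1:10) {
    m <- random_tpm(5, sparsify = 0.3)
    pc <- if (rep %% 2) maxent_distribution(m$space) else random_pc(m$space)
    cause <- sample(m$space$labels, 1)
    effect <- sample(m$space$labels, 1)
    expect_identical(measure_value(pearl_pns(m, pc, cause, effect)),
                     measure_value(cs_eells(m, pc, cause, effect)))
    expect_identical(measure_value(pearl_pn(m, pc, cause, effect)),
                     measure_value(cs_lewis(m, pc, cause, effect)))
    expect_identical(measure_value(pearl_ps(m, pc, cause, effect)),
                     measure_value(cs_cheng(m, pc, cause, effect)))
  }
})

test_that("closest-possible-world lewis uses the nearest state, averaging ties", {
  # 1-bit switch: unique neighbor is the other state
  sw <- transition_model(matrix(c(1, 0, 0, 1), 2, byrow = TRUE),
                         state_space(c("1", "0")))
  expect_equal(measure_value(cs_lewis_cpw(sw, NULL, "1", "1")), 1)

  # nearest neighbor sharing the cause's row: zero drop
  m <- transition_model(matrix(rep(c(0.25, 0.25, 0.25, 0.25), 4), 4,
                               byrow = TRUE),
                        state_space(c("00", "01", "10", "11")))
  expect_equal(measure_value(cs_lewis_cpw(m, NULL, "00", "11")), 0)

  # two equidistant neighbors: the measure is the mean of both drops
  tpm <- rbind(c(0.5, 0.5, 0, 0),
               c(1, 0, 0, 0),
               c(0, 0, 1, 0),
               c(0.25, 0.25, 0.25, 0.25))
  m <- transition_model(tpm, state_space(c("00", "01", "10", "11")))
  v01 <- (0.5 - 1) / 0.5
  v10 <- (0.5 - 0) / 0.5
  expect_equal(measure_value(cs_lewis_cpw(m, NULL, "00", "00")),
               mean(c(v01, v10)))
})

test_that("bit-flip measures mean Hamming displacement of the effect", {
  labels4 <- c("00", "01", "10", "11")
  # constant map: every cause lands on the same effect, no displacement
  const <- transition_model({
    m <- matrix(0, 4, 4); m[, 4] <- 1; m
  }, state_space(labels4))
  expect_equal(measure_value(cs_bit_flip(const, "01", "11")), 0)

  # identity map: each single-bit flip displaces the output by exactly 1
  ident <- transition_model(diag(4), state_space(labels4))
  expect_equal(measure_value(cs_bit_flip(ident, "10", "10")), 1)

  # noisy system vs brute-force triple loop
  set.seed(131)
  m <- random_tpm(8, labels = c("000", "001", "010", "011",
                                "100", "101", "110", "111"))
  expect_equal(measure_value(cs_bit_flip(m, "010", "101")),
               oracle_bit_flip(m, "010", "101"), tolerance = 1e-12)
})

test_that("effect information is the log probability ratio in bits", {
  m2 <- transition_model(rbind(c(1, 0), c(0, 1)))
  pc <- maxent_distribution(m2$space)
  expect_equal(measure_value(effect_information(m2, pc, "s1", "s1")), 1)

  r <- c(0.4, 0.6)
  flat <- transition_model(rbind(r, r, deparse.level = 0))
  expect_equal(measure_value(effect_information(flat,
                                                maxent_distribution(flat$space),
                                                "s1", "s2")), 0)

  # identity ei = log2(n) (det(e,c) - deg(e)) on random systems
  set.seed(141)
  for (rep in 1:5) {
    m <- random_tpm(6)
    pc <- random_pc(m$space)
    n <- 6
    expect_equal(
      measure_value(effect_information(m, pc, "s2", "s3")),
      log2(n) * (determinism_transition(m, "s2", "s3") -
                   degeneracy_effect(m, pc, "s3")),
      tolerance = 1e-9
    )
  }
})

test_that("effective information and effectiveness meet their identities", {
  perm16 <- transition_model(diag(16)[c(2:16, 1), ])
  pc <- maxent_distribution(perm16$space)
  expect_equal(measure_value(effective_information(perm16, pc)), 4)
  expect_equal(measure_value(effectiveness(perm16, pc)), 1)

  r <- c(0.1, 0.2, 0.3, 0.4)
  flat <- transition_model(matrix(r, 4, 4, byrow = TRUE))
  expect_equal(measure_value(effective_information(flat,
                                                   maxent_distribution(flat$space))),
               0)

  macro <- transition_model(matrix(c(0, 1, 1, 0), 2, byrow = TRUE))
  expect_equal(measure_value(effective_information(macro,
                                                   maxent_distribution(macro$space))),
               1)

  b00 <- bipartite_model(dilution = 0, rewiring = 0)
  expect_equal(measure_value(effectiveness(b00,
                                           maxent_distribution(b00$space))),
               0.25)

  # EI = log2(n) (det - deg) on sparse random systems
  set.seed(151)
  for (rep in 1:5) {
    m <- random_tpm(7, sparsify = 0.4)
    pc <- random_pc(m$space)
    expect_equal(measure_value(effective_information(m, pc)),
                 log2(7) * (determinism_system(m, pc) -
                              degeneracy_system(m, pc)),
                 tolerance = 1e-9)
  }
})

test_that("expectations match brute-force joint sums", {
  set.seed(161)
  m <- random_tpm(5)
  pc <- maxent_distribution(m$space)
  w <- observational_distribution(m)$weights
  # eells expectation vs double loop
  acc <- 0
  for (ci in 1:5) for (ei in 1:5) {
    acc <- acc + w[ci] * m$matrix[ci, ei] *
      measure_value(cs_eells(m, pc, paste0("s", ci), paste0("s", ei)))
  }
  expect_equal(measure_value(cs_expectation("eells", m, pc)), unname(acc),
               tolerance = 1e-9)

  # expectation of ei with intervention weighting is the effective information
  expect_equal(
    measure_value(cs_expectation("effect_information", m, pc,
                                 weights = "intervention")),
    measure_value(effective_information(m, pc)),
    tolerance = 1e-9
  )
})

test_that("the lewis expectation vanishes identically", {
  set.seed(171)
  for (rep in 1:5) {
    m <- random_tpm(6, sparsify = 0.4)
    expect_lt(abs(measure_value(cs_expectation("lewis", m, "maxent"))), 1e-9)
    expect_lt(abs(measure_value(cs_expectation("lewis", m, random_pc(m$space)))),
              1e-9)
  }
  b <- bipartite_model(dilution = 0.6, rewiring = 0.3)
  expect_lt(abs(measure_value(cs_expectation("lewis", b, "local"))), 1e-9)
})

test_that("per-transition measures are invariant under state relabeling", {
  set.seed(181)
  m <- random_tpm(5)
  pc <- random_pc(m$space)
  perm <- sample(5)
  labels2 <- paste0("t", 1:5)
  mm <- m$matrix[perm, perm]
  dimnames(mm) <- NULL
  m2 <- transition_model(mm, state_space(labels2))
  pc2 <- custom_distribution(m2$space, unname(pc$weights[perm]))
  ci <- which(perm == 2); ei <- which(perm == 4)
  for (meas in c("eells", "suppes", "cheng", "good", "lewis", "galton")) {
    expect_equal(
      measure_value(causal_measure(meas, m, pc, "s2", "s4")),
      measure_value(causal_measure(meas, m2, pc2, labels2[ci], labels2[ei])),
      tolerance = 1e-12, label = meas
    )
  }
})
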