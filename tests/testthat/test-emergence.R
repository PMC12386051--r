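test_that("the bipartite macro TPM is the deterministic two-state oscillator", {
  for (d in seq(0, 1, 0.25)) {
    for (g in seq(0, 1, 0.25)) {
      b <- bipartite_model(dilution = d, rewiring = g)
      mac <- coarse_grain(b, bipartite_macro_mapping(b))
      expect_equal(mac$matrix,
                   matrix(c(0, 1, 1, 0), 2, byrow = TRUE,
                          dimnames = list(c("ON", "OFF"), c("ON", "OFF"))))
    }
  }
})

test_that("coarse-graining recovers the original model under identity mapping", {
  set.seed(191)
  m <- random_tpm(6)
  cg <- coarse_graining(m$space, stats::setNames(m$space$labels,
                                                 m$space$labels))
  expect_equal(coarse_grain(m, cg)$matrix, m$matrix)
})

test_that("coarse-graining aggregates rows like the brute-force oracle", {
  nm <- nand_model(2, 0.1)
  cg <- nand_macro_mapping(nm)
  mac <- coarse_grain(nm, cg)
  expect_equal(mac$matrix, oracle_coarse_grain(nm, cg$map)[rownames(mac$matrix),
                                                           colnames(mac$matrix)])
  # ON row comes from the single microstate 11
  expect_equal(mac$matrix["ON", "OFF"], sum(nm$matrix["11", c("00", "01", "10")]))

  # weighted aggregation on a generic model matches the oracle too
  set.seed(201)
  m <- random_tpm(6)
  map <- stats::setNames(c("x", "x", "y", "y", "y", "z"), m$space$labels)
  cg2 <- coarse_graining(m$space, map)
  pc <- random_pc(m$space)
  expect_equal(coarse_grain(m, cg2, pc)$matrix,
               oracle_coarse_grain(m, map, pc$weights)[c("x", "y", "z"),
                                                       c("x", "y", "z")],
               tolerance = 1e-12)
  expect_equal(rowSums(coarse_grain(m, cg2, pc)$matrix), c(x = 1, y = 1, z = 1),
               tolerance = 1e-9)
})

test_that("macro intervention distributions behave on the two-state macroscale", {
  b <- bipartite_model(dilution = 0.5, rewiring = 0.5)
  mac <- coarse_grain(b, bipartite_macro_mapping(b))
  expect_equal(unname(macro_intervention("maxent", mac)$weights), c(0.5, 0.5))
  expect_equal(unname(macro_intervention("observational", mac)$weights),
               c(0.5, 0.5))
  loc <- macro_intervention("local", mac, center = "ON", delta = 1)
  expect_equal(unname(loc$weights), c(0.5, 0.5))  # ball covers both states
  loc0 <- macro_intervention("local", mac, center = "ON", delta = 0)
  expect_equal(unname(loc0$weights), c(1, 0))
})

test_that("causal emergence of effective information hits its exact anchors", {
  # deterministic non-degenerate micro: EI_micro = 4 bits, macro = 1 bit
  b <- bipartite_model(dilution = 1, rewiring = 0)
  cg <- bipartite_macro_mapping(b)
  r <- causal_emergence("effect_information", b, cg, scope = "expectation",
                        intervention = "maxent", weights = "intervention")
  expect_equal(r$cs_micro, 4)
  expect_equal(r$cs_macro, 1)
  expect_equal(r$ce, -3)
  expect_equal(r$direction, "reduction")

  # fully diluted micro: EI_micro = 1 bit, CE = 0
  b0 <- bipartite_model(dilution = 0, rewiring = 0)
  r0 <- causal_emergence("effect_information", b0, bipartite_macro_mapping(b0),
                         scope = "expectation", intervention = "maxent",
                         weights = "intervention")
  expect_equal(r0$cs_micro, 1)
  expect_equal(r0$ce, 0)
})

test_that("secondary transitions show causal emergence for eells", {
  b <- bipartite_model(dilution = 1, rewiring = 0)
  cg <- bipartite_macro_mapping(b)
  r <- causal_emergence("eells", b, cg, "0000", "1110",
                        scope = "transition", intervention = "maxent")
  expect_equal(r$cs_macro, 1)  # macro ON -> OFF is deterministic and necessary
  expect_lt(r$cs_micro, 0)     # micro secondary transition never fires
  expect_gt(r$ce, 0)
  expect_equal(r$direction, "emergence")
})

test_that("infinite causal emergence arises from -Inf micro against finite macro", {
  b <- bipartite_model(dilution = 1, rewiring = 0)
  cg <- bipartite_macro_mapping(b)
  # micro effect information of a never-firing transition is -Inf
  r <- causal_emergence("effect_information", b, cg, "0000", "1110",
                        scope = "transition", intervention = "maxent")
  expect_identical(r$cs_micro, -Inf)
  expect_identical(r$ce, Inf)
  expect_true(r$defined)
})

test_that("causal emergence is antisymmetric under swapping the scales", {
  b <- bipartite_model(dilution = 0.5, rewiring = 0.2)
  cg <- bipartite_macro_mapping(b)
  r <- causal_emergence("suppes", b, cg, scope = "expectation",
                        intervention = "maxent")
  mac <- coarse_grain(b, cg)
  micro_e <- measure_value(cs_expectation("suppes", b, "maxent"))
  macro_e <- measure_value(cs_expectation("suppes", mac, "maxent"))
  expect_equal(r$ce, macro_e - micro_e, tolerance = 1e-12)
  expect_equal(macro_e - micro_e, -(micro_e - macro_e))
})

test_that("supervenience check accepts the bipartite family and flags violations", {
  for (d in c(0, 0.5, 1)) {
    b <- bipartite_model(dilution = d, rewiring = 0.5)
    chk <- supervenience_check(b, bipartite_macro_mapping(b))
    expect_true(chk$consistent)
    expect_equal(chk$residual, 0)
  }
  set.seed(211)
  m <- random_tpm(6)
  cg <- coarse_graining(m$space, stats::setNames(m$space$labels,
                                                 m$space$labels))
  expect_true(supervenience_check(m, cg)$consistent)

  # hand-built counterexample: members of one macrostate disagree
  bad <- transition_model(rbind(c(1, 0, 0, 0),
                                c(0, 0, 0, 1),
                                c(0, 0, 1, 0),
                                c(0, 0, 0, 1)))
  cg_bad <- coarse_graining(bad$space,
                            stats::setNames(c("u", "u", "v", "v"),
                                            bad$space$labels))
  chk <- supervenience_check(bad, cg_bad)
  expect_false(chk$consistent)
  expect_gt(chk$residual, 0)
})

test_that("sweep tables have the promised shape and no silent NaN cells", {
  sw <- ce_sweep(measures = c("eells", "effect_information"),
                 dilution = c(0, 0.5, 1), rewiring = c(0, 1),
                 scopes = c("main", "expectation"))
  expect_equal(nrow(sw), 2 * 3 * 2 * 2)
  expect_true(all(!is.nan(sw$ce)))
  expect_true(all(is.na(sw$ce) == !sw$defined))
  # deterministic output: rerun is identical
  sw2 <- ce_sweep(measures = c("eells", "effect_information"),
                  dilution = c(0, 0.5, 1), rewiring = c(0, 1),
                  scopes = c("main", "expectation"))
  expect_identical(sw, sw2)
})
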