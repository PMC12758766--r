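test_that("odds transform behaves at the boundaries", {
  expect_equal(odds(0.5), 1)
  expect_equal(odds(0), 0)
  expect_equal(odds(0.111), 0.111 / 0.889)
  expect_identical(odds(1), Inf)
  expect_error(odds(1.2), "\\[0, 1\\]")
  expect_error(odds(-0.1), "\\[0, 1\\]")
})

test_that("electivity index reproduces published diet-selection values from counts", {
  ref <- reference_electivity()
  for (season in names(ref)) {
    blk <- ref[[season]]
    G <- counts_from_percent(blk$rows$gut_pct, blk$N_G)
    A <- counts_from_percent(blk$rows$habitat_pct, blk$N_A)
    X <- electivity_index(G / blk$N_G, A / blk$N_A)
    expect_equal(round(X, 3), blk$rows$index,
                 info = paste("season:", season))
  }
})

test_that("electivity index is antisymmetric, monotone and bounded", {
  set.seed(5)
  g <- runif(50, 0.01, 0.99)
  a <- runif(50, 0.01, 0.99)
  X <- electivity_index(g, a)
  expect_true(all(X >= 0 & X <= 1))
  expect_equal(electivity_index(a, g), 1 - X, tolerance = 1e-12)
  expect_equal(electivity_index(0.3, 0.3), 0.5)
  # strictly increasing in g, decreasing in a
  gg <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(electivity_index(gg, 0.4)) > 0))
  expect_true(all(diff(electivity_index(0.4, gg)) < 0))
  # undefined when the taxon is absent from the habitat but eaten
  expect_true(is.na(electivity_index(0.2, 0)))
})

test_that("beta Monte-Carlo intervals are seed-deterministic and stable", {
  ci1 <- beta_mc_ci(1, 9, 2, 40, seed = 99)
  ci2 <- beta_mc_ci(1, 9, 2, 40, seed = 99)
  expect_identical(ci1, ci2)

  # across seeds each endpoint wobbles by less than 0.02 around its center
  # at 10k draws
  cis <- t(vapply(1:20, function(s) beta_mc_ci(1, 9, 2, 40, seed = s),
                  numeric(2L)))
  expect_lt(max(abs(cis[, 1] - mean(cis[, 1]))), 0.02)
  expect_lt(max(abs(cis[, 2] - mean(cis[, 2]))), 0.02)

  # the interval brackets the point estimate and is comparably wide to the
  # published 0.231-0.956 for these counts
  X <- electivity_index(1 / 9, 2 / 40)
  expect_true(all(cis[, 1] < X & X < cis[, 2]))
  expect_true(all(cis[, 1] > 0.05 & cis[, 1] < 0.45))
  expect_true(all(cis[, 2] > 0.85))
  expect_error(beta_mc_ci(5, 3, 1, 10), "invalid gut")
})

test_that("interval-based classification follows the 0.5 overlap rule", {
  expect_equal(classify_selection(0.818, 0.448, 0.957), "none")
  expect_equal(classify_selection(0.9, 0.6, 0.99), "positive")
  expect_equal(classify_selection(0.2, 0.05, 0.45), "negative")
  expect_equal(classify_selection(NA, 0.1, 0.9), "undefined")

  # equal gut/habitat proportions: the interval straddles 0.5 for
  # essentially every seed
  cls <- vapply(1:20, function(s) {
    ci <- beta_mc_ci(5, 50, 5, 50, seed = s)
    classify_selection(0.5, ci[["ci_low"]], ci[["ci_high"]])
  }, character(1L))
  expect_gte(mean(cls == "none"), 0.95)

  # extreme counts: everything in guts, nothing in the habitat sample
  ci <- beta_mc_ci(20, 20, 0, 40, seed = 1)
  expect_gt(ci[["ci_low"]], 0.5)
})

test_that("electivity tables mirror the published layout and edge cases", {
  ref <- reference_electivity()$summer
  # the gut also held one prey taxon absent from the habitat aliquot,
  # completing the total of 9 identified gut items
  gut <- composition_table(
    c(ref$rows$taxon, "Pontellina plumata"),
    c(counts_from_percent(ref$rows$gut_pct, ref$N_G), 1L))
  # summer habitat aliquot: the four shared taxa plus the rest of the 40
  habitat <- composition_table(
    c(ref$rows$taxon, "other"),
    c(counts_from_percent(ref$rows$habitat_pct, ref$N_A), 24L))
  tab <- electivity_table(gut, habitat, n_sims = 2000, seed = 4)
  shared <- match(ref$rows$taxon, tab$taxon)
  expect_equal(round(tab$index[shared], 3), ref$rows$index)
  expect_true(all(tab$classification[shared] == "none"))
  # the pooled remainder was never eaten: no index, like the dashes
  expect_true(is.na(tab$index[tab$taxon == "other"]))

  # gut-only taxon is undefined
  gut2 <- composition_table(c("a", "b"), c(3L, 2L))
  hab2 <- composition_table(c("a", "c"), c(10L, 5L))
  tab2 <- electivity_table(gut2, hab2, n_sims = 500, seed = 1)
  expect_equal(tab2$classification[tab2$taxon == "b"], "undefined")
  expect_true(is.na(tab2$index[tab2$taxon == "c"]))

  # identical compositions give 0.5 everywhere
  same <- composition_table(c("a", "b"), c(6L, 4L))
  tab3 <- electivity_table(same, same, n_sims = 500, seed = 2)
  expect_equal(tab3$index, c(0.5, 0.5))
})

test_that("count reconstruction from printed percentages is exact-rational", {
  expect_equal(counts_from_percent(c(11.1, 33.3), 9), c(1L, 3L))
  expect_equal(counts_from_percent(c(4.3, 21.7, 8.7, 39.1), 23),
               c(1L, 5L, 2L, 9L))
  expect_error(counts_from_percent(12.0, 9), "not consistent")
  expect_error(counts_from_percent(101, 9), "\\[0, 100\\]")
})
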