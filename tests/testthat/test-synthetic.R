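test_that("station-grid generation is seed-deterministic", {
  cfg <- scenario_config("summer", "neritic", n_stations = 6, seed = 31)
  g1 <- generate_station_grid(cfg)
  g2 <- generate_station_grid(cfg)
  expect_identical(g1, g2)
  g3 <- generate_station_grid(scenario_config("summer", "neritic",
                                              n_stations = 6, seed = 32))
  expect_false(identical(g1$stations$temp_c, g3$stations$temp_c))
  expect_error(scenario_config("summer", "neritic", n_stations = 0, seed = 1),
               ">= 1")
  expect_error(scenario_config("summer", "neritic", n_stations = 5), "seed")
})

test_that("generated densities match the configured stratum means in the large-sample limit", {
  cfg <- scenario_config("summer", "neritic", n_stations = 10000, seed = 33)
  g <- generate_station_grid(cfg)
  expect_lt(abs(mean(g$stations$copepod_density_ind_m3) - 205.2) / 205.2, 0.02)
  expect_true(all(g$stations$copepod_density_ind_m3 > 0))
})

test_that("generated temperatures honor the configured seasonal range", {
  cfg <- scenario_config("winter", "neritic", n_stations = 400, seed = 34)
  g <- generate_station_grid(cfg)
  expect_true(all(g$stations$temp_c >= 18.7 & g$stations$temp_c <= 22.0))
  expect_equal(unique(g$stations$wind_speed_m_s), 3.87)
})

test_that("CTD casts integrate back to the drawn station values exactly", {
  cfg <- scenario_config("fall", "oceanic", n_stations = 5, seed = 35)
  g <- generate_station_grid(cfg)
  for (i in seq_len(nrow(g$stations))) {
    prof <- g$ctd[g$ctd$station_id == g$stations$station_id[i], ]
    expect_equal(integrate_upper_layer(prof$depth_m, prof$temp_c),
                 g$stations$temp_c[i], tolerance = 1e-10)
    expect_equal(integrate_upper_layer(prof$depth_m, prof$sal_psu),
                 g$stations$sal_psu[i], tolerance = 1e-10)
  }
})

test_that("gut-survey generation hits the requested gut fullness", {
  expect_equal(generate_gut_survey(50, 0, seed = 36)$counts, rep(0L, 50))
  g <- generate_gut_survey(10000, 0.04, seed = 37)
  expect_true(g$NPC >= 0.035 && g$NPC <= 0.045)
  gp <- generate_gut_survey(5000, 2.5, seed = 38, mode = "poisson")
  expect_equal(gp$NPC, 2.5, tolerance = 0.05)
  expect_error(generate_gut_survey(10, 1.5, seed = 1), "poisson")
  expect_error(generate_gut_survey(10, -0.1, seed = 1), ">= 0")
})

test_that("diet-pair generation embeds a known selection ground truth", {
  taxa <- paste0("t", 1:5)
  probs <- c(0.3, 0.25, 0.2, 0.15, 0.1)

  # null odds: every estimated index near 0.5
  pair <- generate_diet_pair(taxa, probs, selection_odds = 1,
                             N_G = 5000, N_A = 5000, seed = 39)
  X <- electivity_index(pair$gut$prop, pair$habitat$prop)
  expect_true(all(abs(X - 0.5) < 0.05))

  # a single preferred taxon: its odds ratio recovers the tilt
  odds_vec <- c(1, 1, 1, 1, 4.5)
  probs2 <- c(0.4, 0.2, 0.2, 0.1, 0.1)
  pair2 <- generate_diet_pair(taxa, probs2, selection_odds = odds_vec,
                              N_G = 50000, N_A = 50000, seed = 40)
  X5 <- electivity_index(pair2$gut$prop[5], pair2$habitat$prop[5])
  # expected index when only one taxon is tilted from a 10% baseline
  g_exp <- 0.1 * 4.5 / (0.9 + 0.45)
  X_exp <- electivity_index(g_exp, 0.1)
  expect_equal(X5, X_exp, tolerance = 0.03)
  expect_equal(round(X_exp, 3), 0.818)

  expect_error(generate_diet_pair(taxa, probs[-1], 1, 10, 10, seed = 1),
               "lengths differ")
  expect_error(generate_diet_pair(taxa, probs * 2, 1, 10, 10, seed = 1),
               "sum to 1")
})

test_that("selection detection gains power with gut-sample size", {
  # a 4.5-fold preference is invisible at 9 gut items but detectable at 200
  # habitat aliquot held at the field-survey scale of 40 individuals
  classify_rep <- function(N_G, seeds) {
    vapply(seeds, function(s) {
      pair <- generate_diet_pair(paste0("t", 1:5), c(0.4, 0.2, 0.2, 0.1, 0.1),
                                 selection_odds = c(1, 1, 1, 1, 4.5),
                                 N_G = N_G, N_A = 40, seed = s)
      i <- 5L
      ci <- beta_mc_ci(pair$gut$count[i], pair$gut$total,
                       pair$habitat$count[i], pair$habitat$total,
                       n_sims = 2000, seed = s)
      classify_selection(0.8, ci[["ci_low"]], ci[["ci_high"]])
    }, character(1L))
  }
  small <- classify_rep(9, 1:40)
  large <- classify_rep(200, 1:40)
  expect_gt(mean(small == "none"), 0.5)
  expect_gt(mean(large == "positive"), 0.5)
  expect_gt(mean(large == "positive"), mean(small == "positive"))
})

test_that("null feeding rates give uniform PERMANOVA p-values end-to-end", {
  # feeding rates independent of season and zone: the permutation p of the
  # season term should be uniform over repeated generated datasets
  set.seed(41)
  a <- gl(3, 8, labels = c("summer", "fall", "winter"))
  b <- gl(2, 4, 24, labels = c("neritic", "oceanic"))
  pvals <- vapply(1:200, function(i) {
    fr <- rlnorm(24, log(0.8), 0.4)
    permanova_two_way(euclidean_distance_matrix(fr), a, b,
                      n_perm = 99, seed = 1000 + i)$p_perm[1]
  }, numeric(1L))
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})
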