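test_that("synthetic sites span the study gradient with colder sites closer", {
  sc <- synthetic_scenario(seed = 2)
  sites <- make_sites(sc)
  expect_identical(nrow(sites), 6L)
  expect_equal(range(sites$t_air_c), c(0, 7))
  expect_equal(range(sites$distance_km_override), c(1940, 3093))
  # negative co-variation: distance increases with temperature
  o <- order(sites$t_air_c)
  expect_true(all(diff(sites$distance_km_override[o]) > 0))
  expect_true(all(sites$wind_ms >= 4 & sites$wind_ms <= 8))
  expect_true(all(sites$radiation_wm2 >= 40 & sites$radiation_wm2 <= 80))
  # determinism
  expect_identical(make_sites(sc), make_sites(sc))
  # single site generates, but site-level tests refuse gracefully
  s1 <- make_sites(synthetic_scenario(n_sites = 1, seed = 2))
  expect_identical(nrow(s1), 1L)
  c1 <- make_counts(synthetic_scenario("null", n_sites = 1, seed = 2), s1)
  expect_error(site_effect_test(c1), "2 sites")
})

test_that("synthetic benthos honours explicit site moments and the layer coupling", {
  # zero SD collapses all cores onto the site mean
  bp <- data.frame(site = "S01", top_mean = 2, top_sd = 0,
                   bottom_mean = 8, bottom_sd = 0)
  sc0 <- synthetic_scenario(n_sites = 1, benthos_params = bp, seed = 8)
  cores <- make_benthos(sc0, make_sites(sc0))
  s <- summarize_benthos(cores)
  expect_equal(s$top_mean, 2, tolerance = 1e-9)
  expect_equal(s$bottom_mean, 8, tolerance = 1e-9)
  expect_equal(s$top_sd, 0, tolerance = 1e-12)
  # determinism
  sc <- synthetic_scenario(seed = 9)
  sites <- make_sites(sc)
  expect_identical(make_benthos(sc, sites), make_benthos(sc, sites))
  # large-n: within-site layers positively correlated, near the 0.5 calibration
  scl <- synthetic_scenario(n_sites = 1, n_cores_per_site = 10000, seed = 10,
                            benthos_params = data.frame(
                              site = "S01", top_mean = 1.5, top_sd = 1.2,
                              bottom_mean = 8, bottom_sd = 7.2))
  big <- make_benthos(scl, make_sites(scl))
  dens <- layer_density(ash_free_dry_mass(big$dry_mass_g, big$ash_mass_g),
                        big$core_area_m2)
  r <- cor(dens[big$layer == "top"], dens[big$layer == "bottom"])
  expect_gt(r, 0.4)
  expect_lt(r, 0.6)
})

test_that("null counts are unbiased and count generation is deterministic", {
  sc <- synthetic_scenario("null", n_sites = 2, n_sessions_per_site = 500, seed = 12)
  sites <- make_sites(sc)
  counts <- make_counts(sc, sites)
  expect_true(all(counts$n_male + counts$n_female >= 10))
  pf <- sum(counts$n_female) / sum(counts$n_male + counts$n_female)
  expect_lt(abs(pf - 0.5), 0.02)
  expect_identical(make_counts(sc, sites), make_counts(sc, sites))
  # hypothesis links demand their drivers
  scr <- synthetic_scenario("resource_partitioning", seed = 12)
  expect_error(make_counts(scr, sites), "benthos_summary")
  scb <- synthetic_scenario("bergmann", seed = 12)
  expect_error(make_counts(scb, sites), "costs")
})

test_that("session sizes follow the truncated flock-size distribution", {
  sc <- synthetic_scenario("null", n_sites = 1, n_sessions_per_site = 3000, seed = 21)
  counts <- make_counts(sc, make_sites(sc))
  n <- counts$n_male + counts$n_female
  expect_true(all(n >= 10))
  # truncation at 10 lifts the mean above 117; moments near the target
  expect_lt(abs(mean(n) - 140) / 140, 0.1)
  expect_gt(sd(n), 70)
})

test_that("synthetic APS respects null and boundary regimes", {
  # no effects: group means statistically indistinguishable
  sc0 <- synthetic_scenario("null", seed = 25, aps_cost_slope = 0,
                            aps_male_effect = 0, aps_interaction = 0)
  sites <- make_sites(sc0); costs <- wintering_cost(sites)
  aps <- make_aps(sc0, sites, costs)
  a <- one_way_anova(aps$score, paste(aps$site, aps$sex))
  expect_gt(a$p_value, 0.01)
  # latent far below the lowest cut: every score is 1
  scb <- synthetic_scenario("null", seed = 25, aps_intercept = -10)
  apsb <- make_aps(scb, sites, costs)
  expect_true(all(apsb$score == 1L))
  expect_identical(make_aps(sc0, sites, costs), make_aps(sc0, sites, costs))
})

test_that("a full study is a pure function of its scenario", {
  sc <- synthetic_scenario(seed = 33)
  s1 <- generate_study(sc)
  s2 <- generate_study(sc)
  expect_identical(s1$sites, s2$sites)
  expect_identical(s1$cores, s2$cores)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$aps, s2$aps)
  # stages regenerate independently from the root seed
  expect_identical(make_benthos(sc, s1$sites), s1$cores)
})
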