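test_that("basal metabolic rate follows the temperate-shorebird allometry", {
  # frozen from hand evaluation of 5.06 * BM^0.729
  expect_equal(basal_metabolic_rate(0.270), 1.94811549608, tolerance = 1e-9)
  expect_equal(basal_metabolic_rate(0.323), 2.22003159674, tolerance = 1e-9)
  # allometric exponent < 1: per-kg rate declines with mass
  expect_lt(basal_metabolic_rate(0.323) / 0.323, basal_metabolic_rate(0.270) / 0.270)
  masses <- seq(0.1, 1.0, by = 0.05)
  expect_true(all(diff(basal_metabolic_rate(masses) / masses) < 0))
  expect_true(all(diff(basal_metabolic_rate(masses)) > 0))
  expect_error(basal_metabolic_rate(0), "positive")
  expect_error(basal_metabolic_rate(-0.3), "positive")
})

test_that("standardized heat loss responds to each climate forcing as physics demands", {
  f <- sex_profile("female")
  coeffs <- heat_loss_coefficients()
  # no gradient, no wind, no sun: exactly zero
  expect_identical(
    standardized_heat_loss(f, coeffs, climate_conditions(41, 0, 0)), 0)
  # frozen hand evaluation: 0.1111*41*(1 + 0.3*sqrt(7)) - 0.002*45
  expect_equal(
    standardized_heat_loss(f, coeffs, climate_conditions(0, 7, 45)),
    8.08059853911, tolerance = 1e-9)
  hl <- function(t_air, wind = 7, rad = 45, p = f)
    standardized_heat_loss(p, coeffs, climate_conditions(t_air, wind, rad))
  expect_gt(hl(0), hl(7))                       # colder -> more loss
  expect_gte(hl(0, wind = 10), hl(0, wind = 5)) # windier -> more loss
  expect_lte(hl(0, rad = 80), hl(0, rad = 40))  # sunnier -> less loss
  # conductance scaling of the conductive term (radiation off)
  m <- sex_profile("male")
  expect_equal(hl(0, rad = 0, p = f) / hl(0, rad = 0, p = m),
               f$thermal_conductance / m$thermal_conductance)
  # floored at zero at warm, calm, sunny conditions
  expect_identical(hl(40.9, wind = 0, rad = 1000), 0)
})

test_that("maintenance cost is BMR plus heat loss", {
  expect_identical(maintenance_cost(2, 3), 5)
  expect_identical(maintenance_cost(2, 0), 2)
  expect_error(maintenance_cost(-1, 0), ">= 0")
  expect_error(maintenance_cost(2, -0.1), ">= 0")
})

test_that("great-circle distance is a haversine agreeing with its independent oracle", {
  expect_identical(great_circle_distance(55, 8, 55, 8), 0)
  # wintering site -> breeding grounds, frozen haversine value
  bg <- breeding_grounds()
  d <- great_circle_distance(55 + 1 / 60, 8 + 26 / 60, bg["lat"], bg["lon"])
  expect_equal(unname(d), 1861.645, tolerance = 1e-3)
  # symmetry and antipodal maximum
  expect_equal(great_circle_distance(10, 20, -30, 100),
               great_circle_distance(-30, 100, 10, 20))
  expect_equal(great_circle_distance(0, 0, 0, 180), pi * 6371, tolerance = 1e-9)
  # random pairs vs spherical law of cosines
  set.seed(42)
  la1 <- runif(50, -85, 85); lo1 <- runif(50, -180, 180)
  la2 <- runif(50, -85, 85); lo2 <- runif(50, -180, 180)
  expect_equal(great_circle_distance(la1, lo1, la2, lo2),
               slc_distance(la1, lo1, la2, lo2), tolerance = 1e-8)
  expect_error(great_circle_distance(91, 0, 0, 0), "latitude")
  expect_error(great_circle_distance(0, 200, 0, 0), "longitude")
})

test_that("migration cost is linear in distance with the sex-specific rate", {
  f <- sex_profile("female"); m <- sex_profile("male")
  expect_identical(migration_cost(0, f), 0)
  expect_equal(migration_cost(1940, f), 3466.13333333, tolerance = 1e-8)
  expect_equal(migration_cost(1940, m), 2845.33333333, tolerance = 1e-8)
  expect_equal(migration_cost(2 * 1234, f), 2 * migration_cost(1234, f))
  expect_gt(migration_cost(1000, f), migration_cost(1000, m))
  expect_error(migration_cost(-5, f), ">= 0")
})

test_that("wintering cost table is internally consistent and uses distance overrides", {
  sites <- table1_sites()
  costs <- wintering_cost(sites)
  cfg <- energetics_config()
  expect_setequal(costs$site, sites$site)
  expect_equal(costs$maintenance_w, costs$bmr_w + costs$heat_loss_w)
  expect_true(all(costs$maintenance_w >= costs$bmr_w))
  expect_equal(costs$seasonal_total_kj,
               costs$maintenance_w * cfg$winter_days * 86.4 + costs$migration_kj)
  # recorded one-way route distances are used verbatim
  expect_setequal(costs$distance_km, sites$distance_km_override)
  # females always pay more than males
  wide <- merge(costs[costs$sex == "female", c("site", "seasonal_total_kj")],
                costs[costs$sex == "male", c("site", "seasonal_total_kj")],
                by = "site", suffixes = c("_f", "_m"))
  expect_true(all(wide$seasonal_total_kj_f > wide$seasonal_total_kj_m))
  # migration is a small fraction of the seasonal budget, order a few percent
  share <- costs$migration_kj / (costs$seasonal_total_kj - costs$migration_kj)
  expect_true(all(share > 0.005 & share < 0.08))
  # without an override the haversine from lat/lon is used
  s2 <- sites; s2$distance_km_override <- NA
  bg <- breeding_grounds()
  c2 <- wintering_cost(s2)
  expect_equal(sort(unique(c2$distance_km)),
               sort(unname(great_circle_distance(sites$lat, sites$lon, bg["lat"], bg["lon"]))))
  expect_error(wintering_cost(sites[, c("site", "t_air_c")]), "climate")
})

test_that("seasonal cost falls monotonically along the temperature gradient at fixed distance", {
  sites <- table1_sites()
  sites <- sites[order(sites$t_air_c), ]
  sites$distance_km_override <- 2200   # hold migration fixed, vary climate only
  for (sex in c("female", "male")) {
    costs <- wintering_cost(sites, profiles = list(sex_profile(sex)))
    costs <- costs[match(sites$site, costs$site), ]
    expect_true(all(diff(costs$seasonal_total_kj) < 0))
  }
})
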