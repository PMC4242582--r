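#' Sex-specific physiological and flight parameters
#'
#' Bundles the three sex-specific constants of the wintering-cost model:
#' winter body mass (kg), thermal conductance of a live bird (W per degree C)
#' and the empirical flight-cost rate (kJ per hour). Defaults are the mean
#' winter-catch values for bar-tailed godwits: males 0.270 kg, conductance
#' 0.0914, flight cost 55 kJ/h; females 0.323 kg, 0.1111, 67 kJ/h.
#'
#' @param sex "male" or "female".
#' @param body_mass Body mass in kg (> 0).
#' @param thermal_conductance Whole-bird thermal conductance in W per degree C (> 0).
#' @param flight_cost_rate Flight cost in kJ per hour (> 0).
#' @return An object of class `sex_profile`.
#' @examples
#' sex_profile("female")
#' sex_profile("male", body_mass = 0.25)
#' @export
sex_profile <- function(sex = c("female", "male"),
                        body_mass = NULL,
                        thermal_conductance = NULL,
                        flight_cost_rate = NULL) {
  sex <- match.arg(sex)
  defaults <- list(
    male   = list(body_mass = 0.270, thermal_conductance = 0.0914, flight_cost_rate = 55),
    female = list(body_mass = 0.323, thermal_conductance = 0.1111, flight_cost_rate = 67)
  )[[sex]]
  p <- list(
    sex = sex,
    body_mass = if (is.null(body_mass)) defaults$body_mass else body_mass,
    thermal_conductance = if (is.null(thermal_conductance)) defaults$thermal_conductance else thermal_conductance,
    flight_cost_rate = if (is.null(flight_cost_rate)) defaults$flight_cost_rate else flight_cost_rate
  )
  for (f in c("body_mass", "thermal_conductance", "flight_cost_rate")) {
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1L || !is.finite(p[[f]]) || p[[f]] <= 0)
      stop("'", f, "' must be a single positive number", call. = FALSE)
  }
  structure(p, class = "sex_profile")
}

#' @export
print.sex_profile <- function(x, ...) {
  cat(sprintf("<sex_profile> %s: BM = %.3f kg, K_es = %.4f W/degC, C_sex = %g kJ/h\n",
              x$sex, x$body_mass, x$thermal_conductance, x$flight_cost_rate))
  invisible(x)
}

#' Heat-loss model coefficients
#'
#' Coefficients of the standardized-heat-loss equation: the wind coefficient
#' `K_u` and wind-speed exponent act multiplicatively on the conductive term,
#' the radiation coefficient `K_r` converts global radiation (W/m^2) into a
#' reduction of heat loss (W), and `body_temperature` is the assumed core
#' temperature (41 degrees C for both sexes). The original regression values
#' of `K_u`, `K_r` and the exponent are not in the public record, so the
#' defaults here are documented placeholders: `K_u = 0.30` with exponent 0.5
#' (convective loss growing with the square root of wind speed) and
#' `K_r = 0.002`. Every cost table records the values actually used.
#'
#' @param K_u Wind coefficient (>= 0).
#' @param K_r Radiation coefficient (>= 0), W of heat-loss relief per W/m^2.
#' @param wind_exponent Exponent on wind speed (finite).
#' @param body_temperature Core body temperature in degrees C, in (35, 45).
#' @return An object of class `heat_loss_coefficients`.
#' @export
heat_loss_coefficients <- function(K_u = 0.30, K_r = 0.002,
                                   wind_exponent = 0.5, body_temperature = 41) {
  stopifnot(is.numeric(K_u), length(K_u) == 1L, is.finite(K_u), K_u >= 0,
            is.numeric(K_r), length(K_r) == 1L, is.finite(K_r), K_r >= 0,
            is.numeric(wind_exponent), length(wind_exponent) == 1L, is.finite(wind_exponent))
  if (!is.numeric(body_temperature) || length(body_temperature) != 1L ||
      body_temperature <= 35 || body_temperature >= 45)
    stop("'body_temperature' must lie in (35, 45) degrees C", call. = FALSE)
  structure(list(K_u = K_u, K_r = K_r, wind_exponent = wind_exponent,
                 body_temperature = body_temperature),
            class = "heat_loss_coefficients")
}

#' Site climate forcing
#'
#' @param t_air Mean winter (October-March) air temperature, degrees C.
#' @param wind Mean winter wind speed, m/s (>= 0).
#' @param radiation Mean winter global radiation, W/m^2 (>= 0).
#' @return An object of class `climate_conditions`. All fields may be vectors
#'   of equal length for multi-site use.
#' @export
climate_conditions <- function(t_air, wind, radiation) {
  stopifnot(is.numeric(t_air), is.numeric(wind), is.numeric(radiation))
  n <- max(length(t_air), length(wind), length(radiation))
  t_air <- rep_len(t_air, n); wind <- rep_len(wind, n); radiation <- rep_len(radiation, n)
  if (any(!is.finite(t_air)) || any(!is.finite(wind)) || any(!is.finite(radiation)))
    stop("climate values must be finite", call. = FALSE)
  if (any(wind < 0)) stop("'wind' must be >= 0", call. = FALSE)
  if (any(radiation < 0)) stop("'radiation' must be >= 0", call. = FALSE)
  structure(list(t_air = t_air, wind = wind, radiation = radiation),
            class = "climate_conditions")
}

#' Model configuration constants
#'
#' @param flight_speed Average migratory flight speed, km/h (default 75).
#' @param winter_days Length of the winter season used to integrate
#'   maintenance power to seasonal energy (default 182 days, October-March).
#' @param earth_radius_km Sphere radius for great-circle distances (default 6371).
#' @return An object of class `energetics_config`.
#' @export
energetics_config <- function(flight_speed = 75, winter_days = 182,
                              earth_radius_km = 6371) {
  stopifnot(is.numeric(flight_speed), flight_speed > 0,
            is.numeric(winter_days), winter_days > 0,
            is.numeric(earth_radius_km), earth_radius_km > 0)
  structure(list(flight_speed = flight_speed, winter_days = winter_days,
                 earth_radius_km = earth_radius_km),
            class = "energetics_config")
}

#' Breeding-grounds reference coordinate
#'
#' Fixed point in northern Norway (70 deg 16' N, 24 deg 05' E) used as the
#' destination for all migration distances.
#'
#' @return Named numeric vector `c(lat, lon)` in decimal degrees.
#' @export
breeding_grounds <- function() c(lat = 70 + 16 / 60, lon = 24 + 5 / 60)

#' Basal metabolic rate of a temperate-wintering shorebird
#'
#' Mass allometry for shorebirds wintering in temperate Europe:
#' \deqn{BMR = 5.06 \cdot BM^{0.729}}
#' with BM in kg and BMR in W. The exponent below 1 makes the mass-specific
#' rate (W/kg) decline with body mass, which is the energetic core of the
#' Bergmann argument: the larger sex radiates less heat per unit mass.
#'
#' @param body_mass Body mass in kg; may be a vector, all entries > 0.
#' @return BMR in W.
#' @examples
#' basal_metabolic_rate(c(male = 0.270, female = 0.323))
#' @export
basal_metabolic_rate <- function(body_mass) {
  if (!is.numeric(body_mass) || any(!is.finite(body_mass)) || any(body_mass <= 0))
    stop("'body_mass' must be positive and finite", call. = FALSE)
  5.06 * body_mass^0.729
}

#' Standardized heat loss
#'
#' Thermoregulatory power demand of a bird exposed to the stated air
#' temperature, wind speed and global radiation:
#' \deqn{H_{sm} = \max\{0,\; K_{es} (T_b - T_a)(1 + K_u u^{exp}) - K_r R_g\}}
#' The conductive term scales with the bird's thermal conductance and the
#' body-air temperature gradient, wind inflates it, and solar radiation
#' offsets part of it. The result is floored at zero: heat loss is an *extra*
#' cost on top of basal metabolism and cannot subsidise it at warm sites.
#'
#' @param profile A [sex_profile].
#' @param coeffs A [heat_loss_coefficients].
#' @param climate A [climate_conditions]; vector fields give vector output.
#' @return Heat loss in W (>= 0), one value per climate entry.
#' @export
standardized_heat_loss <- function(profile, coeffs = heat_loss_coefficients(),
                                   climate) {
  stopifnot(inherits(profile, "sex_profile"),
            inherits(coeffs, "heat_loss_coefficients"),
            inherits(climate, "climate_conditions"))
  gradient <- coeffs$body_temperature - climate$t_air
  conductive <- profile$thermal_conductance * gradient *
    (1 + coeffs$K_u * climate$wind^coeffs$wind_exponent)
  pmax(0, conductive - coeffs$K_r * climate$radiation)
}

#' Maintenance cost
#'
#' Maintenance power is basal metabolic rate plus the extra thermoregulatory
#' cost (standardized heat loss): `M_maint = BMR + H_sm`, in W.
#'
#' @param bmr Basal metabolic rate, W (>= 0).
#' @param heat_loss Standardized heat loss, W (>= 0).
#' @return Maintenance power in W.
#' @export
maintenance_cost <- function(bmr, heat_loss) {
  if (!is.numeric(bmr) || any(bmr < 0)) stop("'bmr' must be >= 0", call. = FALSE)
  if (!is.numeric(heat_loss) || any(heat_loss < 0)) stop("'heat_loss' must be >= 0", call. = FALSE)
  bmr + heat_loss
}

#' Great-circle (orthodrome) distance
#'
#' Haversine distance on a sphere of radius `radius_km` between points given
#' in decimal degrees. Vectorized over coordinates.
#'
#' @param lat1,lon1 Origin latitude/longitude, decimal degrees.
#' @param lat2,lon2 Destination latitude/longitude, decimal degrees.
#' @param radius_km Sphere radius in km (default 6371).
#' @return Distance in km.
#' @examples
#' great_circle_distance(55.0167, 8.4333, 70.2667, 24.0833) # ~1862 km
#' @export
great_circle_distance <- function(lat1, lon1, lat2, lon2, radius_km = 6371) {
  if (any(abs(c(lat1, lat2)) > 90)) stop("latitude out of [-90, 90]", call. = FALSE)
  if (any(abs(c(lon1, lon2)) > 180)) stop("longitude out of [-180, 180]", call. = FALSE)
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 + cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * radius_km * asin(pmin(1, sqrt(a)))
}

#' Round-trip migration cost
#'
#' \deqn{C_{flight} = \frac{2 D}{S} C_{sex}} with one-way distance D (km),
#' flight speed S (km/h, default 75) and the sex-specific flight-cost rate
#' (kJ/h). Linear in distance; at equal distance females pay more than males
#' (67 vs 55 kJ/h).
#'
#' @param distance_km One-way distance to the breeding grounds, km (>= 0).
#' @param profile A [sex_profile].
#' @param config An [energetics_config].
#' @return Round-trip migration cost in kJ.
#' @examples
#' migration_cost(1940, sex_profile("female")) # ~3466 kJ
#' @export
migration_cost <- function(distance_km, profile, config = energetics_config()) {
  stopifnot(inherits(profile, "sex_profile"), inherits(config, "energetics_config"))
  if (!is.numeric(distance_km) || any(distance_km < 0))
    stop("'distance_km' must be >= 0", call. = FALSE)
  (2 * distance_km / config$flight_speed) * profile$flight_cost_rate
}

# kJ delivered by 1 W sustained for one day
.KJ_PER_WATT_DAY <- 86.4

#' Full wintering-cost breakdown per site and sex
#'
#' Evaluates the complete cost model on a site table: BMR, standardized heat
#' loss, maintenance power, one-way migration distance (per-site override if
#' present, otherwise a haversine to the breeding grounds), round-trip
#' migration cost, and the seasonal total
#' `maintenance * winter_days * 86.4 + migration` in kJ.
#'
#' @param sites Data frame with columns `site`, `t_air_c`, `wind_ms`,
#'   `radiation_wm2` and either `distance_km_override` or `lat`/`lon`.
#' @param profiles List of [sex_profile] objects (default both sexes).
#' @param coeffs A [heat_loss_coefficients].
#' @param config An [energetics_config].
#' @return Data frame with one row per site x sex: `site`, `sex`, `bmr_w`,
#'   `heat_loss_w`, `maintenance_w`, `distance_km`, `migration_kj`,
#'   `seasonal_total_kj`. The coefficient values used are attached as
#'   attribute `"parameters"` for provenance.
#' @export
wintering_cost <- function(sites,
                           profiles = list(sex_profile("male"), sex_profile("female")),
                           coeffs = heat_loss_coefficients(),
                           config = energetics_config()) {
  required <- c("site", "t_air_c", "wind_ms", "radiation_wm2")
  missing_cols <- setdiff(required, names(sites))
  if (length(missing_cols))
    stop("site table lacks climate columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  dist <- .resolve_distances(sites, config)
  climate <- climate_conditions(sites$t_air_c, sites$wind_ms, sites$radiation_wm2)
  out <- do.call(rbind, lapply(profiles, function(p) {
    bmr <- basal_metabolic_rate(p$body_mass)
    hl <- standardized_heat_loss(p, coeffs, climate)
    maint <- maintenance_cost(bmr, hl)
    mig <- migration_cost(dist, p, config)
    data.frame(site = as.character(sites$site), sex = p$sex,
               bmr_w = bmr, heat_loss_w = hl, maintenance_w = maint,
               distance_km = dist, migration_kj = mig,
               seasonal_total_kj = maint * config$winter_days * .KJ_PER_WATT_DAY + mig,
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$distance_km, out$site, out$sex), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "parameters") <- list(
    coefficients = unclass(coeffs), config = unclass(config),
    profiles = lapply(profiles, unclass)
  )
  out
}

.resolve_distances <- function(sites, config) {
  n <- nrow(sites)
  dist <- rep(NA_real_, n)
  if ("distance_km_override" %in% names(sites))
    dist <- as.numeric(sites$distance_km_override)
  need <- is.na(dist)
  if (any(need)) {
    if (!all(c("lat", "lon") %in% names(sites)))
      stop("sites without 'distance_km_override' need 'lat'/'lon' columns", call. = FALSE)
    bg <- breeding_grounds()
    dist[need] <- great_circle_distance(sites$lat[need], sites$lon[need],
                                        bg["lat"], bg["lon"],
                                        radius_km = config$earth_radius_km)
  }
  if (any(is.na(dist) | dist < 0))
    stop("could not resolve a non-negative distance for every site", call. = FALSE)
  dist
}
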