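#' Define a synthetic study scenario
#'
#' A scenario fixes every parameter of the synthetic study generator: the
#' named generative hypothesis that links site sex ratios to site
#' properties, the sampling design (sites, cores, scan sessions), the
#' climate/distance gradient, the benthos model, and the abdominal-profile
#' model. Together with a seed it determines the generated study completely.
#'
#' The three hypotheses set the site-level probability that a scanned bird
#' is female through a logit link:
#' \itemize{
#'   \item `resource_partitioning`: `logit(pF) = a + b * (bottom_pct / 100)`
#'     -- females go where the biomass is buried deep (defaults a = -6.4,
#'     b = 8, spanning roughly 25-75% female across typical sites);
#'   \item `bergmann`: `logit(pF) = a + b * z(cost)` with the site wintering
#'     cost standardized across sites (defaults a = 0, b = 1);
#'   \item `null`: `logit(pF) = a` (default a = 0, i.e. 50:50 everywhere).
#' }
#'
#' The benthos model draws, per site, a latent depth-resource factor `f`
#' that simultaneously raises the bottom-layer share of biomass and the
#' bottom-layer density while lowering the top-layer density (sites rich in
#' deep-living prey such as lugworms are exactly the sites where little
#' biomass sits near the surface). Within a site, the two layers of a core
#' share a common local-richness factor with loading `layer_coupling`
#' (default 0.76, giving a within-site core-level top/bottom correlation of
#' about 0.5).
#'
#' @param hypothesis One of "resource_partitioning", "bergmann", "null".
#' @param n_sites,n_cores_per_site,n_sessions_per_site Sampling design
#'   (defaults 6, 10, 10).
#' @param session_size_mean,session_size_sd,session_size_min Scan-session
#'   flock sizes: truncated normal, defaults mean 117, SD 108.4, floor 10.
#' @param link_intercept,link_slope Logit-link parameters; NULL picks the
#'   hypothesis-specific defaults above.
#' @param overdispersion_sd Extra session-level SD on the logit scale
#'   (default 0: binomial-only noise).
#' @param t_air_range,distance_range Climate gradient: air temperature
#'   (degrees C, default 0-7) and one-way distance to the breeding grounds
#'   (km, default 1940-3093), co-varying so colder sites are closer.
#' @param wind_range,radiation_range Uniform ranges for site wind (m/s) and
#'   global radiation (W/m^2).
#' @param share_center,share_load Bottom-share link: logit-scale center and
#'   loading on the site depth-resource factor.
#' @param bottom_meanlog,bottom_load Log-scale center of site bottom-layer
#'   density (g AFDM/m^2) and its loading on the depth-resource factor.
#' @param top_meanlog,top_antiload,top_noiselog Log-scale center of site
#'   top-layer density, its (negative) loading on the depth-resource
#'   factor, and independent site noise.
#' @param cv_top,cv_bottom Within-site coefficient of variation of per-core
#'   layer AFDM (defaults 0.8 and 0.9, the scale seen across the six study
#'   sites).
#' @param layer_coupling Shared-factor loading coupling a core's two layers.
#' @param benthos_params Optional data frame (`site`, `top_mean`, `top_sd`,
#'   `bottom_mean`, `bottom_sd`) of explicit per-site moments overriding the
#'   parametric site model, e.g. to moment-match an observed site.
#' @param aps_intercept,aps_cost_slope,aps_male_effect,aps_interaction,aps_sd
#'   Latent-Gaussian abdominal-profile model: score latent mean is
#'   `intercept + cost_slope * z(cost) + male_effect * male +
#'   interaction * z(cost) * male`, SD `aps_sd`; defaults 3, 0.4, -0.2,
#'   0.2, 1 (males steepen with cost).
#' @param n_aps_per_group Scored birds per site x sex (default 50).
#' @param seed Root seed (default 1); all four stages derive their own
#'   streams from it.
#' @return An object of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(hypothesis = c("resource_partitioning", "bergmann", "null"),
                               n_sites = 6, n_cores_per_site = 10,
                               n_sessions_per_site = 10,
                               session_size_mean = 117, session_size_sd = 108.4,
                               session_size_min = 10,
                               link_intercept = NULL, link_slope = NULL,
                               overdispersion_sd = 0,
                               t_air_range = c(0, 7),
                               distance_range = c(1940, 3093),
                               wind_range = c(4, 8),
                               radiation_range = c(40, 80),
                               share_center = 1.4, share_load = 0.9,
                               bottom_meanlog = 1.7, bottom_load = 0.75,
                               top_meanlog = 0.1, top_antiload = 0.4,
                               top_noiselog = 0.3,
                               cv_top = 0.8, cv_bottom = 0.9,
                               layer_coupling = 0.76,
                               benthos_params = NULL,
                               aps_intercept = 3, aps_cost_slope = 0.4,
                               aps_male_effect = -0.2, aps_interaction = 0.2,
                               aps_sd = 1, n_aps_per_group = 50,
                               seed = 1) {
  hypothesis <- match.arg(hypothesis)
  if (is.null(link_intercept))
    link_intercept <- switch(hypothesis, resource_partitioning = -6.4,
                             bergmann = 0, null = 0)
  if (is.null(link_slope))
    link_slope <- switch(hypothesis, resource_partitioning = 8,
                         bergmann = 1, null = 0)
  stopifnot(n_sites >= 1, n_cores_per_site >= 1, n_sessions_per_site >= 1,
            session_size_min >= 1, session_size_mean > 0,
            overdispersion_sd >= 0, aps_sd > 0, n_aps_per_group >= 1,
            layer_coupling >= 0, layer_coupling <= 1,
            cv_top > 0, cv_bottom > 0)
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed))
    stop("'seed' must be a single integer", call. = FALSE)
  structure(as.list(environment()), class = "synthetic_scenario")
}

# Per-stage seed streams derived from the root seed, so each stage can be
# regenerated on its own while the full study stays a pure function of
# (scenario, seed).
.stage_seed <- function(seed, stage) {
  offsets <- c(sites = 101L, benthos = 211L, counts = 307L, aps = 401L)
  (as.integer(seed) %% 1000000L) * 1009L + offsets[[stage]]
}

# Truncated-normal flock sizes (rejection sampling), rounded to whole birds.
.rtrunc_sizes <- function(n, mean, sd, lower) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(2 * n, mean, sd)
    out <- c(out, x[x >= lower])
  }
  round(out[seq_len(n)])
}

# lognormal (meanlog, sdlog) matching a target mean and sd
.lognormal_params <- function(m, s) {
  sl <- sqrt(log(1 + (s / m)^2))
  list(meanlog = log(m) - sl^2 / 2, sdlog = sl)
}

#' Generate synthetic study sites
#'
#' Sites span the temperature gradient with air temperature evenly spaced
#' over `t_air_range` and one-way distance increasing linearly with
#' temperature over `distance_range` (colder sites are closer to the Arctic
#' breeding grounds). Wind and radiation are drawn uniformly from the
#' scenario ranges and recorded in the output; also draws the latent site
#' depth-resource factor used by the benthos stage.
#'
#' @param scenario A [synthetic_scenario].
#' @return Data frame: `site`, `t_air_c`, `wind_ms`, `radiation_wm2`,
#'   `distance_km_override`, `depth_factor`.
#' @export
make_sites <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  set.seed(.stage_seed(scenario$seed, "sites"))
  n <- scenario$n_sites
  t_air <- if (n == 1) mean(scenario$t_air_range) else
    seq(scenario$t_air_range[1], scenario$t_air_range[2], length.out = n)
  frac <- if (n == 1) 0.5 else (t_air - t_air[1]) / diff(range(t_air))
  dist <- scenario$distance_range[1] + frac * diff(scenario$distance_range)
  data.frame(
    site = sprintf("S%02d", seq_len(n)),
    t_air_c = t_air,
    wind_ms = stats::runif(n, scenario$wind_range[1], scenario$wind_range[2]),
    radiation_wm2 = stats::runif(n, scenario$radiation_range[1], scenario$radiation_range[2]),
    distance_km_override = dist,
    depth_factor = stats::rnorm(n),
    stringsAsFactors = FALSE
  )
}

#' Generate synthetic benthic cores
#'
#' Per-core layer AFDM is lognormal with site-specific moments. With the
#' default parametric site model, the site depth-resource factor raises the
#' bottom share and bottom density while lowering the top density; a
#' core-level shared factor couples the two layers within a site. Explicit
#' `benthos_params` in the scenario bypass the parametric model. Dry and ash
#' masses are synthesized around the AFDM with an ash fraction of 70-90% of
#' dry mass, typical of sieved soft-sediment samples.
#'
#' @param scenario A [synthetic_scenario].
#' @param sites Output of [make_sites].
#' @return Long-format core table: `site`, `core_id`, `layer`,
#'   `dry_mass_g`, `ash_mass_g`, `core_area_m2`.
#' @export
make_benthos <- function(scenario, sites) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  set.seed(.stage_seed(scenario$seed, "benthos"))
  area <- 0.0177
  nc <- scenario$n_cores_per_site
  if (!is.null(scenario$benthos_params)) {
    bp <- scenario$benthos_params
    stopifnot(all(c("site", "top_mean", "top_sd", "bottom_mean", "bottom_sd") %in% names(bp)))
    site_moments <- data.frame(site = bp$site,
                               m_top = bp$top_mean, s_top = bp$top_sd,
                               m_bot = bp$bottom_mean, s_bot = bp$bottom_sd)
  } else {
    f <- sites$depth_factor
    h <- stats::rnorm(nrow(sites))
    m_bot <- exp(scenario$bottom_meanlog + scenario$bottom_load * f)
    m_top <- exp(scenario$top_meanlog - scenario$top_antiload * f +
                   scenario$top_noiselog * h)
    site_moments <- data.frame(site = sites$site,
                               m_top = m_top, s_top = scenario$cv_top * m_top,
                               m_bot = m_bot, s_bot = scenario$cv_bottom * m_bot)
  }
  lam <- scenario$layer_coupling
  rows <- lapply(seq_len(nrow(site_moments)), function(i) {
    sm <- site_moments[i, ]
    pt <- .lognormal_params(sm$m_top, max(sm$s_top, 1e-12))
    pb <- .lognormal_params(sm$m_bot, max(sm$s_bot, 1e-12))
    if (sm$s_top == 0) pt <- list(meanlog = log(sm$m_top), sdlog = 0)
    if (sm$s_bot == 0) pb <- list(meanlog = log(sm$m_bot), sdlog = 0)
    z <- stats::rnorm(nc)
    top_d <- exp(pt$meanlog + pt$sdlog * (lam * z + sqrt(1 - lam^2) * stats::rnorm(nc)))
    bot_d <- exp(pb$meanlog + pb$sdlog * (lam * z + sqrt(1 - lam^2) * stats::rnorm(nc)))
    afdm <- c(top_d, bot_d) * area
    ash_frac <- stats::runif(2 * nc, 0.70, 0.90)
    dry <- afdm / (1 - ash_frac)
    data.frame(site = sm$site,
               core_id = rep(sprintf("C%02d", seq_len(nc)), 2),
               layer = rep(c("top", "bottom"), each = nc),
               dry_mass_g = dry, ash_mass_g = dry - afdm,
               core_area_m2 = area, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate synthetic sex-ratio count sessions
#'
#' Each site's true probability that a scanned bird is female comes from the
#' scenario's hypothesis link; sessions then draw a flock size from the
#' truncated normal (mean 117, SD 108.4, floor 10) and a female count from a
#' binomial (optionally with logit-normal overdispersion across sessions).
#'
#' @param scenario A [synthetic_scenario].
#' @param sites Output of [make_sites].
#' @param benthos_summary Output of [summarize_benthos]; required for the
#'   resource-partitioning link.
#' @param costs Output of [wintering_cost]; required for the Bergmann link.
#' @return Count table: `site`, `session_id`, `n_male`, `n_female`, plus the
#'   per-site `true_pf` attached as attribute `"true_pf"`.
#' @export
make_counts <- function(scenario, sites, benthos_summary = NULL, costs = NULL) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  set.seed(.stage_seed(scenario$seed, "counts"))
  a <- scenario$link_intercept; b <- scenario$link_slope
  eta <- switch(scenario$hypothesis,
    null = rep(a, nrow(sites)),
    resource_partitioning = {
      if (is.null(benthos_summary))
        stop("resource_partitioning link needs 'benthos_summary'", call. = FALSE)
      bp <- benthos_summary$bottom_pct_mean[match(sites$site, benthos_summary$site)]
      a + b * bp / 100
    },
    bergmann = {
      if (is.null(costs)) stop("bergmann link needs 'costs'", call. = FALSE)
      sc <- stats::aggregate(seasonal_total_kj ~ site, data = costs, FUN = mean)
      cost <- sc$seasonal_total_kj[match(sites$site, sc$site)]
      z <- if (stats::sd(cost) > 0) (cost - mean(cost)) / stats::sd(cost) else cost * 0
      a + b * z
    })
  pf <- stats::plogis(eta)
  ns <- scenario$n_sessions_per_site
  rows <- lapply(seq_len(nrow(sites)), function(i) {
    n <- .rtrunc_sizes(ns, scenario$session_size_mean, scenario$session_size_sd,
                       scenario$session_size_min)
    p <- pf[i]
    if (scenario$overdispersion_sd > 0)
      p <- stats::plogis(stats::qlogis(p) + stats::rnorm(ns, 0, scenario$overdispersion_sd))
    y <- stats::rbinom(ns, n, p)
    data.frame(site = sites$site[i],
               session_id = sprintf("%s_K%02d", sites$site[i], seq_len(ns)),
               n_male = n - y, n_female = y, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "true_pf") <- stats::setNames(pf, sites$site)
  out
}

#' Generate synthetic abdominal-profile scores
#'
#' Ordinal 1-5 scores from a discretized latent Gaussian whose mean is
#' linear in the standardized site x sex wintering cost, sex, and their
#' interaction; the default positive interaction makes the male score
#' increase faster with cost (the smaller sex holding relatively larger
#' stores at expensive sites). The latent value is rounded to the nearest
#' score and clamped to 1-5.
#'
#' @param scenario A [synthetic_scenario].
#' @param sites Output of [make_sites].
#' @param costs Output of [wintering_cost] for these sites.
#' @return APS table: `site`, `sex`, `score`, with the latent model
#'   coefficients attached as attribute `"latent_model"`.
#' @export
make_aps <- function(scenario, sites, costs) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  set.seed(.stage_seed(scenario$seed, "aps"))
  cs <- costs[costs$site %in% sites$site, c("site", "sex", "seasonal_total_kj")]
  if (nrow(cs) == 0) stop("no costs for these sites", call. = FALSE)
  z <- if (stats::sd(cs$seasonal_total_kj) > 0)
    (cs$seasonal_total_kj - mean(cs$seasonal_total_kj)) / stats::sd(cs$seasonal_total_kj)
  else cs$seasonal_total_kj * 0
  n <- scenario$n_aps_per_group
  rows <- lapply(seq_len(nrow(cs)), function(i) {
    male <- as.numeric(cs$sex[i] == "male")
    mu <- scenario$aps_intercept + scenario$aps_cost_slope * z[i] +
      scenario$aps_male_effect * male + scenario$aps_interaction * z[i] * male
    latent <- stats::rnorm(n, mu, scenario$aps_sd)
    data.frame(site = cs$site[i], sex = cs$sex[i],
               score = pmin(5L, pmax(1L, as.integer(round(latent)))),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "latent_model") <- list(intercept = scenario$aps_intercept,
                                    cost_slope = scenario$aps_cost_slope,
                                    male_effect = scenario$aps_male_effect,
                                    interaction = scenario$aps_interaction,
                                    sd = scenario$aps_sd,
                                    cost_z = stats::setNames(z, paste(cs$site, cs$sex)))
  out
}

#' Generate a complete synthetic study
#'
#' Runs the four generator stages in order (sites, benthos, counts, APS),
#' computing wintering costs in between, and returns every table plus the
#' scenario echo. A pure function of the scenario (including its seed).
#'
#' @param scenario A [synthetic_scenario].
#' @param profiles,coeffs,config Energetics parameters passed to
#'   [wintering_cost].
#' @return List of class `synthetic_study`: `sites`, `cores`,
#'   `benthos_summary`, `costs`, `counts`, `aps`, `scenario`.
#' @export
generate_study <- function(scenario = synthetic_scenario(),
                           profiles = list(sex_profile("male"), sex_profile("female")),
                           coeffs = heat_loss_coefficients(),
                           config = energetics_config()) {
  sites <- make_sites(scenario)
  cores <- make_benthos(scenario, sites)
  bs <- summarize_benthos(cores)
  costs <- wintering_cost(sites, profiles, coeffs, config)
  counts <- make_counts(scenario, sites, benthos_summary = bs, costs = costs)
  aps <- make_aps(scenario, sites, costs)
  structure(list(sites = sites, cores = cores, benthos_summary = bs,
                 costs = costs, counts = counts, aps = aps,
                 scenario = scenario),
            class = "synthetic_study")
}

#' Write a synthetic study to CSV files plus a scenario echo
#'
#' Writes `sites.csv`, `cores.csv`, `counts.csv`, `aps.csv` and
#' `scenario.json` (all scenario parameters including the seed) into `dir`.
#' Output bytes are deterministic for a fixed scenario.
#'
#' @param study A `synthetic_study` from [generate_study].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the vector of files written.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("sites.csv", "cores.csv", "counts.csv",
                            "aps.csv", "scenario.json"))
  .write_csv(study$sites, paths[1])
  .write_csv(study$cores, paths[2])
  .write_csv(study$counts, paths[3])
  .write_csv(study$aps, paths[4])
  sc <- study$scenario
  sc$benthos_params <- if (is.null(sc$benthos_params)) NULL else as.list(sc$benthos_params)
  jsonlite::write_json(unclass(sc), paths[5], auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(paths)
}
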