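# Shared helpers: independent oracles and tiny data builders.

# Spherical-law-of-cosines distance, the independent great-circle oracle.
slc_distance <- function(lat1, lon1, lat2, lon2, radius_km = 6371) {
  r <- pi / 180
  x <- sin(lat1 * r) * sin(lat2 * r) +
    cos(lat1 * r) * cos(lat2 * r) * cos((lon2 - lon1) * r)
  radius_km * acos(pmin(1, pmax(-1, x)))
}

# Quick count-session table builder.
counts_df <- function(site, n_male, n_female) {
  data.frame(site = site,
             session_id = sprintf("K%03d", seq_along(site)),
             n_male = n_male, n_female = n_female,
             stringsAsFactors = FALSE)
}

# Long-format core table from per-core layer AFDM (g); unit-organic dry mass
# so dry - ash equals the requested AFDM exactly.
cores_df <- function(site, core_id, top_afdm, bottom_afdm, area = 0.0177) {
  data.frame(site = rep(site, 2), core_id = rep(core_id, 2),
             layer = rep(c("top", "bottom"), each = length(core_id)),
             dry_mass_g = c(top_afdm, bottom_afdm),
             ash_mass_g = 0,
             core_area_m2 = area, stringsAsFactors = FALSE)
}

# Exact expected ordinal score of a rounded-and-clamped latent N(mu, sd):
# the estimand of a least-squares fit to the generated scores.
expected_score <- function(mu, sd) {
  p1 <- stats::pnorm((1.5 - mu) / sd)
  p5 <- 1 - stats::pnorm((4.5 - mu) / sd)
  pk <- vapply(2:4, function(k)
    stats::pnorm((k + 0.5 - mu) / sd) - stats::pnorm((k - 0.5 - mu) / sd), 0)
  1 * p1 + sum((2:4) * pk) + 5 * p5
}

table1_sites <- function() read_sites(gw_example("study_sites.csv"))
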