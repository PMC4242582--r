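#' Ash-free dry mass of a benthic sample
#'
#' AFDM = dry mass - ash mass: the organic fraction remaining after
#' incineration, the standard proxy for edible prey biomass.
#'
#' @param dry_mass Dry mass in g.
#' @param ash_mass Ash mass in g; must satisfy 0 <= ash <= dry.
#' @return AFDM in g (>= 0). Vectorized.
#' @export
ash_free_dry_mass <- function(dry_mass, ash_mass) {
  if (!is.numeric(dry_mass) || !is.numeric(ash_mass))
    stop("masses must be numeric", call. = FALSE)
  if (any(dry_mass < 0) || any(ash_mass < 0))
    stop("masses must be >= 0", call. = FALSE)
  if (any(ash_mass > dry_mass))
    stop("ash mass exceeds dry mass", call. = FALSE)
  dry_mass - ash_mass
}

#' AFDM density of a core layer
#'
#' @param afdm AFDM in g (>= 0).
#' @param core_area Core surface area in m^2 (> 0, default 0.0177).
#' @return Density in g AFDM per m^2.
#' @export
layer_density <- function(afdm, core_area = 0.0177) {
  if (any(core_area <= 0)) stop("'core_area' must be > 0", call. = FALSE)
  afdm / core_area
}

#' Percentage of a core's AFDM in the bottom layer
#'
#' The bottom layer (5-30 cm) holds prey reachable only by probing; the
#' fraction of a core's biomass buried there is the per-core depth-access
#' statistic. Undefined (NA) when both layers are empty.
#'
#' @param top_afdm,bottom_afdm Layer AFDM in g (>= 0). Vectorized.
#' @return Percentage in `[0, 100]`, or NA for an all-zero core.
#' @export
bottom_fraction <- function(top_afdm, bottom_afdm) {
  if (any(top_afdm < 0, na.rm = TRUE) || any(bottom_afdm < 0, na.rm = TRUE))
    stop("layer AFDM must be >= 0", call. = FALSE)
  total <- top_afdm + bottom_afdm
  ifelse(total > 0, 100 * bottom_afdm / total, NA_real_)
}

#' Summarize benthic cores per site
#'
#' Converts long-format core records (one row per site x core x layer) into
#' site summaries: per-layer mean and sample SD (n-1) of AFDM density, and
#' the bottom-layer percentage computed per core first and then averaged
#' (mean of ratios, not ratio of pooled means -- the two differ whenever
#' core totals vary, so a site's mean bottom percentage is generally not
#' the percentage implied by its mean layer densities).
#'
#' Records with ash > dry are dropped with a warning. A core missing one
#' layer contributes to the other layer's summary but not to the bottom
#' percentage; all-zero cores are likewise excluded from the percentage.
#'
#' @param cores Data frame with columns `site`, `core_id`, `layer`
#'   ("top"/"bottom"), `dry_mass_g`, `ash_mass_g`, and optional
#'   `core_area_m2` (default 0.0177).
#' @return Data frame with one row per site: `site`, `n_cores`, `top_n`,
#'   `top_mean`, `top_sd`, `bottom_n`, `bottom_mean`, `bottom_sd`,
#'   `bottom_pct_n`, `bottom_pct_mean`, `bottom_pct_sd`. Densities in
#'   g AFDM per m^2; single-observation SDs are reported as 0.
#' @export
summarize_benthos <- function(cores) {
  required <- c("site", "core_id", "layer", "dry_mass_g", "ash_mass_g")
  missing_cols <- setdiff(required, names(cores))
  if (length(missing_cols))
    stop("core table lacks columns: ", paste(missing_cols, collapse = ", "), call. = FALSE)
  if (nrow(cores) == 0) stop("no core records", call. = FALSE)
  if (!all(cores$layer %in% c("top", "bottom")))
    stop("'layer' must be 'top' or 'bottom'", call. = FALSE)
  if (!"core_area_m2" %in% names(cores)) cores$core_area_m2 <- 0.0177
  cores$core_area_m2[is.na(cores$core_area_m2)] <- 0.0177

  bad <- cores$ash_mass_g > cores$dry_mass_g
  if (any(bad)) {
    warning(sum(bad), " record(s) with ash > dry mass excluded", call. = FALSE)
    cores <- cores[!bad, , drop = FALSE]
    if (nrow(cores) == 0) stop("no valid core records", call. = FALSE)
  }
  cores$afdm <- ash_free_dry_mass(cores$dry_mass_g, cores$ash_mass_g)
  cores$density <- layer_density(cores$afdm, cores$core_area_m2)

  sd0 <- function(x) if (length(x) < 2) 0 else stats::sd(x)
  res <- lapply(split(cores, as.character(cores$site)), function(d) {
    top <- d$density[d$layer == "top"]
    bot <- d$density[d$layer == "bottom"]
    # per-core percentages need both layers present
    wide <- merge(d[d$layer == "top", c("core_id", "afdm")],
                  d[d$layer == "bottom", c("core_id", "afdm")],
                  by = "core_id", suffixes = c("_top", "_bottom"))
    pct <- bottom_fraction(wide$afdm_top, wide$afdm_bottom)
    pct <- pct[!is.na(pct)]
    data.frame(
      site = d$site[1], n_cores = length(unique(d$core_id)),
      top_n = length(top),
      top_mean = if (length(top)) mean(top) else NA_real_,
      top_sd = if (length(top)) sd0(top) else NA_real_,
      bottom_n = length(bot),
      bottom_mean = if (length(bot)) mean(bot) else NA_real_,
      bottom_sd = if (length(bot)) sd0(bot) else NA_real_,
      bottom_pct_n = length(pct),
      bottom_pct_mean = if (length(pct)) mean(pct) else NA_real_,
      bottom_pct_sd = if (length(pct)) sd0(pct) else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, res)
  out <- out[order(out$site), , drop = FALSE]
  rownames(out) <- NULL
  out
}
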