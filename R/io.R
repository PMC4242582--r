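# Deterministic CSV writing: fixed column order as given, no row names,
# no quoting surprises.
.write_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Path to a packaged example data file
#'
#' @param file File name under `extdata`; with no argument, lists the
#'   available files.
#' @return Full path (or vector of file names).
#' @export
gw_example <- function(file = NULL) {
  base <- system.file("extdata", package = "godwitwinter", mustWork = TRUE)
  if (is.null(file)) return(list.files(base))
  path <- file.path(base, file)
  if (!file.exists(path)) stop("no packaged file '", file, "'", call. = FALSE)
  path
}

#' Read a site table
#'
#' Expected columns: `site`, `t_air_c`, `wind_ms`, `radiation_wm2`, and
#' either `distance_km_override` or `lat`/`lon` (decimal degrees).
#'
#' @param path CSV path.
#' @return Validated data frame.
#' @export
read_sites <- function(path) {
  if (!file.exists(path)) stop("site file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("site", "t_air_c", "wind_ms", "radiation_wm2")
  missing_cols <- setdiff(required, names(d))
  if (length(missing_cols))
    stop("site file lacks columns: ", paste(missing_cols, collapse = ", "), call. = FALSE)
  if (!"distance_km_override" %in% names(d) && !all(c("lat", "lon") %in% names(d)))
    stop("site file needs 'distance_km_override' or 'lat'/'lon'", call. = FALSE)
  if (anyDuplicated(d$site)) stop("duplicate site names", call. = FALSE)
  d
}

#' Read a benthic core table
#'
#' Expected columns: `site`, `core_id`, `layer` ("top"/"bottom"),
#' `dry_mass_g`, `ash_mass_g`, optional `core_area_m2`.
#'
#' @param path CSV path.
#' @return Validated data frame.
#' @export
read_benthic_cores <- function(path) {
  if (!file.exists(path)) stop("core file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("site", "core_id", "layer", "dry_mass_g", "ash_mass_g")
  missing_cols <- setdiff(required, names(d))
  if (length(missing_cols))
    stop("core file lacks columns: ", paste(missing_cols, collapse = ", "), call. = FALSE)
  if (!all(d$layer %in% c("top", "bottom")))
    stop("'layer' must be 'top' or 'bottom'", call. = FALSE)
  if (any(d$dry_mass_g < 0) || any(d$ash_mass_g < 0))
    stop("masses must be >= 0", call. = FALSE)
  d
}

#' Read a sex-ratio count table
#'
#' Expected columns: `site`, `session_id`, `n_male`, `n_female`.
#'
#' @param path CSV path.
#' @return Validated data frame.
#' @export
read_count_sessions <- function(path) {
  if (!file.exists(path)) stop("count file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  .check_counts(d)
  d
}

#' Read an abdominal-profile score table
#'
#' Expected columns: `site`, `sex`, `score` (integers 1-5).
#'
#' @param path CSV path.
#' @return Validated data frame.
#' @export
read_aps_records <- function(path) {
  if (!file.exists(path)) stop("APS file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("site", "sex", "score")
  missing_cols <- setdiff(required, names(d))
  if (length(missing_cols))
    stop("APS file lacks columns: ", paste(missing_cols, collapse = ", "), call. = FALSE)
  if (!all(d$score %in% 1:5)) stop("scores must be integers in 1..5", call. = FALSE)
  d
}
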