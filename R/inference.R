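#' Container for a test result
#'
#' Uniform result object for the statistical battery: statistic, degrees of
#' freedom (scalar or pair), two-sided p-value, an effect-size estimate where
#' one exists, and a method label. p-values below 1e-16 are stored as the
#' bound 1e-16 with `p_bounded = TRUE` rather than as zero.
#'
#' @param statistic Test statistic.
#' @param df Degrees of freedom (length 1 or 2); NA allowed for degenerate
#'   results.
#' @param p_value Two-sided p-value in `[0, 1]` (or NA).
#' @param estimate Optional effect size (r, percent female, ...).
#' @param method Human-readable method label.
#' @param note Optional note (e.g. why a result is degenerate).
#' @return An object of class `gw_test`.
#' @export
gw_test <- function(statistic, df, p_value, estimate = NA_real_,
                    method = "test", note = NULL) {
  p_bounded <- FALSE
  if (length(p_value) == 1 && is.finite(p_value)) {
    if (p_value < 0 || p_value > 1) stop("p-value outside [0, 1]", call. = FALSE)
    if (p_value < 1e-16) { p_value <- 1e-16; p_bounded <- TRUE }
  }
  structure(list(statistic = statistic, df = df, p_value = p_value,
                 estimate = estimate, method = method,
                 p_bounded = p_bounded, note = note),
            class = "gw_test")
}

#' @export
print.gw_test <- function(x, ...) {
  dftxt <- paste(format(x$df, digits = 4), collapse = ", ")
  ptxt <- if (isTRUE(x$p_bounded)) "< 1e-16" else format(x$p_value, digits = 4)
  cat(sprintf("<gw_test> %s\n  statistic = %s, df = %s, p = %s",
              x$method, format(x$statistic, digits = 5), dftxt, ptxt))
  if (length(x$estimate) == 1 && is.finite(x$estimate))
    cat(sprintf(", estimate = %s", format(x$estimate, digits = 4)))
  cat("\n")
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Site effect on session sex ratios
#'
#' Likelihood-ratio comparison of Gaussian linear models on the session
#' empirical logits, with versus without a site factor. The reported
#' statistic is the LR chi-square `2 (l1 - l0)` with df = sites - 1. Because
#' with one observation per session a session-level random effect is
#' confounded with the residual, fixed-effects Gaussian models are the
#' identifiable form of the session-level mixed model. For nested Gaussian
#' linear models the LR statistic is a monotone transform of the exact F
#' statistic, so the p-value is taken from the exact finite-sample F
#' distribution rather than the asymptotic chi-square, which keeps the test
#' calibrated at the study's modest session counts.
#'
#' @param counts Data frame with columns `site`, `session_id`, `n_male`,
#'   `n_female`, spanning at least two sites.
#' @return A [gw_test]; `df` is sites - 1 (the chi-square df).
#' @export
site_effect_test <- function(counts) {
  .check_counts(counts)
  site <- factor(counts$site)
  k <- nlevels(site)
  if (k < 2) stop("need at least 2 sites", call. = FALSE)
  if (nrow(counts) <= k) stop("need more sessions than sites", call. = FALSE)
  lg <- adjusted_logit(counts$n_female, counts$n_male + counts$n_female)
  fit1 <- stats::lm(lg ~ site)
  fit0 <- stats::lm(lg ~ 1)
  n <- length(lg); q <- as.integer(k - 1)
  rss0 <- sum(stats::residuals(fit0)^2)
  rss1 <- sum(stats::residuals(fit1)^2)
  if (rss0 < 1e-300) {           # all sessions identical: nothing to explain
    chi2 <- 0; p <- 1
  } else if (rss1 < 1e-300) {    # site factor fits perfectly
    chi2 <- Inf; p <- 0
  } else {
    chi2 <- max(0, n * log(rss0 / rss1))
    f <- ((rss0 - rss1) / q) / (rss1 / (n - k))
    p <- stats::pf(f, q, n - k, lower.tail = FALSE)
  }
  gw_test(statistic = chi2, df = q, p_value = p,
          method = "Gaussian likelihood-ratio test for a site effect on session logits (exact-F p)")
}

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA (possibly unbalanced) via
#' [stats::aov]. With two groups the F statistic equals the square of the
#' pooled two-sample t statistic.
#'
#' @param values Numeric response vector.
#' @param group Grouping factor (>= 2 levels).
#' @return A [gw_test] with the F statistic and `(k-1, N-k)` df.
#' @export
one_way_anova <- function(values, group) {
  group <- factor(group)
  if (nlevels(group) < 2) stop("need at least 2 groups", call. = FALSE)
  if (length(values) != length(group)) stop("lengths differ", call. = FALSE)
  tab <- stats::anova(stats::aov(values ~ group))
  f <- tab[["F value"]][1]
  p <- tab[["Pr(>F)"]][1]
  if (is.na(f)) { f <- 0; p <- 1 } # zero residual variance with equal means
  gw_test(statistic = f, df = c(tab$Df[1], tab$Df[2]), p_value = p,
          method = "one-way ANOVA")
}

#' Tukey honest-significant-difference contrasts
#'
#' All pairwise group contrasts with family-wise adjustment from the
#' studentized range ([stats::TukeyHSD]); unbalanced groups use the
#' Tukey-Kramer form.
#'
#' @inheritParams one_way_anova
#' @param conf_level Family-wise confidence level (default 0.95).
#' @return Data frame: `contrast`, `diff`, `lwr`, `upr`, `p_adj`.
#' @export
tukey_hsd <- function(values, group, conf_level = 0.95) {
  group <- factor(group)
  if (nlevels(group) < 2) stop("need at least 2 groups", call. = FALSE)
  tk <- stats::TukeyHSD(stats::aov(values ~ group), conf.level = conf_level)$group
  out <- data.frame(contrast = rownames(tk), tk, row.names = NULL,
                    stringsAsFactors = FALSE)
  names(out) <- c("contrast", "diff", "lwr", "upr", "p_adj")
  out
}

#' Pearson correlation test
#'
#' Two-sided Pearson correlation via [stats::cor.test]; p from
#' `t = r sqrt(df / (1 - r^2))` with df = n - 2.
#'
#' @param x,y Numeric vectors of equal length >= 3 with non-zero variance.
#' @return A [gw_test] with `estimate = r`.
#' @export
pearson_test <- function(x, y) {
  if (length(x) != length(y)) stop("lengths differ", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: zero variance", call. = FALSE)
  ht <- stats::cor.test(x, y, method = "pearson")
  gw_test(statistic = unname(ht$statistic), df = unname(ht$parameter),
          p_value = ht$p.value, estimate = unname(ht$estimate),
          method = "Pearson correlation")
}

#' Least-squares linear model fit
#'
#' Thin wrapper over [stats::lm] returning the quantities the analyses
#' report: coefficient table, R-squared, overall F with df, and its p-value
#' (bounded below at 1e-16, never printed as zero). Supports both model
#' shapes used downstream: seasonal cost ~ distance, and abdominal profile
#' score ~ cost * sex.
#'
#' @param formula Model formula.
#' @param data Data frame.
#' @return List of class `gw_linear_fit`: `coefficients` (matrix as from
#'   `summary.lm`), `r_squared`, `f_statistic`, `df`, `p_value`,
#'   `p_bounded`, `model` (the lm object).
#' @export
linear_fit <- function(formula, data) {
  fit <- stats::lm(formula, data = data)
  if (any(is.na(stats::coef(fit))))
    stop("singular design: coefficients not estimable", call. = FALSE)
  sm <- summary(fit)
  if (is.null(sm$fstatistic)) stop("model has no tested coefficients", call. = FALSE)
  fst <- sm$fstatistic
  p <- stats::pf(fst[1], fst[2], fst[3], lower.tail = FALSE)
  p_bounded <- FALSE
  if (!is.finite(p) || p < 1e-16) { p <- 1e-16; p_bounded <- TRUE }
  structure(list(coefficients = sm$coefficients,
                 r_squared = sm$r.squared,
                 f_statistic = unname(fst[1]),
                 df = unname(fst[2:3]),
                 p_value = unname(p),
                 p_bounded = p_bounded,
                 model = fit),
            class = "gw_linear_fit")
}

#' @export
print.gw_linear_fit <- function(x, ...) {
  cat("<gw_linear_fit>\n")
  stats::printCoefmat(x$coefficients)
  ptxt <- if (x$p_bounded) "< 1e-16" else format(x$p_value, digits = 4)
  cat(sprintf("R-squared = %.4f, F(%g, %g) = %.4g, p = %s\n",
              x$r_squared, x$df[1], x$df[2], x$f_statistic, ptxt))
  invisible(x)
}

.safe_pearson <- function(x, y, method) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0)
    return(gw_test(statistic = NA_real_, df = NA_real_, p_value = NA_real_,
                   estimate = NA_real_, method = method,
                   note = "correlation undefined (degenerate input)"))
  out <- pearson_test(x, y)
  out$method <- method
  out
}

#' Four-correlation hypothesis panel
#'
#' The head-to-head comparison of the two candidate explanations for where
#' the females winter. Four Pearson tests:
#' \itemize{
#'   \item `cost`: percent female vs seasonal wintering cost, site level
#'     (cost averaged over the sexes per site) -- the Bergmann prediction;
#'   \item `bottom`: percent female vs bottom-layer AFDM density, sample
#'     level (each core paired with its site's percent female);
#'   \item `top`: percent female vs top-layer AFDM density, sample level;
#'   \item `bottom_pct`: percent female vs mean bottom-layer percentage,
#'     site level -- the resource-partitioning prediction.
#' }
#' Under resource partitioning the signature is bottom positive, top
#' negative, cost near zero. Degenerate inputs (constant percent female)
#' yield flagged NA results rather than errors.
#'
#' @param sexratio Output of [site_sex_ratio].
#' @param costs Output of [wintering_cost].
#' @param benthos_summary Output of [summarize_benthos].
#' @param cores Core table as for [summarize_benthos] (sample-level tests).
#' @param biomass_level "sample" (default, pairs each core with its site's
#'   percent female) or "site" (site means only).
#' @return Named list of four [gw_test] objects:
#'   `cost`, `bottom`, `top`, `bottom_pct`.
#' @export
hypothesis_panel <- function(sexratio, costs, benthos_summary, cores,
                             biomass_level = c("sample", "site")) {
  biomass_level <- match.arg(biomass_level)
  for (nm in c("site", "pct_female")) if (!nm %in% names(sexratio))
    stop("'sexratio' lacks column ", nm, call. = FALSE)
  if (!all(c("site", "seasonal_total_kj") %in% names(costs)))
    stop("'costs' lacks site/seasonal_total_kj columns", call. = FALSE)

  site_cost <- stats::aggregate(seasonal_total_kj ~ site, data = costs, FUN = mean)
  m <- merge(sexratio, site_cost, by = "site")
  cost_test <- .safe_pearson(m$pct_female, m$seasonal_total_kj,
                             "Pearson: % female vs wintering cost (site level)")

  pf_of <- stats::setNames(sexratio$pct_female, sexratio$site)
  if (biomass_level == "sample") {
    cores <- cores[cores$ash_mass_g <= cores$dry_mass_g, , drop = FALSE]
    if (!"core_area_m2" %in% names(cores)) cores$core_area_m2 <- 0.0177
    dens <- layer_density(ash_free_dry_mass(cores$dry_mass_g, cores$ash_mass_g),
                          cores$core_area_m2)
    pf <- pf_of[as.character(cores$site)]
    topsel <- cores$layer == "top"; botsel <- cores$layer == "bottom"
    bottom_test <- .safe_pearson(pf[botsel], dens[botsel],
                                 "Pearson: % female vs bottom-layer AFDM (sample level)")
    top_test <- .safe_pearson(pf[topsel], dens[topsel],
                              "Pearson: % female vs top-layer AFDM (sample level)")
  } else {
    mb <- merge(sexratio, benthos_summary, by = "site")
    bottom_test <- .safe_pearson(mb$pct_female, mb$bottom_mean,
                                 "Pearson: % female vs bottom-layer AFDM (site level)")
    top_test <- .safe_pearson(mb$pct_female, mb$top_mean,
                              "Pearson: % female vs top-layer AFDM (site level)")
  }
  mp <- merge(sexratio, benthos_summary, by = "site")
  pct_test <- .safe_pearson(mp$pct_female, mp$bottom_pct_mean,
                            "Pearson: % female vs bottom-layer percentage (site level)")
  list(cost = cost_test, bottom = bottom_test, top = top_test,
       bottom_pct = pct_test)
}
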