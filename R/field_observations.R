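#' Empirical logit of a session's female proportion
#'
#' Log-odds of the adjusted proportion `(y + 0.5) / (n + 1)`, which stays
#' finite for all-male and all-female scan sessions and keeps a 50:50 session
#' exactly at logit 0. Antisymmetric in the two sexes:
#' `adjusted_logit(k, n) == -adjusted_logit(n - k, n)`.
#'
#' @param n_female Number of females counted (0 <= n_female <= n_total).
#' @param n_total Total birds in the session (>= 1). Vectorized.
#' @return Empirical logit (real).
#' @examples
#' adjusted_logit(50, 100) # 0
#' adjusted_logit(0, 10)   # about -3.045
#' @export
adjusted_logit <- function(n_female, n_total) {
  if (any(n_total < 1)) stop("'n_total' must be >= 1", call. = FALSE)
  if (any(n_female < 0) || any(n_female > n_total))
    stop("'n_female' must lie in [0, n_total]", call. = FALSE)
  stats::qlogis((n_female + 0.5) / (n_total + 1))
}

.check_counts <- function(counts) {
  required <- c("site", "session_id", "n_male", "n_female")
  missing_cols <- setdiff(required, names(counts))
  if (length(missing_cols))
    stop("count table lacks columns: ", paste(missing_cols, collapse = ", "), call. = FALSE)
  if (nrow(counts) == 0) stop("no count sessions", call. = FALSE)
  if (any(counts$n_male < 0) || any(counts$n_female < 0))
    stop("counts must be >= 0", call. = FALSE)
  if (any(counts$n_male + counts$n_female < 1))
    stop("every session needs at least one bird", call. = FALSE)
  invisible(counts)
}

#' Site-level sex ratio from scan sessions
#'
#' The session is the unit of replication: each session's female proportion
#' is empirical-logit transformed, sessions are averaged per site (equally
#' weighted by default, regardless of flock size), and the mean with its 95%
#' t-interval (df = sessions - 1) is back-transformed to percent female.
#' With a single session the interval degenerates to the point estimate and
#' the `single_session` flag is set.
#'
#' @param counts Data frame with columns `site`, `session_id`, `n_male`,
#'   `n_female`.
#' @param weight_by_size If TRUE, sessions are weighted by flock size
#'   (sensitivity variant; the default mirrors treating the session as the
#'   random unit).
#' @param conf_level Confidence level (default 0.95).
#' @return Data frame per site: `site`, `pct_female`, `ci_low`, `ci_high`,
#'   `n_sessions`, `n_birds`, `single_session`.
#' @export
site_sex_ratio <- function(counts, weight_by_size = FALSE, conf_level = 0.95) {
  .check_counts(counts)
  res <- lapply(split(counts, as.character(counts$site)), function(d) {
    n <- d$n_male + d$n_female
    lg <- adjusted_logit(d$n_female, n)
    w <- if (weight_by_size) n / sum(n) else rep(1 / length(lg), length(lg))
    m <- sum(w * lg)
    k <- length(lg)
    if (k > 1) {
      # weighted SE reduces to the usual t-interval under equal weights
      v <- sum(w * (lg - m)^2) * k / (k - 1)
      se <- sqrt(v / k)
      tq <- stats::qt(1 - (1 - conf_level) / 2, df = k - 1)
      lo <- m - tq * se; hi <- m + tq * se
    } else {
      lo <- hi <- m
    }
    data.frame(site = d$site[1],
               pct_female = 100 * stats::plogis(m),
               ci_low = 100 * stats::plogis(lo),
               ci_high = 100 * stats::plogis(hi),
               n_sessions = k, n_birds = sum(n),
               single_session = k == 1,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out <- out[order(out$site), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Test a site's sex ratio against 50:50
#'
#' Two-sided one-sample t-test of the session empirical logits against 0
#' (a balanced sex ratio). Requires at least two sessions.
#'
#' @param n_male,n_female Per-session counts for one site.
#' @return A [gw_test] with the t statistic, df and p-value; the estimate is
#'   the back-transformed mean logit as percent female.
#' @export
sex_bias_test <- function(n_male, n_female) {
  if (length(n_male) != length(n_female)) stop("count vectors differ in length", call. = FALSE)
  if (length(n_male) < 2) stop("need at least 2 sessions", call. = FALSE)
  lg <- adjusted_logit(n_female, n_male + n_female)
  if (stats::sd(lg) == 0 && mean(lg) == 0) {
    return(gw_test(statistic = 0, df = length(lg) - 1, p_value = 1,
                   estimate = 50, method = "one-sample t-test on session logits"))
  }
  ht <- stats::t.test(lg, mu = 0)
  gw_test(statistic = unname(ht$statistic), df = unname(ht$parameter),
          p_value = ht$p.value, estimate = 100 * stats::plogis(mean(lg)),
          method = "one-sample t-test on session logits")
}

#' Field sexing validation accuracy
#'
#' Percentage of marked, known-sex individuals assigned correctly in the
#' field, reported to one decimal.
#'
#' @param n_correct Correct assignments (0 <= n_correct <= n_sightings).
#' @param n_sightings Total sightings (>= 1).
#' @return Percentage, rounded to one decimal.
#' @examples
#' validation_accuracy(354, 364) # 97.3
#' @export
validation_accuracy <- function(n_correct, n_sightings) {
  if (any(n_sightings < 1)) stop("'n_sightings' must be >= 1", call. = FALSE)
  if (any(n_correct < 0) || any(n_correct > n_sightings))
    stop("'n_correct' must lie in [0, n_sightings]", call. = FALSE)
  round(100 * n_correct / n_sightings, 1)
}

#' Mean abdominal profile score per site and sex
#'
#' The abdominal profile score (1 = lean to 5 = bulging abdomen) indexes a
#' bird's fat stores. Group means are reported per site x sex with the
#' number of scored birds; empty groups are omitted.
#'
#' @param aps Data frame with columns `site`, `sex`, `score` (integers 1-5).
#' @return Data frame: `site`, `sex`, `mean_score`, `n`.
#' @export
aps_summary <- function(aps) {
  required <- c("site", "sex", "score")
  missing_cols <- setdiff(required, names(aps))
  if (length(missing_cols))
    stop("APS table lacks columns: ", paste(missing_cols, collapse = ", "), call. = FALSE)
  if (nrow(aps) == 0) stop("no APS records", call. = FALSE)
  if (!all(aps$score %in% 1:5)) stop("scores must be integers in 1..5", call. = FALSE)
  agg_mean <- stats::aggregate(score ~ site + sex, data = aps, FUN = mean)
  agg_n <- stats::aggregate(score ~ site + sex, data = aps, FUN = length)
  out <- merge(agg_mean, agg_n, by = c("site", "sex"), suffixes = c("_mean", "_n"))
  names(out) <- c("site", "sex", "mean_score", "n")
  out <- out[order(out$site, out$sex), , drop = FALSE]
  rownames(out) <- NULL
  out
}
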