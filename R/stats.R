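#' Two-sample rank-sum (Mann-Whitney / Wilcoxon) test
#'
#' Computes the Mann-Whitney U statistic from mid-ranks and a two-sided
#' p-value: exact (full null rank distribution) when there are no ties
#' and `max(n1, n2) <= exact_max`, otherwise the normal approximation
#' with tie and continuity correction. The exactness cutoff of 12 keeps
#' the test exact at the cohort sizes this pipeline targets (10 per
#' group) while bounding runtime for larger samples.
#'
#' @param x,y numeric samples (both non-empty).
#' @param exact_max largest group size for which the exact distribution is
#'   used (default 12).
#' @return a `rank_sum_result` list: `u_statistic` (U of sample `x`),
#'   `p_two_sided`, `method` (`"exact"` or `"normal_approx"`), `n1`, `n2`.
#' @examples
#' rank_sum_test(c(1, 2), c(3, 4))  # U = 0, exact p = 1/3
#' @export
rank_sum_test <- function(x, y, exact_max = 12L) {
  if (length(x) < 1 || length(y) < 1) stop("both samples must be non-empty")
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(c(x, y)))
  use_exact <- !ties && max(n1, n2) <= exact_max
  if (use_exact) {
    wt <- stats::wilcox.test(x, y, exact = TRUE,
                             alternative = "two.sided")
    stopifnot(isTRUE(all.equal(unname(wt$statistic), u)))
    p <- wt$p.value
  } else {
    # normal approximation with tie and continuity correction; a fully
    # tied pooled sample carries no ordering information (p = 1)
    nn <- n1 + n2
    tie_tab <- table(r)
    sigma2 <- n1 * n2 / 12 *
      ((nn + 1) - sum(tie_tab^3 - tie_tab) / (nn * (nn - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (u - n1 * n2 / 2 - 0.5 * sign(u - n1 * n2 / 2)) / sqrt(sigma2)
      p <- 2 * stats::pnorm(-abs(z))
    }
  }
  structure(list(u_statistic = u, p_two_sided = min(1, p),
                 method = if (use_exact) "exact" else "normal_approx",
                 n1 = n1, n2 = n2),
            class = "rank_sum_result")
}

# canonical row order of the group comparison table
feature_measures <- function() {
  c("inflow", "outflow", "degree", "cost", "clustering",
    "local_efficiency", "betweenness", "avg_path_length")
}

#' Compare the two outcome groups on every measure x band
#'
#' Runs one two-sided rank-sum test per measure x band on the SOZ-region
#' feature values, seizure-free versus non-seizure-free, with no
#' multiplicity correction. Rows are ordered deterministically
#' (measures in the canonical order, the four bands within each measure),
#' and the result is invariant to the order of the input records.
#'
#' @param features long-format feature data.frame as produced by
#'   [extract_soz_features()] / the pipeline: columns `patient_id`,
#'   `group`, `band`, `measure`, `value`.
#' @return a `group_stats_table` data.frame (32 rows) with group medians
#'   and quartiles, `u_statistic`, `p_value`, `method` and a
#'   direction-of-difference flag (`"lower"`/`"higher"`/`"equal"` in the
#'   seizure-free group, by median).
#' @export
compare_groups <- function(features) {
  stopifnot(all(c("patient_id", "group", "band", "measure", "value")
                %in% names(features)))
  groups <- unique(features$group)
  if (!setequal(groups, c("seizure_free", "non_seizure_free")))
    stop("features must contain exactly the groups seizure_free and non_seizure_free")
  for (g in c("seizure_free", "non_seizure_free"))
    if (length(unique(features$patient_id[features$group == g])) < 2)
      stop(sprintf("group %s has fewer than 2 patients", g))
  bands <- names(eeg_bands())
  rows <- list()
  for (m in feature_measures()) for (b in bands) {
    sel <- features$measure == m & features$band == b
    xs <- features[sel & features$group == "seizure_free", ]
    ys <- features[sel & features$group == "non_seizure_free", ]
    x <- xs$value[order(xs$patient_id)]
    y <- ys$value[order(ys$patient_id)]
    # avg_path_length is NA for isolated nodes; such patients drop out of
    # this row's samples (the row itself is always reported)
    x <- x[is.finite(x)]
    y <- y[is.finite(y)]
    if (length(x) >= 1 && length(y) >= 1) {
      tst <- rank_sum_test(x, y)
      q1 <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
      q2 <- stats::quantile(y, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
      dir <- if (q1[2] < q2[2]) "lower" else if (q1[2] > q2[2]) "higher" else "equal"
    } else {
      tst <- list(u_statistic = NA_real_, p_two_sided = NA_real_,
                  method = "insufficient", n1 = length(x), n2 = length(y))
      q1 <- q2 <- rep(NA_real_, 3)
      dir <- NA_character_
    }
    rows[[length(rows) + 1]] <- data.frame(
      measure = m, band = b,
      median_sf = q1[2], q1_sf = q1[1], q3_sf = q1[3],
      median_nsf = q2[2], q1_nsf = q2[1], q3_nsf = q2[3],
      u_statistic = tst$u_statistic, p_value = tst$p_two_sided,
      method = tst$method, n_sf = tst$n1, n_nsf = tst$n2,
      direction_sf = dir, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("group_stats_table", "data.frame")
  out
}

#' Five-number boxplot summary with Tukey outliers
#'
#' Quartiles by linear interpolation (type-7); whiskers extend to the most
#' extreme values within 1.5 x IQR of the quartiles; values beyond are
#' flagged as outliers.
#'
#' @param values numeric vector (non-empty).
#' @return list with `min`, `q1`, `median`, `q3`, `max` (whisker ends) and
#'   `outliers`.
#' @export
boxplot_summary <- function(values) {
  stopifnot(length(values) >= 1)
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  lo <- q[1] - 1.5 * iqr
  hi <- q[3] + 1.5 * iqr
  inside <- values >= lo & values <= hi
  list(min = min(values[inside]), q1 = q[1], median = q[2], q3 = q[3],
       max = max(values[inside]), outliers = sort(values[!inside]))
}
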