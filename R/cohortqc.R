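# Cohort feature-table quality control and the summary statistics used for
# baseline group comparisons: Tukey-fence outlier filtering, missingness
# thresholds, log2 fold-change features, two-sample tests from summary
# data, and Fisher's exact test.

#' Tukey-fence outlier flags
#'
#' A value is an outlier when it falls strictly outside
#' `[Q1 - k*IQR, Q3 + k*IQR]`, quartiles by linear interpolation (type 7).
#' The default fence multiplier is a deliberately wide `k = 4`, so only
#' gross outliers are flagged. Missing values are excluded from the
#' quartiles and never flagged. Constant data (IQR = 0) flags nothing, by
#' the strict-inequality definition.
#'
#' @param values Numeric vector (NA allowed; >= 4 non-missing values).
#' @param k Fence multiplier (default 4).
#' @return Logical vector, same length as `values` (`FALSE` for NA).
#' @export
tukey_outlier_flags <- function(values, k = 4) {
  ok <- !is.na(values)
  if (!any(ok)) stop("all values are missing")
  if (sum(ok) < 4L) stop("need at least 4 non-missing values")
  q <- stats::quantile(values[ok], c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  flags <- values < q[1] - k * iqr | values > q[2] + k * iqr
  flags[!ok] <- FALSE
  flags
}

#' Feature-table quality-control filter
#'
#' Discards features with more than `max_missing` missing values or more
#' than `max_outlier` Tukey-fence outliers (among non-missing values,
#' relative to the total row count). Sample order is preserved.
#'
#' @param table A `feature_table` (data frame whose feature columns are
#'   listed in `attr(, "feature_names")`, or all numeric columns after the
#'   id columns).
#' @param max_missing,max_outlier Discard thresholds (default 0.10 each).
#' @param k Tukey fence multiplier (default 4).
#' @return List with `table` (retained features) and `decisions` (one row
#'   per feature: `feature`, `fraction_missing`, `fraction_outlier`,
#'   `retained`).
#' @export
qc_filter <- function(table, max_missing = 0.10, max_outlier = 0.10, k = 4) {
  stopifnot(nrow(table) > 0)
  feats <- attr(table, "feature_names")
  if (is.null(feats))
    feats <- names(table)[vapply(table, is.numeric, TRUE)]
  dec <- lapply(feats, function(f) {
    v <- table[[f]]
    fm <- mean(is.na(v))
    fo <- if (all(is.na(v))) 1 else sum(tukey_outlier_flags(v, k)[!is.na(v)]) / length(v)
    data.frame(feature = f, fraction_missing = fm, fraction_outlier = fo,
               retained = fm <= max_missing && fo <= max_outlier,
               stringsAsFactors = FALSE)
  })
  dec <- do.call(rbind, dec)
  drop <- dec$feature[!dec$retained]
  out <- table[, !(names(table) %in% drop), drop = FALSE]
  attr(out, "feature_names") <- setdiff(feats, drop)
  class(out) <- class(table)
  list(table = out, decisions = dec)
}

#' Per-sample log2 fold change between timepoints
#'
#' `log2(value_to / value_from)` per sample and feature; missing or zero
#' inputs propagate to missing outputs.
#'
#' @param table A `feature_table` with `sample_id` and `timepoint` columns.
#' @param from,to Timepoint labels (defaults CID1 -> CID2, i.e. the change
#'   during weight loss).
#' @return Data frame: `sample_id`, `group` (if present), then one log2
#'   fold-change column per feature.
#' @export
log2_fold_change <- function(table, from = "CID1", to = "CID2") {
  feats <- attr(table, "feature_names")
  if (is.null(feats))
    feats <- names(table)[vapply(table, is.numeric, TRUE)]
  a <- table[table$timepoint == from, , drop = FALSE]
  b <- table[table$timepoint == to, , drop = FALSE]
  ids <- intersect(a$sample_id, b$sample_id)
  a <- a[match(ids, a$sample_id), ]; b <- b[match(ids, b$sample_id), ]
  fc <- sapply(feats, function(f) {
    x <- a[[f]]; y <- b[[f]]
    bad <- is.na(x) | is.na(y) | x <= 0 | y <= 0
    out <- log2(y / x); out[bad] <- NA
    out
  })
  res <- data.frame(sample_id = ids, stringsAsFactors = FALSE)
  if ("group" %in% names(a)) res$group <- a$group
  cbind(res, as.data.frame(fc))
}

#' Two-sample t test from summary statistics
#'
#' Welch's statistic with Satterthwaite degrees of freedom by default;
#' pooled-variance Student's t optionally. With zero variance in both
#' groups and equal means, `t = 0, p = 1` by convention.
#'
#' @param m1,sd1,n1 Mean, SD and size of group 1.
#' @param m2,sd2,n2 Mean, SD and size of group 2.
#' @param kind `"welch"` (default) or `"pooled"`.
#' @return List with `t`, `df`, `p` (two-sided).
#' @examples
#' ttest_from_summary(36.0502, 5.3902, 50, 34.4904, 4.7794, 50)
#' @export
ttest_from_summary <- function(m1, sd1, n1, m2, sd2, n2,
                               kind = c("welch", "pooled")) {
  kind <- match.arg(kind)
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  if (sd1 == 0 && sd2 == 0) {
    if (m1 == m2) return(list(t = 0, df = n1 + n2 - 2, p = 1))
    return(list(t = sign(m1 - m2) * Inf, df = n1 + n2 - 2, p = 0))
  }
  if (kind == "welch") {
    v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  t <- (m1 - m2) / se
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact hypergeometric test: the sum of probabilities of all tables with
#' the observed margins whose probability does not exceed the observed
#' table's.
#'
#' @param a,b,c,d Cell counts, row-wise (`a b / c d`), non-negative
#'   integers with positive margins.
#' @return Two-sided p value.
#' @examples
#' fisher_exact_2x2(14, 36, 30, 20)  # 0.002333
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  m <- matrix(counts, nrow = 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("table margins must be positive")
  stats::fisher.test(m)$p.value
}

#' Export the matrices downstream multivariate tools consume
#'
#' Baseline (CID1) concentrations, log2 fold changes over the intervention,
#' clinical covariates, and a seeded 75/25 train/test split stratified by
#' group. Model training itself (sPLS-DA, mixed models) is out of scope
#' here; these are the exact inputs such tools take.
#'
#' @param table A `feature_table`.
#' @param seed Seed for the stratified split.
#' @param train_fraction Fraction per group assigned to training
#'   (default 0.75).
#' @return List with `baseline`, `log2fc`, `covariates`, `split`.
#' @export
export_analysis_matrices <- function(table, seed = 1L, train_fraction = 0.75) {
  feats <- attr(table, "feature_names")
  if (is.null(feats))
    feats <- names(table)[vapply(table, is.numeric, TRUE)]
  base <- table[table$timepoint == "CID1", , drop = FALSE]
  covs <- base[, setdiff(names(base), feats), drop = FALSE]
  set.seed(seed)
  split <- do.call(rbind, lapply(split(base, base$group), function(g) {
    ntr <- round(train_fraction * nrow(g))
    idx <- sample.int(nrow(g), ntr)
    data.frame(sample_id = g$sample_id,
               set = ifelse(seq_len(nrow(g)) %in% idx, "train", "test"),
               group = g$group, stringsAsFactors = FALSE)
  }))
  rownames(split) <- NULL
  list(baseline = base[, c("sample_id", feats)],
       log2fc = log2_fold_change(table),
       covariates = covs, split = split)
}
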