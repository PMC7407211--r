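# Quantification and the bioanalytical validation calculus: 1/x-weighted
# calibration, back-calculation, LOD/LOQ, recovery, matrix effect,
# trueness and precision.

#' Fit a 1/x-weighted calibration curve
#'
#' Weighted least squares of the analyte/IS area ratio on the nominal
#' concentration, fitted on per-level mean ratios with weights `1/x`.
#' The weighted coefficient of determination is `1 - SSE_w/SST_w` with the
#' same weights. Back-calculated concentrations `(ratio - intercept)/slope`
#' and percent deviations from nominal are computed per replicate. The
#' lower limit of quantitation (LLOQ) is the lowest level whose mean
#' absolute deviation is within 20 %; other levels are held to 15 %. A
#' curve is accepted when R² > 0.995 over at least six levels and all
#' levels meet their deviation bound.
#'
#' @param levels Data frame with columns `conc` (nominal µM, > 0) and
#'   `ratio` (analyte/IS area ratio), one row per replicate injection.
#' @param analyte Optional analyte name carried in the result.
#' @return A list of class `calibration_curve`: `slope`, `intercept`, `r2`,
#'   `weighting`, per-level summary, per-replicate `backcalc`, `lloq`,
#'   `uloq`, `n_points_used`, `accepted`.
#' @export
fit_calibration <- function(levels, analyte = NA_character_) {
  stopifnot(is.data.frame(levels), all(c("conc", "ratio") %in% names(levels)))
  if (any(levels$conc <= 0)) stop("nominal concentrations must be > 0")
  conc_all <- sort(unique(levels$conc))
  if (length(conc_all) < 6L) stop("need at least 6 distinct calibration levels")
  conc_u <- conc_all
  # a lowest level failing its 20 % bound is dropped and the curve refitted,
  # as long as six levels remain
  repeat {
    means <- vapply(conc_u, function(cc) mean(levels$ratio[levels$conc == cc]), 0)
    df <- data.frame(conc = conc_u, ratio = means)
    fit <- stats::lm(ratio ~ conc, data = df, weights = 1 / conc)
    slope <- unname(stats::coef(fit)[2])
    intercept <- unname(stats::coef(fit)[1])
    back <- (levels$ratio - intercept) / slope
    dev_pct <- 100 * (back - levels$conc) / levels$conc
    lev_dev <- vapply(conc_u, function(cc)
      mean(abs(dev_pct[levels$conc == cc])), 0)
    if (lev_dev[1] > 20 && length(conc_u) > 6L) conc_u <- conc_u[-1]
    else break
  }
  w <- 1 / conc_u
  sse <- sum(w * stats::residuals(fit)^2)
  sst <- sum(w * (means - sum(w * means) / sum(w))^2)
  r2 <- 1 - sse / sst
  pass15 <- lev_dev <= 15
  lloq <- if (lev_dev[1] <= 20) conc_u[1] else NA_real_
  uloq <- if (any(pass15)) max(conc_u[pass15]) else NA_real_
  ok_level <- pass15
  ok_level[1] <- lev_dev[1] <= 20
  accepted <- r2 > 0.995 && length(conc_u) >= 6L && all(ok_level)
  used <- levels$conc %in% conc_u
  structure(list(analyte = analyte, slope = slope, intercept = intercept,
                 r2 = r2, weighting = "1/x",
                 levels = data.frame(conc = conc_u, mean_ratio = means,
                                     mean_abs_dev_pct = lev_dev,
                                     n = as.integer(table(factor(levels$conc[used],
                                                                 conc_u)))),
                 backcalc = data.frame(conc = levels$conc,
                                       ratio = levels$ratio,
                                       backcalc = back, dev_pct = dev_pct,
                                       used = used),
                 lloq = lloq, uloq = uloq,
                 n_points_used = length(conc_u), accepted = accepted),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration> %s: ratio = %.4g * conc + %.4g (1/x weights)\n",
              ifelse(is.na(x$analyte), "curve", x$analyte),
              x$slope, x$intercept))
  cat(sprintf("  R2 = %.5f over %d levels; LLOQ %.4g, ULOQ %.4g µM; %s\n",
              x$r2, x$n_points_used, x$lloq, x$uloq,
              if (x$accepted) "ACCEPTED" else "not accepted"))
  invisible(x)
}

#' Back-calculate a concentration from a calibration curve
#'
#' @param ratio Analyte/IS area ratio(s).
#' @param curve A `calibration_curve`.
#' @return Concentrations (µM) with attribute `flag` marking values below
#'   the LLOQ or above the ULOQ.
#' @export
quantify <- function(ratio, curve) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (curve$slope == 0) stop("calibration slope is zero")
  conc <- (ratio - curve$intercept) / curve$slope
  flag <- rep("ok", length(conc))
  if (!is.na(curve$lloq)) flag[conc < curve$lloq] <- "<LLOQ"
  if (!is.na(curve$uloq)) flag[conc > curve$uloq] <- ">ULOQ"
  structure(conc, flag = flag)
}

#' Single-point internal-standard concentration estimate
#'
#' `analyte_area / is_area * is_conc`, assuming a response factor of 1
#' relative to the class-matched internal standard. This is an estimate for
#' species without calibration standards, not a validated quantification.
#'
#' @param analyte_area,is_area Peak areas (IS area > 0).
#' @param is_conc Internal-standard concentration (µM).
#' @return Estimated concentration (µM).
#' @export
estimate_conc_by_is <- function(analyte_area, is_area, is_conc) {
  if (any(is_area <= 0)) stop("internal-standard area must be > 0")
  analyte_area / is_area * is_conc
}

#' Limit of detection from per-level signal-to-noise
#'
#' The lowest concentration whose (median, across replicates) S/N is at
#' least 3.
#'
#' @param levels_with_snr Data frame with columns `conc` and `snr`.
#' @param min_snr S/N threshold (default 3).
#' @return LOD in µM; `NA` with attribute `defined = FALSE` when no level
#'   qualifies.
#' @export
compute_lod <- function(levels_with_snr, min_snr = 3) {
  stopifnot(nrow(levels_with_snr) > 0)
  cc <- sort(unique(levels_with_snr$conc))
  ok <- vapply(cc, function(x)
    stats::median(levels_with_snr$snr[levels_with_snr$conc == x]) >= min_snr,
    TRUE)
  if (!any(ok)) return(structure(NA_real_, defined = FALSE))
  structure(cc[which(ok)[1]], defined = TRUE)
}

#' Limit of quantitation from replicate precision
#'
#' The lowest concentration whose replicate coefficient of variation is at
#' most 20 %.
#'
#' @param levels_with_cv Data frame with columns `conc` and `cv` (percent),
#'   or `conc` and `value` replicate measurements from which the CV is
#'   computed per level.
#' @param max_cv CV threshold in percent (default 20).
#' @return LOQ in µM; `NA` with attribute `defined = FALSE` when no level
#'   qualifies.
#' @export
compute_loq <- function(levels_with_cv, max_cv = 20) {
  stopifnot(nrow(levels_with_cv) > 0)
  if (!"cv" %in% names(levels_with_cv)) {
    stopifnot("value" %in% names(levels_with_cv))
    cc <- sort(unique(levels_with_cv$conc))
    cv <- vapply(cc, function(x) {
      v <- levels_with_cv$value[levels_with_cv$conc == x]
      if (length(v) < 3L) stop("LOQ requires at least triplicates per level")
      100 * stats::sd(v) / mean(v)
    }, 0)
    levels_with_cv <- data.frame(conc = cc, cv = cv)
  }
  cc <- sort(unique(levels_with_cv$conc))
  ok <- vapply(cc, function(x)
    all(levels_with_cv$cv[levels_with_cv$conc == x] <= max_cv), TRUE)
  if (!any(ok)) return(structure(NA_real_, defined = FALSE))
  structure(cc[which(ok)[1]], defined = TRUE)
}

#' Extraction recovery
#'
#' Signal area of a pre-extraction spike divided by the mean area of
#' post-extraction spikes, as a percentage.
#'
#' @param area_spiked_pre Area of the sample spiked before extraction.
#' @param areas_spiked_post Replicate areas of samples spiked after
#'   extraction.
#' @return Recovery in percent.
#' @export
compute_recovery <- function(area_spiked_pre, areas_spiked_post) {
  m <- mean(areas_spiked_post)
  if (m <= 0) stop("post-extraction spike mean must be > 0")
  100 * area_spiked_pre / m
}

#' Matrix effect from calibration slopes
#'
#' `100 * slope_matrix / slope_solvent`; 100 % means no suppression or
#' enhancement.
#'
#' @param curve_matrix,curve_solvent Accepted `calibration_curve`s built in
#'   matrix and in solvent.
#' @return Matrix effect in percent.
#' @export
compute_matrix_effect <- function(curve_matrix, curve_solvent) {
  stopifnot(inherits(curve_matrix, "calibration_curve"),
            inherits(curve_solvent, "calibration_curve"))
  if (curve_solvent$slope == 0) stop("solvent slope is zero")
  if (!curve_matrix$accepted || !curve_solvent$accepted)
    warning("matrix effect computed from non-accepted calibration curve(s)")
  100 * curve_matrix$slope / curve_solvent$slope
}

#' Trueness and precision from a QC design
#'
#' QC samples measured in replicate at several spike levels on several
#' days. Per level: trueness = 100 * mean(measured)/nominal; repeatability
#' CV = pooled within-day relative standard deviation; intermediate
#' precision CV from the one-way (by day) variance decomposition,
#' sqrt(within-day variance + between-day variance component) relative to
#' the grand mean.
#'
#' @param qc Data frame with columns `level` (nominal µM), `day`,
#'   `replicate`, `measured` (µM).
#' @param max_missing_fraction Maximum tolerated fraction of missing
#'   level-day combinations (default 0.2).
#' @return Data frame of class `validation_precision`: one row per level
#'   with `nominal`, `trueness_pct`, `repeatability_cv_pct`,
#'   `intermediate_cv_pct`, `n_days`, `n`.
#' @export
precision_trueness <- function(qc, max_missing_fraction = 0.2) {
  stopifnot(all(c("level", "day", "measured") %in% names(qc)))
  qc <- qc[!is.na(qc$measured), ]
  out <- lapply(sort(unique(qc$level)), function(lv) {
    d <- qc[qc$level == lv, ]
    days <- unique(d$day)
    if (length(days) < 2L) stop("precision requires at least 2 days")
    reps <- table(d$day)
    if (any(reps < 2L)) stop("need at least 2 replicates per day and level")
    n_expected <- length(unique(qc$day))
    if (1 - length(days) / n_expected > max_missing_fraction)
      stop("too many missing level/day combinations")
    grand <- mean(d$measured)
    day_means <- tapply(d$measured, d$day, mean)
    n0 <- mean(reps)  # balanced designs: replicates per day
    ss_w <- sum((d$measured - day_means[as.character(d$day)])^2)
    ms_w <- ss_w / (nrow(d) - length(days))
    ss_b <- sum(reps * (day_means - grand)^2)
    ms_b <- ss_b / (length(days) - 1)
    var_between <- max(0, (ms_b - ms_w) / n0)
    data.frame(nominal = lv, trueness_pct = 100 * grand / lv,
               repeatability_cv_pct = 100 * sqrt(ms_w) / grand,
               intermediate_cv_pct = 100 * sqrt(ms_w + var_between) / grand,
               n_days = length(days), n = nrow(d))
  })
  structure(do.call(rbind, out),
            class = c("validation_precision", "data.frame"))
}

#' Measure analyte peak areas in a run
#'
#' For each library entry: extract the MS1 chromatogram at the adduct m/z,
#' detect peaks and keep the one nearest the expected retention time
#' (within `rt_window`).
#'
#' @param run An `aif_run`.
#' @param lib Library rows (with `name`, `formula`, `adduct`,
#'   `expected_rt`).
#' @param ppm Mass tolerance (default 5).
#' @param rt_window Maximum apex distance from the expected rt (default
#'   0.3 min; ignored when no expected rt exists).
#' @param min_snr Peak-detection S/N threshold.
#' @return Data frame: `name`, `apex_rt`, `height`, `area`, `snr` (`NA`
#'   rows for undetected analytes).
#' @export
measure_areas <- function(run, lib, ppm = 5, rt_window = 0.3, min_snr = 3) {
  out <- lapply(seq_len(nrow(lib)), function(i) {
    mz <- ion_mz(lib$formula[i], lib$adduct[i])$mz
    x <- extract_xic(run, mz, tol = ppm, ms_level = 1L)
    pk <- detect_peaks(x, min_snr = min_snr)
    exp_rt <- if ("expected_rt" %in% names(lib)) lib$expected_rt[i] else NA
    if (nrow(pk) && !is.na(exp_rt)) {
      pk <- pk[abs(pk$apex_rt - exp_rt) <= rt_window, , drop = FALSE]
    }
    best <- .best_peak(pk, exp_rt)
    if (is.null(best))
      return(data.frame(name = lib$name[i], apex_rt = NA_real_,
                        height = NA_real_, area = NA_real_, snr = NA_real_))
    data.frame(name = lib$name[i], apex_rt = best$apex_rt,
               height = best$height, area = best$area, snr = best$snr)
  })
  do.call(rbind, out)
}

#' Analyte/IS area ratios for a set of runs
#'
#' Convenience wrapper used by the calibration and QC workflows: measures
#' areas in every run and returns the analyte/IS ratio per run and analyte.
#'
#' @param runs Named list of `aif_run`.
#' @param lib Full library (analytes and their internal standards).
#' @param analytes Names of the analytes to ratio (default: all non-IS
#'   rows of `lib`).
#' @param ... Passed to [measure_areas()].
#' @return Data frame: `run_id`, `name`, `area`, `is_area`, `ratio`,
#'   `snr`.
#' @export
measure_area_ratios <- function(runs, lib, analytes = NULL, ...) {
  if (is.null(analytes)) analytes <- lib$name[!lib$is_internal_standard]
  out <- lapply(names(runs), function(id) {
    m <- measure_areas(runs[[id]], lib, ...)
    rownames(m) <- m$name
    do.call(rbind, lapply(analytes, function(a) {
      isn <- lib$internal_standard_ref[lib$name == a]
      data.frame(run_id = id, name = a, area = m[a, "area"],
                 is_area = m[isn, "area"],
                 ratio = m[a, "area"] / m[isn, "area"],
                 snr = m[a, "snr"], stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, out)
}
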