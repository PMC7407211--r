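# Extracted-ion chromatograms and peak handling. This replaces the vendor
# integration algorithm; equivalence with vendor output is not claimed.

#' Extract an ion chromatogram
#'
#' One point per scan at the requested MS level: the sum of centroid
#' intensities inside the ppm window (zero when no centroid falls inside —
#' this zero-filling is deliberate and affects the MAD noise estimate).
#'
#' @param run An `aif_run`.
#' @param mz Target m/z (Da).
#' @param tol Mass tolerance in ppm (default 5).
#' @param ms_level 1 (full scans) or 2 (AIF scans).
#' @return A list of class `xic` with `target_mz`, `tol_ppm`, `ms_level`,
#'   `rt` (minutes, ascending) and `intensity`.
#' @export
extract_xic <- function(run, mz, tol = 5, ms_level = 1L) {
  stopifnot(inherits(run, "aif_run"))
  w <- ppm_window(mz, tol)
  keep <- vapply(run$spectra, function(s) s$ms_level == ms_level, TRUE)
  if (!any(keep)) stop("run has no scans at ms_level ", ms_level)
  sp <- run$spectra[keep]
  rt <- vapply(sp, function(s) s$rt, 0)
  inten <- vapply(sp, function(s) {
    lo <- findInterval(w[1], s$mz, left.open = TRUE) + 1L
    hi <- findInterval(w[2], s$mz)
    if (hi < lo) 0 else sum(s$intensity[lo:hi])
  }, 0)
  structure(list(target_mz = mz, tol_ppm = tol, ms_level = as.integer(ms_level),
                 rt = rt, intensity = inten), class = "xic")
}

#' @export
print.xic <- function(x, ...) {
  cat(sprintf("<xic> m/z %.4f +/- %g ppm, MS%d, %d scans, max %.3g\n",
              x$target_mz, x$tol_ppm, x$ms_level, length(x$rt),
              if (length(x$intensity)) max(x$intensity) else 0))
  invisible(x)
}

#' @export
plot.xic <- function(x, ...) {
  plot(x$rt, x$intensity, type = "l", xlab = "retention time (min)",
       ylab = "intensity (counts)",
       main = sprintf("m/z %.4f (MS%d)", x$target_mz, x$ms_level), ...)
  invisible(x)
}

# MAD-based noise; values negligible relative to the trace maximum are
# treated as exactly zero so noiseless traces flag an infinite SNR.
.robust_noise <- function(baseline_values, ref) {
  n <- 1.4826 * stats::mad(baseline_values, constant = 1)
  if (ref > 0 && n < 1e-9 * ref) 0 else n
}

.moving_mean <- function(x, k = 5L) {
  if (length(x) < k) return(x)
  pad <- (k - 1L) %/% 2L
  xx <- c(rep(x[1], pad), x, rep(x[length(x)], pad))
  as.numeric(stats::filter(xx, rep(1 / k, k), sides = 2))[(pad + 1L):(pad + length(x))]
}

#' Detect chromatographic peaks in an XIC
#'
#' Local maxima of the 5-point-smoothed trace above a robust noise
#' threshold; bounds at flanking valleys or baseline return; overlapping
#' peaks are split at the valley. Height and area are computed on the raw
#' trace after subtracting the baseline level (median of out-of-peak
#' intensities); the reported height is the baseline-subtracted smoothed
#' apex, which is far less biased by single-scan noise than a raw maximum.
#' Noise is `1.4826 * MAD` of the raw trace outside all
#' detected peak bounds; when that noise is exactly zero the peak SNR is
#' `Inf` (flagged via `noise = 0`). The detection threshold is applied to
#' the smoothed apex height so single-scan noise spikes are not reported
#' as peaks.
#'
#' @param xic An `xic`.
#' @param min_snr Minimum signal-to-noise to keep a peak (default 3,
#'   matching the detection-limit rule).
#' @param min_points Minimum number of scans required (default 5).
#' @return A data frame of class `peak_table`: `apex_rt`, `left_rt`,
#'   `right_rt`, `height`, `area`, `snr`, sorted by `apex_rt`, with the
#'   noise estimate in `attr(, "noise")`.
#' @export
detect_peaks <- function(xic, min_snr = 3, min_points = 5L) {
  stopifnot(inherits(xic, "xic"))
  n <- length(xic$intensity)
  if (n < min_points) stop("trace has fewer than min_points scans")
  empty <- structure(data.frame(apex_rt = numeric(0), left_rt = numeric(0),
                                right_rt = numeric(0), height = numeric(0),
                                area = numeric(0), snr = numeric(0)),
                     class = c("peak_table", "data.frame"), noise = 0)
  y <- .moving_mean(xic$intensity)
  if (max(y) <= 0) return(empty)
  # candidate apices: strict local maxima of the smoothed trace
  apex <- which(diff(sign(diff(y))) < 0) + 1L
  apex <- apex[y[apex] > 0]
  if (!length(apex)) return(empty)
  apex <- apex[order(y[apex], decreasing = TRUE)]
  base_level <- stats::median(y)
  bounds <- matrix(NA_integer_, nrow = 0, ncol = 3)
  for (a in apex) {
    if (nrow(bounds) &&
        any(a >= bounds[, 1] & a <= bounds[, 2])) next  # inside a found peak
    floor_y <- base_level + 0.01 * y[a]
    l <- a
    while (l > 1L && y[l - 1L] <= y[l] && y[l] > floor_y) l <- l - 1L
    r <- a
    while (r < n && y[r + 1L] <= y[r] && y[r] > floor_y) r <- r + 1L
    bounds <- rbind(bounds, c(l, r, a))
  }
  colnames(bounds) <- c("l", "r", "a")
  bounds <- bounds[order(bounds[, "a"]), , drop = FALSE]
  # split overlaps at the shared valley scan
  if (nrow(bounds) > 1L) for (i in seq_len(nrow(bounds) - 1L)) {
    if (bounds[i, "r"] > bounds[i + 1L, "l"]) {
      lo <- bounds[i, "a"]; hi <- bounds[i + 1L, "a"]
      valley <- lo + which.min(y[lo:hi]) - 1L
      bounds[i, "r"] <- valley
      bounds[i + 1L, "l"] <- valley
    }
  }
  in_peak <- logical(n)
  for (i in seq_len(nrow(bounds)))
    in_peak[bounds[i, "l"]:bounds[i, "r"]] <- TRUE
  baseline <- if (all(in_peak)) 0 else stats::median(xic$intensity[!in_peak])
  noise <- if (all(in_peak)) 0 else
    .robust_noise(xic$intensity[!in_peak], max(xic$intensity))
  pk <- do.call(rbind, lapply(seq_len(nrow(bounds)), function(i) {
    l <- bounds[i, "l"]; r <- bounds[i, "r"]
    seg <- xic$intensity[l:r]
    if (r - l + 1L < min_points) return(NULL)
    # detection threshold on the smoothed apex: the 5-point mean suppresses
    # single-scan noise spikes that would otherwise pass a raw-height test
    a <- bounds[i, "a"]
    if (noise > 0 && y[a] - baseline < min_snr * noise) return(NULL)
    sm <- y[l:r]
    apex_i <- l + which.max(seg) - 1L
    height <- max(sm) - baseline
    area <- integrate_xic(xic, xic$rt[l], xic$rt[r]) -
      baseline * (xic$rt[r] - xic$rt[l])
    data.frame(apex_rt = xic$rt[apex_i], left_rt = xic$rt[l],
               right_rt = xic$rt[r], height = height, area = area,
               snr = if (noise == 0) Inf else height / noise)
  }))
  if (is.null(pk)) return(empty)
  pk <- pk[pk$snr >= min_snr & pk$area > 0, , drop = FALSE]
  pk <- pk[order(pk$apex_rt), , drop = FALSE]
  rownames(pk) <- NULL
  structure(pk, class = c("peak_table", "data.frame"), noise = noise)
}

#' Trapezoidal integration of an XIC segment
#'
#' @param xic An `xic`.
#' @param left_rt,right_rt Bounds in minutes, inside the trace and ordered.
#' @return Area in counts·min.
#' @export
integrate_xic <- function(xic, left_rt, right_rt) {
  stopifnot(inherits(xic, "xic"))
  if (left_rt > right_rt) stop("inverted integration bounds")
  if (left_rt < min(xic$rt) - 1e-9 || right_rt > max(xic$rt) + 1e-9)
    stop("integration bounds outside the trace")
  sel <- xic$rt >= left_rt & xic$rt <= right_rt
  if (sum(sel) < 2L) return(0)
  rt <- xic$rt[sel]; y <- xic$intensity[sel]
  sum(diff(rt) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Signal-to-noise of a peak within its trace
#'
#' Noise is the robust spread (`1.4826 * MAD`) of raw intensities outside
#' the bounds of all detected peaks; a zero-noise (synthetic noiseless)
#' trace yields `Inf`, flagged by the `"noise"` attribute.
#'
#' @param xic An `xic`.
#' @param peak A one-row slice of a `peak_table` (or list with `left_rt`,
#'   `right_rt`, `height`).
#' @param peaks Optional full `peak_table` whose bounds are all excluded
#'   from the baseline; defaults to `peak` alone.
#' @param min_baseline_points Minimum scans that must remain in the
#'   baseline (default 5).
#' @return SNR (dimensionless), with attribute `noise`.
#' @export
estimate_snr <- function(xic, peak, peaks = NULL, min_baseline_points = 5L) {
  stopifnot(inherits(xic, "xic"))
  if (is.null(peaks)) peaks <- peak
  base <- rep(TRUE, length(xic$rt))
  for (i in seq_len(nrow(as.data.frame(peaks))))
    base[xic$rt >= peaks$left_rt[i] & xic$rt <= peaks$right_rt[i]] <- FALSE
  if (sum(base) < min_baseline_points)
    stop("trace leaves fewer than ", min_baseline_points, " baseline scans")
  noise <- .robust_noise(xic$intensity[base], max(xic$intensity))
  snr <- if (noise == 0) Inf else peak$height / noise
  structure(snr, noise = noise)
}

#' Do two peaks co-elute?
#'
#' `TRUE` iff the apex distance is within `rt_tol` and the rt intervals
#' overlap.
#'
#' @param peak_a,peak_b One-row peak records.
#' @param rt_tol Apex tolerance in minutes (default 0.1).
#' @return Logical.
#' @export
coelute <- function(peak_a, peak_b, rt_tol = 0.1) {
  abs(peak_a$apex_rt - peak_b$apex_rt) <= rt_tol &&
    peak_a$left_rt <= peak_b$right_rt && peak_b$left_rt <= peak_a$right_rt
}
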