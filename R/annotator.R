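# Identification logic: three-criteria selectivity confirmation, untargeted
# bile-acid and lysophospholipid screening over a candidate space,
# sn-positional-isomer assignment and retention-time prediction.

# Map a compound-level class tag (possibly combined with "+") to the
# diagnostic fragments expected in AIF scans. Tags without registered
# fragments (e.g. unconjugated "bile-acid") contribute none.
.TAG_MAP <- c(LPC = "LPL-headgroup-PC", `O-LPC` = "LPL-headgroup-PC",
              LPE = "LPL-headgroup-PE", LPI = "LPL-headgroup-PI",
              LPS = "LPL-headgroup-PS", LPG = "LPL-headgroup-PG")

#' Diagnostic fragments expected for a compound class tag
#'
#' Combined tags are joined with `+` (e.g. `"glycine-conjugate+sulfate"`,
#' `"LPC+fatty-acyl(16:0)"`). Lipid-class shorthands (LPC, LPE, ...) map to
#' their head-group registry entries. Tags without registered fragments
#' (unconjugated bile acids) yield an empty set.
#'
#' @param class_tag Compound class tag.
#' @return Data frame in the [fragment_registry()] layout (possibly empty).
#' @export
class_fragments <- function(class_tag) {
  tags <- strsplit(class_tag, "+", fixed = TRUE)[[1]]
  tags <- ifelse(tags %in% names(.TAG_MAP), .TAG_MAP[tags], tags)
  out <- lapply(tags, function(tg) {
    tryCatch(fragment_registry(tg), error = function(e) NULL)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(name = character(0), composition = character(0),
                      kind = character(0), mz = numeric(0),
                      loss_mass = numeric(0), class_tag = character(0))
  out
}

.best_peak <- function(peaks, expected_rt = NA) {
  if (!nrow(peaks)) return(NULL)
  i <- if (!is.na(expected_rt)) which.min(abs(peaks$apex_rt - expected_rt))
       else which.max(peaks$height)
  peaks[i, , drop = FALSE]
}

# Does any detected peak in the fragment-level XIC co-elute with ms1_peak?
.fragment_coelutes <- function(run, fmz, ms1_peak, ppm, rt_tol, min_snr) {
  x2 <- extract_xic(run, fmz, tol = ppm, ms_level = 2L)
  pk2 <- detect_peaks(x2, min_snr = min_snr)
  any(vapply(seq_len(nrow(pk2)), function(i)
    coelute(pk2[i, ], ms1_peak, rt_tol), TRUE))
}

#' Confirm an analyte's identity by the three selectivity criteria
#'
#' 1. a peak in the MS1 chromatogram extracted at the analyte m/z
#'    (+/- `ppm`); 2. a co-eluting peak in a fragment-level chromatogram of
#'    at least one class-diagnostic fragment (for classes without
#'    diagnostic fragments, the surviving precursor in the AIF scans is
#'    used); 3. the apex retention time matches the reference standard's
#'    within `rt_tol`. An analyte is confirmed when criteria 1 and 2 hold
#'    and criterion 3 holds or no standard retention time exists
#'    (`rt_source = "predicted"`).
#'
#' @param run An `aif_run`.
#' @param compound One library row (or list) with `name`, `class_tag`,
#'   `formula`, `adduct`, `expected_rt`, `rt_source`.
#' @param rt_tol Apex tolerance in minutes (default 0.1).
#' @param ppm Mass tolerance (default 5).
#' @param min_snr Peak-detection S/N threshold (default 3).
#' @return A list of class `annotation`: the three criteria, matched
#'   fragments, the MS1 peak and `confirmed`.
#' @export
confirm_identity <- function(run, compound, rt_tol = 0.1, ppm = 5,
                             min_snr = 3) {
  mz <- ion_mz(compound$formula, compound$adduct)$mz
  x1 <- extract_xic(run, mz, tol = ppm, ms_level = 1L)
  pk1 <- detect_peaks(x1, min_snr = min_snr)
  expected_rt <- if (!is.null(compound$expected_rt)) compound$expected_rt else NA
  has_std_rt <- !is.na(expected_rt) &&
    identical(compound$rt_source, "standard")
  best <- .best_peak(pk1, expected_rt)
  criterion_ms1 <- !is.null(best)
  matched <- character(0)
  criterion_ms2 <- FALSE
  if (criterion_ms1) {
    frs <- class_fragments(compound$class_tag)
    if (!nrow(frs))   # no diagnostic fragments: use the surviving precursor
      frs <- data.frame(name = "precursor (AIF survivor)", kind = "anion",
                        mz = mz, loss_mass = NA_real_)
    for (i in seq_len(nrow(frs))) {
      fmz <- if (frs$kind[i] == "anion") frs$mz[i] else mz - frs$loss_mass[i]
      if (.fragment_coelutes(run, fmz, best, ppm, rt_tol, min_snr))
        matched <- c(matched, frs$name[i])
    }
    criterion_ms2 <- length(matched) > 0
  }
  criterion_rt <- if (!criterion_ms1 || !has_std_rt) NA else
    abs(best$apex_rt - expected_rt) <= rt_tol
  confirmed <- isTRUE(criterion_ms1) && isTRUE(criterion_ms2) &&
    (isTRUE(criterion_rt) || !has_std_rt)
  structure(list(compound = compound$name, mz = mz, ms1_peak = best,
                 criterion_ms1 = criterion_ms1,
                 criterion_ms2_fragment = criterion_ms2,
                 matched_fragments = matched, criterion_rt = criterion_rt,
                 confirmed = confirmed), class = "annotation")
}

#' @export
print.annotation <- function(x, ...) {
  cat(sprintf("<annotation> %s m/z %.4f: MS1 %s, MS2 %s (%s), RT %s -> %s\n",
              x$compound, x$mz, x$criterion_ms1, x$criterion_ms2_fragment,
              if (length(x$matched_fragments))
                paste(x$matched_fragments, collapse = "; ") else "none",
              ifelse(is.na(x$criterion_rt), "n/a", x$criterion_rt),
              if (x$confirmed) "CONFIRMED" else "not confirmed"))
  invisible(x)
}

#' Candidate space for untargeted bile-acid screening
#'
#' Cross product of C24 cholanoic-acid cores carrying 1-3 hydroxyls with
#' conjugations (none, glycine, taurine, sulfate, glucuronide) and their
#' pairwise combinations (capped at two groups; the two amidations never
#' co-occur).
#'
#' @return Data frame with `name`, `formula`, `class_tag`, `mz`
#'   (deprotonated).
#' @export
bile_acid_candidates <- function() {
  cores <- data.frame(core = c("mono-OH", "di-OH", "tri-OH"),
                      formula = c("C24H40O3", "C24H40O4", "C24H40O5"),
                      stringsAsFactors = FALSE)
  add <- list("glycine-conjugate" = c(C = 2, H = 3, N = 1, O = 1),
              "taurine-conjugate" = c(C = 2, H = 5, N = 1, O = 2, S = 1),
              "sulfate" = c(S = 1, O = 3),
              "glucuronide" = c(C = 6, H = 8, O = 6))
  combos <- c(list(character(0)), as.list(names(add)),
              list(c("glycine-conjugate", "sulfate"),
                   c("taurine-conjugate", "sulfate"),
                   c("glycine-conjugate", "glucuronide"),
                   c("taurine-conjugate", "glucuronide"),
                   c("sulfate", "glucuronide")))
  out <- list()
  for (i in seq_len(nrow(cores))) for (cb in combos) {
    f <- parse_formula(cores$formula[i])
    v <- stats::setNames(as.numeric(f), names(f))
    for (g in cb) {
      a <- add[[g]]
      for (el in names(a)) v[el] <- ifelse(el %in% names(v), v[el], 0) + a[el]
    }
    comp <- format_formula(v)
    tag <- if (length(cb)) paste(cb, collapse = "+") else "bile-acid"
    out[[length(out) + 1L]] <- data.frame(
      name = paste0(cores$core[i],
                    if (length(cb)) paste0("+", paste(cb, collapse = "+")) else ""),
      formula = comp, class_tag = tag,
      mz = ion_mz(comp, "[M-H]-")$mz, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

.screen_candidates <- function(run, cands, ppm, rt_tol, min_snr,
                               ms1_range = c(-Inf, Inf)) {
  hits <- list()
  for (i in seq_len(nrow(cands))) {
    if (cands$mz[i] < ms1_range[1] || cands$mz[i] > ms1_range[2]) next
    x1 <- extract_xic(run, cands$mz[i], tol = ppm, ms_level = 1L)
    pk1 <- detect_peaks(x1, min_snr = min_snr)
    if (!nrow(pk1)) next
    frs <- class_fragments(cands$class_tag[i])
    for (p in seq_len(nrow(pk1))) {
      pk <- pk1[p, , drop = FALSE]
      matched <- character(0)
      if (nrow(frs)) for (j in seq_len(nrow(frs))) {
        fmz <- if (frs$kind[j] == "anion") frs$mz[j]
               else cands$mz[i] - frs$loss_mass[j]
        if (.fragment_coelutes(run, fmz, pk, ppm, rt_tol, min_snr))
          matched <- c(matched, frs$name[j])
      }
      hits[[length(hits) + 1L]] <- data.frame(
        candidate = cands$name[i], class_tag = cands$class_tag[i],
        formula = cands$formula[i], query_mz = cands$mz[i],
        apex_rt = pk$apex_rt, height = pk$height, area = pk$area,
        n_expected_fragments = nrow(frs), n_matched = length(matched),
        matched_fragments = paste(matched, collapse = "; "),
        score = if (nrow(frs)) length(matched) / nrow(frs) else 0,
        mass_only = length(matched) == 0L, stringsAsFactors = FALSE)
    }
  }
  if (!length(hits))
    return(data.frame(candidate = character(0), class_tag = character(0),
                      formula = character(0), query_mz = numeric(0),
                      apex_rt = numeric(0), height = numeric(0),
                      area = numeric(0), n_expected_fragments = integer(0),
                      n_matched = integer(0),
                      matched_fragments = character(0), score = numeric(0),
                      mass_only = logical(0)))
  do.call(rbind, hits)
}

#' Untargeted bile-acid screen
#'
#' For every candidate's deprotonated mass, detect MS1 peaks and test
#' which conjugate diagnostic fragments co-elute. Candidates without
#' diagnostic fragments (unconjugated) are reported as `mass_only` hits.
#'
#' @param run An `aif_run`.
#' @param candidates Candidate table, default [bile_acid_candidates()].
#' @param ppm,rt_tol,min_snr Tolerances (defaults 5 ppm, 0.1 min, S/N 3).
#' @return Data frame of candidate hits, one row per (candidate, MS1 peak),
#'   with a co-elution `score` (fraction of expected fragments matched).
#' @export
screen_bile_acids <- function(run, candidates = bile_acid_candidates(),
                              ppm = 5, rt_tol = 0.1, min_snr = 3) {
  if (!nrow(candidates)) stop("empty candidate space")
  .screen_candidates(run, candidates, ppm, rt_tol, min_snr,
                     ms1_range = run$metadata$ms1_range)
}

.LPL_FORMULA <- list(
  LPC     = function(n, db) sprintf("C%dH%dNO7P", n + 8, 2 * n - 2 * db + 18),
  `O-LPC` = function(n, db) sprintf("C%dH%dNO6P", n + 8, 2 * n - 2 * db + 20),
  LPE     = function(n, db) sprintf("C%dH%dNO7P", n + 5, 2 * n - 2 * db + 12),
  LPI     = function(n, db) sprintf("C%dH%dO12P", n + 9, 2 * n - 2 * db + 17),
  LPS     = function(n, db) sprintf("C%dH%dNO9P", n + 6, 2 * n - 2 * db + 12),
  LPG     = function(n, db) sprintf("C%dH%dO9P",  n + 6, 2 * n - 2 * db + 13))

#' Lysophospholipid candidate space
#'
#' Classes LPC and O-LPC (acetate adduct) and LPE/LPI/LPS/LPG
#' (deprotonated), acyl chains C12-C22 with 0-6 double bonds.
#'
#' @param carbons,double_bonds Integer vectors spanning the acyl space.
#' @param classes Head-group classes to include.
#' @return Data frame with `name`, `class`, `carbons`, `double_bonds`,
#'   `formula`, `adduct`, `class_tag`, `mz`.
#' @export
lpl_candidates <- function(carbons = 12:22, double_bonds = 0:6,
                           classes = names(.LPL_FORMULA)) {
  grid <- expand.grid(class = classes, n = carbons, db = double_bonds,
                      stringsAsFactors = FALSE)
  grid <- grid[2 * grid$n - 2 * grid$db - 1 > 0, ]
  out <- lapply(seq_len(nrow(grid)), function(i) {
    cl <- grid$class[i]; n <- grid$n[i]; db <- grid$db[i]
    comp <- .LPL_FORMULA[[cl]](n, db)
    adduct <- if (cl %in% c("LPC", "O-LPC")) "[M+CH3COO]-" else "[M-H]-"
    data.frame(name = sprintf("%s(%d:%d)", cl, n, db), class = cl,
               carbons = n, double_bonds = db, formula = comp,
               adduct = adduct,
               class_tag = sprintf("%s+fatty-acyl(%d:%d)", cl, n, db),
               mz = ion_mz(comp, adduct)$mz, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Untargeted lysophospholipid screen
#'
#' A hit requires an MS1 peak at the class-appropriate adduct mass; the
#' co-eluting acyl carboxylate and/or head-group fragment assigns the acyl
#' chain and the class. The adduct rule (acetate if and only if a choline
#' lipid) is built into the candidate space, so a head-group assignment can
#' never conflict with the adduct. Hits with no co-eluting fragment are
#' reported `mass_only` (unconfirmed).
#'
#' @param run An `aif_run`.
#' @param candidates Candidate table from [lpl_candidates()].
#' @param ppm,rt_tol,min_snr Tolerances.
#' @return Data frame of candidate hits (see [screen_bile_acids()]).
#' @export
screen_lpl <- function(run, candidates = lpl_candidates(), ppm = 5,
                       rt_tol = 0.1, min_snr = 3) {
  if (!nrow(candidates)) stop("empty candidate space")
  .screen_candidates(run, candidates, ppm, rt_tol, min_snr,
                     ms1_range = run$metadata$ms1_range)
}

#' Assign sn-positional isomer labels to an LPL's peaks
#'
#' With exactly two peaks separated by an offset inside
#' `rt_offset_range` and a minor/major area ratio at most `ratio_max`,
#' the pair is labelled as positional isomers: with `sn2_first = TRUE`
#' (default) the earlier peak is the 2-acyl isomer and the later the
#' 1-acyl isomer. Otherwise only the dominant peak is labelled `sn1`.
#' The `consistent` attribute records whether the minor peak eluted
#' first, flagging runs that contradict the expected elution order
#' instead of silently relabelling them.
#'
#' @param peaks A `peak_table` from one LPL's MS1 XIC.
#' @param rt_offset_range Allowed apex separation, minutes
#'   (default 0.15-0.5).
#' @param ratio_max Maximum minor/major area ratio for a pair
#'   (default 0.35).
#' @param sn2_first Expected elution order (2-isomer first).
#' @return The peaks with an `isomer_label` column (`"sn1"`, `"sn2"` or
#'   `NA`), plus attributes `consistent` and `pair`.
#' @export
assign_sn_isomers <- function(peaks, rt_offset_range = c(0.15, 0.5),
                              ratio_max = 0.35, sn2_first = TRUE) {
  peaks <- as.data.frame(peaks)
  if (!nrow(peaks)) stop("no peaks to label")
  peaks <- peaks[order(peaks$apex_rt), , drop = FALSE]
  rownames(peaks) <- NULL
  peaks$isomer_label <- NA_character_
  consistent <- NA; pair <- FALSE
  if (nrow(peaks) == 2L) {
    offset <- diff(peaks$apex_rt)
    ratio <- min(peaks$area) / max(peaks$area)
    if (offset >= rt_offset_range[1] && offset <= rt_offset_range[2] &&
        ratio <= ratio_max) {
      pair <- TRUE
      peaks$isomer_label <- if (sn2_first) c("sn2", "sn1") else c("sn1", "sn2")
      consistent <- peaks$area[1] < peaks$area[2]  # minor eluted first?
      if (!sn2_first) consistent <- !consistent
    }
  }
  if (!pair) peaks$isomer_label[which.max(peaks$area)] <- "sn1"
  structure(peaks, consistent = consistent, pair = pair)
}

#' Predict a lysophospholipid's retention time within a class
#'
#' Least-squares plane `rt = a + b * carbons + c * double_bonds` over the
#' class anchors (equivalent-carbon-number convention).
#'
#' @param carbons,double_bonds Acyl descriptors of the query.
#' @param anchors Data frame with columns `carbons`, `double_bonds`, `rt`
#'   (>= 3 rows within the class).
#' @param tol Stated prediction tolerance, minutes (default 0.3).
#' @return Predicted rt (minutes) with attribute `tol`.
#' @export
predict_rt <- function(carbons, double_bonds, anchors, tol = 0.3) {
  if (nrow(anchors) < 3L) stop("need at least 3 retention-time anchors")
  fit <- stats::lm(rt ~ carbons + double_bonds, data = anchors)
  p <- stats::predict(fit, newdata = data.frame(carbons = carbons,
                                                double_bonds = double_bonds))
  structure(unname(p), tol = tol)
}
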