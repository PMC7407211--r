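# Containers for spectra and runs, plus readers/writers for the formats the
# pipeline touches: mzML (interchange), JSON-lines (diffable fixtures), TSV
# compound libraries / sample sheets, CSV result tables.

#' Construct a single spectrum
#'
#' @param ms_level 1 (full scan) or 2 (all-ion fragmentation scan).
#' @param rt Retention time in minutes.
#' @param mz Centroid m/z values (will be sorted ascending).
#' @param intensity Centroid intensities (counts, >= 0).
#' @param aif Logical; `TRUE` for fragment-level scans acquired without
#'   precursor isolation. Forced `TRUE` whenever `ms_level == 2`.
#' @return A list of class `aif_spectrum`.
#' @export
new_spectrum <- function(ms_level, rt, mz, intensity, aif = ms_level == 2L) {
  stopifnot(ms_level %in% c(1L, 2L), length(mz) == length(intensity))
  if (any(intensity < 0)) stop("intensities must be >= 0")
  o <- order(mz)
  mz <- as.numeric(mz[o]); intensity <- as.numeric(intensity[o])
  if (anyDuplicated(mz)) {
    # merge coincident centroids so the m/z axis stays strictly ascending
    intensity <- as.numeric(tapply(intensity, factor(mz, levels = unique(mz)), sum))
    mz <- unique(mz)
  }
  structure(list(ms_level = as.integer(ms_level), rt = as.numeric(rt),
                 mz = mz, intensity = intensity,
                 aif = isTRUE(aif) || ms_level == 2L),
            class = "aif_spectrum")
}

#' Construct an LC-MS run
#'
#' @param spectra List of `aif_spectrum`, any order (sorted by rt).
#' @param metadata Named list; defaults describe the negative-mode AIF
#'   acquisition this package targets (MS1 m/z 370-700, NCE 50).
#' @return A list of class `aif_run`.
#' @export
new_run <- function(spectra, metadata = list()) {
  if (!length(spectra)) stop("a run needs at least one spectrum")
  rts <- vapply(spectra, function(s) s$rt, 0)
  spectra <- spectra[order(rts)]
  lv <- vapply(spectra, function(s) s$ms_level, 0L)
  if (!any(lv == 1L)) stop("run contains no MS1 scans")
  md <- utils::modifyList(list(polarity = "negative",
                               ms1_range = c(370, 700),
                               resolving_power_ms1 = 70000,
                               resolving_power_ms2 = 17500,
                               nce = 50), metadata)
  structure(list(spectra = spectra, metadata = md), class = "aif_run")
}

#' @export
print.aif_run <- function(x, ...) {
  lv <- vapply(x$spectra, function(s) s$ms_level, 0L)
  rts <- range(vapply(x$spectra, function(s) s$rt, 0))
  cat(sprintf("<aif_run> %d spectra (%d MS1, %d AIF), rt %.2f-%.2f min, %s mode\n",
              length(x$spectra), sum(lv == 1L), sum(lv == 2L),
              rts[1], rts[2], x$metadata$polarity))
  invisible(x)
}

#' Read a centroided mzML run
#'
#' Profile-mode data are rejected; MS2 scans without an isolation window are
#' flagged as all-ion fragmentation.
#'
#' @param path Path to an mzML file.
#' @return An `aif_run`.
#' @export
read_mzml <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  fh <- mzR::openMSfile(path)
  on.exit(mzR::close(fh))
  hdr <- mzR::header(fh)
  if (!nrow(hdr)) stop("empty mzML file")
  if (any(!is.na(hdr$centroided) & !hdr$centroided))
    stop("profile-mode spectra found; this reader requires centroided data")
  if (!any(hdr$msLevel == 1L)) stop("run contains no MS1 scans")
  pk <- mzR::peaks(fh)
  if (is.matrix(pk)) pk <- list(pk)
  spectra <- lapply(seq_len(nrow(hdr)), function(i) {
    aif <- hdr$msLevel[i] == 2L &&
      (is.na(hdr$isolationWindowTargetMZ[i]) ||
         hdr$isolationWindowTargetMZ[i] <= 0)
    new_spectrum(hdr$msLevel[i], hdr$retentionTime[i] / 60,
                 pk[[i]][, 1], pk[[i]][, 2], aif = aif)
  })
  pol <- if (all(hdr$polarity == 1L)) "positive" else "negative"
  new_run(spectra, metadata = list(polarity = pol, source = path))
}

#' Write a run to mzML
#'
#' @param run An `aif_run`.
#' @param path Output path (.mzML).
#' @return `path`, invisibly.
#' @export
write_mzml <- function(run, path) {
  stopifnot(inherits(run, "aif_run"))
  n <- length(run$spectra)
  lv <- vapply(run$spectra, function(s) s$ms_level, 0L)
  npk <- vapply(run$spectra, function(s) length(s$mz), 0L)
  tic <- vapply(run$spectra, function(s) sum(s$intensity), 0)
  bpi <- vapply(run$spectra, function(s) if (length(s$intensity)) max(s$intensity) else 0, 0)
  bpm <- vapply(run$spectra, function(s)
    if (length(s$mz)) s$mz[which.max(s$intensity)] else 0, 0)
  pol <- if (identical(run$metadata$polarity, "positive")) 1L else 0L
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n), msLevel = lv,
    polarity = rep(pol, n), peaksCount = npk, totIonCurrent = tic,
    retentionTime = vapply(run$spectra, function(s) s$rt, 0) * 60,
    basePeakMZ = bpm, basePeakIntensity = bpi,
    collisionEnergy = ifelse(lv == 2L, run$metadata$nce, NA_real_),
    ionisationEnergy = rep(0, n),
    lowMZ = vapply(run$spectra, function(s) if (length(s$mz)) min(s$mz) else 0, 0),
    highMZ = vapply(run$spectra, function(s) if (length(s$mz)) max(s$mz) else 0, 0),
    precursorScanNum = rep(NA_integer_, n), precursorMZ = rep(NA_real_, n),
    precursorCharge = rep(NA_integer_, n), precursorIntensity = rep(NA_real_, n),
    mergedScan = rep(NA_integer_, n), mergedResultScanNum = rep(NA_integer_, n),
    mergedResultStartScanNum = rep(NA_integer_, n),
    mergedResultEndScanNum = rep(NA_integer_, n),
    injectionTime = rep(0, n), filterString = rep(NA_character_, n),
    spectrumId = paste0("scan=", seq_len(n)), centroided = rep(TRUE, n),
    ionMobilityDriftTime = rep(NA_real_, n),
    isolationWindowTargetMZ = rep(NA_real_, n),
    isolationWindowLowerOffset = rep(NA_real_, n),
    isolationWindowUpperOffset = rep(NA_real_, n),
    scanWindowLowerLimit = rep(run$metadata$ms1_range[1], n),
    scanWindowUpperLimit = rep(run$metadata$ms1_range[2], n),
    stringsAsFactors = FALSE)
  pks <- lapply(run$spectra, function(s) cbind(mz = s$mz, intensity = s$intensity))
  mzR::writeMSData(pks, file = path, header = hdr)
  invisible(path)
}

#' Write / read the compact JSON-lines fixture format
#'
#' One JSON object per line, one line per spectrum; metadata on the first
#' line. Lossless for the fields the pipeline uses and diffable in review.
#'
#' @param run An `aif_run`.
#' @param path File path (.jsonl).
#' @return `path` / an `aif_run`.
#' @export
write_run_jsonl <- function(run, path) {
  stopifnot(inherits(run, "aif_run"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(jsonlite::toJSON(list(metadata = run$metadata),
                              auto_unbox = TRUE, digits = NA), con)
  for (s in run$spectra)
    writeLines(jsonlite::toJSON(list(ms_level = s$ms_level, rt = s$rt,
                                     aif = s$aif, mz = s$mz,
                                     intensity = s$intensity),
                                auto_unbox = TRUE, digits = NA), con)
  invisible(path)
}

#' @rdname write_run_jsonl
#' @export
read_run_jsonl <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  md <- jsonlite::fromJSON(lines[1])$metadata
  spectra <- lapply(lines[-1], function(l) {
    s <- jsonlite::fromJSON(l)
    new_spectrum(s$ms_level, s$rt, s$mz, s$intensity, aif = s$aif)
  })
  new_run(spectra, metadata = md)
}

#' Read a compound/standard library
#'
#' Tab-separated, one compound per row. Required columns: `name`,
#' `class_tag`, `formula`, `adduct`, `is_internal_standard`,
#' `internal_standard_ref`; optional: `expected_rt`, `rt_source`,
#' `nominal_is_concentration`. Formulas are parsed, adducts checked against
#' the supported negative-mode set, internal-standard references resolved
#' within the library and choline-lipid classes (LPC, O-LPC) required to use
#' the acetate adduct.
#'
#' @param path TSV path; default is the library shipped with the package
#'   (a reconstructed 26-bile-acid panel plus class-matched deuterated
#'   internal standards — synthetic reference data, not vendor-supplied).
#' @return A validated data frame with an added `mz` column.
#' @export
read_compound_library <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "compound_library.tsv", package = "aifquant")
    if (path == "") path <- file.path("inst", "extdata", "compound_library.tsv")
  }
  if (!file.exists(path)) stop("no such file: ", path)
  lib <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("name", "class_tag", "formula", "adduct",
            "is_internal_standard", "internal_standard_ref")
  miss <- setdiff(need, names(lib))
  if (length(miss)) stop("library is missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(lib$name))
    stop("duplicate compound names: ",
         paste(unique(lib$name[duplicated(lib$name)]), collapse = ", "))
  if (!all(lib$adduct %in% c("[M-H]-", "[M+CH3COO]-")))
    stop("unsupported adduct in library")
  choline <- grepl("^LPC|^O-LPC", lib$class_tag)
  if (any(choline != (lib$adduct == "[M+CH3COO]-")))
    stop("acetate adduct must be used for choline lipids (LPC/O-LPC) and only for them")
  lib$mz <- vapply(seq_len(nrow(lib)),
                   function(i) ion_mz(lib$formula[i], lib$adduct[i])$mz, 0)
  lib$is_internal_standard <- as.logical(lib$is_internal_standard)
  ref <- lib$internal_standard_ref
  dangling <- !is.na(ref) & nzchar(ref) & !(ref %in% lib$name)
  if (any(dangling))
    stop("dangling internal_standard_ref: ",
         paste(unique(ref[dangling]), collapse = ", "))
  if (is.null(lib$expected_rt)) lib$expected_rt <- NA_real_
  if (is.null(lib$rt_source)) lib$rt_source <- "standard"
  lib
}

#' Read a sample sheet
#'
#' @param path TSV with columns `run_id`, `role`
#'   (blank/calibrant/QC/study), `spike_stage` (pre/post/none), `day`,
#'   `replicate`, and one `conc_<analyte>` column per spiked analyte (µM).
#' @return A data frame.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  sh <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("run_id", "role")
  miss <- setdiff(need, names(sh))
  if (length(miss)) stop("sample sheet is missing columns: ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(sh$role), c("blank", "calibrant", "QC", "study"))
  if (length(bad)) stop("unknown role: ", paste(bad, collapse = ", "))
  cc <- grep("^conc_", names(sh), value = TRUE)
  if (any(sh$role == "calibrant") && !length(cc))
    stop("calibrant rows require conc_<analyte> columns")
  sh
}

#' Write result tables as CSV with a run log
#'
#' Deterministic column order, concentrations serialized at 4 significant
#' digits, missing values as empty cells. A `run_log.json` with the tool
#' version and a configuration hash accompanies every output set.
#'
#' @param tables Named list of data frames.
#' @param out_dir Output directory (created if absent).
#' @param config Optional named list recorded (hashed) in the run log.
#' @return Character vector of files written, invisibly.
#' @export
write_results <- function(tables, out_dir, config = list()) {
  stopifnot(is.list(tables), length(names(tables)) == length(tables))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (nm in names(tables)) {
    tab <- tables[[nm]]
    num <- vapply(tab, is.numeric, TRUE)
    tab[num] <- lapply(tab[num], function(x) ifelse(is.na(x), NA, signif(x, 4)))
    f <- file.path(out_dir, paste0(nm, ".csv"))
    utils::write.csv(tab, f, row.names = FALSE, na = "")
    files <- c(files, f)
  }
  cfg_file <- tempfile(fileext = ".json")
  jsonlite::write_json(config, cfg_file, auto_unbox = TRUE, digits = NA)
  log <- list(tool = "aifquant",
              version = as.character(utils::packageVersion("aifquant")),
              config_hash = unname(tools::md5sum(cfg_file)),
              files = basename(files),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  unlink(cfg_file)
  logf <- file.path(out_dir, "run_log.json")
  jsonlite::write_json(log, logf, auto_unbox = TRUE, digits = NA)
  invisible(c(files, logf))
}
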