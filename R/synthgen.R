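# Seeded generator of synthetic negative-mode AIF LC-MS runs, calibration /
# QC series, and cohort feature tables. The generator writes the same
# containers the readers produce, so every downstream module is testable
# without any instrument data.

#' Simulator configuration
#'
#' Defaults describe the acquisition the pipeline targets: one MS1 plus one
#' all-ion-fragmentation scan per cycle, 0.5 s sampling per level, a 19-min
#' gradient, MS1 m/z 370-700, +/- 2 ppm mass jitter and an additive noise
#' floor plus a 2 % proportional term. The noise floor (sd 6000 counts on a
#' response of 1e6 area units per µM) puts the S/N of a 0.003 µM analyte
#' near 5, i.e. just above the S/N >= 3 detection rule.
#'
#' @param scan_interval_s Sampling interval per MS level (seconds).
#' @param run_length_min Run length (minutes).
#' @param ms1_range,ms2_range Acquisition m/z ranges.
#' @param ppm_jitter Uniform mass jitter half-width (ppm).
#' @param noise_sd Additive baseline noise sd (counts); 0 for noiseless.
#' @param baseline_level Mean baseline offset (counts).
#' @param prop_noise Proportional intensity noise (fraction).
#' @param m1_per_carbon M+1 isotope abundance per carbon (0.0107).
#' @param precursor_survival Fraction of the precursor surviving in AIF
#'   scans (bile acids fragment weakly, so the deprotonated molecule is
#'   still visible at the fragment level).
#' @param seed Integer seed; a fixed seed gives a bit-identical run.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(scan_interval_s = 0.5, run_length_min = 19,
                       ms1_range = c(370, 700), ms2_range = c(50, 700),
                       ppm_jitter = 2, noise_sd = 6000,
                       baseline_level = 18000, prop_noise = 0.02,
                       m1_per_carbon = 0.0107, precursor_survival = 0.2,
                       seed = 1L) {
  stopifnot(scan_interval_s > 0, run_length_min > 0)
  structure(list(scan_interval_s = scan_interval_s,
                 run_length_min = run_length_min, ms1_range = ms1_range,
                 ms2_range = ms2_range, ppm_jitter = ppm_jitter,
                 noise_sd = noise_sd, baseline_level = baseline_level,
                 prop_noise = prop_noise, m1_per_carbon = m1_per_carbon,
                 precursor_survival = precursor_survival,
                 seed = as.integer(seed)), class = "sim_config")
}

#' Define a simulated compound
#'
#' @param name Compound name.
#' @param class_tag Class tag (`"bile-acid"`, `"glycine-conjugate"`,
#'   `"LPC+fatty-acyl(16:0)"`, combined tags joined with `+`, ...).
#' @param formula Neutral formula string.
#' @param adduct `"[M-H]-"` or `"[M+CH3COO]-"`.
#' @param conc True concentration (µM).
#' @param apex_rt Apex retention time (minutes).
#' @param response_factor Peak area (counts·min) per µM.
#' @param sigma Gaussian peak width (minutes).
#' @param fragment_yield Fraction of the precursor intensity carried by each
#'   diagnostic fragment in AIF scans.
#' @param sn2_fraction For lysophospholipids: fraction of the total signal
#'   eluting as the minor 2-acyl isomer (default 0.09, i.e. ~1:10).
#' @param sn_offset Minutes separating the 2-isomer (earlier) from the
#'   1-isomer (default 0.3).
#' @return A list of class `sim_compound`.
#' @export
sim_compound <- function(name, class_tag, formula, adduct, conc, apex_rt,
                         response_factor = 1e6, sigma = 0.04,
                         fragment_yield = 0.3, sn2_fraction = 0.09,
                         sn_offset = 0.3) {
  stopifnot(conc >= 0, sigma > 0, fragment_yield >= 0, fragment_yield <= 1,
            sn2_fraction >= 0, sn2_fraction < 1)
  structure(list(name = name, class_tag = class_tag, formula = formula,
                 adduct = adduct, conc = conc, apex_rt = apex_rt,
                 response_factor = response_factor, sigma = sigma,
                 fragment_yield = fragment_yield,
                 sn2_fraction = sn2_fraction, sn_offset = sn_offset,
                 mz = ion_mz(formula, adduct)$mz),
            class = "sim_compound")
}

#' Build simulated compounds from a compound library
#'
#' @param lib A library data frame from [read_compound_library()].
#' @param conc Named vector of concentrations (µM) for non-IS entries, or a
#'   single value applied to all; internal standards use their
#'   `nominal_is_concentration`.
#' @param ... Passed to [sim_compound()].
#' @return List of `sim_compound`.
#' @export
sim_from_library <- function(lib, conc, ...) {
  lapply(seq_len(nrow(lib)), function(i) {
    ci <- if (lib$is_internal_standard[i]) {
      lib$nominal_is_concentration[i]
    } else if (length(conc) == 1L && is.null(names(conc))) {
      conc
    } else {
      unname(conc[lib$name[i]])
    }
    if (is.na(ci)) stop("no concentration for '", lib$name[i], "'")
    sim_compound(lib$name[i], lib$class_tag[i], lib$formula[i],
                 lib$adduct[i], ci, lib$expected_rt[i], ...)
  })
}

.is_lpl_tag <- function(class_tag) grepl("(^|\\+)(O-)?LP[CEISG]", class_tag)

.carbon_count <- function(formula, adduct) {
  f <- parse_formula(formula)
  nC <- if ("C" %in% names(f)) f[["C"]] else 0L
  nC + if (adduct == "[M+CH3COO]-") 2L else 0L
}

#' Simulate one AIF LC-MS run
#'
#' MS1 scans carry Gaussian elution profiles at the adduct m/z (with ppm
#' jitter) plus M+1 isotope satellites; AIF scans carry the class
#' diagnostic fragments sharing the precursor's elution profile scaled by
#' the fragment yield, plus a surviving-precursor channel.
#' Lysophospholipids elute as an sn-isomer pair: the minor 2-isomer
#' `sn_offset` minutes before the major 1-isomer. Noise is an additive
#' baseline floor plus a proportional term.
#'
#' @param compounds List of [sim_compound()].
#' @param config A [sim_config()].
#' @return A list with `run` (an `aif_run`) and `truth` (a data frame of
#'   per-elution-component ground truth: name, component, mz, conc,
#'   apex_rt, area, sigma).
#' @export
simulate_run <- function(compounds, config = sim_config()) {
  stopifnot(length(compounds) > 0)
  set.seed(config$seed)
  dt <- config$scan_interval_s / 60
  t1 <- seq(0, config$run_length_min, by = dt)
  t2 <- t1 + dt / 2
  ch1_mz <- numeric(0); ch1_prof <- list()
  ch2_mz <- numeric(0); ch2_prof <- list()
  truth <- list()
  for (cp in compounds) {
    if (cp$mz < config$ms1_range[1] || cp$mz > config$ms1_range[2])
      stop("compound '", cp$name, "' is outside the simulable MS1 range")
    lpl <- .is_lpl_tag(cp$class_tag)
    comps <- if (lpl && cp$sn2_fraction > 0) {
      data.frame(component = c("sn2", "sn1"),
                 rt = c(cp$apex_rt - cp$sn_offset, cp$apex_rt),
                 frac = c(cp$sn2_fraction, 1 - cp$sn2_fraction))
    } else {
      data.frame(component = "main", rt = cp$apex_rt, frac = 1)
    }
    area_total <- cp$response_factor * cp$conc
    prof_at <- function(tt) {
      out <- numeric(length(tt))
      for (j in seq_len(nrow(comps))) {
        h <- area_total * comps$frac[j] / (cp$sigma * sqrt(2 * pi))
        out <- out + h * exp(-(tt - comps$rt[j])^2 / (2 * cp$sigma^2))
      }
      out
    }
    p1 <- prof_at(t1)
    ch1_mz <- c(ch1_mz, cp$mz); ch1_prof <- c(ch1_prof, list(p1))
    nC <- .carbon_count(cp$formula, cp$adduct)
    ch1_mz <- c(ch1_mz, isotope_m1(cp$mz))
    ch1_prof <- c(ch1_prof, list(p1 * config$m1_per_carbon * nC))
    # fragment-level channels
    p2 <- prof_at(t2)
    frs <- class_fragments(cp$class_tag)
    if (nrow(frs)) for (j in seq_len(nrow(frs))) {
      fmz <- if (frs$kind[j] == "anion") frs$mz[j] else cp$mz - frs$loss_mass[j]
      if (fmz < config$ms2_range[1] || fmz > config$ms2_range[2]) next
      ch2_mz <- c(ch2_mz, fmz)
      ch2_prof <- c(ch2_prof, list(p2 * cp$fragment_yield))
    }
    ch2_mz <- c(ch2_mz, cp$mz)
    ch2_prof <- c(ch2_prof, list(p2 * config$precursor_survival))
    truth[[cp$name]] <- data.frame(
      name = cp$name, component = comps$component, mz = cp$mz,
      conc = cp$conc, apex_rt = comps$rt,
      area = area_total * comps$frac, sigma = cp$sigma,
      stringsAsFactors = FALSE)
  }
  build <- function(tt, mzs, profs, lvl) {
    m <- do.call(rbind, profs)              # channels x scans
    nch <- nrow(m); ns <- ncol(m)
    if (config$prop_noise > 0)
      m <- m * (1 + matrix(stats::rnorm(nch * ns, 0, config$prop_noise), nch))
    if (config$noise_sd > 0 || config$baseline_level > 0)
      m <- m + pmax(matrix(stats::rnorm(nch * ns, config$baseline_level,
                                        config$noise_sd), nch), 0)
    m[m < 0] <- 0
    jit <- matrix(stats::runif(nch * ns, -config$ppm_jitter,
                               config$ppm_jitter), nch) * 1e-6
    mzm <- mzs * (1 + jit)
    lapply(seq_len(ns), function(s) {
      keep <- m[, s] > 0
      new_spectrum(lvl, tt[s], mzm[keep, s], m[keep, s])
    })
  }
  sp1 <- build(t1, ch1_mz, ch1_prof, 1L)
  sp2 <- build(t2, ch2_mz, ch2_prof, 2L)
  run <- new_run(c(sp1, sp2),
                 metadata = list(ms1_range = config$ms1_range,
                                 seed = config$seed))
  list(run = run, truth = do.call(rbind, c(truth, make.row.names = FALSE)))
}

#' Simulate a calibration series
#'
#' One run per level and replicate, each containing the analytes at the
#' level concentration plus their internal standards at nominal amounts.
#' A `suppression` factor below 1 scales the analyte (not IS) response,
#' emulating matrix ionization suppression for matrix-effect testing.
#'
#' @param lib Library rows for the analytes plus their internal standards.
#' @param levels Nominal concentrations (µM), ascending; default 8 points
#'   spanning 0.003-5 µM.
#' @param replicates Injections per level (default 3).
#' @param config A [sim_config()]; each run is seeded from `config$seed`
#'   plus a run index, so the series is reproducible.
#' @param suppression Multiplicative response factor on analytes (1 =
#'   solvent, e.g. 0.8 = 20 % suppression in matrix).
#' @param ... Passed to [sim_compound()] via [sim_from_library()].
#' @return List with `runs` (named list of `aif_run`), `sheet` (sample
#'   sheet data frame) and `truth`.
#' @export
simulate_calibration_series <- function(lib,
                                        levels = c(0.003, 0.01, 0.03, 0.1,
                                                   0.3, 1, 2, 5),
                                        replicates = 3,
                                        config = sim_config(),
                                        suppression = 1, ...) {
  stopifnot(!is.unsorted(levels), all(levels > 0))
  runs <- list(); rows <- list(); idx <- 0L
  for (lv in seq_along(levels)) for (rep in seq_len(replicates)) {
    idx <- idx + 1L
    cps <- sim_from_library(lib, conc = levels[lv], ...)
    for (k in seq_along(cps))
      if (!lib$is_internal_standard[k])
        cps[[k]]$response_factor <- cps[[k]]$response_factor * suppression
    cfg <- config
    cfg$seed <- (config$seed + 7919L * idx) %% .Machine$integer.max
    sim <- simulate_run(cps, cfg)
    id <- sprintf("cal_L%02d_R%d", lv, rep)
    runs[[id]] <- sim$run
    rows[[idx]] <- data.frame(run_id = id, role = "calibrant",
                              level = levels[lv], replicate = rep,
                              suppression = suppression,
                              stringsAsFactors = FALSE)
  }
  list(runs = runs, sheet = do.call(rbind, rows),
       truth = list(levels = levels, replicates = replicates,
                    suppression = suppression))
}

#' Simulate a cohort feature table
#'
#' Log-normal lipid concentrations for two groups (responder /
#' non-responder) at three timepoints (CID1-CID3). Designated
#' responder-associated features carry a multiplicative group effect at
#' baseline that attenuates over the follow-up timepoints. A chosen number
#' of features violate QC by construction: excess missingness or gross
#' (50-fold) outliers.
#'
#' @param n_per_group Samples per group (default 50).
#' @param n_features Number of lipid features (default 116).
#' @param n_missing_violators Features given > 10 % missing values
#'   (default 7).
#' @param n_outlier_violators Features given > 10 % gross outliers
#'   (default 5).
#' @param n_effect_features Features with a responder effect (default 10).
#' @param effect_size Multiplicative group effect at CID1 (default 1.5);
#'   attenuated to its square root at CID2 and further at CID3.
#' @param base_missing Background missingness fraction (default 0.02).
#' @param seed Integer seed.
#' @return List with `table` (a `feature_table` data frame: sample_id,
#'   group, timepoint, age, gender, then one column per lipid) and `truth`
#'   (names of planted QC violators and effect features).
#' @export
simulate_cohort_table <- function(n_per_group = 50, n_features = 116,
                                  n_missing_violators = 7,
                                  n_outlier_violators = 5,
                                  n_effect_features = 10, effect_size = 1.5,
                                  base_missing = 0.02, seed = 1L) {
  stopifnot(n_missing_violators + n_outlier_violators <= n_features,
            n_effect_features <= n_features)
  set.seed(seed)
  n <- 2L * n_per_group
  feats <- sprintf("lipid_%03d", seq_len(n_features))
  samples <- data.frame(
    sample_id = sprintf("S%03d", seq_len(n)),
    group = rep(c("responder", "non-responder"), each = n_per_group),
    age = round(stats::rnorm(n, 42, 6)),
    gender = sample(c("M", "F"), n, replace = TRUE),
    stringsAsFactors = FALSE)
  tps <- c("CID1", "CID2", "CID3")
  grid <- merge(samples, data.frame(timepoint = tps), by = NULL)
  grid <- grid[order(grid$sample_id, grid$timepoint), ]
  rownames(grid) <- NULL
  meanlog <- stats::rnorm(n_features, log(0.5), 1)
  sdlog <- stats::runif(n_features, 0.3, 0.5)
  eff_idx <- seq_len(n_effect_features)
  eff_by_tp <- c(CID1 = effect_size, CID2 = sqrt(effect_size),
                 CID3 = effect_size^0.25)
  vals <- matrix(NA_real_, nrow(grid), n_features,
                 dimnames = list(NULL, feats))
  for (j in seq_len(n_features)) {
    x <- stats::rlnorm(nrow(grid), meanlog[j], sdlog[j])
    if (j %in% eff_idx) {
      resp <- grid$group == "responder"
      x[resp] <- x[resp] * eff_by_tp[grid$timepoint[resp]]
    }
    vals[, j] <- x
  }
  miss_idx <- seq_len(n_missing_violators)
  out_idx <- n_missing_violators + seq_len(n_outlier_violators)
  nr <- nrow(grid)
  for (j in seq_len(n_features)) {
    rate <- if (j %in% miss_idx) 0.15 else base_missing
    nmiss <- if (j %in% miss_idx) max(ceiling(0.12 * nr), stats::rbinom(1, nr, rate))
             else min(stats::rbinom(1, nr, rate), floor(0.08 * nr))
    if (nmiss > 0) vals[sample.int(nr, nmiss), j] <- NA
  }
  for (j in out_idx) {
    ok <- which(!is.na(vals[, j]))
    nout <- ceiling(0.12 * nr)
    pick <- sample(ok, min(nout, length(ok)))
    vals[pick, j] <- vals[pick, j] * 50
  }
  tab <- cbind(grid, as.data.frame(vals))
  attr(tab, "feature_names") <- feats
  class(tab) <- c("feature_table", "data.frame")
  list(table = tab,
       truth = list(missing_violators = feats[miss_idx],
                    outlier_violators = feats[out_idx],
                    effect_features = feats[eff_idx]))
}
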