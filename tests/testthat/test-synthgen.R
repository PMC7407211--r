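lib <- read_compound_library()

test_that("the same seed reproduces a bit-identical run", {
  sub <- lib[lib$name %in% c("GCA", "GCA-d5"), ]
  cps <- sim_from_library(sub, conc = 0.3)
  a <- simulate_run(cps, short_config(seed = 17, run_length = 5))
  b <- simulate_run(cps, short_config(seed = 17, run_length = 5))
  expect_identical(a, b)
  c <- simulate_run(cps, short_config(seed = 18, run_length = 5))
  expect_false(identical(a$run, c$run))
})

test_that("a noiseless compound is recovered at its true area and apex", {
  gca <- lib[lib$name == "GCA", ]
  cfg <- short_config(seed = 1)
  cfg$noise_sd <- 0; cfg$baseline_level <- 0; cfg$prop_noise <- 0
  sim <- simulate_run(sim_from_library(gca, conc = 0.5), cfg)
  x <- extract_xic(sim$run, gca$mz)
  pk <- detect_peaks(x)
  expect_identical(nrow(pk), 1L)
  expect_equal(pk$area, sim$truth$area, tolerance = 0.02)
  expect_lt(abs(pk$apex_rt - sim$truth$apex_rt), 0.5 / 60 + 1e-9)
})

test_that("compounds outside the MS1 range are rejected", {
  bad <- sim_compound("tiny", "bile-acid", "C10H16O2", "[M-H]-",
                      conc = 1, apex_rt = 2)
  expect_error(simulate_run(list(bad), short_config()), "range")
})

test_that("lysophospholipids elute as an sn pair at the set fraction", {
  lpc <- lib[lib$name == "LPC(16:0)", ]
  sim <- simulate_run(sim_from_library(lpc, conc = 1),
                      short_config(seed = 23, run_length = 12))
  expect_identical(sim$truth$component, c("sn2", "sn1"))
  x <- extract_xic(sim$run, lpc$mz)
  pk <- detect_peaks(x)
  expect_identical(nrow(pk), 2L)
  ratio <- min(pk$area) / max(pk$area)
  expect_equal(ratio, 0.09 / 0.91, tolerance = 0.05)
  expect_lt(abs(diff(pk$apex_rt) - 0.3), 0.02)
})

test_that("M+1 satellites appear at the expected isotopic abundance", {
  gca <- lib[lib$name == "GCA", ]
  cfg <- short_config(seed = 1)
  cfg$noise_sd <- 0; cfg$baseline_level <- 0; cfg$prop_noise <- 0
  sim <- simulate_run(sim_from_library(gca, conc = 1), cfg)
  x0 <- extract_xic(sim$run, gca$mz)
  x1 <- extract_xic(sim$run, isotope_m1(gca$mz))
  expect_equal(max(x1$intensity) / max(x0$intensity), 0.0107 * 26,
               tolerance = 0.01)
})

test_that("a noiseless calibration series is exactly linear", {
  sub <- lib[lib$name %in% c("GCA", "GCA-d5"), ]
  cfg <- short_config(seed = 2)
  cfg$noise_sd <- 0; cfg$baseline_level <- 0; cfg$prop_noise <- 0
  cfg$ppm_jitter <- 1e-9
  ser <- simulate_calibration_series(sub, replicates = 1, config = cfg)
  rat <- measure_area_ratios(ser$runs, sub)
  rat$conc <- ser$sheet$level[match(rat$run_id, ser$sheet$run_id)]
  cc <- fit_calibration(data.frame(conc = rat$conc, ratio = rat$ratio))
  expect_equal(cc$r2, 1, tolerance = 1e-4)
  expect_true(cc$accepted)
})

test_that("an ionization-suppression factor reads out as the matrix effect", {
  sub <- lib[lib$name %in% c("TCA", "TCA-d5"), ]
  serS <- simulate_calibration_series(sub, replicates = 2,
                                      config = short_config(seed = 41))
  serM <- simulate_calibration_series(sub, replicates = 2,
                                      config = short_config(seed = 42),
                                      suppression = 0.8)
  get_curve <- function(ser) {
    rat <- measure_area_ratios(ser$runs, sub)
    rat$conc <- ser$sheet$level[match(rat$run_id, ser$sheet$run_id)]
    fit_calibration(data.frame(conc = rat$conc, ratio = rat$ratio))
  }
  me <- compute_matrix_effect(get_curve(serM), get_curve(serS))
  expect_equal(me, 80, tolerance = 0.03)
})

test_that("the cohort generator plants exactly the designed QC violations", {
  sim <- simulate_cohort_table(seed = 19)
  expect_identical(nrow(sim$table), 300L)    # 100 subjects x 3 timepoints
  expect_identical(length(attr(sim$table, "feature_names")), 116L)
  out <- qc_filter(sim$table)
  discarded <- out$decisions$feature[!out$decisions$retained]
  expect_setequal(discarded,
                  c(sim$truth$missing_violators, sim$truth$outlier_violators))
  expect_identical(sum(out$decisions$retained), 104L)
  # fixed seed reproduces the table
  sim2 <- simulate_cohort_table(seed = 19)
  expect_identical(sim$table, sim2$table)
})

test_that("null features reject at the nominal 5 % rate", {
  sim <- simulate_cohort_table(n_per_group = 50, n_features = 1000,
                               n_missing_violators = 0,
                               n_outlier_violators = 0,
                               n_effect_features = 0, base_missing = 0,
                               seed = 101)
  base <- sim$table[sim$table$timepoint == "CID1", ]
  g1 <- base$group == "responder"
  p <- vapply(attr(sim$table, "feature_names"), function(f) {
    x <- log(base[[f]][g1]); y <- log(base[[f]][!g1])
    ttest_from_summary(mean(x), sd(x), length(x),
                       mean(y), sd(y), length(y))$p
  }, 0)
  expect_equal(mean(p < 0.05), 0.05, tolerance = 0.4)
  expect_gt(mean(p < 0.05), 0.02)
  expect_lt(mean(p < 0.05), 0.08)
})

test_that("replicate CV falls as concentration rises (constant noise floor)", {
  sub <- lib[lib$name %in% c("GCA", "GCA-d5"), ]
  concs <- c(0.003, 0.01, 0.05, 0.3, 1.5, 8, 40, 150)
  cvs <- vapply(concs, function(cc) {
    areas <- vapply(1:6, function(r) {
      cps <- sim_from_library(sub, conc = cc)
      sim <- simulate_run(cps, short_config(seed = 1000L + round(cc * 13) + r,
                                            run_length = 6.5))
      m <- measure_areas(sim$run, sub[sub$name == "GCA", ])
      m$area
    }, 0)
    100 * stats::sd(areas, na.rm = TRUE) / mean(areas, na.rm = TRUE)
  }, 0)
  rho <- stats::cor(concs, cvs, method = "spearman")
  expect_lt(rho, -0.5)
})
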