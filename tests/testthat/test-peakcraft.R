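test_that("XIC extraction respects the ppm window exactly", {
  s <- new_spectrum(1L, 1.0, c(400.0000, 400.0024, 500), c(100, 50, 7))
  r <- new_run(list(s, new_spectrum(1L, 1.1, 400, 20)))
  x <- extract_xic(r, 400, tol = 5)
  # 400.0024 is 6 ppm away: contributes nothing at 5 ppm
  expect_equal(x$intensity, c(100, 20))
  x2 <- extract_xic(r, 400, tol = 7)
  expect_equal(x2$intensity, c(150, 20))
  expect_error(extract_xic(r, 400, ms_level = 2L), "no scans")
})

test_that("a noiseless Gaussian is recovered with accurate apex and area", {
  sigma <- 0.04; h <- 1e6
  x <- gauss_xic(apex_rt = 2, sigma = sigma, height = h)
  pk <- detect_peaks(x)
  expect_identical(nrow(pk), 1L)
  expect_lt(abs(pk$apex_rt - 2), 0.5 / 60 + 1e-9)       # within one scan
  expect_equal(pk$area, h * sigma * sqrt(2 * pi), tolerance = 0.02)
  expect_identical(pk$snr, Inf)                          # noiseless flag
  expect_identical(attr(pk, "noise"), 0)
})

test_that("flat and empty traces yield no peaks", {
  x <- gauss_xic(height = 0)
  expect_identical(nrow(detect_peaks(x)), 0L)
  expect_error(detect_peaks(structure(list(rt = 1:3 / 10, intensity = rep(0, 3),
                                           target_mz = 1, tol_ppm = 5,
                                           ms_level = 1L), class = "xic")),
               "min_points")
})

test_that("a 10:1 pair 0.3 min apart is split at the valley", {
  sigma <- 0.04
  rt <- seq(0, 4, by = 0.5 / 60)
  y <- 1e6 * exp(-(rt - 2.3)^2 / (2 * sigma^2)) +
       1e5 * exp(-(rt - 2.0)^2 / (2 * sigma^2))
  x <- structure(list(target_mz = 500, tol_ppm = 5, ms_level = 1L,
                      rt = rt, intensity = y), class = "xic")
  pk <- detect_peaks(x)
  expect_identical(nrow(pk), 2L)
  ratio <- min(pk$area) / max(pk$area)
  expect_equal(ratio, 0.1, tolerance = 0.15)
  expect_lt(pk$right_rt[1], pk$apex_rt[2])  # valley split between apices
})

test_that("trapezoidal integration matches geometry and is additive", {
  rt <- seq(0, 4, by = 0.5 / 60)
  tri <- pmax(0, 1 - abs(rt - 2))  # triangle height 1 spanning 2 min
  x <- structure(list(target_mz = 1, tol_ppm = 5, ms_level = 1L,
                      rt = rt, intensity = tri), class = "xic")
  expect_equal(integrate_xic(x, 1, 3), 1.0, tolerance = 1e-4)
  expect_identical(integrate_xic(gauss_xic(height = 0), 1, 3), 0)
  g <- gauss_xic(apex_rt = 2, sigma = 0.04, height = 1e6)
  expect_equal(integrate_xic(g, 1.5, 2.5), 1e6 * 0.04 * sqrt(2 * pi),
               tolerance = 0.02)
  # additivity to float tolerance
  expect_equal(integrate_xic(g, 1, 2) + integrate_xic(g, 2, 3),
               integrate_xic(g, 1, 3), tolerance = 1e-9)
  expect_error(integrate_xic(g, 3, 1), "inverted")
  expect_error(integrate_xic(g, -1, 2), "outside")
})

test_that("SNR tracks the injected height-to-noise ratio", {
  sn <- vapply(1:8, function(seed) {
    x <- gauss_xic(apex_rt = 2, height = 10 * 1000, noise_sd = 1000,
                   baseline = 5000, seed = seed)
    pk <- detect_peaks(x)
    if (!nrow(pk)) return(NA_real_)
    pk$snr[which.max(pk$height)]
  }, 0)
  expect_true(all(!is.na(sn)))
  expect_equal(mean(sn), 10, tolerance = 0.3)
  # scale invariance of SNR
  x <- gauss_xic(apex_rt = 2, height = 2e4, noise_sd = 1000, baseline = 5000,
                 seed = 3)
  x10 <- x; x10$intensity <- x$intensity * 10
  p1 <- detect_peaks(x); p10 <- detect_peaks(x10)
  expect_equal(p10$snr[which.max(p10$height)], p1$snr[which.max(p1$height)],
               tolerance = 1e-9)
})

test_that("estimate_snr flags noiseless traces and excludes peak regions", {
  g <- gauss_xic(apex_rt = 2, sigma = 0.04, height = 1e6)
  pk <- detect_peaks(g)
  s <- estimate_snr(g, pk[1, ])
  expect_identical(as.numeric(s), Inf)
  expect_identical(attr(s, "noise"), 0)
  narrow <- structure(list(target_mz = 1, tol_ppm = 5, ms_level = 1L,
                           rt = seq(1.9, 2.1, by = 0.5 / 60),
                           intensity = rep(1, 25)), class = "xic")
  expect_error(estimate_snr(narrow, data.frame(left_rt = 1.8, right_rt = 2.2,
                                               height = 1)), "baseline")
})

test_that("peak detection is deterministic and recovers simulated truth", {
  x <- gauss_xic(apex_rt = 2, height = 5e5, noise_sd = 2000, baseline = 8000,
                 seed = 11)
  expect_identical(detect_peaks(x), detect_peaks(x))
  # parameter recovery across 100 seeded single-peak traces
  res <- vapply(1:100, function(seed) {
    sigma <- 0.04; h <- 8e5
    x <- gauss_xic(apex_rt = 2, sigma = sigma, height = h, noise_sd = 3000,
                   baseline = 9000, seed = seed)
    pk <- detect_peaks(x)
    i <- which.max(pk$height)
    c(rel_area = abs(pk$area[i] - h * sigma * sqrt(2 * pi)) /
        (h * sigma * sqrt(2 * pi)),
      apex_err = abs(pk$apex_rt[i] - 2))
  }, c(rel_area = 0, apex_err = 0))
  expect_lt(mean(res["rel_area", ]), 0.05)
  expect_lt(max(res["apex_err", ]), 0.5 / 60 + 1e-9)
})

test_that("co-elution combines apex distance and interval overlap", {
  p <- function(apex, l, r) data.frame(apex_rt = apex, left_rt = l, right_rt = r)
  expect_true(coelute(p(2, 1.9, 2.1), p(2, 1.9, 2.1)))
  expect_false(coelute(p(2, 1.9, 2.1), p(2.3, 2.2, 2.4)))
  expect_true(coelute(p(2, 1.9, 2.1), p(2.05, 1.95, 2.15)))
  # apices close but intervals disjoint: not co-eluting
  expect_false(coelute(p(2, 1.99, 2.01), p(2.08, 2.07, 2.09)))
})
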