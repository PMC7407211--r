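lib <- read_compound_library()

test_that("class tags expand to the right diagnostic fragments", {
  expect_identical(nrow(class_fragments("bile-acid")), 0L)
  gs <- class_fragments("glycine-conjugate+sulfate")
  expect_setequal(gs$class_tag, c("glycine-conjugate", "sulfate"))
  lp <- class_fragments("LPC+fatty-acyl(16:0)")
  expect_true(any(grepl("phosphocholine", lp$name)))
  expect_true(any(grepl("16:0", lp$name)))
})

test_that("a spiked conjugate passes all three criteria and shifts break them", {
  gca <- lib[lib$name == "GCA", ]
  sim <- simulate_run(sim_from_library(gca, conc = 0.5), short_config(seed = 2))
  ann <- confirm_identity(sim$run, gca)
  expect_true(ann$criterion_ms1)
  expect_true(ann$criterion_ms2_fragment)
  expect_true(ann$criterion_rt)
  expect_true(ann$confirmed)
  expect_true("glycine fragment" %in% ann$matched_fragments)

  # same signals but the fragment elutes 0.3 min later: criterion 2 fails
  mz <- gca$mz
  frag <- fragment_registry("glycine-conjugate")$mz
  r <- channel_run(list(chan(mz, 2.0, 1e6, level = 1L),
                        chan(frag, 2.3, 3e5, level = 2L)))
  ann2 <- confirm_identity(r, list(name = "GCA", class_tag = "glycine-conjugate",
                                   formula = gca$formula, adduct = gca$adduct,
                                   expected_rt = 2.0, rt_source = "standard"))
  expect_true(ann2$criterion_ms1)
  expect_false(ann2$criterion_ms2_fragment)
  expect_false(ann2$confirmed)

  # wrong retention time: criterion 3 fails even with co-eluting fragment
  r3 <- channel_run(list(chan(mz, 2.0, 1e6, level = 1L),
                         chan(frag, 2.0, 3e5, level = 2L)))
  ann3 <- confirm_identity(r3, list(name = "GCA", class_tag = "glycine-conjugate",
                                    formula = gca$formula, adduct = gca$adduct,
                                    expected_rt = 2.5, rt_source = "standard"))
  expect_false(isTRUE(ann3$criterion_rt))
  expect_false(ann3$confirmed)
})

test_that("a blank run confirms nothing", {
  sub <- lib[lib$name %in% c("GCA", "TCA", "GCA-d5", "TCA-d5"), ]
  cps <- sim_from_library(sub, conc = 0)
  sim <- simulate_run(cps, short_config(seed = 13))
  for (nm in c("GCA", "TCA")) {
    ann <- confirm_identity(sim$run, sub[sub$name == nm, ])
    expect_false(ann$confirmed, label = paste("blank", nm))
  }
})

test_that("the bile-acid candidate space covers cores and capped conjugations", {
  cand <- bile_acid_candidates()
  expect_identical(nrow(cand), 30L)   # 3 cores x (1 + 4 + 5 pairings)
  expect_true("tri-OH" %in% cand$name)
  expect_true(any(cand$class_tag == "glycine-conjugate+sulfate"))
  # no double amidation
  expect_false(any(grepl("glycine.*taurine|taurine.*glycine", cand$class_tag)))
  # glyco-lithocholate candidate mass matches its named compound
  glca <- cand[cand$name == "mono-OH+glycine-conjugate", ]
  expect_equal(glca$mz, ion_mz("C26H43NO4", "[M-H]-")$mz, tolerance = 1e-6)
})

test_that("untargeted screen finds spiked species with their conjugate fragments", {
  cand <- bile_acid_candidates()
  # a sulfo-glyco species: MS1 peak + sulfate and glycine fragments co-eluting
  sglca <- cand[cand$class_tag == "glycine-conjugate+sulfate" &
                  grepl("mono-OH", cand$name), ]
  r <- channel_run(list(
    chan(sglca$mz, 2.2, 2e6, level = 1L),
    chan(96.9601, 2.2, 4e5, level = 2L),
    chan(74.0248, 2.2, 3e5, level = 2L),
    chan(sglca$mz - monoisotopic_mass("SO3"), 2.2, 2e5, level = 2L)))
  hits <- screen_bile_acids(r, cand)
  hit <- hits[hits$candidate == sglca$name, ]
  expect_identical(nrow(hit), 1L)
  expect_identical(hit$n_matched, 3L)   # HSO4-, SO3 loss, glycine
  expect_equal(hit$score, 1.0)
  expect_false(hit$mass_only)

  # MS1 peak with no fragments: mass-only hit
  tri <- cand[cand$name == "tri-OH", ]
  r2 <- channel_run(list(chan(tri$mz, 1.5, 1e6, level = 1L)))
  hits2 <- screen_bile_acids(r2, cand)
  expect_true(all(hits2$mass_only))
  expect_error(screen_bile_acids(r2, cand[0, ]), "empty")
})

test_that("a twelve-species screen recovers exactly twelve hits", {
  cand <- bile_acid_candidates()
  set.seed(4)
  picks <- cand[sample(nrow(cand), 12), ]
  rts <- seq(1.2, 5.6, by = 0.4)
  chans <- list()
  for (i in seq_len(12)) {
    chans <- c(chans, list(chan(picks$mz[i], rts[i], 2e6, level = 1L)))
    frs <- class_fragments(picks$class_tag[i])
    for (j in seq_len(nrow(frs))) {
      fmz <- if (frs$kind[j] == "anion") frs$mz[j]
             else picks$mz[i] - frs$loss_mass[j]
      chans <- c(chans, list(chan(fmz, rts[i], 5e5, level = 2L)))
    }
  }
  r <- channel_run(chans, run_length = 6.5)
  hits <- screen_bile_acids(r, cand)
  expect_identical(nrow(hits), 12L)
  expect_setequal(hits$candidate, unique(picks$name))
})

test_that("LPL screening assigns class by head group and acyl by carboxylate", {
  cand <- lpl_candidates(carbons = 16:18, double_bonds = 0:2)
  lpc <- lib[lib$name == "LPC(16:0)", ]
  sim <- simulate_run(sim_from_library(lpc, conc = 1),
                      short_config(seed = 3, run_length = 12))
  hits <- screen_lpl(sim$run, cand)
  good <- hits[!hits$mass_only, ]
  expect_true("LPC(16:0)" %in% good$candidate)
  h <- good[good$candidate == "LPC(16:0)", ][1, ]
  expect_true(grepl("16:0", h$matched_fragments))
  expect_true(grepl("phosphocholine", h$matched_fragments))
})

test_that("shared acyl fragments are disambiguated by head group and adduct", {
  cand <- lpl_candidates(carbons = 18, double_bonds = 2,
                         classes = c("LPC", "LPE"))
  both <- lib[lib$name %in% c("LPC(18:2)", "LPE(18:2)"), ]
  sim <- simulate_run(sim_from_library(both, conc = 1),
                      short_config(seed = 8, run_length = 12))
  hits <- screen_lpl(sim$run, cand)
  good <- hits[!hits$mass_only, ]
  expect_true(all(c("LPC(18:2)", "LPE(18:2)") %in% good$candidate))
  # the LPC hit carries the choline fragment, the LPE hit the ethanolamine one
  expect_true(grepl("phosphocholine",
                    good$matched_fragments[good$candidate == "LPC(18:2)"][1]))
  expect_true(grepl("phosphoethanolamine",
                    good$matched_fragments[good$candidate == "LPE(18:2)"][1]))
  # candidate space itself enforces the adduct rule
  expect_true(all((cand$class %in% c("LPC", "O-LPC")) ==
                    (cand$adduct == "[M+CH3COO]-")))
})

test_that("low-abundance species yield unconfirmed mass-only hits", {
  cand <- lpl_candidates(carbons = 16, double_bonds = 0, classes = "LPE")
  mz <- cand$mz[1]
  r <- channel_run(list(chan(mz, 2.0, 1e6, level = 1L)))  # no fragments at all
  hits <- screen_lpl(r, cand)
  expect_identical(nrow(hits), 1L)
  expect_true(hits$mass_only)
  expect_equal(hits$score, 0)
})

test_that("sn-isomer labelling follows offset, ratio and elution-order rules", {
  p <- function(rt, area) data.frame(apex_rt = rt, left_rt = rt - 0.1,
                                     right_rt = rt + 0.1, height = area,
                                     area = area, snr = 100)
  pair <- rbind(p(9.40, 1), p(9.70, 10))
  lab <- assign_sn_isomers(pair)
  expect_identical(lab$isomer_label, c("sn2", "sn1"))
  expect_true(attr(lab, "consistent"))
  # permutation invariance
  lab2 <- assign_sn_isomers(pair[2:1, ])
  expect_identical(lab2$isomer_label, lab$isomer_label)
  # single peak: dominant only
  one <- assign_sn_isomers(p(9.4, 5))
  expect_identical(one$isomer_label, "sn1")
  expect_true(is.na(attr(one, "consistent")))
  # 1:1 pair: not an sn pair, dominant-only + no consistency claim
  eq <- assign_sn_isomers(rbind(p(9.40, 10), p(9.70, 10.5)))
  expect_identical(sum(eq$isomer_label == "sn1", na.rm = TRUE), 1L)
  expect_false(isTRUE(attr(eq, "pair")))
  # offset outside the window: not a pair
  far <- assign_sn_isomers(rbind(p(9.40, 1), p(10.2, 10)))
  expect_false(isTRUE(attr(far, "pair")))
  # major eluting first contradicts the expected order: flagged inconsistent
  odd <- assign_sn_isomers(rbind(p(9.40, 10), p(9.70, 1)))
  expect_identical(odd$isomer_label, c("sn2", "sn1"))
  expect_false(attr(odd, "consistent"))
  expect_error(assign_sn_isomers(pair[0, ]), "no peaks")
})

test_that("retention-time prediction fits the class plane", {
  anchors <- expand.grid(carbons = c(14, 16, 18, 20), double_bonds = 0:2)
  anchors$rt <- 2 + 0.5 * anchors$carbons - 0.4 * anchors$double_bonds
  expect_equal(as.numeric(predict_rt(17, 1, anchors)),
               2 + 0.5 * 17 - 0.4 * 1, tolerance = 1e-6)
  # leave-one-out on noisy linear data stays within 0.05 min
  set.seed(21)
  anchors$rt <- anchors$rt + rnorm(nrow(anchors), 0, 0.01)
  err <- vapply(seq_len(nrow(anchors)), function(i) {
    p <- predict_rt(anchors$carbons[i], anchors$double_bonds[i], anchors[-i, ])
    abs(p - anchors$rt[i])
  }, 0)
  expect_lt(max(err), 0.05)
  expect_error(predict_rt(16, 0, anchors[1:2, ]), "3")
})
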