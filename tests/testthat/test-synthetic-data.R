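test_that("generator parameters are validated against the stated ranges", {
  expect_s3_class(generator_params(), "generator_params")
  expect_error(generator_params(fine_coarse_conc_ratio = c(Cd = 2.5, Cr = 1.7,
                                                           Cu = 1.5, Ni = 1.3,
                                                           Pb = 1.8)),
               "\\[1.3, 1.9\\]")
  expect_error(generator_params(ba_fine_coarse_drop = 0.9), "\\[0.4, 0.6\\]")
})

test_that("soil panel is seed-stable with the configured structure", {
  p <- generator_params()
  a <- generate_soil_panel(p, seed = 7)
  b <- generate_soil_panel(p, seed = 7)
  expect_identical(a, b)
  expect_false(identical(a$conc_mg_kg,
                         generate_soil_panel(p, seed = 8)$conc_mg_kg))
  expect_true(all(a$conc_mg_kg > 0))
  # panel mean near the configured target (Pb within 5% at 17 sites)
  pb <- mean(a$conc_mg_kg[a$metal == "Pb"])
  expect_equal(pb, 432, tolerance = 0.05)
  # latent means: monotone decline and exact anchors
  truth <- attr(a, "ground_truth")
  expect_true(all(apply(truth, 1, function(r) all(diff(r) < 0))))
  expect_equal(unname(truth[, 1] / truth[, 4]),
               unname(p$fine_coarse_conc_ratio[rownames(truth)]),
               tolerance = 1e-12)
  expect_equal(unname(rowMeans(truth)), unname(p$metal_means[rownames(truth)]),
               tolerance = 1e-12)
})

test_that("zero-noise panel equals the latent fraction means", {
  p <- generator_params(noise_cv = c(conc = 0, ba = 0))
  a <- generate_soil_panel(p, seed = 1)
  truth <- attr(a, "ground_truth")
  expect_equal(a$conc_mg_kg, unname(truth[cbind(a$metal, a$fraction)]),
               tolerance = 1e-12)
})

test_that("realized fine/coarse enrichment stays inside the survey band", {
  p <- generator_params()
  ratios <- vapply(1:20, function(s) {
    panel <- generate_soil_panel(p, seed = s)
    fm <- tapply(panel$conc_mg_kg, list(panel$metal, panel$fraction), mean)
    fm[, "<63"] / fm[, "250-352"]
  }, numeric(5))
  expect_true(all(rowMeans(ratios) >= 1.25 & rowMeans(ratios) <= 1.95))
})

test_that("PBET extracts round-trip their latent bioaccessibility", {
  p0 <- generator_params(noise_cv = c(conc = 0, ba = 0))
  panel <- generate_soil_panel(p0, seed = 1)
  ext <- generate_pbet_extracts(panel, p0, seed = 1)
  s <- summarize_ba(ext)
  truth <- attr(ext, "ground_truth_ba")
  for (ph in c("gastric", "intestinal")) {
    sub <- s[s$phase == ph, ]
    expect_equal(sub$mean_ba,
                 unname(truth[[ph]][cbind(sub$metal, sub$fraction)]),
                 tolerance = 1e-12)
  }
  # with noise: gastric >= intestinal in every record, BA in (0, 1]
  p <- generator_params()
  ext2 <- generate_pbet_extracts(generate_soil_panel(p, seed = 2), p,
                                 seed = 2)
  wide <- tidyr::pivot_wider(ext2[, c("sample_id", "metal", "fraction",
                                      "phase", "ba")],
                             names_from = "phase", values_from = "ba")
  expect_true(all(wide$gastric >= wide$intestinal))
  expect_true(all(ext2$ba > 0 & ext2$ba <= 1))
  # recomputing BA from the written extract columns reproduces it
  expect_equal(compute_ba(ext2$extract_conc_mg_L, ext2$volume_L,
                          ext2$total_conc_mg_kg, ext2$soil_mass_kg),
               ext2$ba, tolerance = 1e-12)
})

test_that("hand-dust cohort recovers the configured fractions and D50", {
  p <- generator_params()
  psds <- generate_hand_psds(p, seed = 1)
  expect_length(psds, 30)
  pooled <- pooled_weights(psds)
  expect_lt(abs(pooled$w[["<63"]] - 0.643), 0.03)
  d50 <- vapply(psds, percentile_diameter, numeric(1), p = 50)
  expect_lt(abs(mean(d50) - 46.5), 2)
  # zero perturbation: every child is the mean vector
  p0 <- generator_params(hand_fraction_tau = 0)
  psds0 <- generate_hand_psds(p0, seed = 1)
  w0 <- bin_psd(psds0[[1]], p$scheme)
  expect_equal(unname(w0 / sum(w0)),
               unname(p$hand_fraction_means / sum(p$hand_fraction_means)),
               tolerance = 1e-9)
  expect_equal(bin_psd(psds0[[2]], p$scheme), w0, tolerance = 1e-12)
  d50_0 <- percentile_diameter(psds0[[1]], 50)
  expect_equal(d50_0, 46.5, tolerance = 0.1)
})

test_that("end_to_end_fixture ships a coherent ground truth", {
  p0 <- generator_params(noise_cv = c(conc = 0, ba = 0),
                         hand_fraction_tau = 0)
  fx <- end_to_end_fixture(p0, seed = 1)
  got <- run_deterministic(fx$panel, fx$extracts, psd = fx$psds,
                           params = fx$params, weights = "hand")
  expect_equal(got$hq, fx$truth_hq$hq, tolerance = 1e-9)
  expect_equal(got$hi, fx$truth_hq$hi, tolerance = 1e-9)

  # noisy bundle: pipeline cell HQs stay within 3 standard errors
  fx2 <- end_to_end_fixture(generator_params(), seed = 3)
  got2 <- run_deterministic(fx2$panel, fx2$extracts, psd = fx2$psds,
                            params = fx2$params, weights = "hand")
  n <- generator_params()$n_sites
  cv <- 0.15
  rel_se <- sqrt(2) * cv / sqrt(n)   # conc and BA noise combined
  rel_err <- abs(got2$hq / fx2$truth_hq$hq - 1)
  expect_true(all(rel_err < 3 * rel_se))
})

test_that("means calibrated to the reference table reproduce its totals", {
  # HQ is linear in the metal mean, so scaling the generator means by the
  # ratio of target to unit-mean weighted totals must recover the
  # reference Total row from the noise-free ground truth.
  ref <- smelter_hq_reference()
  params <- default_params()
  base <- generator_params(noise_cv = c(conc = 0, ba = 0),
                           metal_means = stats::setNames(rep(1, 5),
                                                         names(ref$total)))
  unit <- end_to_end_fixture(base, params = params, seed = 1)
  unit_tab <- hq_table(unit$truth_conc, unit$truth_ba$intestinal, params,
                       weights = soil_weights())
  cal <- generator_params(noise_cv = c(conc = 0, ba = 0),
                          metal_means = ref$total / unit_tab$totals)
  fx <- end_to_end_fixture(cal, params = params, seed = 1)
  tab <- hq_table(fx$truth_conc, fx$truth_ba$intestinal, params,
                  weights = soil_weights())
  expect_equal(unname(tab$totals / ref$total), rep(1, 5), tolerance = 0.03)
  expect_equal(tab$hi, sum(ref$total), tolerance = 0.03)
})

test_that("fixture files are written and round-trip", {
  dir <- withr::local_tempdir()
  p0 <- generator_params(n_sites = 4, n_children = 5)
  fx <- end_to_end_fixture(p0, dir = dir, seed = 2)
  expect_true(all(file.exists(file.path(dir, c("psd.csv", "conc.csv",
                                               "pbet.csv", "params.yaml",
                                               "ground_truth.csv")))))
  back <- read_hq_csv(file.path(dir, "ground_truth.csv"))
  expect_equal(back$hq, fx$truth_hq$hq, tolerance = 1e-9)
  expect_equal(back$hi, fx$truth_hq$hi, tolerance = 1e-9)
  cfg <- read_params_yaml(file.path(dir, "params.yaml"))
  expect_equal(cfg$params$BW, fx$params$BW)
  psds <- read_psd_csv(file.path(dir, "psd.csv"))
  expect_length(psds, 5)
})
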