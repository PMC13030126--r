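test_that("scheme and weight constructors enforce their invariants", {
  s <- size_scheme()
  expect_equal(s$labels, c("<63", "63-150", "150-250", "250-352"))
  expect_error(size_scheme(c(0, 63, 63)), "strictly increasing")
  expect_error(size_scheme(352), "at least two")
  expect_error(fraction_weights(c(0.5, 0.5, 0.5, 0.5), s), "sum to 1")
  expect_error(fraction_weights(c(-0.1, 0.6, 0.3, 0.2), s), "nonnegative")
  w <- fraction_weights(c(2, 1, 1, 0), s, normalize = TRUE)
  expect_equal(sum(w$w), 1)
})

test_that("bin_psd splits straddling bins proportionally to width", {
  s <- size_scheme()
  uniform <- psd_record("u", c(0, 352), 1)
  expect_equal(unname(bin_psd(uniform, s)),
               c(63, 87, 100, 102) / 352, tolerance = 1e-12)
  aligned <- psd_record("a", s$edges, c(0.643, 0.309, 0.0431, 0.0049))
  expect_equal(unname(bin_psd(aligned, s)),
               c(0.643, 0.309, 0.0431, 0.0049))
  expect_error(bin_psd(psd_record("x", c(400, 500), 1), s),
               "no mass in scheme range")
})

test_that("bin_psd matches the 1-um brute-force oracle and conserves mass", {
  s <- size_scheme()
  withr::with_seed(42, {
    for (i in 1:100) {
      psd <- random_int_psd()
      got <- bin_psd(psd, s)
      expect_equal(got, brute_force_bin(psd, s), tolerance = 1e-6)
      in_range <- brute_force_bin(psd, size_scheme(c(0, 352)))
      expect_equal(sum(got), unname(in_range), tolerance = 1e-9)
    }
  })
})

test_that("percentile_diameter follows the log-linear convention", {
  expect_equal(percentile_diameter(psd_record("u", c(10, 1000), 1), 50),
               100, tolerance = 1e-9)
  half <- psd_record("h", c(0, 63, 150), c(0.5, 0.5))
  expect_equal(percentile_diameter(half, 50), 63)
  expect_error(percentile_diameter(half, 0), "in \\(0, 100\\)")
  expect_error(percentile_diameter(half, 100), "in \\(0, 100\\)")
})

test_that("percentile_diameter is monotone in p and bracketed by bin edges", {
  withr::with_seed(7, {
    for (i in 1:20) {
      psd <- random_int_psd(n_bins = 12)
      ps <- c(5, 10, 25, 50, 75, 90, 95)
      d <- vapply(ps, function(p) percentile_diameter(psd, p), numeric(1))
      expect_true(all(diff(d) >= -1e-12))
      expect_true(all(d >= min(psd$bin_edges) - 1e-9 &
                      d <= max(psd$bin_edges) + 1e-9))
    }
  })
})

test_that("pooled_weights averages per-subject proportions and renormalizes", {
  s <- size_scheme()
  cohort <- pooled_weights(
    psd_record("a", s$edges, c(64.3, 30.9, 4.31, 0.490)), s)
  expect_equal(unname(cohort$w), c(0.643, 0.309, 0.0431, 0.0049),
               tolerance = 1e-3)
  expect_equal(sum(cohort$w), 1, tolerance = 1e-12)
  expect_equal(cohort$provenance, "hand_dust")

  one <- psd_record("b", s$edges, c(0.25, 0.25, 0.25, 0.25))
  expect_equal(unname(pooled_weights(one, s)$w), rep(0.25, 4))

  two <- list(psd_record("c", s$edges, c(1, 0, 0, 0) + 1e-15),
              psd_record("d", s$edges, c(0, 1, 0, 0) + 1e-15))
  expect_equal(unname(pooled_weights(two, s)$w), c(0.5, 0.5, 0, 0),
               tolerance = 1e-9)

  # normalization-invariance: scaling subject masses changes nothing
  withr::with_seed(3, {
    raw <- lapply(1:5, function(i) random_int_psd(10))
    scaled <- lapply(raw, function(p)
      psd_record(p$subject_id, p$bin_edges, p$mass_per_bin * runif(1, 1, 9)))
    expect_equal(pooled_weights(raw, s)$w, pooled_weights(scaled, s)$w,
                 tolerance = 1e-12)
  })
})

test_that("soil_weights_under_cap fills the coarse remainder", {
  w <- soil_weights_under_cap(c(44.6, 30.9, 14.9))
  expect_equal(unname(w$w), c(0.446, 0.309, 0.149, 0.096), tolerance = 1e-12)
  expect_equal(w$provenance, "soil")
  expect_equal(unname(soil_weights_under_cap(c(100, 0, 0))$w), c(1, 0, 0, 0))
  expect_equal(unname(soil_weights_under_cap(c(50, 30, 15))$w),
               c(0.50, 0.30, 0.15, 0.05))
  expect_error(soil_weights_under_cap(c(80, 30, 15)), "exceed 100")
})

test_that("enrichment_ratio quantifies selective adherence", {
  hand <- hand_dust_weights()
  soil <- soil_weights()
  r <- enrichment_ratio(hand, soil)
  expect_equal(unname(r), c(1.4417, 1.0000, 0.2893, 0.0510),
               tolerance = 1e-3)
  expect_equal(unname(enrichment_ratio(soil, soil)), rep(1, 4))
  s <- size_scheme()
  fine_only <- fraction_weights(c(1, 0, 0, 0), s)
  unif <- fraction_weights(rep(0.25, 4), s)
  expect_equal(unname(enrichment_ratio(fine_only, unif)), c(4, 0, 0, 0))
  expect_true(is.infinite(enrichment_ratio(unif, fine_only)[2]))
  other <- fraction_weights(c(0.5, 0.5), size_scheme(c(0, 63, 150)))
  expect_error(enrichment_ratio(hand, other), "different schemes")
})

test_that("psd CSV round-trips through the readers", {
  s <- size_scheme()
  psds <- list(a = psd_record("a", s$edges, c(0.6, 0.3, 0.08, 0.02)),
               b = psd_record("b", c(10, 63, 200), c(0.7, 0.3)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_psd_csv(psds, path)
  back <- read_psd_csv(path)
  expect_equal(back$a$mass_per_bin, psds$a$mass_per_bin)
  expect_equal(back$b$bin_edges, psds$b$bin_edges)
})
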