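make_matrices <- function() {
  labels <- size_scheme()$labels
  list(
    conc = matrix(c(300, 200, 150, 100,
                    20, 15, 12, 10), 2, 4, byrow = TRUE,
                  dimnames = list(c("Pb", "Cd"), labels)),
    ba = matrix(c(0.24, 0.20, 0.16, 0.12,
                  0.30, 0.26, 0.22, 0.16), 2, 4, byrow = TRUE,
                dimnames = list(c("Pb", "Cd"), labels))
  )
}

test_that("all-fixed specs collapse the simulation to the point estimate", {
  m <- make_matrices()
  p <- default_params()
  rfd <- default_rfd()[c("Pb", "Cd")]
  det <- hq_table(m$conc, m$ba, p, rfd = rfd)
  cfg <- simulation_config(n_iter = 50, seed = 3, params = p)
  sim <- run_simulation(fixed_spec_list(m$conc), fixed_spec_list(m$ba),
                        ir_spec = dist_spec("fixed", value = p$IR_S),
                        config = cfg, rfd = rfd)
  for (metal in c("Pb", "Cd")) {
    expect_identical(unique(sim$distributions[[metal]]$samples),
                     unname(det$totals[metal]))
    expect_equal(sim$distributions[[metal]]$exceedance, 0)
  }
})

test_that("seeded simulations are bit-stable; different seeds differ", {
  m <- make_matrices()
  p <- default_params()
  rfd <- default_rfd()[c("Pb", "Cd")]
  specs_c <- lapply(fixed_spec_list(m$conc), function(row)
    lapply(row, function(s) dist_spec("lognormal",
                                      meanlog = log(s$params$value),
                                      sdlog = 0.3)))
  specs_b <- lapply(fixed_spec_list(m$ba), function(row)
    lapply(row, function(s) dist_spec("normal", mean = s$params$value,
                                      sd = 0.05)))
  run <- function(seed) run_simulation(
    specs_c, specs_b,
    config = simulation_config(n_iter = 2000, seed = seed, params = p),
    rfd = rfd)
  s1 <- run(9); s2 <- run(9); s3 <- run(10)
  expect_identical(s1$distributions$Pb$samples, s2$distributions$Pb$samples)
  expect_identical(s1$summary, s2$summary)
  expect_false(identical(s1$distributions$Pb$samples,
                         s3$distributions$Pb$samples))
  # different seeds agree statistically (medians within a few percent)
  expect_equal(s1$summary$p50, s3$summary$p50, tolerance = 0.05)
  # percentiles monotone, samples nonnegative
  expect_true(all(s1$summary$p5 <= s1$summary$p50 &
                  s1$summary$p50 <= s1$summary$p95))
  expect_true(all(s1$distributions$Pb$samples >= 0))
})

test_that("simulation results are invariant to metal ordering", {
  m <- make_matrices()
  p <- default_params()
  cfg <- simulation_config(n_iter = 500, seed = 4, params = p)
  cs <- fixed_spec_list(m$conc); bs <- fixed_spec_list(m$ba)
  cs$Pb <- lapply(cs$Pb, function(s) dist_spec("normal",
                                               mean = s$params$value,
                                               sd = 5))
  fwd <- run_simulation(cs, bs, config = cfg,
                        rfd = default_rfd()[c("Pb", "Cd")])
  rev <- run_simulation(cs[c("Cd", "Pb")], bs[c("Cd", "Pb")], config = cfg,
                        rfd = default_rfd()[c("Cd", "Pb")])
  expect_identical(fwd$distributions$Pb$samples, rev$distributions$Pb$samples)
})

test_that("symmetric low-CV inputs keep the MC mean near the point estimate", {
  m <- make_matrices()
  p <- default_params()
  rfd <- default_rfd()[c("Pb", "Cd")]
  det <- hq_table(m$conc, m$ba, p, rfd = rfd)
  cs <- lapply(fixed_spec_list(m$conc), function(row)
    lapply(row, function(s) dist_spec("normal", mean = s$params$value,
                                      sd = 0.03 * s$params$value)))
  bs <- lapply(fixed_spec_list(m$ba), function(row)
    lapply(row, function(s) dist_spec("normal", mean = s$params$value,
                                      sd = 0.03 * s$params$value)))
  sim <- run_simulation(cs, bs, ir_spec = dist_spec("fixed", value = p$IR_S),
                        config = simulation_config(n_iter = 10000, seed = 6,
                                                   params = p),
                        rfd = rfd)
  for (metal in c("Pb", "Cd")) {
    expect_equal(sim$distributions[[metal]]$percentiles[["mean"]],
                 unname(det$totals[metal]), tolerance = 0.01)
  }
})

test_that("missing specs are hard errors naming the cell", {
  m <- make_matrices()
  cs <- fixed_spec_list(m$conc); bs <- fixed_spec_list(m$ba)
  cs$Pb[["<63"]] <- NULL
  cfg <- simulation_config(n_iter = 10, seed = 1, params = default_params())
  expect_error(run_simulation(cs, bs, config = cfg,
                              rfd = default_rfd()[c("Pb", "Cd")]),
               "missing concentration spec for \\(Pb, <63\\)")
})

test_that("summarize_cdf interpolates between order statistics", {
  expect_equal(summarize_cdf(c(10, 20, 30, 40), 50)$value, 25)
  expect_equal(summarize_cdf(c(10, 20, 30, 40), 99.999)$value, 40,
               tolerance = 1e-2)
  u <- withr::with_seed(8, runif(10000))
  expect_equal(summarize_cdf(u, 95)$value, 0.95, tolerance = 0.01)
  tab <- summarize_cdf(u, c(90, 10, 50))
  expect_true(all(diff(tab$value) > 0))
  expect_error(summarize_cdf(numeric(0), 50), "empty")
  expect_error(summarize_cdf(1:5, 100), "\\(0, 100\\)")
})
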