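#' Parameters of the study-like synthetic-data generator
#'
#' Defines the ground truth of a simulated survey: a panel of courtyard
#' soils (sites x size fractions x metals), matching PBET extracts for
#' both digestion phases, and a cohort of children's hand-dust
#' particle-size distributions.  Defaults reproduce the bundled
#' smelter-survey summary statistics (see [smelter_reference]): 17
#' sites, 30 children, the published mean concentrations, gastric and
#' intestinal bioaccessibility means, fine/coarse enrichment ratios in
#' 1.3-1.9, a 50 percent bioaccessibility drop from finest to coarsest
#' fraction, and hand-dust mass fractions 64.3/30.9/4.31/0.490 percent
#' with a cohort median diameter of 46.5 um.
#'
#' Site-to-site noise is multiplicative lognormal with the given CVs
#' (mean-preserving).  Per-child fraction vectors are logistic-normal
#' perturbations of the mean vector with spread `hand_fraction_tau`,
#' calibrated so the finest-fraction SD is about 5 percentage points.
#'
#' @param n_sites,n_children Panel and cohort sizes.
#' @param metal_means Named mean total concentrations, mg/kg.
#' @param fine_coarse_conc_ratio Named per-metal ratio of finest to
#'   coarsest fraction mean concentration; must lie in `[1.3, 1.9]`.
#' @param ba_means_gastric,ba_means_intestinal Named mean
#'   bioaccessibilities, percent.
#' @param ba_fine_coarse_drop Fractional drop of BA from finest to
#'   coarsest fraction, in `[0.4, 0.6]`.
#' @param hand_fraction_means,soil_fraction_means Mean mass fractions,
#'   percent, for the four default fractions.
#' @param noise_cv Named CVs: `conc` and `ba` site-level lognormal
#'   noise.
#' @param hand_fraction_tau Logistic-normal spread of per-child
#'   fraction vectors.
#' @param target_d50 Cohort median diameter target, um; fixes the
#'   lower edge of the finest hand-dust sub-bin analytically.
#' @param scheme A four-fraction [size_scheme()].
#' @param seed Default seed used when generator calls are not given
#'   one.
#' @return A `generator_params` list.
#' @export
generator_params <- function(n_sites = 17, n_children = 30,
                             metal_means = smelter_metal_means(),
                             fine_coarse_conc_ratio = c(Cd = 1.9, Cr = 1.7,
                                                        Cu = 1.5, Ni = 1.3,
                                                        Pb = 1.8),
                             ba_means_gastric = smelter_ba_means("gastric"),
                             ba_means_intestinal =
                               smelter_ba_means("intestinal"),
                             ba_fine_coarse_drop = 0.5,
                             hand_fraction_means = smelter_hand_fractions(),
                             soil_fraction_means = smelter_soil_fractions(),
                             noise_cv = c(conc = 0.15, ba = 0.15),
                             hand_fraction_tau = 0.17,
                             target_d50 = 46.5,
                             scheme = size_scheme(), seed = 1) {
  stopifnot(n_sites >= 1, n_children >= 1, n_fractions(scheme) == 4)
  if (any(metal_means <= 0) || any(ba_means_gastric <= 0) ||
      any(ba_means_intestinal <= 0)) {
    stop("means must be positive", call. = FALSE)
  }
  if (any(fine_coarse_conc_ratio < 1.3 | fine_coarse_conc_ratio > 1.9)) {
    stop("fine/coarse concentration ratios must lie in [1.3, 1.9]",
         call. = FALSE)
  }
  if (ba_fine_coarse_drop < 0.4 || ba_fine_coarse_drop > 0.6) {
    stop("ba_fine_coarse_drop must lie in [0.4, 0.6]", call. = FALSE)
  }
  if (any(noise_cv < 0) || hand_fraction_tau < 0) {
    stop("noise parameters must be nonnegative", call. = FALSE)
  }
  structure(
    list(n_sites = n_sites, n_children = n_children,
         metal_means = metal_means,
         fine_coarse_conc_ratio = fine_coarse_conc_ratio,
         ba_means_gastric = ba_means_gastric,
         ba_means_intestinal = ba_means_intestinal,
         ba_fine_coarse_drop = ba_fine_coarse_drop,
         hand_fraction_means = hand_fraction_means,
         soil_fraction_means = soil_fraction_means,
         noise_cv = noise_cv, hand_fraction_tau = hand_fraction_tau,
         target_d50 = target_d50, scheme = scheme, seed = seed),
    class = "generator_params"
  )
}

# Geometric interpolation of per-fraction means between a fine and a
# coarse anchor, scaled so the across-fraction average equals `mean`.
fraction_means_geometric <- function(mean, fine_coarse_ratio, k = 4) {
  s <- fine_coarse_ratio^(-1 / (k - 1))
  fine <- k * mean / sum(s^(0:(k - 1)))
  fine * s^(0:(k - 1))
}

# Mean-preserving multiplicative lognormal noise.
lognormal_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a site-by-fraction-by-metal soil concentration panel
#'
#' Latent fraction-level means interpolate geometrically between the
#' finest and coarsest fractions, anchored so that the across-fraction
#' mean equals `metal_means` and the fine/coarse ratio equals
#' `fine_coarse_conc_ratio`; per-site values add mean-preserving
#' lognormal noise.
#'
#' @param p A [generator_params()].
#' @param seed Integer seed (defaults to `p$seed`).
#' @return Tibble `site`, `metal`, `fraction`, `conc_mg_kg` with
#'   attribute `ground_truth` (the metals-by-fractions latent mean
#'   matrix).
#' @export
generate_soil_panel <- function(p, seed = p$seed) {
  stopifnot(inherits(p, "generator_params"))
  metals <- names(p$metal_means)
  labels <- p$scheme$labels
  truth <- t(vapply(metals, function(m) {
    fraction_means_geometric(p$metal_means[[m]],
                             p$fine_coarse_conc_ratio[[m]])
  }, numeric(4)))
  dimnames(truth) <- list(metals, labels)
  grid <- expand.grid(site = sprintf("S%02d", seq_len(p$n_sites)),
                      metal = metals, fraction = labels,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[order(grid$site, grid$metal, grid$fraction), ]
  noise <- withr::with_seed(derive_seed(seed, "soil_panel"),
                            lognormal_noise(nrow(grid), p$noise_cv[["conc"]]))
  grid$conc_mg_kg <- truth[cbind(grid$metal, grid$fraction)] * noise
  out <- tibble::as_tibble(grid)
  attr(out, "ground_truth") <- truth
  out
}

# Latent fraction-level BA means (unitless fractions) for one phase.
ba_fraction_means <- function(means_percent, drop) {
  t(vapply(names(means_percent), function(m) {
    pmin(fraction_means_geometric(means_percent[[m]] / 100, 1 / (1 - drop)),
         1)
  }, numeric(4)))
}

#' Generate PBET extract measurements for a soil panel
#'
#' For every site, metal, fraction and phase a latent bioaccessibility
#' is drawn around its fraction-level mean (lognormal noise, truncated
#' to (0, 1], intestinal capped at the same site's gastric draw so the
#' phase ordering always holds) and the extract concentration is
#' back-computed through the bioaccessibility equation with the
#' standard reactor geometry V = 0.05 L, M = 0.0005 kg.  With zero
#' noise, [summarize_ba()] on the output reproduces the latent means
#' exactly.
#'
#' @param panel Output of [generate_soil_panel()].
#' @param p A [generator_params()].
#' @param seed Integer seed.
#' @return Tibble of PBET measurements (both phases) with columns as
#'   in [read_pbet_csv()], plus the realized `ba`; attribute
#'   `ground_truth_ba` holds the latent fraction-mean BA arrays.
#' @export
generate_pbet_extracts <- function(panel, p, seed = p$seed) {
  stopifnot(inherits(p, "generator_params"))
  metals <- names(p$metal_means)
  labels <- p$scheme$labels
  gas <- ba_fraction_means(p$ba_means_gastric, p$ba_fine_coarse_drop)
  int <- ba_fraction_means(p$ba_means_intestinal, p$ba_fine_coarse_drop)
  dimnames(gas) <- dimnames(int) <- list(metals, labels)
  cv <- p$noise_cv[["ba"]]
  base <- panel[, c("site", "metal", "fraction", "conc_mg_kg")]
  n <- nrow(base)
  noise_g <- withr::with_seed(derive_seed(seed, "ba_gastric"),
                              lognormal_noise(n, cv))
  noise_i <- withr::with_seed(derive_seed(seed, "ba_intestinal"),
                              lognormal_noise(n, cv))
  ba_g <- pmin(gas[cbind(base$metal, base$fraction)] * noise_g, 1)
  ba_i <- pmin(int[cbind(base$metal, base$fraction)] * noise_i, ba_g)
  make_phase <- function(ba, phase) {
    tibble::tibble(
      sample_id = base$site, metal = base$metal, fraction = base$fraction,
      phase = phase,
      extract_conc_mg_L = ba * base$conc_mg_kg * 0.0005 / 0.05,
      volume_L = 0.05, soil_mass_kg = 0.0005,
      total_conc_mg_kg = base$conc_mg_kg, ba = ba
    )
  }
  out <- dplyr::bind_rows(make_phase(ba_g, "gastric"),
                          make_phase(ba_i, "intestinal"))
  attr(out, "ground_truth_ba") <- list(gastric = gas, intestinal = int)
  out
}

# Lower edge of the finest hand-dust sub-bin such that the mean
# fraction vector has the target median diameter under log-linear
# interpolation (the finest fraction carries > 50 % of the mass, so
# the median always falls inside it).
finest_lower_edge <- function(p) {
  w1 <- p$hand_fraction_means[[1]] / sum(p$hand_fraction_means)
  upper <- p$scheme$edges[2]
  a <- 0.5 / w1
  10^((log10(p$target_d50) - a * log10(upper)) / (1 - a))
}

#' Generate a cohort of children's hand-dust size distributions
#'
#' Each child's four fraction masses are a logistic-normal perturbation
#' of the cohort mean vector; within a fraction, mass is spread
#' log-uniformly over six log-spaced sub-bins.  Hand-adhered dust
#' carries essentially no mass below a few tens of micrometres of the
#' finest sieve cut, so the finest fraction spans `[L, 63)` um with
#' `L` chosen analytically from `target_d50` (about 16 um at the
#' defaults).
#'
#' @param p A [generator_params()].
#' @param seed Integer seed.
#' @return List of `n_children` [psd_record()]s.
#' @export
generate_hand_psds <- function(p, seed = p$seed) {
  stopifnot(inherits(p, "generator_params"))
  k_sub <- 6L
  edges_frac <- p$scheme$edges
  edges_frac[1] <- finest_lower_edge(p)
  sub_edges <- unlist(lapply(seq_len(4), function(i) {
    10^seq(log10(edges_frac[i]), log10(edges_frac[i + 1]),
           length.out = k_sub + 1)[-(k_sub + 1)]
  }))
  sub_edges <- c(sub_edges, edges_frac[5])
  mu <- log(p$hand_fraction_means / sum(p$hand_fraction_means))
  withr::with_seed(derive_seed(seed, "hand_psd"), {
    lapply(seq_len(p$n_children), function(i) {
      z <- mu + stats::rnorm(4, 0, p$hand_fraction_tau)
      w <- exp(z) / sum(exp(z))
      psd_record(sprintf("child%02d", i), sub_edges,
                 rep(w / k_sub, each = k_sub))
    })
  })
}

#' Full synthetic input bundle with analytic ground truth
#'
#' Generates the soil panel, PBET extracts and hand-dust cohort,
#' computes the deterministic hazard-quotient table implied by the
#' latent (noise-free) means under the realized pooled hand-dust
#' weights, and optionally writes everything as CSV/YAML files.  On a
#' zero-noise bundle the deterministic pipeline reproduces the ground
#' truth to numerical precision.
#'
#' @param p A [generator_params()].
#' @param params An [exposure_params()] used for the ground-truth HQ
#'   table (and written into the bundle).
#' @param rfd Named RfD vector.
#' @param dir Optional directory; when given, writes `psd.csv`,
#'   `conc.csv`, `pbet.csv`, `params.yaml` and `ground_truth.csv`.
#' @param seed Integer seed.
#' @return List with `panel`, `extracts`, `psds`, `weights` (realized
#'   pooled hand-dust weights), `truth_conc`, `truth_ba`, and
#'   `truth_hq` (an `hq_table`).
#' @export
end_to_end_fixture <- function(p = generator_params(),
                               params = exposure_params(EF = 350, ED = 6,
                                                        BW = 20, AT = 2190),
                               rfd = default_rfd(), dir = NULL,
                               seed = p$seed) {
  panel <- generate_soil_panel(p, seed = seed)
  extracts <- generate_pbet_extracts(panel, p, seed = seed)
  psds <- generate_hand_psds(p, seed = seed)
  weights <- pooled_weights(psds, p$scheme)
  truth_conc <- attr(panel, "ground_truth")
  truth_ba <- attr(extracts, "ground_truth_ba")
  truth_hq <- hq_table(truth_conc, truth_ba$intestinal, params,
                       rfd = rfd, weights = weights)
  bundle <- list(panel = panel, extracts = extracts, psds = psds,
                 weights = weights, truth_conc = truth_conc,
                 truth_ba = truth_ba, truth_hq = truth_hq,
                 params = params, rfd = rfd, seed = seed)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_psd_csv(psds, file.path(dir, "psd.csv"))
    readr::write_csv(panel, file.path(dir, "conc.csv"))
    readr::write_csv(extracts[, setdiff(names(extracts), "ba")],
                     file.path(dir, "pbet.csv"))
    yaml::write_yaml(
      list(exposure = unclass(params), rfd = as.list(rfd), seed = seed),
      file.path(dir, "params.yaml"))
    write_hq_csv(truth_hq, file.path(dir, "ground_truth.csv"))
  }
  bundle
}
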