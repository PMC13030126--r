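#' Deterministic exposure-and-risk run
#'
#' The point-estimate workflow: pool the hand-dust PSD cohort into
#' fraction weights (or take a preset/custom weight vector), average
#' the soil concentrations and intestinal-phase bioaccessibility per
#' (metal, fraction), apply the dose model and assemble the
#' hazard-quotient table with totals, hazard index and contribution
#' decomposition.  Missing (metal, fraction) cells are a hard error
#' naming the cell — nothing is imputed.
#'
#' @param conc Soil panel: path to a CSV with `site`, `metal`,
#'   `fraction`, `conc_mg_kg`, or an equivalent data frame.
#' @param pbet PBET extracts: path to a CSV as in [read_pbet_csv()],
#'   or an equivalent data frame (a precomputed `ba` column is used if
#'   present).
#' @param psd Hand-dust PSDs: path to a CSV as in [read_psd_csv()], a
#'   list of [psd_record()]s, or `NULL` when `weights` is given
#'   directly.
#' @param params An [exposure_params()].
#' @param weights `"hand"` (pool the `psd` cohort; preset
#'   [hand_dust_weights()] if no PSDs given), `"soil"`
#'   ([soil_weights()]), or a [fraction_weights()] object.
#' @param phase Digestion phase feeding the dose model (default
#'   `"intestinal"`, the phase relevant to absorption).
#' @param rfd Named RfD vector.
#' @param qc Optional [qc_config()] applied when reading `pbet` from a
#'   file.
#' @param scheme A [size_scheme()].
#' @param out_dir Optional output directory for `hq.csv` and
#'   `contributions.csv`.
#' @return The [hq_table()] (invisibly contains weights and notes).
#' @export
run_deterministic <- function(conc, pbet, psd = NULL, params,
                              weights = c("soil", "hand"),
                              phase = c("intestinal", "gastric"),
                              rfd = default_rfd(), qc = NULL,
                              scheme = size_scheme(), out_dir = NULL) {
  phase <- match.arg(phase)
  panel <- if (is.character(conc)) {
    readr::read_csv(conc, show_col_types = FALSE)
  } else tibble::as_tibble(conc)
  need <- c("metal", "fraction", "conc_mg_kg")
  miss <- setdiff(need, names(panel))
  if (length(miss)) {
    stop("conc table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  check_metals(panel$metal)
  extracts <- if (is.character(pbet)) read_pbet_csv(pbet, qc = qc)
              else tibble::as_tibble(pbet)
  if (is.character(psd)) psd <- read_psd_csv(psd)
  w <- resolve_weights(weights, psd, scheme)
  metals <- sort(unique(panel$metal))
  labels <- scheme$labels
  conc_mat <- summary_matrix(panel, "conc_mg_kg", metals, labels,
                             what = "concentration")
  ba_tab <- summarize_ba(extracts[extracts$phase == phase, ])
  ba_tab$value <- ba_tab$mean_ba
  ba_mat <- summary_matrix(ba_tab, "value", metals, labels,
                           what = paste(phase, "bioaccessibility"))
  tab <- hq_table(conc_mat, ba_mat, params, rfd = rfd[metals], weights = w)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_hq_csv(tab, file.path(out_dir, "hq.csv"))
    write_contributions_csv(tab, file.path(out_dir, "contributions.csv"))
  }
  tab
}

resolve_weights <- function(weights, psd, scheme) {
  if (inherits(weights, "fraction_weights")) return(weights)
  choice <- match.arg(weights[1], c("soil", "hand"))
  if (choice == "soil") return(soil_weights(scheme))
  if (!is.null(psd)) pooled_weights(psd, scheme) else hand_dust_weights(scheme)
}

# Mean per (metal, fraction) as a complete metals-by-fractions matrix;
# an absent cell is a hard, named error.
summary_matrix <- function(df, value_col, metals, labels, what) {
  mat <- matrix(NA_real_, length(metals), length(labels),
                dimnames = list(metals, labels))
  agg <- dplyr::summarise(
    dplyr::group_by(df, .data$metal, .data$fraction),
    v = mean(.data[[value_col]]), .groups = "drop")
  ok <- agg$fraction %in% labels
  mat[cbind(agg$metal[ok], agg$fraction[ok])] <- agg$v[ok]
  if (anyNA(mat)) {
    cell <- which(is.na(mat), arr.ind = TRUE)[1, ]
    stop("missing ", what, " for (", metals[cell[1]], ", ",
         labels[cell[2]], ")", call. = FALSE)
  }
  mat
}

#' Probabilistic exposure-and-risk run
#'
#' Fits a distribution per (metal, fraction) to the across-site
#' concentrations and to the intestinal bioaccessibilities
#' ([fit_best()]); a cell whose fit fails falls back to a fixed value
#' at its mean, with a warning.  The fitted specs, a triangular
#' ingestion rate and fixed exposure parameters then drive
#' [run_simulation()].
#'
#' @inheritParams run_deterministic
#' @param n_iter Monte Carlo iterations.
#' @param seed Integer seed (full run is reproducible).
#' @param ir_spec [dist_spec()] for the ingestion rate, mg/d.
#' @param families Candidate families passed to [fit_best()].
#' @param out_dir Optional directory for `mc_percentiles.csv`.
#' @return A list: `risk` (the `risk_summary`), `fits` (tibble of the
#'   selected family and A-squared per input cell), `weights`.
#' @export
run_probabilistic <- function(conc, pbet, psd = NULL, params,
                              weights = c("soil", "hand"),
                              phase = c("intestinal", "gastric"),
                              rfd = default_rfd(), n_iter = 10000, seed = 1,
                              ir_spec = dist_spec("triangular", min = 66,
                                                  mode = 103, max = 161),
                              families = c("normal", "lognormal",
                                           "triangular", "uniform", "gamma",
                                           "weibull"),
                              scheme = size_scheme(), out_dir = NULL) {
  phase <- match.arg(phase)
  panel <- if (is.character(conc)) {
    readr::read_csv(conc, show_col_types = FALSE)
  } else tibble::as_tibble(conc)
  extracts <- if (is.character(pbet)) read_pbet_csv(pbet)
              else tibble::as_tibble(pbet)
  if (is.character(psd)) psd <- read_psd_csv(psd)
  w <- resolve_weights(weights, psd, scheme)
  metals <- sort(intersect(unique(panel$metal), names(rfd)))
  labels <- scheme$labels
  ext <- extracts[extracts$phase == phase, ]
  fit_cell <- function(x, metal, fraction, variable) {
    res <- tryCatch(fit_best(x, families), error = function(e) NULL)
    if (is.null(res)) {
      warning("fit failed for ", variable, " (", metal, ", ", fraction,
              "): fixed at mean", call. = FALSE)
      res <- list(spec = dist_spec("fixed", value = mean(x)),
                  ad_statistic = NA_real_)
    }
    res
  }
  fits <- list()
  conc_specs <- ba_specs <- stats::setNames(
    rep(list(stats::setNames(vector("list", length(labels)), labels)),
        length(metals)), metals)
  for (m in metals) for (f in labels) {
    xc <- panel$conc_mg_kg[panel$metal == m & panel$fraction == f]
    xb <- ext$ba[ext$metal == m & ext$fraction == f]
    if (!length(xc) || !length(xb)) {
      stop("missing data for (", m, ", ", f, ")", call. = FALSE)
    }
    rc <- fit_cell(xc, m, f, "concentration")
    rb <- fit_cell(xb, m, f, "bioaccessibility")
    conc_specs[[m]][[f]] <- rc$spec
    ba_specs[[m]][[f]] <- rb$spec
    fits[[paste(m, f)]] <- tibble::tibble(
      metal = m, fraction = f,
      conc_family = rc$spec$family, conc_a2 = rc$ad_statistic,
      ba_family = rb$spec$family, ba_a2 = rb$ad_statistic)
  }
  cfg <- simulation_config(n_iter = n_iter, seed = seed, params = params,
                           weights = w)
  risk <- run_simulation(conc_specs, ba_specs, ir_spec, cfg,
                         rfd = rfd[metals])
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    readr::write_csv(risk$summary, file.path(out_dir, "mc_percentiles.csv"))
  }
  list(risk = risk, fits = dplyr::bind_rows(fits), weights = w)
}

#' Write / read a hazard-quotient table as long CSV
#'
#' The file carries full-precision values (`hq`) plus a 3-significant-
#' figure display twin (`hq_display`); totals, the hazard index and
#' weights travel as extra rows so the file round-trips losslessly
#' through `read_hq_csv()`.
#'
#' @param tab An `hq_table`.
#' @param path Output path.
#' @return `path`, invisibly (`read_hq_csv` returns an `hq_table`).
#' @export
write_hq_csv <- function(tab, path) {
  stopifnot(inherits(tab, "hq_table"))
  metals <- rownames(tab$hq)
  labels <- colnames(tab$hq)
  long <- expand.grid(metal = metals, fraction = labels,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  long$hq <- tab$hq[cbind(long$metal, long$fraction)]
  long$row_type <- "hq"
  tot <- tibble::tibble(metal = names(tab$totals), fraction = "Total",
                        hq = unname(tab$totals), row_type = "total")
  wrow <- tibble::tibble(metal = "weights", fraction = labels,
                         hq = unname(tab$weights$w), row_type = "weight")
  hi <- tibble::tibble(metal = "HI", fraction = "Total", hq = tab$hi,
                       row_type = "hi")
  out <- dplyr::bind_rows(tibble::as_tibble(long), tot, wrow, hi)
  out$hq_display <- signif(out$hq, 3)
  out$provenance <- tab$weights$provenance
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_hq_csv
#' @export
read_hq_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  hqr <- df[df$row_type == "hq", ]
  metals <- unique(hqr$metal)
  labels <- unique(hqr$fraction)
  mat <- matrix(NA_real_, length(metals), length(labels),
                dimnames = list(metals, labels))
  mat[cbind(hqr$metal, hqr$fraction)] <- hqr$hq
  wrow <- df[df$row_type == "weight", ]
  edges <- parse_label_edges(wrow$fraction)
  w <- fraction_weights(wrow$hq, size_scheme(edges),
                        provenance = wrow$provenance[1])
  hq_table_from_matrix(mat, weights = w)
}

# Recover numeric scheme edges from labels like "<63", "63-150".
parse_label_edges <- function(labels) {
  lower <- numeric(length(labels))
  open <- grepl("^<", labels)
  lower[!open] <- as.numeric(sub("-.*$", "", labels[!open]))
  upper <- as.numeric(sub("^.*[-<]", "", labels))
  c(lower[1], upper)
}

write_contributions_csv <- function(tab, path) {
  long <- expand.grid(metal = rownames(tab$contributions),
                      fraction = colnames(tab$contributions),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  long$share <- tab$contributions[cbind(long$metal, long$fraction)]
  long$share_percent_display <- signif(100 * long$share, 3)
  readr::write_csv(tibble::as_tibble(long), path)
  invisible(path)
}

#' Read exposure parameters and RfDs from a YAML config
#'
#' Expects top-level keys `exposure` (fields of [exposure_params()])
#' and optionally `rfd` (named map, mg/(kg d)).
#'
#' @param path YAML file.
#' @return List with `params` ([exposure_params()]) and `rfd`.
#' @export
read_params_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$exposure)) stop("config lacks an 'exposure' block",
                                  call. = FALSE)
  params <- do.call(exposure_params, cfg$exposure)
  rfd <- if (!is.null(cfg$rfd)) unlist(cfg$rfd) else default_rfd()
  list(params = params, rfd = rfd)
}
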