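#' Bioaccessible fraction from a PBET extraction
#'
#' The in vitro bioaccessibility of a metal is the share of its total
#' soil content solubilized in the simulated gastric or intestinal
#' fluid:
#' \deqn{BA = \frac{C \cdot V}{T \cdot M}}
#' with `C` the extract concentration (mg/L), `V` the reactor fluid
#' volume (L), `T` the total soil content (mg/kg) and `M` the soil mass
#' in the reactor (kg).  The result is a unitless fraction; multiply by
#' 100 only at I/O.  Values above 1 are physically impossible
#' (mass-balance violation) but can arise from measurement noise; they
#' are kept and flagged with a warning rather than rejected.
#'
#' @param C Extract concentration, mg/L.
#' @param V Reactor solution volume, L (0.05 L in the standard
#'   geometry).
#' @param T_total Total metal content of the soil, mg/kg.
#' @param M Soil mass in the reactor, kg (0.0005 kg standard).
#' @return Bioaccessible fraction(s), unitless.
#' @examples
#' compute_ba(C = 1.0411, V = 0.05, T_total = 432, M = 0.0005)  # ~0.241
#' @export
compute_ba <- function(C, V = 0.05, T_total, M = 0.0005) {
  if (any(C < 0, na.rm = TRUE) || any(V < 0) || any(T_total < 0) ||
      any(M < 0)) {
    stop("PBET inputs must be nonnegative", call. = FALSE)
  }
  if (any(T_total * M == 0)) {
    stop("bioaccessibility undefined: T * M = 0", call. = FALSE)
  }
  ba <- C * V / (T_total * M)
  if (any(ba > 1, na.rm = TRUE)) {
    warning(sum(ba > 1, na.rm = TRUE),
            " bioaccessibility value(s) exceed 100% (mass-balance QC flag)",
            call. = FALSE)
  }
  ba
}

#' Censored-value substitution at the limit of detection
#'
#' Values below the instrumental LOD (or explicitly flagged as censored
#' via `NA`) are replaced by `lod / sqrt(2)`, the standard substitution
#' for left-censored environmental concentrations; everything else
#' passes through unchanged.
#'
#' @param values Measured concentrations, mg/kg; `NA` marks a
#'   below-detection flag.
#' @param lod Limit of detection, mg/kg (scalar or one per value).
#' @return Vector with censored entries substituted.
#' @examples
#' substitute_below_lod(c(5, NA, 0.01), lod = 0.03)
#' @export
substitute_below_lod <- function(values, lod) {
  if (any(lod <= 0)) stop("lod must be positive", call. = FALSE)
  if (any(values < 0, na.rm = TRUE)) {
    stop("measured values must be nonnegative", call. = FALSE)
  }
  below <- is.na(values) | values < lod
  values[below] <- (lod / sqrt(2))[if (length(lod) > 1) below else 1]
  values
}

#' Blank deduction with a zero floor
#'
#' Subtracts the procedural blank from a raw extract concentration,
#' clipping at zero (a clip is reported as a warning so batches with
#' unusually high blanks are visible).
#'
#' @param value,blank Concentrations, mg/L, both nonnegative.
#' @return `pmax(value - blank, 0)`.
#' @export
blank_subtract <- function(value, blank) {
  if (any(value < 0, na.rm = TRUE) || any(blank < 0, na.rm = TRUE)) {
    stop("value and blank must be nonnegative", call. = FALSE)
  }
  out <- value - blank
  n_clip <- sum(out < 0, na.rm = TRUE)
  if (n_clip > 0) {
    warning(n_clip, " value(s) below blank clipped to zero", call. = FALSE)
  }
  pmax(out, 0)
}

#' Certified-reference-material recovery
#'
#' @param measured,certified Concentrations, mg/kg; `certified` must be
#'   positive.
#' @param bounds Acceptable recovery interval in percent
#'   (default 85-115).
#' @return A tibble with `recovery_percent` and logical `pass`.
#' @examples
#' recovery_percent(93.6, 100)
#' @export
recovery_percent <- function(measured, certified, bounds = c(85, 115)) {
  if (any(certified <= 0)) stop("certified value must be > 0", call. = FALSE)
  if (bounds[1] >= bounds[2]) stop("bounds must be ordered", call. = FALSE)
  pct <- 100 * measured / certified
  tibble::tibble(
    recovery_percent = pct,
    pass = pct >= bounds[1] & pct <= bounds[2]
  )
}

#' Replicate precision: mean, SD and relative standard deviation
#'
#' Sample SD uses the n-1 denominator (analytical triplicates).  A zero
#' mean leaves the RSD undefined (`NA` with an attribute flag) rather
#' than infinite.
#'
#' @param values Numeric vector, length >= 2.
#' @return List with `mean`, `sd`, `rsd_percent`.
#' @export
replicate_stats <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2 || anyNA(values)) {
    stop("need at least two non-missing replicate values", call. = FALSE)
  }
  m <- mean(values)
  s <- stats::sd(values)
  rsd <- if (m == 0) NA_real_ else 100 * s / m
  out <- list(mean = m, sd = s, rsd_percent = rsd)
  if (m == 0) attr(out, "rsd_undefined") <- TRUE
  out
}

#' QC configuration for a PBET / total-concentration batch
#'
#' @param lod_per_metal Named LOD vector, mg/kg (defaults to the
#'   bundled survey LODs).
#' @param recovery_bounds Acceptable CRM recovery, percent.
#' @param rsd_limit Replicate RSD limit, percent.
#' @param cv_limit Parallel-sample coefficient-of-variation limit,
#'   percent.
#' @return A `qc_config` list.
#' @export
qc_config <- function(lod_per_metal = default_lods(),
                      recovery_bounds = c(85, 115),
                      rsd_limit = 10, cv_limit = 5) {
  if (any(lod_per_metal <= 0) || rsd_limit <= 0 || cv_limit <= 0 ||
      recovery_bounds[1] >= recovery_bounds[2]) {
    stop("invalid QC configuration", call. = FALSE)
  }
  structure(list(lod_per_metal = lod_per_metal,
                 recovery_bounds = recovery_bounds,
                 rsd_limit = rsd_limit, cv_limit = cv_limit),
            class = "qc_config")
}

#' Summarize bioaccessibility by metal, phase and fraction
#'
#' Accepts a long table of PBET measurements.  If a `ba` column (a
#' unitless fraction) is absent it is computed from
#' `extract_conc_mg_L`, `volume_L`, `total_conc_mg_kg` and
#' `soil_mass_kg` via [compute_ba()].  Cells with no data are simply
#' absent from the output, never imputed.
#'
#' @param measurements Data frame with at least `metal`, `fraction`,
#'   `phase` and either `ba` or the four raw PBET columns.
#' @return Tibble with `metal`, `phase`, `fraction`, `mean_ba`, `sd_ba`
#'   (`NA` for singletons) and `n`.
#' @export
summarize_ba <- function(measurements) {
  df <- tibble::as_tibble(measurements)
  if (!nrow(df)) stop("no measurements", call. = FALSE)
  need <- c("metal", "fraction", "phase")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  check_metals(df$metal)
  if (!all(df$phase %in% c("gastric", "intestinal"))) {
    stop("phase must be 'gastric' or 'intestinal'", call. = FALSE)
  }
  if (!"ba" %in% names(df)) {
    raw <- c("extract_conc_mg_L", "volume_L", "total_conc_mg_kg",
             "soil_mass_kg")
    miss <- setdiff(raw, names(df))
    if (length(miss)) {
      stop("need a 'ba' column or raw PBET columns (missing: ",
           paste(miss, collapse = ", "), ")", call. = FALSE)
    }
    df$ba <- compute_ba(df$extract_conc_mg_L, df$volume_L,
                        df$total_conc_mg_kg, df$soil_mass_kg)
  }
  dplyr::summarise(
    dplyr::group_by(df, .data$metal, .data$phase, .data$fraction),
    mean_ba = mean(.data$ba),
    sd_ba = if (dplyr::n() > 1) stats::sd(.data$ba) else NA_real_,
    n = dplyr::n(),
    .groups = "drop"
  )
}

#' Read PBET extract measurements from CSV
#'
#' Columns: `sample_id`, `metal`, `fraction`, `phase`,
#' `extract_conc_mg_L`, `volume_L`, `soil_mass_kg`, `total_conc_mg_kg`
#' and optionally `blank_mg_L` (deducted on read, clipped at zero).
#'
#' @param path CSV file path.
#' @param qc Optional [qc_config()]; when given, extract concentrations
#'   are blank-deducted and totals below the per-metal LOD are
#'   substituted by LOD/sqrt(2), in that order.
#' @return Tibble of measurements with a computed `ba` column.
#' @export
read_pbet_csv <- function(path, qc = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("sample_id", "metal", "fraction", "phase", "extract_conc_mg_L",
            "volume_L", "soil_mass_kg", "total_conc_mg_kg")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("pbet csv missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  check_metals(df$metal)
  if (!is.null(qc)) {
    if ("blank_mg_L" %in% names(df)) {
      df$extract_conc_mg_L <- blank_subtract(df$extract_conc_mg_L,
                                             df$blank_mg_L)
    }
    lod <- qc$lod_per_metal[df$metal]
    df$total_conc_mg_kg <- substitute_below_lod(df$total_conc_mg_kg, lod)
  } else if ("blank_mg_L" %in% names(df) && any(df$blank_mg_L > 0)) {
    df$extract_conc_mg_L <- blank_subtract(df$extract_conc_mg_L,
                                           df$blank_mg_L)
  }
  df$ba <- compute_ba(df$extract_conc_mg_L, df$volume_L,
                      df$total_conc_mg_kg, df$soil_mass_kg)
  df
}
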