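#' Particle-size fraction scheme
#'
#' A scheme is the ordered set of sieve diameters (in micrometres) that
#' everything else in the package is keyed on.  Fractions are half-open
#' intervals `[lower, upper)`; the default matches the four sieve cuts
#' commonly used for hand-adherable soil: <63, 63-150, 150-250 and
#' 250-352 um.
#'
#' @param edges Strictly increasing, nonnegative diameters in um.  At
#'   least two edges are required.
#' @return An object of class `size_scheme` with elements `edges` and
#'   derived `labels` (e.g. `"<63"`, `"63-150"`).
#' @examples
#' size_scheme()
#' size_scheme(c(0, 50, 100))
#' @export
size_scheme <- function(edges = c(0, 63, 150, 250, 352)) {
  edges <- as.numeric(edges)
  if (length(edges) < 2) {
    stop("a size scheme needs at least two edges", call. = FALSE)
  }
  if (anyNA(edges) || any(edges < 0)) {
    stop("scheme edges must be nonnegative and non-missing", call. = FALSE)
  }
  if (any(diff(edges) <= 0)) {
    stop("scheme edges must be strictly increasing", call. = FALSE)
  }
  structure(
    list(edges = edges, labels = fraction_labels(edges)),
    class = "size_scheme"
  )
}

fraction_labels <- function(edges) {
  lower <- edges[-length(edges)]
  upper <- edges[-1]
  ifelse(lower == 0,
         paste0("<", format_um(upper)),
         paste0(format_um(lower), "-", format_um(upper)))
}

format_um <- function(x) {
  format(x, trim = TRUE, scientific = FALSE, drop0trailing = TRUE)
}

#' @export
print.size_scheme <- function(x, ...) {
  cat("size_scheme:", length(x$labels), "fractions (um):",
      paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}

n_fractions <- function(scheme) length(scheme$edges) - 1L

is_size_scheme <- function(x) inherits(x, "size_scheme")

same_scheme <- function(a, b) {
  length(a$edges) == length(b$edges) && all(a$edges == b$edges)
}

#' Normalized per-fraction exposure weights
#'
#' Weights are the unitless mass fractions used to combine per-fraction
#' doses into a total dose; they must be nonnegative and sum to one.
#'
#' @param w Nonnegative numeric vector, one weight per scheme fraction.
#' @param scheme A [size_scheme()].
#' @param provenance One of `"hand_dust"`, `"soil"`, `"custom"`; records
#'   where the weight vector came from (hand-rinse dust distribution,
#'   sieved soil distribution, or user supplied).
#' @param normalize If `TRUE`, divide `w` by its sum; otherwise `w` must
#'   already sum to 1 within `1e-9`.
#' @return A `fraction_weights` object.
#' @examples
#' fraction_weights(c(0.5, 0.3, 0.15, 0.05), size_scheme())
#' @export
fraction_weights <- function(w, scheme = size_scheme(),
                             provenance = c("custom", "hand_dust", "soil"),
                             normalize = FALSE) {
  provenance <- match.arg(provenance)
  stopifnot(is_size_scheme(scheme))
  w <- as.numeric(w)
  if (length(w) != n_fractions(scheme)) {
    stop("need one weight per scheme fraction (", n_fractions(scheme), ")",
         call. = FALSE)
  }
  if (anyNA(w) || any(w < 0)) {
    stop("weights must be nonnegative and non-missing", call. = FALSE)
  }
  s <- sum(w)
  if (normalize) {
    if (s <= 0) stop("cannot normalize all-zero weights", call. = FALSE)
    w <- w / s
  } else if (abs(s - 1) > 1e-9) {
    stop("weights must sum to 1 (got ", format(s), "); use normalize = TRUE",
         call. = FALSE)
  }
  names(w) <- scheme$labels
  structure(
    list(w = w, scheme = scheme, provenance = provenance),
    class = "fraction_weights"
  )
}

#' @export
print.fraction_weights <- function(x, ...) {
  cat("fraction_weights (", x$provenance, "):\n", sep = "")
  print(round(x$w, 5))
  invisible(x)
}

as_weight_vector <- function(w, n = NULL) {
  if (inherits(w, "fraction_weights")) return(w$w)
  w <- as.numeric(w)
  if (!is.null(n) && length(w) != n) {
    stop("weight length mismatch", call. = FALSE)
  }
  w
}
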