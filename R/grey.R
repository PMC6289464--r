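#' Net elemental map
#'
#' A background-subtracted elemental map: one signed intensity (electron
#' counts) per pixel of a cell section. Negative values occur naturally after
#' background subtraction and are kept.
#'
#' @param values numeric matrix of signed intensities; must be finite, with at
#'   least 2 pixels.
#' @param element element symbol (`"N"`, `"P"`, `"other"`).
#' @param provenance `"three_window"` if computed from an image triplet,
#'   `"file"` if read from disk, `"synthetic"` for generated maps.
#' @param preprocessing `"none"` or `"negatives_zeroed"`.
#' @param invalid_pixels count of pixels where background extrapolation was
#'   undefined (carried along from [compute_net_map()]).
#' @return An object of class `net_map`.
#' @export
net_map <- function(values, element = c("other", "N", "P"),
                    provenance = c("file", "three_window", "synthetic"),
                    preprocessing = c("none", "negatives_zeroed"),
                    invalid_pixels = 0L) {
  element <- match.arg(element)
  provenance <- match.arg(provenance)
  preprocessing <- match.arg(preprocessing)
  values <- as_matrix_checked(values, "values")
  if (length(values) < 2L) stop("a net map needs at least 2 pixels")
  structure(list(values = values, element = element, provenance = provenance,
                 preprocessing = preprocessing,
                 invalid_pixels = as.integer(invalid_pixels)),
            class = "net_map")
}

#' @export
print.net_map <- function(x, ...) {
  cat(sprintf("<net_map> %s (%s), %d x %d px, values [%.4g, %.4g], preprocessing: %s\n",
              x$element, x$provenance, nrow(x$values), ncol(x$values),
              min(x$values), max(x$values), x$preprocessing))
  if (x$invalid_pixels > 0)
    cat("  ", x$invalid_pixels, "pixels had undefined background (set to 0)\n")
  invisible(x)
}

#' Zero the negative pixels of a net map
#'
#' The preprocessing step that distinguishes workflow B: all negative map
#' values are set to 0 before grey-level quantization. Piling roughly half the
#' background noise into a single value reshapes the grey histogram so that
#' moderately element-rich structures form a distinct first peak on the
#' relative-entropy curve, whose end then serves as the threshold
#' (see [find_g1()]).
#'
#' @param map a [net_map()].
#' @return The map with `values = pmax(values, 0)` and preprocessing recorded
#'   as `"negatives_zeroed"`. Idempotent.
#' @export
zero_negatives <- function(map) {
  stopifnot(inherits(map, "net_map"))
  map$values[map$values < 0] <- 0
  map$preprocessing <- "negatives_zeroed"
  map
}

#' Quantize a net map to 256 grey levels
#'
#' Linear mapping of intensities to the 8-bit grey scale:
#' \deqn{g = \mathrm{round}(255 (x - x_{min}) / (x_{max} - x_{min})),}
#' with round-half-away-from-zero, so the minimum maps to level 0 and the
#' maximum to level 255. A constant map has no dynamic range and is rejected —
#' on real data that indicates an acquisition problem.
#'
#' @param map a [net_map()].
#' @return An object of class `grey_image`: integer matrix `levels` in
#'   `[0, 255]` plus the map's preprocessing flag.
#' @export
to_grey <- function(map) {
  stopifnot(inherits(map, "net_map"))
  x <- map$values
  mn <- min(x); mx <- max(x)
  if (mx == mn)
    stop("degenerate net map: all pixel values equal (", mn,
         "); grey mapping is undefined")
  # values are scaled to [0, 255] >= 0, so half-away-from-zero == floor(x + .5)
  g <- floor(255 * (x - mn) / (mx - mn) + 0.5)
  storage.mode(g) <- "integer"
  structure(list(levels = g, preprocessing = map$preprocessing,
                 element = map$element),
            class = "grey_image")
}

#' @export
print.grey_image <- function(x, ...) {
  cat(sprintf("<grey_image> %d x %d px, levels [%d, %d], preprocessing: %s\n",
              nrow(x$levels), ncol(x$levels), min(x$levels), max(x$levels),
              x$preprocessing))
  invisible(x)
}

# shared input check: coerce to a finite numeric matrix
as_matrix_checked <- function(x, what) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x))
    stop("'", what, "' must be a numeric matrix")
  if (!all(is.finite(x)))
    stop("'", what, "' contains non-finite values")
  storage.mode(x) <- "double"
  dimnames(x) <- NULL
  x
}
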