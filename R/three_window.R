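#' Energy-filtered window image
#'
#' Bundles one energy-filtered image with its energy-loss value. Three such
#' images (two pre-edge, one post-edge) form the input of the three-window
#' background-subtraction method.
#'
#' @param intensity numeric matrix of electron counts per pixel; all values
#'   must be finite.
#' @param energy_loss scalar energy loss in eV at which the window was
#'   recorded.
#' @param role one of `"pre1"`, `"pre2"`, `"post"`.
#' @return An object of class `window_image`.
#' @seealso [fit_powerlaw_background()], [compute_net_map()]
#' @export
window_image <- function(intensity, energy_loss, role = c("pre1", "pre2", "post")) {
  role <- match.arg(role)
  intensity <- as_matrix_checked(intensity, "intensity")
  if (!is.numeric(energy_loss) || length(energy_loss) != 1L ||
      !is.finite(energy_loss) || energy_loss <= 0)
    stop("'energy_loss' must be a single positive finite number (eV)")
  structure(list(intensity = intensity, energy_loss = as.numeric(energy_loss),
                 role = role),
            class = "window_image")
}

#' @export
print.window_image <- function(x, ...) {
  cat(sprintf("<window_image> %s @ %.6g eV, %d x %d px, counts [%.4g, %.4g]\n",
              x$role, x$energy_loss, nrow(x$intensity), ncol(x$intensity),
              min(x$intensity), max(x$intensity)))
  invisible(x)
}

#' Per-pixel power-law background model from two pre-edge images
#'
#' Fits, independently at every pixel, the power law \eqn{I(E) = A E^{-r}}
#' through the two pre-edge measurements. Two points determine the power law
#' exactly:
#' \deqn{r = \ln(I_1 / I_2) / \ln(E_2 / E_1), \qquad A = I_1 E_1^{r}.}
#' Pixels where either pre-edge intensity is non-positive have no defined
#' logarithm; they are flagged invalid and excluded from extrapolation.
#'
#' @param pre1,pre2 [window_image()] objects; same shape, distinct energies.
#' @return An object of class `background_model` with matrices `A`
#'   (counts·eV^r), `r` (dimensionless) and logical `valid`; invalid pixels
#'   carry `NA` in `A` and `r`.
#' @export
fit_powerlaw_background <- function(pre1, pre2) {
  stopifnot(inherits(pre1, "window_image"), inherits(pre2, "window_image"))
  if (!identical(dim(pre1$intensity), dim(pre2$intensity)))
    stop("pre-edge images have mismatching shapes: ",
         paste(dim(pre1$intensity), collapse = "x"), " vs ",
         paste(dim(pre2$intensity), collapse = "x"))
  e1 <- pre1$energy_loss; e2 <- pre2$energy_loss
  if (e1 == e2)
    stop("pre-edge energies are equal (", e1, " eV); the power law is undetermined")
  i1 <- pre1$intensity; i2 <- pre2$intensity
  valid <- i1 > 0 & i2 > 0
  r <- A <- matrix(NA_real_, nrow(i1), ncol(i1))
  r[valid] <- log(i1[valid] / i2[valid]) / log(e2 / e1)
  A[valid] <- i1[valid] * e1^r[valid]
  structure(list(A = A, r = r, valid = valid,
                 energies = c(pre1 = e1, pre2 = e2)),
            class = "background_model")
}

#' @export
print.background_model <- function(x, ...) {
  cat(sprintf("<background_model> %d x %d px, %d invalid px, r in [%.4g, %.4g]\n",
              nrow(x$A), ncol(x$A), sum(!x$valid),
              suppressWarnings(min(x$r, na.rm = TRUE)),
              suppressWarnings(max(x$r, na.rm = TRUE))))
  invisible(x)
}

#' Net elemental map by three-window background subtraction
#'
#' Extrapolates the fitted per-pixel power-law background to the post-edge
#' energy and subtracts it from the post-edge image:
#' \eqn{net = I_{post} - A E_{post}^{-r}}. Negative net values are preserved
#' (they are genuine background-subtraction residuals; zeroing them is a
#' workflow-specific preprocessing step, see [zero_negatives()]). Pixels where
#' the background fit is undefined produce net 0 and are tallied in the map's
#' `invalid_pixels` attribute.
#'
#' @param post a [window_image()] with role `"post"`; its energy loss must
#'   exceed both pre-edge energies.
#' @param model a `background_model` from [fit_powerlaw_background()].
#' @param element element symbol recorded on the map (`"N"`, `"P"` or
#'   `"other"`).
#' @return A [net_map()] with provenance `"three_window"`.
#' @export
compute_net_map <- function(post, model, element = c("other", "N", "P")) {
  element <- match.arg(element)
  stopifnot(inherits(post, "window_image"), inherits(model, "background_model"))
  if (!identical(dim(post$intensity), dim(model$A)))
    stop("post-edge image and background model have mismatching shapes")
  if (post$energy_loss <= max(model$energies))
    stop("post-edge energy (", post$energy_loss,
         " eV) must exceed both pre-edge energies")
  bg <- model$A * post$energy_loss^(-model$r)
  net <- post$intensity - bg
  net[!model$valid] <- 0
  net_map(net, element = element, provenance = "three_window",
          invalid_pixels = sum(!model$valid))
}
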