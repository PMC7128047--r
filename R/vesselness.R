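# Multiscale Hessian-based vessel enhancement. The per-scale response is
# built from the eigenvalues of the Gaussian-scale Hessian: with signed
# ordering lam1 <= lam2, a dark tube (an intensity valley) has lam1 ~ 0 along
# the axis and lam2 >> 0 across it, so the response gates on lam1 <= 0 and
# grows with the fractional anisotropy of the eigenvalue pair.

#' Gaussian smoothing
#'
#' Isotropic Gaussian convolution with reflective boundary handling.
#'
#' @param img grayscale matrix.
#' @param sigma standard deviation in pixels (> 0).
#' @return smoothed matrix of the same shape.
#' @export
gaussian_smooth <- function(img, sigma) {
  g <- gaussian_kernel_1d(sigma, 0L)
  conv2_sep(img, g, g)
}

#' Hessian field at one scale
#'
#' Second derivatives of the image at Gaussian scale `sigma`, computed by
#' convolution with analytic Gaussian-derivative kernels. With
#' `scale_normalize = TRUE` (the default) each derivative is multiplied by
#' `sigma^2`, which makes responses comparable across scales so that the
#' multiscale maximum selects the scale matched to the local vessel width.
#'
#' @param img grayscale matrix.
#' @param sigma scale in pixels (> 0).
#' @param scale_normalize multiply second derivatives by `sigma^2`?
#' @return object of class `hessian_field` with matrices `gxx`, `gxy`, `gyy`
#'   and the scale `sigma`.
#' @export
hessian_at_scale <- function(img, sigma, scale_normalize = TRUE) {
  g0 <- gaussian_kernel_1d(sigma, 0L)
  g1 <- gaussian_kernel_1d(sigma, 1L)
  g2 <- gaussian_kernel_1d(sigma, 2L)
  gxx <- conv2_sep(img, g0, g2)
  gyy <- conv2_sep(img, g2, g0)
  gxy <- conv2_sep(img, g1, g1)
  if (scale_normalize) {
    s2 <- sigma^2
    gxx <- gxx * s2; gyy <- gyy * s2; gxy <- gxy * s2
  }
  if (!all(is.finite(gxx)) || !all(is.finite(gxy)) || !all(is.finite(gyy)))
    stopf("non-finite values in the Hessian field at sigma = %g", sigma)
  structure(list(gxx = gxx, gxy = gxy, gyy = gyy, sigma = sigma),
            class = "hessian_field")
}

#' Pixelwise eigendecomposition of a 2x2 symmetric Hessian field
#'
#' Closed-form eigenvalues with signed ordering `lam1 <= lam2`, and the unit
#' eigenvector of `lam2`. For a dark vessel, that eigenvector points across
#' the vessel (the direction of strongest positive curvature), which is the
#' direction later used to offset background seeds. `ordering = "magnitude"`
#' instead sorts by absolute value (classic Frangi convention).
#'
#' @param h `hessian_field` object.
#' @param ordering `"signed"` (default) or `"magnitude"`.
#' @return object of class `eigen_field` with matrices `lam1`, `lam2`,
#'   `v2x`, `v2y`.
#' @export
eigen_decompose <- function(h, ordering = c("signed", "magnitude")) {
  ordering <- match.arg(ordering)
  gxx <- h$gxx; gyy <- h$gyy; gxy <- h$gxy
  mid <- (gxx + gyy) / 2
  dif <- (gxx - gyy) / 2
  rad <- sqrt(dif^2 + gxy^2)
  lam1 <- mid - rad
  lam2 <- mid + rad
  if (ordering == "magnitude") {
    swap <- abs(lam1) > abs(lam2)
    tmp <- lam1[swap]; lam1[swap] <- lam2[swap]; lam2[swap] <- tmp
  }
  # eigenvector of the larger-(signed)-eigenvalue axis; always taken for the
  # signed lam2 = mid + rad, the cross-vessel axis of a dark tube
  lam_hi <- mid + rad
  vx <- gxy
  vy <- lam_hi - gxx
  nrm <- sqrt(vx^2 + vy^2)
  deg <- nrm < 1e-12
  vx2 <- lam_hi - gyy
  vy2 <- gxy
  nrm2 <- sqrt(vx2^2 + vy2^2)
  vx[deg] <- vx2[deg]; vy[deg] <- vy2[deg]; nrm[deg] <- nrm2[deg]
  iso <- nrm < 1e-12
  vx[iso] <- 1; vy[iso] <- 0; nrm[iso] <- 1
  structure(list(lam1 = lam1, lam2 = lam2, v2x = vx / nrm, v2y = vy / nrm,
                 sigma = h$sigma),
            class = "eigen_field")
}

#' Fractional anisotropy of the Hessian eigenvalues
#'
#' `FAH = |lam1 - lam2| / sqrt(lam1^2 + lam2^2)`, defined as 0 where both
#' eigenvalues vanish. It is 0 for isotropic (blob-like) structure and 1 when
#' one eigenvalue dominates, the signature of a line; the mathematical upper
#' bound sqrt(2) is reached for equal-and-opposite eigenvalues.
#'
#' @param e `eigen_field` object.
#' @return matrix of anisotropy values in `[0, sqrt(2)]`.
#' @export
fractional_anisotropy <- function(e) {
  s <- sqrt(e$lam1^2 + e$lam2^2)
  fa <- abs(e$lam1 - e$lam2)
  out <- ifelse(s > 0, fa / s, 0)
  dim(out) <- dim(e$lam1)
  out
}

#' Vesselness response at one scale
#'
#' The response is 0 where `lam1 > 0` (a dark tube cannot have negative
#' curvature along its axis), and otherwise
#' `(1 - exp(-s^2 / (2 c^2))) * exp(FAH - 1)` with
#' `s = sqrt(lam1^2 + lam2^2)`. FAH is clipped to `[0, 1]` before
#' exponentiation so the response stays in `[0, 1]` and equals the structure
#' strength factor exactly at FAH = 1. `exponent_form = "inverse"` switches
#' the anisotropy factor to `exp(-1 / FAH)` (0 at FAH = 0).
#'
#' @param e `eigen_field` object.
#' @param c contrast-sensitivity parameter (> 0), default 0.2 on the `[0,1]`
#'   intensity scale.
#' @param exponent_form `"anisotropy"` for `exp(FAH - 1)` (default) or
#'   `"inverse"` for `exp(-1/FAH)`.
#' @return matrix of responses in `[0, 1]`.
#' @export
vesselness_at_scale <- function(e, c = 0.2, exponent_form = c("anisotropy", "inverse")) {
  exponent_form <- match.arg(exponent_form)
  if (!is.numeric(c) || length(c) != 1L || c <= 0) stopf("c must be a single positive number")
  s2 <- e$lam1^2 + e$lam2^2
  fa <- pmin(fractional_anisotropy(e), 1)
  aniso <- if (exponent_form == "anisotropy") exp(fa - 1) else ifelse(fa > 0, exp(-1 / fa), 0)
  v <- (1 - exp(-s2 / (2 * c^2))) * aniso
  v[e$lam1 > 0] <- 0
  v <- clamp01(v)
  dim(v) <- dim(e$lam1)
  v
}

#' Default scale grid
#'
#' The scale set `sigma = 0.2 m`, `m = 1, ..., 25`, spanning sub-pixel to
#' 5-px Gaussian scales and covering vessel widths of roughly 2 to 12 px.
#'
#' @param m number of scales.
#' @param step scale increment in pixels.
#' @return numeric vector of scales.
#' @export
default_scales <- function(m = 25L, step = 0.2) step * seq_len(m)

#' Multiscale vesselness map
#'
#' Computes the vesselness response at every scale and keeps, per pixel, the
#' maximum response together with the scale achieving it and the cross-vessel
#' eigenvector at that scale. The map is zeroed outside the FOV.
#'
#' @param img grayscale matrix (the green channel).
#' @param sigmas vector of scales in pixels.
#' @param c contrast-sensitivity parameter of [vesselness_at_scale()].
#' @param fov optional logical FOV mask.
#' @param scale_normalize see [hessian_at_scale()].
#' @param exponent_form see [vesselness_at_scale()].
#' @param ordering see [eigen_decompose()].
#' @return object of class `vesselness_map`: list with `values` (matrix in
#'   `[0, 1]`), `sigmas`, `argmax_sigma` (matrix), and `eigen` (an
#'   `eigen_field` holding per-pixel values at the maximizing scale).
#' @export
multiscale_vesselness <- function(img, sigmas = default_scales(), c = 0.2,
                                  fov = NULL, scale_normalize = TRUE,
                                  exponent_form = c("anisotropy", "inverse"),
                                  ordering = c("signed", "magnitude")) {
  exponent_form <- match.arg(exponent_form)
  ordering <- match.arg(ordering)
  img <- as_gray_matrix(img)
  if (length(sigmas) == 0L) stopf("sigmas must contain at least one scale")
  best <- matrix(0, nrow(img), ncol(img))
  arg <- matrix(sigmas[1L], nrow(img), ncol(img))
  lam1 <- best; lam2 <- best
  v2x <- matrix(1, nrow(img), ncol(img)); v2y <- matrix(0, nrow(img), ncol(img))
  first <- TRUE
  for (s in sigmas) {
    e <- eigen_decompose(hessian_at_scale(img, s, scale_normalize), ordering)
    v <- vesselness_at_scale(e, c, exponent_form)
    upd <- if (first) matrix(TRUE, nrow(img), ncol(img)) else v > best
    first <- FALSE
    best[upd] <- v[upd]
    arg[upd] <- s
    lam1[upd] <- e$lam1[upd]; lam2[upd] <- e$lam2[upd]
    v2x[upd] <- e$v2x[upd]; v2y[upd] <- e$v2y[upd]
  }
  if (!is.null(fov)) {
    fov <- as_mask(fov)
    check_same_shape(img, fov, "image and FOV mask")
    best[!fov] <- 0
  }
  structure(list(values = best, sigmas = sigmas, argmax_sigma = arg,
                 eigen = structure(list(lam1 = lam1, lam2 = lam2,
                                        v2x = v2x, v2y = v2y, sigma = NA_real_),
                                   class = "eigen_field")),
            class = "vesselness_map")
}

#' @export
print.vesselness_map <- function(x, ...) {
  cat(sprintf("vesselness map: %d x %d, %d scales in [%g, %g], max response %.4f\n",
              nrow(x$values), ncol(x$values), length(x$sigmas),
              min(x$sigmas), max(x$sigmas), max(x$values)))
  invisible(x)
}
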