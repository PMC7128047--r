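# Centerline extraction. Candidates come from the divergence of the
# normalized gradient vector field (positive at the axis of a dark tube,
# where the field expands), and are corrected by a morphological skeleton
# obtained from a multi-orientation bottom-hat transform, Otsu binarization
# and Zhang-Suen thinning.

#' Gaussian gradient vector field
#'
#' First Gaussian-derivative convolution in x (columns) and y (rows).
#'
#' @param img grayscale matrix.
#' @param sigma Gaussian scale in pixels (> 0).
#' @return object of class `vector_field` with matrices `fx`, `fy`.
#' @export
gradient_field <- function(img, sigma) {
  g0 <- gaussian_kernel_1d(sigma, 0L)
  g1 <- gaussian_kernel_1d(sigma, 1L)
  structure(list(fx = conv2_sep(img, g0, g1),
                 fy = conv2_sep(img, g1, g0),
                 sigma = sigma),
            class = "vector_field")
}

#' Normalize a vector field to unit magnitude
#'
#' Vectors with magnitude below `eps` are set to exactly (0, 0).
#'
#' @param f `vector_field` object (or list with `fx`, `fy`).
#' @param eps magnitude floor on the `[0, 1]` intensity scale.
#' @return `vector_field` with per-pixel magnitude 0 or 1.
#' @export
normalize_field <- function(f, eps = 1e-8) {
  if (eps <= 0) stopf("eps must be positive")
  mag <- sqrt(f$fx^2 + f$fy^2)
  keep <- mag >= eps
  fx <- ifelse(keep, f$fx / mag, 0)
  fy <- ifelse(keep, f$fy / mag, 0)
  dim(fx) <- dim(f$fx); dim(fy) <- dim(f$fy)
  structure(list(fx = fx, fy = fy, sigma = f$sigma), class = "vector_field")
}

#' Divergence of a rotated vector field
#'
#' Rotates every vector by `theta` (standard 2-D rotation) and computes the
#' numerical divergence by central differences. For the normalized gradient
#' field of a dark tube the divergence is positive along the axis, where the
#' field expands.
#'
#' @param nf `vector_field` object (typically normalized).
#' @param theta rotation angle in radians.
#' @return matrix of divergence values.
#' @export
rotated_divergence <- function(nf, theta) {
  ct <- cos(theta); st <- sin(theta)
  rx <- ct * nf$fx - st * nf$fy
  ry <- st * nf$fx + ct * nf$fy
  cdiff_x(rx) + cdiff_y(ry)
}

#' Angle-weighted divergence of a normalized field
#'
#' The directional divergence score
#' `NG(theta) = cos(theta) * dNFx/dx + sin(theta) * dNFy/dy` (central
#' differences): the two partial divergence terms weighted by the rotation
#' angle. Sweeping `theta` emphasizes vessels of different orientations one
#' at a time.
#'
#' @param nf `vector_field` object (typically normalized).
#' @param theta angle in radians.
#' @return matrix of divergence scores.
#' @export
directional_divergence <- function(nf, theta) {
  cos(theta) * cdiff_x(nf$fx) + sin(theta) * cdiff_y(nf$fy)
}

#' Candidate centerlines from the normalized gradient vector field
#'
#' For every pair (theta, sigma), thresholds a divergence score of the
#' normalized gradient field at `phi` and discards 8-connected components
#' smaller than `delta` pixels; the candidate mask is the union over all
#' pairs, intersected with the FOV.
#'
#' Two divergence scores are available. `"directional"` (the default) is
#' [directional_divergence()], the angle-weighted sum of the two partial
#' divergence terms; taking at most one full-strength noise term per angle,
#' it stays below the spatial percolation threshold on noisy images, so the
#' small-component filter `delta` can remove spurious responses.
#' `"rotated"` rotates the field by `theta` and takes the full numerical
#' divergence ([rotated_divergence()]); it is more sensitive but its noise
#' responses merge into large components on low-contrast backgrounds.
#'
#' @param img grayscale matrix.
#' @param thetas rotation angles in radians.
#' @param sigmas Gaussian scales in pixels.
#' @param phi divergence threshold in (0, 1).
#' @param delta minimum component size in pixels.
#' @param fov optional logical FOV mask.
#' @param eps magnitude floor for [normalize_field()].
#' @param divergence_form `"directional"` or `"rotated"`.
#' @return logical matrix of candidate centerline pixels.
#' @export
candidate_centerlines <- function(img, thetas = pi / 8 * (0:7),
                                  sigmas = default_scales(), phi = 0.45,
                                  delta = 50L, fov = NULL, eps = 1e-8,
                                  divergence_form = c("directional", "rotated")) {
  divergence_form <- match.arg(divergence_form)
  img <- as_gray_matrix(img)
  if (!length(thetas) || !length(sigmas)) stopf("thetas and sigmas must be nonempty")
  if (phi <= 0 || phi >= 1) stopf("phi must lie in (0, 1)")
  if (delta < 1) stopf("delta must be >= 1")
  if (!is.null(fov)) {
    fov <- as_mask(fov)
    check_same_shape(img, fov, "image and FOV mask")
  }
  acc <- matrix(FALSE, nrow(img), ncol(img))
  for (s in sigmas) {
    nf <- normalize_field(gradient_field(img, s), eps)
    for (th in thetas) {
      ng <- if (divergence_form == "directional") directional_divergence(nf, th)
            else rotated_divergence(nf, th)
      b <- ng > phi
      if (!is.null(fov)) b <- b & fov
      if (any(b)) acc <- acc | drop_small_components(b, delta, connectivity = 8L)
    }
  }
  if (!is.null(fov)) acc <- acc & fov
  acc
}

#' Summed multi-orientation bottom-hat transform
#'
#' Sum over all (length, angle) pairs of `closing(img, SE) - img` with
#' 1-px-wide linear structuring elements; dark structures narrower than the
#' element respond strongly. The sum is rescaled to `[0, 1]` by its maximum.
#'
#' @param img grayscale matrix.
#' @param lengths element lengths in pixels (default 2--12, step 2).
#' @param angles element orientations in radians (default 0 to 7pi/8,
#'   step pi/8).
#' @return matrix in `[0, 1]`.
#' @export
bottomhat_sum <- function(img, lengths = seq(2L, 12L, by = 2L),
                          angles = pi / 8 * (0:7)) {
  img <- as_gray_matrix(img)
  if (!length(lengths) || !length(angles)) stopf("lengths and angles must be nonempty")
  acc <- matrix(0, nrow(img), ncol(img))
  for (len in lengths) for (a in angles) {
    acc <- acc + (flat_close(img, line_se(len, a)) - img)
  }
  m <- max(acc)
  if (m > 0) acc <- acc / m
  acc
}

#' Otsu threshold
#'
#' Threshold maximizing the between-class variance, searched over the edges
#' of an `nbins`-bin histogram spanning the image range; class statistics are
#' evaluated exactly from the raw pixel values. Ties are broken toward the
#' lower threshold.
#'
#' @param img grayscale matrix (or numeric vector of pixel values) with at
#'   least two distinct values.
#' @param nbins number of histogram bins.
#' @return the threshold value (a scalar); pixels strictly below it form the
#'   background class.
#' @export
otsu_threshold <- function(img, nbins = 256L) {
  v <- if (is.matrix(img) || inherits(img, "Image")) as.vector(as_gray_matrix(img))
       else as.numeric(img)
  if (!length(v)) stopf("empty input to otsu_threshold")
  lo <- min(v); hi <- max(v)
  if (!(hi > lo)) stopf("degenerate input: constant image has no Otsu threshold")
  edges <- seq(lo, hi, length.out = nbins + 1L)[2:nbins]
  vs <- sort(v)
  cs <- cumsum(vs)
  n <- length(vs)
  k <- findInterval(edges, vs, left.open = TRUE)  # count of values < edge (ties: values == edge go right)
  valid <- k > 0L & k < n
  k <- k[valid]; edges <- edges[valid]
  if (!length(k)) stopf("degenerate input: no valid Otsu split")
  w0 <- k / n
  w1 <- 1 - w0
  m0 <- cs[k] / k
  m1 <- (cs[n] - cs[k]) / (n - k)
  crit <- w0 * w1 * (m0 - m1)^2
  edges[which.max(crit)]
}

# 8-neighborhoods of the padded mask, clockwise from north.
zs_neighbors <- function(mp, H, W) {
  rr <- 2:(H + 1L); cc <- 2:(W + 1L)
  list(p2 = mp[rr - 1L, cc], p3 = mp[rr - 1L, cc + 1L], p4 = mp[rr, cc + 1L],
       p5 = mp[rr + 1L, cc + 1L], p6 = mp[rr + 1L, cc], p7 = mp[rr + 1L, cc - 1L],
       p8 = mp[rr, cc - 1L], p9 = mp[rr - 1L, cc - 1L])
}

#' Morphological thinning (Zhang-Suen)
#'
#' Iteratively peels boundary pixels in two alternating sub-iterations until
#' a fixpoint, producing a 1-px-wide skeleton. The output is a subset of the
#' input and preserves 8-connectivity of the foreground.
#'
#' @param mask logical matrix.
#' @return logical matrix, the skeleton.
#' @export
thin_to_skeleton <- function(mask) {
  m <- as_mask(mask)
  H <- nrow(m); W <- ncol(m)
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      mp <- matrix(FALSE, H + 2L, W + 2L)
      mp[2:(H + 1L), 2:(W + 1L)] <- m
      nb <- zs_neighbors(mp, H, W)
      B <- nb$p2 + nb$p3 + nb$p4 + nb$p5 + nb$p6 + nb$p7 + nb$p8 + nb$p9
      ring <- list(nb$p2, nb$p3, nb$p4, nb$p5, nb$p6, nb$p7, nb$p8, nb$p9, nb$p2)
      A <- matrix(0L, H, W)
      for (i in 1:8) A <- A + (!ring[[i]] & ring[[i + 1L]])
      del <- m & B >= 2 & B <= 6 & A == 1L
      if (sub == 1L) {
        del <- del & !(nb$p2 & nb$p4 & nb$p6) & !(nb$p4 & nb$p6 & nb$p8)
      } else {
        del <- del & !(nb$p2 & nb$p4 & nb$p8) & !(nb$p2 & nb$p6 & nb$p8)
      }
      if (any(del)) {
        # simultaneous deletion can erase a small component outright (the
        # classic 2x2-square case); exempt one pixel of any component whose
        # pixels would all be removed, so topology is preserved
        lab <- label_components(m, 8L)
        tot <- tabulate(lab)
        hit <- tabulate(lab[del], nbins = length(tot))
        for (k in which(hit == tot & tot > 0L)) {
          del[which(lab == k & del)[1L]] <- FALSE
        }
      }
      if (any(del)) {
        m[del] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

#' Correct the skeleton with the candidate centerlines
#'
#' Splits both masks into 4-connected regions and keeps every region whose
#' coverage by the skeleton/candidate agreement exceeds `overlap_frac` of
#' its own size; the union of kept regions is cleaned of 8-connected
#' components shorter than `min_length` pixels.
#'
#' The agreement set is the intersection `c_skel & c_can`; `inter_tol`
#' optionally dilates it before the coverage test, trading noise rejection
#' for tolerance to one-pixel disagreements between the two line maps. The
#' default `min_length` matches `delta`, the minimum size already demanded
#' of candidate components: centerline branches shorter than that are
#' indistinguishable from the skeleton fragments that image noise produces.
#'
#' @param c_skel skeleton mask.
#' @param c_can candidate centerline mask.
#' @param overlap_frac required overlap fraction in (0, 1).
#' @param min_length minimum component size in pixels.
#' @param inter_tol spatial tolerance (px) applied to the agreement set.
#' @return logical matrix, the final centerline mask.
#' @export
correct_centerlines <- function(c_skel, c_can, overlap_frac = 0.40, min_length = 50L,
                                inter_tol = 0L) {
  c_skel <- as_mask(c_skel); c_can <- as_mask(c_can)
  check_same_shape(c_skel, c_can, "centerline masks")
  if (overlap_frac <= 0 || overlap_frac >= 1) stopf("overlap_frac must lie in (0, 1)")
  c_inter <- c_skel & c_can
  cov <- c_inter
  if (inter_tol >= 1L && any(c_inter))
    cov <- as_mask(EBImage::dilate(c_inter * 1, disc_se(as.integer(inter_tol))))
  keep_regions <- function(mask) {
    if (!any(mask)) return(mask)
    lab <- label_components(mask, connectivity = 4L)
    sz <- tabulate(lab)
    ov <- tabulate(lab[cov], nbins = length(sz))
    good <- ov / sz > overlap_frac
    out <- mask & good[pmax(lab, 1L)] & lab > 0L
    dim(out) <- dim(mask)
    out
  }
  out <- keep_regions(c_skel) | keep_regions(c_can)
  drop_small_components(out, min_length, connectivity = 8L)
}
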