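# Seeded random-walker segmentation on a vesselness-weighted 8-connected
# pixel lattice. Foreground seeds are the centerline pixels; background
# seeds are offset from each centerline pixel along the cross-vessel
# eigenvector, one pixel beyond the (local) vessel radius. The walker
# probabilities solve the combinatorial Dirichlet problem on the lattice.

#' @name seed_labels
#' @title Seed label codes
#' @description Integer codes used in seed maps: `SEED_UNLABELED` (0),
#'   `SEED_FG` (1, vessel), `SEED_BG` (2, background).
NULL

#' @rdname seed_labels
#' @export
SEED_UNLABELED <- 0L
#' @rdname seed_labels
#' @export
SEED_FG <- 1L
#' @rdname seed_labels
#' @export
SEED_BG <- 2L

guide_matrix <- function(guide, normalize = TRUE) {
  v <- if (inherits(guide, "vesselness_map")) guide$values else as_gray_matrix(guide)
  if (normalize && max(v) > 0) v <- v / max(v)
  v
}

#' Build the weighted 8-connected pixel lattice
#'
#' Nodes are the in-FOV pixels; every 8-neighbor pair inside the FOV gets an
#' edge with weight `exp(-beta * (v_i - v_j)^2)` where `v` is the guide
#' value (the multiscale vesselness response). With
#' `normalize_guide = TRUE` (default) the guide is first rescaled to a
#' maximum of 1, so that `beta` acts on the enhanced image's full dynamic
#' range regardless of the absolute vesselness amplitude of the scene.
#'
#' @param guide `vesselness_map` or grayscale matrix used as the guide image.
#' @param fov logical FOV mask.
#' @param beta edge-weighting parameter (> 0), default 90.
#' @param normalize_guide rescale the guide image to `[0, 1]` by its
#'   maximum?
#' @return object of class `pixel_lattice`: list with `index` (H x W matrix,
#'   0 outside the graph), `edges` (data frame `i`, `j`, `w`), `n`, `fov`,
#'   `beta`.
#' @export
build_lattice <- function(guide, fov, beta = 90, normalize_guide = TRUE) {
  v <- guide_matrix(guide, normalize_guide)
  fov <- as_mask(fov)
  check_same_shape(v, fov, "guide image and FOV mask")
  if (!is.numeric(beta) || length(beta) != 1L || beta <= 0) stopf("beta must be a single positive number")
  if (!any(fov)) stopf("degenerate input: FOV mask has no pixels; no lattice to build")
  H <- nrow(v); W <- ncol(v)
  index <- matrix(0L, H, W)
  index[fov] <- seq_len(sum(fov))
  ii <- integer(0); jj <- integer(0); ww <- numeric(0)
  # offsets covering each undirected 8-neighbor pair once: E, S, SE, SW
  for (off in list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))) {
    dr <- off[1L]; dc <- off[2L]
    r0 <- seq_len(H - dr)
    c0 <- if (dc >= 0L) seq_len(W - dc) else seq.int(1L - dc, W)
    a <- index[r0, c0, drop = FALSE]
    b <- index[r0 + dr, c0 + dc, drop = FALSE]
    ok <- a > 0L & b > 0L
    if (any(ok)) {
      va <- v[r0, c0, drop = FALSE][ok]
      vb <- v[r0 + dr, c0 + dc, drop = FALSE][ok]
      ii <- c(ii, a[ok]); jj <- c(jj, b[ok])
      ww <- c(ww, exp(-beta * (va - vb)^2))
    }
  }
  structure(list(index = index, edges = data.frame(i = ii, j = jj, w = ww),
                 n = sum(fov), fov = fov, beta = beta),
            class = "pixel_lattice")
}

#' @export
print.pixel_lattice <- function(x, ...) {
  cat(sprintf("pixel lattice: %d nodes, %d edges, beta = %g\n",
              x$n, nrow(x$edges), x$beta))
  invisible(x)
}

#' Classify centerline pixels as dense or sparse
#'
#' The centerlines are dilated with a disc of radius `r_mid`; a centerline
#' pixel is DENSE when the dilated mask, cropped to the square window of
#' half-width `2 * r_mid` centered at the pixel, splits into more than one
#' 8-connected component (several vessels run nearby), and SPARSE otherwise.
#'
#' @param c_final centerline mask.
#' @param r_mid mid-range vessel radius in pixels (>= 1).
#' @return object of class `density_map`: list with `dense` (logical matrix,
#'   meaningful only on centerline pixels), `centerline`, `r_mid`.
#' @export
classify_density <- function(c_final, r_mid = 7L) {
  c_final <- as_mask(c_final)
  r_mid <- as.integer(r_mid)
  if (r_mid < 1L) stopf("r_mid must be >= 1")
  H <- nrow(c_final); W <- ncol(c_final)
  dense <- matrix(FALSE, H, W)
  px <- which(c_final, arr.ind = TRUE)
  if (nrow(px)) {
    dil <- as_mask(EBImage::dilate(c_final * 1, disc_se(r_mid)))
    hw <- 2L * r_mid
    for (k in seq_len(nrow(px))) {
      r <- px[k, 1L]; c0 <- px[k, 2L]
      win <- dil[max(1L, r - hw):min(H, r + hw),
                 max(1L, c0 - hw):min(W, c0 + hw), drop = FALSE]
      if (count_components(win, connectivity = 8L) > 1L) dense[r, c0] <- TRUE
    }
  }
  structure(list(dense = dense, centerline = c_final, r_mid = r_mid),
            class = "density_map")
}

#' Place foreground and background seeds automatically
#'
#' Every centerline pixel becomes a foreground seed. For each such pixel the
#' two candidate background seeds lie at distance `r_mid + 1` (DENSE areas)
#' or `r_max + 1` (SPARSE areas) along the cross-vessel unit eigenvector, on
#' both sides; a candidate is kept only if it falls inside the FOV, is not a
#' foreground seed, and is not within 1 px of any centerline pixel.
#'
#' When a guide image is supplied, candidate background seeds falling on
#' vessel-like pixels are rejected: the guide is rescaled to a maximum of 1
#' and candidates above its Otsu threshold (computed over the FOV) are
#' dropped. A background label is a hard boundary condition, and planting
#' one on a pixel the enhancement stage scores as vessel would contradict
#' that evidence -- typically where a neighboring branch's offset lands on
#' a wide vessel whose own centerline was not recovered.
#'
#' @param c_final centerline mask (nonempty).
#' @param eig `eigen_field` carrying the cross-vessel eigenvector (`v2x`,
#'   `v2y`), e.g. the `eigen` component of [multiscale_vesselness()].
#' @param density `density_map` from [classify_density()] (or a logical
#'   matrix of DENSE flags).
#' @param fov logical FOV mask.
#' @param r_mid mid-range vessel radius (px).
#' @param r_max maximum vessel radius (px).
#' @param guide optional `vesselness_map` (or matrix) used to veto
#'   vessel-like background candidates.
#' @return integer matrix of seed labels (see [seed_labels]).
#' @export
place_seeds <- function(c_final, eig, density, fov, r_mid = 7L, r_max = 12L,
                        guide = NULL) {
  c_final <- as_mask(c_final)
  fov <- as_mask(fov)
  check_same_shape(c_final, fov, "centerline and FOV masks")
  if (!any(c_final)) stopf("seeding error: centerline mask is empty")
  dense <- if (inherits(density, "density_map")) density$dense else as_mask(density)
  H <- nrow(c_final); W <- ncol(c_final)
  seeds <- matrix(SEED_UNLABELED, H, W)
  seeds[c_final & fov] <- SEED_FG
  forbidden <- as_mask(EBImage::dilate(c_final * 1, disc_se(1L)))  # within 1 px of a centerline
  px <- which(c_final & fov, arr.ind = TRUE)
  d <- ifelse(dense[px], r_mid + 1L, r_max + 1L)
  ux <- eig$v2x[px]; uy <- eig$v2y[px]
  cand_r <- c(px[, 1L] + round(d * uy), px[, 1L] - round(d * uy))
  cand_c <- c(px[, 2L] + round(d * ux), px[, 2L] - round(d * ux))
  ok <- cand_r >= 1L & cand_r <= H & cand_c >= 1L & cand_c <= W
  cand <- cbind(cand_r[ok], cand_c[ok])
  ok2 <- fov[cand] & !forbidden[cand] & seeds[cand] != SEED_FG
  cand <- cand[ok2, , drop = FALSE]
  if (!is.null(guide) && nrow(cand)) {
    v <- guide_matrix(guide, normalize = TRUE)
    check_same_shape(c_final, v, "centerline mask and guide")
    cut <- tryCatch(otsu_threshold(v[fov]), error = function(e) Inf)
    keep <- v[cand] <= cut
    if (any(keep)) cand <- cand[keep, , drop = FALSE]
    else warnf("all background-seed candidates look vessel-like; keeping them unvetoed")
  }
  if (nrow(cand) == 0L)
    stopf("seeding error: %d foreground seeds but no background seed could be placed",
          sum(seeds == SEED_FG))
  seeds[cand] <- SEED_BG
  seeds
}

#' Solve the random-walker Dirichlet problem
#'
#' Probabilities are fixed to 1 at foreground seeds and 0 at background
#' seeds; at unlabeled nodes they minimize the combinatorial Dirichlet energy
#' `E(u) = 1/2 * sum w_ij (u_i - u_j)^2`, i.e. solve the reduced sparse
#' linear system of the lattice Laplacian. The system is solved exactly by
#' sparse Cholesky factorization. Unlabeled FOV components that contain no
#' seed are assigned probability 0 with a warning.
#'
#' @param lat `pixel_lattice` from [build_lattice()].
#' @param seeds integer seed matrix (see [seed_labels]); seeds outside the
#'   FOV are ignored.
#' @param tol solver tolerance retained in the interface for compatibility
#'   with iterative solvers; the direct solve is exact to machine precision.
#' @return matrix of foreground probabilities in `[0, 1]` (0 outside the
#'   FOV), of class `probability_map`.
#' @export
solve_probabilities <- function(lat, seeds, tol = 1e-8) {
  if (!inherits(lat, "pixel_lattice")) stopf("lat must be a pixel_lattice")
  check_same_shape(lat$index, seeds, "lattice and seed map")
  n <- lat$n
  node_lab <- integer(n)
  in_graph <- lat$index > 0L
  node_lab[lat$index[in_graph & seeds == SEED_FG]] <- 1L
  node_lab[lat$index[in_graph & seeds == SEED_BG]] <- 2L
  if (!any(node_lab == 1L)) stopf("seeding error: no foreground seed inside the lattice")
  if (!any(node_lab == 2L)) stopf("seeding error: no background seed inside the lattice")

  # FOV components without any seed have a singular reduced system
  comp <- label_components(lat$fov, connectivity = 8L)
  node_comp <- comp[in_graph][order(lat$index[in_graph])]
  seeded_comps <- unique(node_comp[node_lab > 0L])
  orphan <- !(node_comp %in% seeded_comps)
  if (any(orphan))
    warnf("%d lattice nodes lie in FOV components without seeds; assigned probability 0",
          sum(orphan))

  u <- numeric(n)
  u[node_lab == 1L] <- 1
  unl <- which(node_lab == 0L & !orphan)
  if (length(unl)) {
    e <- lat$edges
    Wm <- Matrix::sparseMatrix(i = c(e$i, e$j), j = c(e$j, e$i),
                               x = c(e$w, e$w), dims = c(n, n))
    dg <- Matrix::rowSums(Wm)
    L <- Matrix::Diagonal(n, dg) - Wm
    lab_nodes <- which(node_lab > 0L)
    rhs <- -L[unl, lab_nodes, drop = FALSE] %*% u[lab_nodes]
    Luu <- Matrix::forceSymmetric(L[unl, unl, drop = FALSE])
    x <- tryCatch(as.numeric(Matrix::solve(Luu, rhs)),
                  error = function(e2) stopf("random-walker system solve failed: %s",
                                             conditionMessage(e2)))
    u[unl] <- x
  }
  prob <- matrix(0, nrow(lat$index), ncol(lat$index))
  prob[in_graph] <- u[lat$index[in_graph]]
  prob <- clamp01(prob)
  class(prob) <- c("probability_map", class(prob))
  prob
}

#' Binarize a probability map
#'
#' A pixel is vessel when its foreground probability is at least as large as
#' its background probability, i.e. `u >= 0.5` in the two-label case (ties
#' labeled vessel).
#'
#' @param prob probability matrix in `[0, 1]`.
#' @return logical matrix, `TRUE` = vessel.
#' @export
binarize <- function(prob) {
  unclass(prob) >= 0.5
}
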