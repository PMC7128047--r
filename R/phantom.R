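# Synthetic fundus phantoms with exact ground truth. A phantom is a brighter
# shaded background inside a circular field of view, carrying dark
# Gaussian-profile vessel polylines (full widths 2-12 px), optional bright
# lesion-like blobs, and additive Gaussian noise. The generator returns the
# exact vessel mask, axis centerlines, FOV disc and axis distance map, so
# every pipeline stage can be tested without any retinal dataset.

#' Describe one vessel branch
#'
#' @param points n x 2 matrix of (row, col) polyline vertices.
#' @param half_width half-width in pixels (1--6; full widths 2--12).
#' @param depth intensity drop at the axis on the `[0, 1]` scale. The
#'   default follows Beer-Lambert absorption through the blood column:
#'   `0.35 * (1 - exp(-width / 4))`, saturating for large calibers and
#'   leaving capillary-scale vessels faint, as in real fundus photographs.
#' @return a `vessel_branch` list.
#' @export
vessel_branch <- function(points, half_width = 3,
                          depth = 0.35 * (1 - exp(-2 * half_width / 4))) {
  points <- matrix(as.numeric(points), ncol = 2L)
  if (nrow(points) < 2L) stopf("a vessel branch needs at least 2 points")
  if (half_width < 1 || half_width > 6)
    stopf("half_width must lie in [1, 6] px (full widths 2-12), got %g", half_width)
  structure(list(points = points, half_width = half_width, depth = depth),
            class = "vessel_branch")
}

#' Specify a synthetic fundus phantom
#'
#' @param size image size `c(H, W)`.
#' @param vessels list of [vessel_branch()] objects.
#' @param background background intensity inside the FOV.
#' @param shading_amp amplitude of the smooth background shading.
#' @param profile vessel cross-profile: `"gaussian"` (full width read as
#'   the FWHM of the profile, the standard caliber convention) or `"flat"`.
#' @param noise_sd per-pixel standard deviation of the additive noise.
#' @param noise_psf standard deviation (px) of the Gaussian point-spread
#'   function applied to the noise field: photographic grain digitized
#'   through a band-limited optical system is spatially correlated, and
#'   unfiltered single-pixel noise would be an artifact no scanner
#'   produces. Set to 0 for white noise.
#' @param lesions list with `n`, `radius` (range, px) and `brightness` of
#'   bright lesion-like blobs; `n = 0` disables them.
#' @param fov_radius_frac FOV disc radius as a fraction of `min(H, W)`.
#' @param seed RNG seed; a fixed seed makes the phantom bit-reproducible.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(size = c(160L, 160L), vessels = list(),
                         background = 0.72, shading_amp = 0.05,
                         profile = c("gaussian", "flat"), noise_sd = 0.02,
                         noise_psf = 0.8,
                         lesions = list(n = 0L, radius = c(4, 7), brightness = 0.18),
                         fov_radius_frac = 0.46, seed = 1L) {
  profile <- match.arg(profile)
  if (length(size) != 2L || any(size < 32L)) stopf("size must be c(H, W) with H, W >= 32")
  structure(list(size = as.integer(size), vessels = vessels,
                 background = background, shading_amp = shading_amp,
                 profile = profile, noise_sd = noise_sd,
                 noise_psf = noise_psf, lesions = lesions,
                 fov_radius_frac = fov_radius_frac, seed = as.integer(seed)),
            class = "phantom_spec")
}

# Distance from every pixel to a polyline (min over segments); (row, col).
polyline_distance <- function(H, W, points) {
  rr <- matrix(seq_len(H), H, W)
  cc <- matrix(seq_len(W), H, W, byrow = TRUE)
  d2 <- matrix(Inf, H, W)
  for (k in seq_len(nrow(points) - 1L)) {
    p1 <- points[k, ]; p2 <- points[k + 1L, ]
    v <- p2 - p1
    len2 <- sum(v^2)
    if (len2 == 0) {
      d2 <- pmin(d2, (rr - p1[1L])^2 + (cc - p1[2L])^2)
      next
    }
    t <- ((rr - p1[1L]) * v[1L] + (cc - p1[2L]) * v[2L]) / len2
    t <- pmin(pmax(t, 0), 1)
    d2 <- pmin(d2, (rr - (p1[1L] + t * v[1L]))^2 + (cc - (p1[2L] + t * v[2L]))^2)
  }
  sqrt(d2)
}

bresenham_line <- function(r1, c1, r2, c2) {
  dr <- abs(r2 - r1); dc <- abs(c2 - c1)
  sr <- if (r1 < r2) 1L else -1L
  sc <- if (c1 < c2) 1L else -1L
  err <- dc - dr
  out <- matrix(0L, dr + dc + 1L, 2L)
  n <- 0L
  repeat {
    n <- n + 1L
    out[n, ] <- c(r1, c1)
    if (r1 == r2 && c1 == c2) break
    e2 <- 2L * err
    if (e2 > -dr) { err <- err - dr; c1 <- c1 + sc }
    if (e2 < dc) { err <- err + dc; r1 <- r1 + sr }
  }
  out[seq_len(n), , drop = FALSE]
}

#' Generate a synthetic fundus phantom
#'
#' Renders the phantom described by a [phantom_spec()] and returns it with
#' its exact ground truth.
#'
#' @param spec a `phantom_spec`.
#' @return object of class `phantom_bundle`: list with `image` (the
#'   grayscale/green plane), `rgb` (H x W x 3 array whose green channel is
#'   `image`), `vessel_mask`, `axis_mask`, `axis_distance` (distance to the
#'   nearest true axis, px), `lesion_mask`, `fov`, and `spec`.
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) stopf("spec must be a phantom_spec")
  H <- spec$size[1L]; W <- spec$size[2L]
  ctr <- c((H + 1) / 2, (W + 1) / 2)
  radius <- spec$fov_radius_frac * min(H, W)
  rr <- matrix(seq_len(H), H, W)
  cc <- matrix(seq_len(W), H, W, byrow = TRUE)
  fov <- (rr - ctr[1L])^2 + (cc - ctr[2L])^2 <= radius^2

  # validate: every vessel fits inside the FOV disc
  for (vb in spec$vessels) {
    dctr <- sqrt((vb$points[, 1L] - ctr[1L])^2 + (vb$points[, 2L] - ctr[2L])^2)
    if (any(dctr + vb$half_width + 1 > radius))
      stopf("phantom spec error: a vessel extends outside the FOV disc")
  }

  with_seed(spec$seed, {
    img <- matrix(spec$background, H, W)
    if (spec$shading_amp > 0) {
      sh <- gaussian_smooth(matrix(stats::rnorm(H * W), H, W), min(H, W) / 8)
      sh <- sh - mean(sh)
      m <- max(abs(sh))
      if (m > 0) img <- img + sh / m * spec$shading_amp
    }

    vessel_mask <- matrix(FALSE, H, W)
    axis_mask <- matrix(FALSE, H, W)
    axis_distance <- matrix(Inf, H, W)
    drop <- matrix(0, H, W)
    for (vb in spec$vessels) {
      d <- polyline_distance(H, W, vb$points)
      axis_distance <- pmin(axis_distance, d)
      hw <- vb$half_width
      if (spec$profile == "gaussian") {
        # width read as FWHM, the standard caliber measure in fundus
        # imaging: the truth mask edge sits at the half-depth point
        prof_sd <- 2 * hw / 2.355
        drop <- pmax(drop, vb$depth * exp(-d^2 / (2 * prof_sd^2)))
      } else {
        drop <- pmax(drop, vb$depth * (d <= hw))
      }
      vessel_mask <- vessel_mask | d <= hw
      pts <- round(vb$points)
      for (k in seq_len(nrow(pts) - 1L)) {
        ax <- bresenham_line(pts[k, 1L], pts[k, 2L], pts[k + 1L, 1L], pts[k + 1L, 2L])
        axis_mask[ax] <- TRUE
      }
    }
    # overlapping branches attenuate like the deepest local blood column,
    # not additively: summed profiles would render joints as dark blobs
    img <- img - drop
    dim(axis_distance) <- dim(vessel_mask) <- dim(axis_mask) <- c(H, W)

    lesion_mask <- matrix(FALSE, H, W)
    n_les <- spec$lesions$n
    if (n_les > 0L) {
      placed <- 0L; tries <- 0L
      while (placed < n_les && tries < 200L) {
        tries <- tries + 1L
        rad <- stats::runif(1, spec$lesions$radius[1L], spec$lesions$radius[2L])
        ang <- stats::runif(1, 0, 2 * pi)
        rho <- stats::runif(1, 0, radius - rad - 3)
        pr <- ctr[1L] + rho * sin(ang)
        pc <- ctr[2L] + rho * cos(ang)
        dles <- sqrt((rr - pr)^2 + (cc - pc)^2)
        if (any(vessel_mask[dles <= rad + 3])) next  # keep lesions off the vessels
        img <- img + spec$lesions$brightness * exp(-dles^2 / (2 * (rad / 2)^2))
        lesion_mask <- lesion_mask | dles <= rad
        placed <- placed + 1L
      }
      if (placed < n_les)
        warnf("placed only %d of %d lesions without touching vessels", placed, n_les)
    }

    if (spec$noise_sd > 0) {
      nz <- matrix(stats::rnorm(H * W), H, W)
      psf <- if (is.null(spec$noise_psf)) 0 else spec$noise_psf
      if (psf > 0) nz <- gaussian_smooth(nz, psf)
      img <- img + nz * (spec$noise_sd / stats::sd(nz))
    }
    img[!fov] <- 0.02
    img <- clamp01(img)

    rgb <- array(0, dim = c(H, W, 3L))
    rgb[, , 1L] <- ifelse(fov, clamp01(0.5 + 0.45 * img), 0.02)
    rgb[, , 2L] <- img
    rgb[, , 3L] <- 0.3 * img

    structure(list(image = img, rgb = rgb,
                   vessel_mask = vessel_mask & fov,
                   axis_mask = axis_mask & fov,
                   axis_distance = axis_distance,
                   lesion_mask = lesion_mask & fov,
                   fov = fov, spec = spec),
              class = "phantom_bundle")
  })
}

#' @export
print.phantom_bundle <- function(x, ...) {
  cat(sprintf("phantom: %d x %d, %d vessels, %d vessel px, %d axis px, %d lesion px\n",
              nrow(x$image), ncol(x$image), length(x$spec$vessels),
              sum(x$vessel_mask), sum(x$axis_mask), sum(x$lesion_mask)))
  invisible(x)
}

#' Standard phantom test suite
#'
#' Five fixed phantom specifications exercising the pipeline: (a) a single
#' straight tube; (b) a Y-bifurcation; (c) two near-parallel tubes
#' `3 * r_mid` apart, which must trigger DENSE seed spacing; (d) a curved
#' tube with three bright lesion blobs, probing pathology robustness; (e) a
#' full tree spanning vessel widths 2--12 px.
#'
#' @param seed base RNG seed; each spec derives its own fixed seed from it.
#' @return named list of `phantom_spec` objects (`a` ... `e`).
#' @export
default_test_suite_specs <- function(seed = 101L) {
  seed <- as.integer(seed)
  list(
    a = phantom_spec(
      vessels = list(vessel_branch(rbind(c(80, 22), c(80, 139)), half_width = 3)),
      seed = seed),
    b = phantom_spec(
      vessels = list(
        vessel_branch(rbind(c(138, 80), c(88, 80)), half_width = 4),
        vessel_branch(rbind(c(88, 80), c(36, 46)), half_width = 3),
        vessel_branch(rbind(c(88, 80), c(36, 114)), half_width = 3)),
      seed = seed + 1L),
    c = phantom_spec(
      vessels = list(
        vessel_branch(rbind(c(70, 25), c(70, 136)), half_width = 2),
        vessel_branch(rbind(c(91, 25), c(91, 136)), half_width = 2)),
      seed = seed + 2L),
    d = phantom_spec(
      vessels = list(
        vessel_branch(rbind(c(125, 35), c(100, 70), c(80, 95), c(70, 125)),
                      half_width = 3)),
      lesions = list(n = 3L, radius = c(4, 7), brightness = 0.18),
      seed = seed + 3L),
    # tapering trunk entering near the rim, as a retinal trunk tapers away
    # from the optic disc; calibers span the full 2-12 px width range
    e = phantom_spec(
      vessels = list(
        vessel_branch(rbind(c(145, 70), c(120, 78)), half_width = 6),
        vessel_branch(rbind(c(120, 78), c(95, 85)), half_width = 5),
        vessel_branch(rbind(c(95, 85), c(72, 88)), half_width = 4),
        vessel_branch(rbind(c(95, 85), c(60, 55), c(32, 60)), half_width = 3),
        vessel_branch(rbind(c(72, 88), c(45, 112), c(28, 100)), half_width = 2),
        vessel_branch(rbind(c(120, 78), c(100, 50), c(75, 40)), half_width = 1)),
      seed = seed + 4L)
  )
}

#' Write a phantom to disk
#'
#' Writes the RGB image, all ground-truth masks as 8-bit PNGs, and a JSON
#' sidecar describing the spec and the file names.
#'
#' @param bundle `phantom_bundle`.
#' @param dir output directory (created if missing).
#' @param stem file-name stem.
#' @return named vector of the written paths, invisibly.
#' @export
write_phantom <- function(bundle, dir, stem = "phantom") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(image = file.path(dir, paste0(stem, ".png")),
             vessel_mask = file.path(dir, paste0(stem, "_vessels.png")),
             axis_mask = file.path(dir, paste0(stem, "_axis.png")),
             fov = file.path(dir, paste0(stem, "_fov.png")),
             spec = file.path(dir, paste0(stem, ".json")))
  write_rgb_png(bundle$rgb, paths[["image"]])
  write_mask_png(bundle$vessel_mask, paths[["vessel_mask"]])
  write_mask_png(bundle$axis_mask, paths[["axis_mask"]])
  write_mask_png(bundle$fov, paths[["fov"]])
  spec <- bundle$spec
  spec_json <- list(size = spec$size, background = spec$background,
                    shading_amp = spec$shading_amp, profile = spec$profile,
                    noise_sd = spec$noise_sd, noise_psf = spec$noise_psf,
                    lesions = spec$lesions,
                    fov_radius_frac = spec$fov_radius_frac, seed = spec$seed,
                    vessels = lapply(spec$vessels, function(vb)
                      list(points = vb$points, half_width = vb$half_width,
                           depth = vb$depth)),
                    files = as.list(paths[1:4]))
  jsonlite::write_json(spec_json, paths[["spec"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
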