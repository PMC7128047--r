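# Internal numerical helpers shared by all stages.

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

clamp01 <- function(x) pmin(pmax(x, 0), 1)

as_gray_matrix <- function(x) {
  if (inherits(x, "Image")) x <- EBImage::imageData(x)
  if (!is.matrix(x)) stopf("expected a 2-D image matrix, got %s", class(x)[1])
  storage.mode(x) <- "double"
  x
}

as_mask <- function(x) {
  if (inherits(x, "Image")) x <- EBImage::imageData(x)
  if (!is.matrix(x)) stopf("expected a 2-D mask matrix, got %s", class(x)[1])
  x != 0
}

check_same_shape <- function(a, b, what = "inputs") {
  if (!identical(dim(a)[1:2], dim(b)[1:2]))
    stopf("%s must share the same H x W shape (%s vs %s)", what,
          paste(dim(a)[1:2], collapse = "x"), paste(dim(b)[1:2], collapse = "x"))
  invisible(TRUE)
}

# Sampled Gaussian and its analytic derivatives, normalized so that discrete
# convolution is exact on polynomials: order 0 sums to 1, order 1 responds with
# slope 1 to a unit ramp, order 2 responds with 2 to x^2.
gaussian_kernel_1d <- function(sigma, order = 0L) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma <= 0)
    stopf("sigma must be a single positive number (got %s)", format(sigma))
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  t <- seq.int(-r, r)
  g <- exp(-t^2 / (2 * sigma^2))
  if (order == 0L) return(g / sum(g))
  if (order == 1L) {
    k <- -t * g
    return(k / sum(-t * k))
  }
  if (order == 2L) {
    k <- (t^2 - sigma^2) * g
    k <- k - mean(k)
    return(k * (2 / sum(k * t^2)))
  }
  stopf("unsupported derivative order %d", order)
}

# Reflective (mirror, no edge repeat) padding.
pad_reflect <- function(x, ry, rx) {
  H <- nrow(x); W <- ncol(x)
  if (ry >= H || rx >= W)
    stopf("kernel radius (%d, %d) too large for a %d x %d image", ry, rx, H, W)
  ri <- c(if (ry > 0) seq.int(ry + 1L, 2L) else integer(), seq_len(H),
          if (ry > 0) seq.int(H - 1L, H - ry) else integer())
  ci <- c(if (rx > 0) seq.int(rx + 1L, 2L) else integer(), seq_len(W),
          if (rx > 0) seq.int(W - 1L, W - rx) else integer())
  x[ri, ci, drop = FALSE]
}

# Separable 2-D convolution with reflective boundary handling; ky acts along
# rows (the y/vertical axis), kx along columns (x/horizontal). The FFT product
# is delegated to EBImage::filter2 on the padded image.
conv2_sep <- function(x, ky, kx) {
  x <- as_gray_matrix(x)
  ry <- (length(ky) - 1L) %/% 2L
  rx <- (length(kx) - 1L) %/% 2L
  xp <- pad_reflect(x, ry, rx)
  yp <- EBImage::filter2(xp, outer(ky, kx), boundary = "circular")
  yp <- as_gray_matrix(yp)
  yp[seq.int(ry + 1L, ry + nrow(x)), seq.int(rx + 1L, rx + ncol(x)), drop = FALSE]
}

# Central differences (one-sided at the borders); x = columns, y = rows.
cdiff_x <- function(m) {
  W <- ncol(m)
  out <- matrix(0, nrow(m), W)
  if (W >= 3L) out[, 2:(W - 1L)] <- (m[, 3:W] - m[, 1:(W - 2L)]) / 2
  if (W >= 2L) {
    out[, 1L] <- m[, 2L] - m[, 1L]
    out[, W] <- m[, W] - m[, W - 1L]
  }
  out
}

cdiff_y <- function(m) {
  H <- nrow(m)
  out <- matrix(0, H, ncol(m))
  if (H >= 3L) out[2:(H - 1L), ] <- (m[3:H, ] - m[1:(H - 2L), ]) / 2
  if (H >= 2L) {
    out[1L, ] <- m[2L, ] - m[1L, ]
    out[H, ] <- m[H, ] - m[H - 1L, ]
  }
  out
}

#' Label connected components of a binary mask
#'
#' Flood-fill labeling of the `TRUE` pixels of a mask, under 4- or
#' 8-connectivity. Labels are positive integers in discovery order (column
#' major); background pixels are 0.
#'
#' @param mask logical (or 0/1) matrix.
#' @param connectivity 4 or 8.
#' @return integer matrix of the same shape with component labels.
#' @export
label_components <- function(mask, connectivity = 8L) {
  mask <- as_mask(mask)
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(4L, 8L)) stopf("connectivity must be 4 or 8")
  H <- nrow(mask); W <- ncol(mask)
  Hp <- H + 2L
  mp <- matrix(FALSE, Hp, W + 2L)
  mp[2:(H + 1L), 2:(W + 1L)] <- mask
  labp <- matrix(0L, Hp, W + 2L)
  off <- if (connectivity == 8L)
    c(-1L, 1L, -Hp, Hp, -Hp - 1L, -Hp + 1L, Hp - 1L, Hp + 1L)
  else c(-1L, 1L, -Hp, Hp)
  todo <- which(mp)
  lab_id <- 0L
  while (length(todo)) {
    seed_px <- todo[1L]
    lab_id <- lab_id + 1L
    mp[seed_px] <- FALSE
    labp[seed_px] <- lab_id
    frontier <- seed_px
    while (length(frontier)) {
      nb <- as.vector(outer(frontier, off, `+`))
      nb <- unique(nb[mp[nb]])
      if (!length(nb)) break
      mp[nb] <- FALSE
      labp[nb] <- lab_id
      frontier <- nb
    }
    todo <- todo[mp[todo]]
  }
  labp[2:(H + 1L), 2:(W + 1L), drop = FALSE]
}

count_components <- function(mask, connectivity = 8L) {
  max(label_components(mask, connectivity))
}

# Keep only components with at least min_size pixels.
drop_small_components <- function(mask, min_size, connectivity = 8L) {
  mask <- as_mask(mask)
  if (min_size <= 1L || !any(mask)) return(mask)
  lab <- label_components(mask, connectivity)
  sz <- tabulate(lab)
  keep <- lab > 0L & sz[pmax(lab, 1L)] >= min_size
  dim(keep) <- dim(mask)
  keep
}

largest_component <- function(mask, connectivity = 4L) {
  mask <- as_mask(mask)
  if (!any(mask)) return(mask)
  lab <- label_components(mask, connectivity)
  sz <- tabulate(lab)
  out <- lab == which.max(sz)
  dim(out) <- dim(mask)
  out
}

# Disc-shaped structuring element of a given pixel radius (odd-sized brush).
disc_se <- function(radius) {
  radius <- as.integer(radius)
  if (radius < 1L) stopf("structuring-element radius must be >= 1")
  EBImage::makeBrush(2L * radius + 1L, shape = "disc")
}

# 1-px-wide linear structuring element of `length` pixels at angle `angle`
# (radians, measured from the x axis). Even lengths are anchored just off
# center, as is inherent to even-sized flat elements.
line_se <- function(length, angle) {
  length <- as.integer(length)
  if (length < 1L) stopf("structuring-element length must be >= 1")
  t <- seq.int(0L, length - 1L) - (length - 1L) %/% 2L
  xs <- round(t * cos(angle))
  ys <- round(t * sin(angle))
  rx <- max(abs(xs), 1L)
  ry <- max(abs(ys), 1L)
  se <- matrix(0L, 2L * ry + 1L, 2L * rx + 1L)
  se[cbind(ys + ry + 1L, xs + rx + 1L)] <- 1L
  se
}

# Offsets (dr, dc) of the nonzero entries of a structuring element relative
# to its center pixel.
se_offsets <- function(se) {
  pts <- which(se != 0, arr.ind = TRUE)
  cbind(pts[, 1L] - (nrow(se) + 1L) %/% 2L,
        pts[, 2L] - (ncol(se) + 1L) %/% 2L)
}

# Flat grayscale dilation / erosion / closing by explicit max/min over the
# structuring-element offsets (exact for the small linear elements used by
# the bottom-hat transform). Outside-image samples act as -Inf (dilation)
# and +Inf (erosion), the standard flat-morphology border convention.
flat_dilate <- function(img, off) {
  H <- nrow(img); W <- ncol(img)
  out <- matrix(-Inf, H, W)
  for (k in seq_len(nrow(off))) {
    dr <- off[k, 1L]; dc <- off[k, 2L]
    pr <- max(1L, 1L + dr):min(H, H + dr)
    pc <- max(1L, 1L + dc):min(W, W + dc)
    out[pr, pc] <- pmax(out[pr, pc], img[pr - dr, pc - dc])
  }
  out
}

flat_erode <- function(img, off) {
  H <- nrow(img); W <- ncol(img)
  out <- matrix(Inf, H, W)
  for (k in seq_len(nrow(off))) {
    dr <- off[k, 1L]; dc <- off[k, 2L]
    pr <- max(1L, 1L - dr):min(H, H - dr)
    pc <- max(1L, 1L - dc):min(W, W - dc)
    out[pr, pc] <- pmin(out[pr, pc], img[pr + dr, pc + dc])
  }
  out
}

flat_close <- function(img, se) {
  off <- se_offsets(se)
  flat_erode(flat_dilate(img, off), off)
}

# Run code under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
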