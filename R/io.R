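# Image loading, green-channel extraction, and the field-of-view mask.
# Convention used throughout the package: images are H x W matrices indexed
# [row, col], row 1 at the top; x denotes the column (horizontal) axis and y
# the row (vertical) axis. Intensities are normalized to [0, 1] at load time
# and every downstream parameter is interpreted on that scale.

# Binary PPM (P6) / PGM (P5) reader, returned in x-first (width, height[,
# channel]) orientation to match EBImage::imageData. Values scaled by the
# header's maxval.
read_pnm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 2L))
  if (!magic %in% c("P5", "P6"))
    stopf("cannot read image '%s': unsupported PNM magic '%s' (binary P5/P6 only)",
          path, magic)
  fields <- integer(0)
  while (length(fields) < 3L) {
    ch <- rawToChar(readBin(con, "raw", 1L))
    if (ch == "#") {
      repeat {
        ch <- rawToChar(readBin(con, "raw", 1L))
        if (ch %in% c("\n", "\r") || !length(ch)) break
      }
    } else if (grepl("[0-9]", ch)) {
      tok <- ch
      repeat {
        ch <- rawToChar(readBin(con, "raw", 1L))
        if (!grepl("[0-9]", ch)) break
        tok <- paste0(tok, ch)
      }
      fields <- c(fields, as.integer(tok))
    }
  }
  W <- fields[1L]; H <- fields[2L]; maxval <- fields[3L]
  if (W < 1L || H < 1L) stopf("image '%s' is zero-sized", path)
  nch <- if (magic == "P6") 3L else 1L
  n <- W * H * nch
  vals <- if (maxval > 255L)
    readBin(con, "integer", n, size = 2L, signed = FALSE, endian = "big")
  else as.integer(readBin(con, "raw", n))
  if (length(vals) < n) stopf("cannot read image '%s': truncated pixel data", path)
  if (nch == 3L) {
    aperm(array(vals / maxval, dim = c(3L, W, H)), c(2L, 3L, 1L))
  } else {
    matrix(vals / maxval, nrow = W, ncol = H)
  }
}

#' Load a fundus photograph as an RGB array
#'
#' Reads a PNG/TIFF/PPM/JPEG file and returns an `H x W x 3` numeric array
#' with intensities in `[0, 1]`, rows indexing the image rows. Grayscale
#' files are replicated to three channels with a warning; an alpha channel,
#' if present, is dropped.
#'
#' @param path path to an image file.
#' @return numeric `H x W x 3` array in `[0, 1]`.
#' @seealso [green_channel()], [compute_fov_mask()]
#' @export
load_image <- function(path) {
  if (!is.character(path) || length(path) != 1L)
    stopf("path must be a single file path")
  if (!file.exists(path)) stopf("cannot read image: no such file '%s'", path)
  if (grepl("\\.(ppm|pgm)$", path, ignore.case = TRUE)) {
    px <- read_pnm(path)   # binary PPM/PGM (the STARE distribution format)
  } else {
    img <- tryCatch(EBImage::readImage(path),
                    error = function(e) stopf("cannot read image '%s': %s", path, conditionMessage(e)))
    px <- EBImage::imageData(img)
  }
  if (length(px) == 0L) stopf("image '%s' is zero-sized", path)
  if (is.matrix(px)) {
    warnf("'%s' is grayscale; replicating to 3 channels", path)
    px <- array(px, dim = c(dim(px), 3L))
  }
  if (length(dim(px)) != 3L) stopf("image '%s' has unsupported dimensions", path)
  if (dim(px)[3L] > 3L) px <- px[, , 1:3, drop = FALSE]
  if (dim(px)[3L] == 1L) {
    warnf("'%s' has a single channel; replicating to 3 channels", path)
    px <- array(px[, , 1L], dim = c(dim(px)[1:2], 3L))
  }
  if (dim(px)[3L] == 2L) stopf("image '%s' has 2 channels; expected 1, 3 or 4", path)
  # EBImage stores x (width) first; transpose to [row, col, channel]
  px <- aperm(px, c(2L, 1L, 3L))
  if (max(px) > 1) px <- px / 255
  storage.mode(px) <- "double"
  clamp01(px)
}

#' Extract the normalized green channel
#'
#' The green channel carries the best vessel/background contrast in fundus
#' photography and is the working image of the whole pipeline.
#'
#' @param img `H x W x 3` array (values in `[0, 1]` or 0--255 integers).
#' @return `H x W` matrix in `[0, 1]`.
#' @export
green_channel <- function(img) {
  if (is.matrix(img)) stopf("green_channel expects an RGB array, not a matrix")
  if (length(dim(img)) != 3L || dim(img)[3L] < 2L)
    stopf("green_channel expects an H x W x 3 array")
  g <- img[, , 2L]
  if (max(g) > 1) g <- g / 255
  clamp01(g)
}

#' Compute the circular field-of-view mask
#'
#' The camera aperture is recovered by thresholding the red channel at a
#' fraction of its maximum, keeping the largest 4-connected component,
#' opening with a small disc and filling holes. All later computation and
#' evaluation is restricted to this mask.
#'
#' @param img `H x W x 3` RGB array; a plain matrix is accepted and used
#'   directly as the thresholding channel.
#' @param low_frac threshold as a fraction of the red-channel maximum.
#' @param open_radius radius (px) of the disc used for morphological opening.
#' @return logical `H x W` matrix, `TRUE` inside the field of view.
#' @export
compute_fov_mask <- function(img, low_frac = 0.15, open_radius = 3L) {
  red <- if (is.matrix(img)) as_gray_matrix(img) else {
    if (length(dim(img)) != 3L) stopf("compute_fov_mask expects an RGB array or matrix")
    img[, , 1L]
  }
  if (max(red) <= 0) stopf("degenerate input: image is entirely black; cannot locate a field of view")
  b <- red > low_frac * max(red)
  if (!any(b))
    stopf("degenerate input: empty FOV mask; try a lower low_frac than %g", low_frac)
  b <- largest_component(b, connectivity = 4L)
  if (open_radius >= 1L) {
    b <- EBImage::opening(b * 1, disc_se(open_radius)) > 0.5
  }
  b <- as_mask(EBImage::fillHull(b * 1))
  if (!any(b))
    stopf("degenerate input: FOV mask empty after opening; try a lower low_frac than %g", low_frac)
  b
}

#' Replace outside-FOV pixels by the mean in-FOV intensity
#'
#' Filling the region outside the camera aperture with the mean interior
#' value suppresses the strong artificial intensity step at the aperture rim,
#' which would otherwise dominate derivative filters and the bottom-hat
#' transform near the boundary.
#'
#' @param img grayscale matrix.
#' @param fov logical FOV mask.
#' @param value fill value; defaults to the mean intensity inside the mask.
#' @return grayscale matrix with outside-FOV pixels replaced.
#' @export
fill_outside_fov <- function(img, fov, value = NULL) {
  img <- as_gray_matrix(img)
  fov <- as_mask(fov)
  check_same_shape(img, fov, "image and FOV mask")
  if (!any(fov)) stopf("FOV mask has no interior pixels")
  if (is.null(value)) value <- mean(img[fov])
  img[!fov] <- value
  img
}

#' Write a binary mask as an 8-bit PNG
#'
#' @param mask logical matrix.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  mask <- as_mask(mask)
  EBImage::writeImage(EBImage::Image(t(mask * 1)), path, type = "png", bits = 8)
  invisible(path)
}

#' Read a binary mask from an image file
#'
#' Pixels above 0.5 are `TRUE`.
#'
#' @param path image path.
#' @return logical matrix.
#' @export
read_mask_png <- function(path) {
  if (!file.exists(path)) stopf("cannot read mask: no such file '%s'", path)
  px <- EBImage::imageData(EBImage::readImage(path))
  if (length(dim(px)) == 3L) px <- px[, , 1L]
  t(px) > 0.5
}

#' Write a grayscale image as a PNG
#'
#' Values are clipped to `[0, 1]` and quantized to the writer's 8-bit
#' depth; use [write_array_tsv()] for a lossless dump of a float map.
#'
#' @param img grayscale matrix.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_gray_png <- function(img, path) {
  img <- clamp01(as_gray_matrix(img))
  EBImage::writeImage(EBImage::Image(t(img)), path, type = "png")
  invisible(path)
}

#' Write / read a numeric matrix as tab-separated text
#'
#' Lossless plain-text serialization for float-valued maps such as
#' vesselness responses and walker probabilities.
#'
#' @param m numeric matrix.
#' @param path file path.
#' @return `write_array_tsv` returns the path invisibly; `read_array_tsv`
#'   returns the matrix.
#' @export
write_array_tsv <- function(m, path) {
  utils::write.table(format(as_gray_matrix(m), digits = 17, trim = TRUE),
                     path, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_array_tsv
#' @export
read_array_tsv <- function(path) {
  as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
}

#' Write an RGB array as a PNG
#'
#' @param img `H x W x 3` array in `[0, 1]`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_rgb_png <- function(img, path) {
  if (length(dim(img)) != 3L) stopf("expected an H x W x 3 array")
  px <- aperm(clamp01(img), c(2L, 1L, 3L))
  EBImage::writeImage(EBImage::Image(px, colormode = "Color"), path, type = "png", bits = 8)
  invisible(path)
}
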