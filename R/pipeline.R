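# End-to-end pipeline: FOV -> vesselness -> centerlines -> random walker
# (-> evaluation), with optional intermediate artifacts and a JSON manifest.

#' Pipeline configuration
#'
#' All tunable parameters of the pipeline with their defaults: scales
#' `sigma = 0.2 m (m = 1..25)`, rotation angles `theta = n pi/8 (n = 0..7)`,
#' vesselness contrast `c = 0.2`, divergence threshold `phi = 0.45`, minimum
#' candidate component `delta = 50` px, bottom-hat element lengths 2--12
#' step 2 and orientations 0--7pi/8 step pi/8, centerline region overlap
#' 0.40, minimum centerline length 50 px, vessel radii
#' `r_min = 2`, `r_max = 12`, `r_mid = (r_min + r_max)/2 = 7`, walker weight
#' `beta = 90`, solver tolerance 1e-8.
#'
#' @param sigmas Gaussian scale grid (px).
#' @param thetas rotation angles (rad) for the divergence detector.
#' @param c vesselness contrast-sensitivity parameter.
#' @param phi divergence threshold.
#' @param delta minimum candidate component size (px).
#' @param se_lengths bottom-hat element lengths (px).
#' @param se_angles bottom-hat element orientations (rad).
#' @param overlap_frac centerline region overlap fraction.
#' @param min_length minimum final centerline component (px).
#' @param r_min,r_max,r_mid minimum / maximum / mid vessel radius (px).
#' @param beta random-walker edge weight parameter.
#' @param solver_tol random-walker solver tolerance.
#' @param exponent_form vesselness anisotropy factor, see
#'   [vesselness_at_scale()].
#' @param scale_normalize multiply Hessian entries by `sigma^2`?
#' @param eigen_ordering eigenvalue ordering, see [eigen_decompose()].
#' @param fov_low_frac,fov_open_radius FOV mask parameters, see
#'   [compute_fov_mask()].
#' @param eps magnitude floor for gradient-field normalization.
#' @param otsu_nbins histogram bins for [otsu_threshold()].
#' @param divergence_form divergence score for the candidate detector, see
#'   [candidate_centerlines()].
#' @param seed RNG seed recorded in manifests (the pipeline itself is
#'   deterministic).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(sigmas = default_scales(),
                            thetas = pi / 8 * (0:7),
                            c = 0.2, phi = 0.45, delta = 50L,
                            se_lengths = seq(2L, 12L, by = 2L),
                            se_angles = pi / 8 * (0:7),
                            overlap_frac = 0.40, min_length = 50L,
                            r_min = 2L, r_max = 12L,
                            r_mid = as.integer((r_min + r_max) / 2),
                            beta = 90, solver_tol = 1e-8,
                            exponent_form = c("anisotropy", "inverse"),
                            scale_normalize = TRUE,
                            eigen_ordering = c("signed", "magnitude"),
                            fov_low_frac = 0.15, fov_open_radius = 3L,
                            eps = 1e-8, otsu_nbins = 256L,
                            divergence_form = c("directional", "rotated"),
                            seed = 1L) {
  structure(list(sigmas = sigmas, thetas = thetas, c = c, phi = phi,
                 delta = as.integer(delta), se_lengths = as.integer(se_lengths),
                 se_angles = se_angles, overlap_frac = overlap_frac,
                 min_length = as.integer(min_length), r_min = as.integer(r_min),
                 r_max = as.integer(r_max), r_mid = as.integer(r_mid),
                 beta = beta, solver_tol = solver_tol,
                 exponent_form = match.arg(exponent_form),
                 scale_normalize = isTRUE(scale_normalize),
                 eigen_ordering = match.arg(eigen_ordering),
                 fov_low_frac = fov_low_frac,
                 fov_open_radius = as.integer(fov_open_radius),
                 eps = eps, otsu_nbins = as.integer(otsu_nbins),
                 divergence_form = match.arg(divergence_form),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Keys absent from the file keep their defaults.
#'
#' @param path YAML file path.
#' @return `pipeline_config` object.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stopf("config file '%s' not found", path)
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stopf("unknown config keys: %s", paste(bad, collapse = ", "))
  do.call(pipeline_config, vals)
}

#' Write a pipeline configuration to YAML
#'
#' @param config `pipeline_config` object.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15L)
  invisible(path)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat(sprintf(paste0("pipeline config: %d scales in [%g, %g], %d angles, c = %g, ",
                     "phi = %g, delta = %d, beta = %g, r = [%d, %d], r_mid = %d\n"),
              length(x$sigmas), min(x$sigmas), max(x$sigmas), length(x$thetas),
              x$c, x$phi, x$delta, x$beta, x$r_min, x$r_max, x$r_mid))
  invisible(x)
}

config_hash <- function(config) {
  s <- paste(utils::capture.output(utils::str(unclass(config), digits.d = 15)),
             collapse = "\n")
  # small stable rolling hash; avoids external digest dependencies
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run the full segmentation pipeline
#'
#' Executes the four stages -- field-of-view masking, multiscale vesselness
#' enhancement, centerline extraction, and seeded random-walker segmentation
#' -- and, when ground truth is supplied, pixelwise evaluation. Before the
#' filtering stages, pixels outside the FOV are filled with the mean in-FOV
#' intensity to suppress aperture-rim responses.
#'
#' @param input a file path, an `H x W x 3` RGB array, or a
#'   `phantom_bundle` (whose RGB plane and ground truth are used).
#' @param config `pipeline_config`.
#' @param truth optional ground-truth vessel mask (taken from the bundle if
#'   `input` is a phantom).
#' @param output_dir optional directory; when given, all intermediates
#'   (FOV, vesselness, candidate/skeleton/final centerlines, seeds,
#'   probabilities, mask) are written as PNGs together with a JSON manifest.
#' @param save_intermediates write intermediate rasters (when `output_dir`
#'   is given)?
#' @return object of class `vessel_segmentation`: list with `fov`, `green`,
#'   `vesselness`, `c_can`, `c_skel`, `c_final`, `density`, `seeds`, `prob`,
#'   `mask`, `metrics` (or NULL), `dice` (or NULL), `times` (per-stage
#'   seconds), `config`, and `manifest` (or NULL).
#' @export
run_pipeline <- function(input, config = pipeline_config(), truth = NULL,
                         output_dir = NULL, save_intermediates = TRUE) {
  if (!inherits(config, "pipeline_config")) stopf("config must be a pipeline_config")
  times <- c()
  tick <- function(expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- force(expr)
    list(val = val, dt = proc.time()[["elapsed"]] - t0)
  }

  if (inherits(input, "phantom_bundle")) {
    rgb <- input$rgb
    if (is.null(truth)) truth <- input$vessel_mask
    input_name <- sprintf("phantom(seed=%d)", input$spec$seed)
  } else if (is.character(input)) {
    rgb <- load_image(input)
    input_name <- input
  } else if (is.array(input) && length(dim(input)) == 3L) {
    rgb <- input
    input_name <- "<array>"
  } else stopf("input must be a file path, an RGB array or a phantom_bundle")

  st <- tick({
    fov <- compute_fov_mask(rgb, config$fov_low_frac, config$fov_open_radius)
    green <- fill_outside_fov(green_channel(rgb), fov)
    fov
  })
  times["fov"] <- st$dt

  st <- tick(multiscale_vesselness(green, config$sigmas, config$c, fov,
                                   config$scale_normalize, config$exponent_form,
                                   config$eigen_ordering))
  vv <- st$val
  times["vesselness"] <- st$dt

  st <- tick({
    c_can <- candidate_centerlines(green, config$thetas, config$sigmas,
                                   config$phi, config$delta, fov, config$eps,
                                   config$divergence_form)
    ibot <- bottomhat_sum(green, config$se_lengths, config$se_angles)
    ibin <- (ibot > otsu_threshold(ibot[fov], config$otsu_nbins)) & fov
    c_skel <- thin_to_skeleton(ibin)
    c_final <- correct_centerlines(c_skel, c_can, config$overlap_frac,
                                   config$min_length) & fov
    list(c_can = c_can, c_skel = c_skel, c_final = c_final)
  })
  cl <- st$val
  times["centerline"] <- st$dt

  st <- tick({
    density <- classify_density(cl$c_final, config$r_mid)
    seeds <- place_seeds(cl$c_final, vv$eigen, density, fov,
                         config$r_mid, config$r_max, guide = vv)
    lat <- build_lattice(vv, fov, config$beta)
    prob <- solve_probabilities(lat, seeds, config$solver_tol)
    mask <- binarize(prob) & fov
    list(density = density, seeds = seeds, prob = prob, mask = mask)
  })
  rw <- st$val
  times["random_walker"] <- st$dt

  mr <- NULL; dice <- NULL
  if (!is.null(truth)) {
    mr <- metrics(confusion(rw$mask, truth, fov))
    dice <- dice_coefficient(rw$mask, truth, fov)
  }

  manifest <- NULL
  if (!is.null(output_dir)) {
    if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
    artifacts <- list()
    if (save_intermediates) {
      artifacts$fov <- write_mask_png(fov, file.path(output_dir, "fov.png"))
      artifacts$vesselness <- write_gray_png(vv$values, file.path(output_dir, "vesselness.png"))
      artifacts$c_can <- write_mask_png(cl$c_can, file.path(output_dir, "centerline_candidates.png"))
      artifacts$c_skel <- write_mask_png(cl$c_skel, file.path(output_dir, "skeleton.png"))
      artifacts$c_final <- write_mask_png(cl$c_final, file.path(output_dir, "centerline_final.png"))
      artifacts$seeds <- write_gray_png(rw$seeds / 2, file.path(output_dir, "seeds.png"))
      artifacts$probability <- write_gray_png(unclass(rw$prob), file.path(output_dir, "probability.png"))
    }
    artifacts$mask <- write_mask_png(rw$mask, file.path(output_dir, "mask.png"))
    manifest <- list(
      package = "retwalk",
      version = as.character(utils::packageVersion("retwalk")),
      r_version = R.version.string,
      input = input_name,
      config_hash = config_hash(config),
      artifacts = lapply(artifacts, basename),
      stage_seconds = as.list(round(times, 3)))
    if (!is.null(mr))
      manifest$metrics <- list(sensitivity = mr$sensitivity,
                               specificity = mr$specificity,
                               accuracy = mr$accuracy, dice = dice)
    jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  structure(list(fov = fov, green = green, vesselness = vv,
                 c_can = cl$c_can, c_skel = cl$c_skel, c_final = cl$c_final,
                 density = rw$density, seeds = rw$seeds, prob = rw$prob,
                 mask = rw$mask, metrics = mr, dice = dice, times = times,
                 config = config, manifest = manifest),
            class = "vessel_segmentation")
}

#' @export
print.vessel_segmentation <- function(x, ...) {
  cat(sprintf("vessel segmentation: %d x %d, %d vessel px (%.1f%% of FOV)\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask),
              100 * sum(x$mask) / sum(x$fov)))
  cat(sprintf("  centerline px: %d (candidates %d, skeleton %d); seeds: %d fg / %d bg\n",
              sum(x$c_final), sum(x$c_can), sum(x$c_skel),
              sum(x$seeds == SEED_FG), sum(x$seeds == SEED_BG)))
  if (!is.null(x$metrics))
    cat(sprintf("  Se = %.4f  Sp = %.4f  Acc = %.4f  Dice = %.4f\n",
                x$metrics$sensitivity, x$metrics$specificity,
                x$metrics$accuracy, x$dice))
  cat(sprintf("  stage seconds: %s\n",
              paste(sprintf("%s %.1f", names(x$times), x$times), collapse = ", ")))
  invisible(x)
}

#' Plot a segmentation result
#'
#' Draws the green channel, the vesselness map, the final centerlines over
#' the image, and the segmentation mask.
#'
#' @param x `vessel_segmentation` object.
#' @param ... ignored.
#' @return `x`, invisibly.
#' @export
plot.vessel_segmentation <- function(x, ...) {
  show <- function(m, main, col = grDevices::gray.colors(256, 0, 1)) {
    graphics::image(t(m[nrow(m):1, , drop = FALSE]), col = col, axes = FALSE,
                    main = main, asp = nrow(m) / ncol(m), useRaster = TRUE)
  }
  op <- graphics::par(mfrow = c(2, 2), mar = c(0.5, 0.5, 2, 0.5))
  on.exit(graphics::par(op))
  show(x$green, "green channel")
  show(x$vesselness$values, "vesselness")
  over <- x$green
  over[x$c_final] <- 1
  show(over, "centerlines")
  show(x$mask * 1, "segmentation")
  invisible(x)
}

#' Batch segmentation of a directory of images
#'
#' Segments every image in `input_dir`; when `truth_dir` holds mask files
#' with matching file names, per-image metrics and their arithmetic mean are
#' reported.
#'
#' @param input_dir directory of input images.
#' @param config `pipeline_config`.
#' @param truth_dir optional directory of ground-truth masks.
#' @param output_dir optional directory for per-image outputs.
#' @return list with `per_image` (named list of `vessel_segmentation`) and
#'   `mean_metrics` (a `metric_report` or NULL).
#' @export
run_batch <- function(input_dir, config = pipeline_config(), truth_dir = NULL,
                      output_dir = NULL) {
  if (!dir.exists(input_dir)) stopf("input directory '%s' not found", input_dir)
  files <- list.files(input_dir, pattern = "\\.(png|tif|tiff|jpg|jpeg|ppm)$",
                      ignore.case = TRUE, full.names = TRUE)
  if (!length(files)) stopf("no images found in '%s'", input_dir)
  per <- list()
  for (f in files) {
    stem <- tools::file_path_sans_ext(basename(f))
    truth <- NULL
    if (!is.null(truth_dir)) {
      cand <- list.files(truth_dir, pattern = paste0("^", stem, "\\."),
                         full.names = TRUE)
      if (length(cand)) truth <- read_mask_png(cand[[1L]])
    }
    out <- if (is.null(output_dir)) NULL else file.path(output_dir, stem)
    per[[stem]] <- run_pipeline(f, config, truth = truth, output_dir = out)
  }
  reports <- Filter(Negate(is.null), lapply(per, `[[`, "metrics"))
  list(per_image = per,
       mean_metrics = if (length(reports)) average_metrics(reports) else NULL)
}
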