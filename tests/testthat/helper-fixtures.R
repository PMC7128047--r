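# Shared fixtures. Expensive end-to-end runs are cached in this environment,
# which persists across test files within one test_check() run.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

# Full pipeline on one of the standard suite phantoms, at default settings.
suite_run <- function(name, clean = FALSE, output_dir = NULL) {
  key <- paste0("run_", name, if (clean) "_clean", if (!is.null(output_dir)) "_out")
  cached(key, {
    sp <- default_test_suite_specs()[[name]]
    if (clean) sp$noise_sd <- 0
    ph <- generate_phantom(sp)
    res <- suppressWarnings(run_pipeline(ph, output_dir = output_dir))
    list(phantom = ph, result = res)
  })
}

# Straight dark tube on a plain background (generator-independent fixture).
tube_image <- function(H = 80, W = 80, row = H / 2, half_width = 3,
                       depth = 0.3, background = 0.8) {
  rr <- matrix(seq_len(H), H, W)
  background - depth * exp(-(rr - row)^2 / (2 * (2 * half_width / 2.355)^2))
}

# Random binary blob mask: thresholded smoothed noise, reproducible.
random_blobs <- function(seed, H = 48, W = 48, thr = 0.6) {
  set.seed(seed)
  m <- gaussian_smooth(matrix(stats::runif(H * W), H, W), 2)
  m > stats::quantile(m, thr)
}

# Fraction of `mask` pixels within `tol` px of any TRUE pixel of `ref`.
fraction_near <- function(mask, ref, tol = 2) {
  a <- which(mask, arr.ind = TRUE)
  b <- which(ref, arr.ind = TRUE)
  if (nrow(a) == 0L) return(NA_real_)
  mean(vapply(seq_len(nrow(a)), function(i) {
    any((b[, 1L] - a[i, 1L])^2 + (b[, 2L] - a[i, 2L])^2 <= tol^2)
  }, logical(1)))
}

# Dense linear-algebra oracle for the random-walker Dirichlet problem.
dense_walker_oracle <- function(lat, seeds) {
  n <- lat$n
  W <- matrix(0, n, n)
  e <- lat$edges
  for (k in seq_len(nrow(e))) {
    W[e$i[k], e$j[k]] <- W[e$i[k], e$j[k]] + e$w[k]
    W[e$j[k], e$i[k]] <- W[e$j[k], e$i[k]] + e$w[k]
  }
  L <- diag(rowSums(W)) - W
  lab <- integer(n)
  in_graph <- lat$index > 0L
  lab[lat$index[in_graph & seeds == SEED_FG]] <- 1L
  lab[lat$index[in_graph & seeds == SEED_BG]] <- 2L
  u <- as.numeric(lab == 1L)
  unl <- which(lab == 0L)
  if (length(unl)) {
    m <- which(lab > 0L)
    u[unl] <- solve(L[unl, unl, drop = FALSE], -L[unl, m, drop = FALSE] %*% u[m])
  }
  prob <- matrix(0, nrow(lat$index), ncol(lat$index))
  prob[in_graph] <- u[lat$index[in_graph]]
  prob
}
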