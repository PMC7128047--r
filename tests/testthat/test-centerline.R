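test_that("gradient fields match analytic gradients", {
  g0 <- gradient_field(matrix(0.3, 20, 20), 1)
  expect_true(all(abs(g0$fx) < 1e-12) && all(abs(g0$fy) < 1e-12))

  ramp <- matrix(1:40, 40, 40, byrow = TRUE)  # img(x, y) = x
  f <- gradient_field(ramp, 1.5)
  i <- 10:30
  expect_equal(f$fx[i, i], matrix(1, 21, 21), tolerance = 1e-8)
  expect_equal(f$fy[i, i], matrix(0, 21, 21), tolerance = 1e-8)

  # around a dark tube the field points away from the axis on both sides
  tube <- tube_image(row = 40)
  ft <- gradient_field(tube, 1.5)
  expect_true(all(ft$fy[35:38, 20:60] < 0))  # above the axis: toward smaller rows
  expect_true(all(ft$fy[42:45, 20:60] > 0))
})

test_that("field normalization yields unit or exactly-zero vectors", {
  vf <- structure(list(fx = matrix(3, 1, 1), fy = matrix(4, 1, 1)),
                  class = "vector_field")
  nf <- normalize_field(vf)
  expect_equal(c(nf$fx, nf$fy), c(0.6, 0.8))

  z <- normalize_field(structure(list(fx = matrix(0, 1, 1), fy = matrix(0, 1, 1)),
                                 class = "vector_field"))
  expect_equal(c(z$fx, z$fy), c(0, 0))

  set.seed(2)
  f <- structure(list(fx = matrix(rnorm(400), 20, 20),
                      fy = matrix(rnorm(400), 20, 20)), class = "vector_field")
  nf <- normalize_field(f)
  mags <- sqrt(nf$fx^2 + nf$fy^2)
  expect_true(all(abs(mags - 1) < 1e-9 | mags == 0))
  expect_error(normalize_field(f, eps = 0), "eps")
})

test_that("divergence operators reproduce closed-form fields", {
  un <- structure(list(fx = matrix(0.6, 30, 30), fy = matrix(0.8, 30, 30)),
                  class = "vector_field")
  for (th in c(0, pi / 8, pi / 2)) {
    dv <- rotated_divergence(un, th)
    expect_true(all(abs(dv[2:29, 2:29]) < 1e-12))
  }

  # radial unit field (x, y)/r has divergence 1/r
  H <- 41
  rr <- matrix(1:H, H, H) - 21; cc <- t(rr)
  r <- sqrt(rr^2 + cc^2); r[r == 0] <- 1
  rad <- structure(list(fx = cc / r, fy = rr / r), class = "vector_field")
  dv <- rotated_divergence(rad, 0)
  expect_lt(abs(dv[21, 31] - 1 / 10), 2e-3)
  expect_lt(abs(dv[31, 21] - 1 / 10), 2e-3)
  # positive at the center of the expanding field
  expect_gt(dv[21, 21], 0)

  # the directional form at theta = 0 is the x-partial alone
  set.seed(4)
  nf <- normalize_field(gradient_field(matrix(runif(900), 30, 30), 1))
  d0 <- directional_divergence(nf, 0)
  dx <- rotated_divergence(structure(list(fx = nf$fx, fy = matrix(0, 30, 30)),
                                     class = "vector_field"), 0)
  expect_equal(d0, dx, tolerance = 1e-12)
})

test_that("candidate centerlines shrink with phi and vanish on flat images", {
  expect_equal(sum(candidate_centerlines(matrix(0.5, 64, 64), sigmas = c(1, 2))), 0)

  tube <- tube_image()
  loose <- candidate_centerlines(tube, phi = 0.30, sigmas = c(1, 2, 3), delta = 10)
  tight <- candidate_centerlines(tube, phi = 0.60, sigmas = c(1, 2, 3), delta = 10)
  expect_true(all(loose[tight]))        # superset monotonicity
  expect_gt(sum(loose), sum(tight))

  # candidates hug the axis of a clean tube
  cand <- candidate_centerlines(tube, sigmas = c(1, 2, 3), delta = 10)
  rows <- which(cand, arr.ind = TRUE)[, 1]
  expect_gte(mean(abs(rows - 40) <= 2), 0.9)
  expect_error(candidate_centerlines(tube, thetas = numeric(0)), "nonempty")
  expect_error(candidate_centerlines(tube, phi = 1.5), "phi")
})

test_that("the summed bottom-hat highlights thin dark lines", {
  expect_equal(bottomhat_sum(matrix(0.5, 32, 32)), matrix(0, 32, 32))

  img <- matrix(0.8, 32, 32); img[16, ] <- 0.2   # 1-px dark line
  bh <- bottomhat_sum(img)
  expect_true(all(bh[16, 3:30] > 0.9))
  expect_true(all(bh[c(1:12, 20:32), ] < 0.2))
  expect_equal(max(bh), 1)

  # closing with a single vertical element: exact flat-morphology oracle
  one <- bottomhat_sum(img, lengths = 4, angles = pi / 2)
  expect_true(all(one[16, ] > 0.99))
})

test_that("Otsu equals exhaustive between-class-variance search", {
  brute_otsu <- function(v, nbins = 256L) {
    edges <- seq(min(v), max(v), length.out = nbins + 1L)[2:nbins]
    crit <- vapply(edges, function(t) {
      lo <- v[v < t]; hi <- v[v >= t]
      if (!length(lo) || !length(hi)) return(-Inf)
      (length(lo) / length(v)) * (length(hi) / length(v)) * (mean(lo) - mean(hi))^2
    }, numeric(1))
    edges[which.max(crit)]
  }
  set.seed(21)
  for (k in 1:50) {
    v <- switch(1 + k %% 3,
                runif(4096),
                c(rnorm(3296, 0.3, 0.08), rnorm(800, 0.8, 0.05)),
                rbeta(4096, 2, 5))
    v <- pmin(pmax(v, 0), 1)
    expect_identical(otsu_threshold(matrix(v, 64, 64)), brute_otsu(v))
  }
})

test_that("Otsu lands between well-separated modes and rejects constants", {
  set.seed(31)
  v <- matrix(c(rnorm(2048, 0.2, 0.05), rnorm(2048, 0.8, 0.05)), 64, 64)
  thr <- otsu_threshold(pmin(pmax(v, 0), 1))
  expect_gt(thr, 0.35); expect_lt(thr, 0.65)

  two <- matrix(rep(c(0.1, 0.9), each = 32), 8, 8)
  t2 <- otsu_threshold(two)
  expect_gt(t2, 0.1); expect_lt(t2, 0.9)
  expect_error(otsu_threshold(matrix(0.5, 8, 8)), "constant")

  # independent implementation in EBImage agrees to within one bin
  img <- matrix(runif(4096), 64, 64)
  expect_lt(abs(otsu_threshold(img) -
                EBImage::otsu(EBImage::Image(img), range = range(img))),
            2 * diff(range(img)) / 256)
})

test_that("thinning produces 1-px skeletons preserving topology", {
  line <- matrix(FALSE, 10, 30); line[5, 3:27] <- TRUE
  expect_identical(thin_to_skeleton(line), line)
  expect_identical(thin_to_skeleton(matrix(FALSE, 6, 6)), matrix(FALSE, 6, 6))

  rect <- matrix(FALSE, 20, 40); rect[8:12, 5:24] <- TRUE
  sk <- thin_to_skeleton(rect)
  expect_true(all(rect[sk]))                       # subset of input
  # a path along the long axis, eroded by at most the half-width per end
  expect_gte(sum(sk), 20 - 5)
  expect_gte(diff(range(which(sk, arr.ind = TRUE)[, 2])), 20 - 6)
  expect_equal(count_components(sk, 8), 1)

  has_2x2 <- function(m) {
    H <- nrow(m); W <- ncol(m)
    any(m[-H, -W] & m[-1, -W] & m[-H, -1] & m[-1, -1])
  }
  for (seed in 1:50) {
    blob <- random_blobs(seed)
    sk <- thin_to_skeleton(blob)
    expect_true(all(blob[sk]))
    expect_false(has_2x2(sk))
    expect_equal(count_components(sk, 8), count_components(blob, 8))
  }
})

test_that("centerline correction keeps mutually supported regions only", {
  m <- matrix(FALSE, 30, 80); m[15, 5:75] <- TRUE
  # identical inputs: output equals input minus sub-min_length components
  expect_identical(correct_centerlines(m, m, min_length = 10), m)
  short <- m; short[15, 20:60] <- FALSE   # splits into 15 + 15 px pieces
  expect_identical(correct_centerlines(short, short, min_length = 50),
                   matrix(FALSE, 30, 80))

  # disjoint masks have empty intersection, hence empty output
  a <- matrix(FALSE, 30, 80); a[10, 5:75] <- TRUE
  b <- matrix(FALSE, 30, 80); b[20, 5:75] <- TRUE
  expect_equal(sum(correct_centerlines(a, b)), 0)

  # an unsupported parallel branch is dropped, the supported one kept
  skel <- matrix(FALSE, 40, 80); skel[15, 5:75] <- TRUE
  can <- skel; can[30, 5:75] <- TRUE
  out <- correct_centerlines(skel, can, min_length = 10)
  expect_true(all(out[15, 5:75]))
  expect_false(any(out[30, ]))
  expect_error(correct_centerlines(skel, can, overlap_frac = 1.2), "overlap_frac")
})

test_that("connected-component labeling distinguishes 4- and 8-connectivity", {
  m <- matrix(FALSE, 5, 5); m[2, 2] <- TRUE; m[3, 3] <- TRUE
  expect_equal(max(label_components(m, 8)), 1)
  expect_equal(max(label_components(m, 4)), 2)
  blob <- random_blobs(3)
  lab <- label_components(blob, 4)
  expect_equal(sum(lab > 0), sum(blob))
  # agreement with EBImage's 4-connected labeler on component count
  expect_equal(max(lab), max(EBImage::bwlabel(blob)))
})
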