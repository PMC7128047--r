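test_that("lattice edge weights follow the similarity kernel", {
  g <- matrix(c(0.5, 0.6), 1, 2)   # two pixels, difference 0.1
  fov <- matrix(TRUE, 1, 2)
  lat <- build_lattice(g, fov, beta = 90, normalize_guide = FALSE)
  expect_equal(nrow(lat$edges), 1)
  expect_equal(lat$edges$w, exp(-0.9), tolerance = 1e-12)

  same <- build_lattice(matrix(0.3, 2, 2), matrix(TRUE, 2, 2), beta = 90)
  expect_true(all(same$edges$w == 1))
  expect_true(all(lat$edges$w > 0 & lat$edges$w <= 1))
  expect_error(build_lattice(g, matrix(FALSE, 1, 2)), "degenerate")
  expect_error(build_lattice(g, fov, beta = 0), "beta")

  # an 8-connected interior pixel carries 8 incident edges
  lat3 <- build_lattice(matrix(runif(9), 3, 3), matrix(TRUE, 3, 3))
  ctr <- lat3$index[2, 2]
  expect_equal(sum(lat3$edges$i == ctr | lat3$edges$j == ctr), 8)
})

test_that("density classification flags closely spaced centerlines", {
  lone <- matrix(FALSE, 60, 60); lone[30, 10:50] <- TRUE
  d1 <- classify_density(lone, r_mid = 7)
  expect_false(any(d1$dense[lone]))

  # two parallel centerlines 3 * r_mid apart: dilated bands stay separate
  two <- matrix(FALSE, 80, 80); two[30, 10:70] <- TRUE; two[51, 10:70] <- TRUE
  d2 <- classify_density(two, r_mid = 7)
  expect_true(any(d2$dense[two]))
  expect_gt(mean(d2$dense[30, 20:60]), 0.8)
})

test_that("automatic seeding places background seeds across the vessel", {
  H <- W <- 64
  cl <- matrix(FALSE, H, W); cl[32, 10:54] <- TRUE
  eig <- structure(list(lam1 = matrix(0, H, W), lam2 = matrix(1, H, W),
                        v2x = matrix(0, H, W), v2y = matrix(1, H, W)),
                   class = "eigen_field")
  fov <- matrix(TRUE, H, W)
  seeds <- place_seeds(cl, eig, matrix(FALSE, H, W), fov, r_mid = 7, r_max = 12)
  expect_true(all(seeds[cl] == SEED_FG))
  # sparse rule: background seeds 13 px above and below the axis
  expect_true(all(seeds[32 + 13, 10:54] == SEED_BG))
  expect_true(all(seeds[32 - 13, 10:54] == SEED_BG))
  expect_equal(sum(seeds == SEED_BG), 2 * 45)

  # dense rule shortens the offset to r_mid + 1
  dseeds <- place_seeds(cl, eig, cl, fov, r_mid = 7, r_max = 12)
  expect_true(all(dseeds[32 + 8, 10:54] == SEED_BG))

  # pixels whose candidates fall outside the FOV contribute no background
  # seeds, without an error as long as other pixels succeed
  holed <- matrix(TRUE, H, W)
  holed[c(32 - 13, 32 + 13), 33:W] <- FALSE
  s2 <- place_seeds(cl, eig, matrix(FALSE, H, W), holed, r_mid = 7, r_max = 12)
  expect_true(all(s2[32 + 13, 10:32] == SEED_BG))
  expect_equal(sum(s2[, 33:W] == SEED_BG), 0)
})

test_that("seeding errors when no background seed is placeable", {
  cl <- matrix(FALSE, 30, 30); cl[15, 5:25] <- TRUE
  eig <- structure(list(lam1 = matrix(0, 30, 30), lam2 = matrix(1, 30, 30),
                        v2x = matrix(0, 30, 30), v2y = matrix(1, 30, 30)),
                   class = "eigen_field")
  tight <- matrix(FALSE, 30, 30); tight[14:16, ] <- TRUE
  expect_error(place_seeds(cl, eig, matrix(FALSE, 30, 30), tight),
               "seeding error")
})

test_that("the walker solution is exact on a uniform 1-D chain", {
  n <- 50
  g <- matrix(0.5, 1, n + 1)
  lat <- build_lattice(g, matrix(TRUE, 1, n + 1), beta = 90)
  seeds <- matrix(SEED_UNLABELED, 1, n + 1)
  seeds[1, 1] <- SEED_FG; seeds[1, n + 1] <- SEED_BG
  u <- solve_probabilities(lat, seeds)
  expect_equal(as.numeric(u), 1 - (0:n) / n, tolerance = 1e-8)
})

test_that("fully seeded lattices return the seed indicator exactly", {
  g <- matrix(runif(16), 4, 4)
  fov <- matrix(TRUE, 4, 4)
  seeds <- matrix(SEED_BG, 4, 4); seeds[2, 2:3] <- SEED_FG
  u <- solve_probabilities(build_lattice(g, fov), seeds)
  expect_identical(unclass(u), (seeds == SEED_FG) * 1)
})

test_that("the sparse solve matches a dense oracle on random small lattices", {
  set.seed(17)
  for (k in 1:25) {
    H <- sample(2:5, 1); W <- sample(2:5, 1)
    lat <- build_lattice(matrix(runif(H * W), H, W), matrix(TRUE, H, W), beta = 30)
    lat$edges$w <- runif(nrow(lat$edges), 0.05, 1)
    seeds <- matrix(SEED_UNLABELED, H, W)
    picks <- sample(H * W, 2)
    seeds[picks[1]] <- SEED_FG; seeds[picks[2]] <- SEED_BG
    u <- solve_probabilities(lat, seeds)
    expect_equal(unclass(u), dense_walker_oracle(lat, seeds), tolerance = 1e-8)
  }
})

test_that("walker probabilities are harmonic and obey the maximum principle", {
  set.seed(23)
  lat <- build_lattice(matrix(runif(100), 10, 10), matrix(TRUE, 10, 10), beta = 50)
  seeds <- matrix(SEED_UNLABELED, 10, 10)
  seeds[2, 2] <- SEED_FG; seeds[9, 9] <- SEED_BG; seeds[5, 9] <- SEED_BG
  u <- solve_probabilities(lat, seeds)
  expect_true(all(u >= 0 & u <= 1))
  expect_true(all(u[seeds == SEED_UNLABELED] < 1 & u[seeds == SEED_UNLABELED] > 0))

  e <- lat$edges
  n <- lat$n
  uvec <- numeric(n); uvec[lat$index[lat$index > 0]] <- unclass(u)[lat$index > 0]
  num <- numeric(n); den <- numeric(n)
  for (k in seq_len(nrow(e))) {
    num[e$i[k]] <- num[e$i[k]] + e$w[k] * uvec[e$j[k]]
    den[e$i[k]] <- den[e$i[k]] + e$w[k]
    num[e$j[k]] <- num[e$j[k]] + e$w[k] * uvec[e$i[k]]
    den[e$j[k]] <- den[e$j[k]] + e$w[k]
  }
  unl <- lat$index[seeds == SEED_UNLABELED]
  expect_lt(max(abs(uvec[unl] - num[unl] / den[unl])), 1e-6)
})

test_that("label swap and weight rescaling act as symmetries", {
  set.seed(29)
  lat <- build_lattice(matrix(runif(64), 8, 8), matrix(TRUE, 8, 8), beta = 50)
  seeds <- matrix(SEED_UNLABELED, 8, 8)
  seeds[1, 1] <- SEED_FG; seeds[8, 8] <- SEED_BG; seeds[4, 7] <- SEED_FG
  u <- solve_probabilities(lat, seeds)

  swapped <- seeds
  swapped[seeds == SEED_FG] <- SEED_BG
  swapped[seeds == SEED_BG] <- SEED_FG
  expect_equal(unclass(solve_probabilities(lat, swapped)), 1 - unclass(u),
               tolerance = 1e-8)

  lat2 <- lat; lat2$edges$w <- lat$edges$w * 7.3
  expect_equal(unclass(solve_probabilities(lat2, seeds)), unclass(u),
               tolerance = 1e-8)
})

test_that("solver handles seedless FOV components and missing labels", {
  fov <- matrix(FALSE, 6, 12)
  fov[2:5, 2:5] <- TRUE; fov[2:5, 8:11] <- TRUE  # two islands
  lat <- build_lattice(matrix(0.5, 6, 12), fov)
  seeds <- matrix(SEED_UNLABELED, 6, 12)
  seeds[3, 3] <- SEED_FG; seeds[4, 4] <- SEED_BG
  expect_warning(u <- solve_probabilities(lat, seeds), "without seeds")
  expect_true(all(unclass(u)[, 8:11] == 0))

  seeds2 <- matrix(SEED_UNLABELED, 6, 12); seeds2[3, 3] <- SEED_FG
  expect_error(solve_probabilities(lat, seeds2), "background")
})

test_that("binarization thresholds at one half with ties labeled vessel", {
  expect_true(all(binarize(matrix(1, 3, 3))))
  p <- matrix(c(0.4999, 0.5, 0.5001, 0), 2, 2)
  expect_identical(as.vector(binarize(p)), c(FALSE, TRUE, TRUE, FALSE))
})
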