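test_that("centroid size matches analytic values and the loop oracle", {
  # unit square corners sit at distance sqrt(1/2) from their centroid:
  # CS = sqrt(4 * 1/2) = sqrt(2)
  sq <- landmark_config(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)), "sq")
  expect_equal(centroid_size(sq), sqrt(2), tolerance = 1e-12)
  cfg <- random_config(35, seed = 2)
  expect_equal(centroid_size(cfg), cs_oracle(cfg$coords), tolerance = 1e-12)
  # homogeneity of degree 1
  expect_equal(centroid_size(cfg$coords * 3.7), 3.7 * centroid_size(cfg),
               tolerance = 1e-10)
  expect_error(centroid_size(matrix(1, 4, 2)), "degenerate")
})

test_that("align_pair recovers similarity transforms exactly", {
  ref <- random_config(30, seed = 5)$coords
  tgt <- similarity_transform(ref, angle = pi / 6, scale = 3, shift = c(2, -1))
  res <- align_pair(ref, tgt)
  expect_lt(res$residual, 1e-10)
  expect_equal(det(res$rotation), 1, tolerance = 1e-12)
})

test_that("align_pair residual equals the brute-force rotation grid minimum", {
  # mirrored scalene triangle: reflection blocked leaves a real residual
  tri <- rbind(c(0, 0), c(3, 0), c(1, 2))
  mir <- cbind(-tri[, 1], tri[, 2])
  res <- align_pair(tri, mir)
  expect_equal(res$residual, opa_grid_oracle(tri, mir), tolerance = 1e-6)
  res_ref <- align_pair(tri, mir, allow_reflection = TRUE)
  expect_lt(res_ref$residual, 1e-10)
  # random pairs against the grid oracle
  for (s in 1:4) {
    a <- random_config(12, seed = s)$coords
    b <- random_config(12, seed = s + 50)$coords
    expect_equal(align_pair(a, b)$residual, opa_grid_oracle(a, b),
                 tolerance = 1e-6)
  }
  expect_error(align_pair(tri, random_config(10, 1)$coords), "mismatch")
})

test_that("sliding projects residuals onto tangents exactly", {
  cfg <- random_config(15, seed = 7)$coords
  sliders <- skatemorph:::make_sliders(15)
  i <- 7
  tang <- cfg[i + 1, ] - cfg[i - 1, ]
  tang <- tang / sqrt(sum(tang^2))
  orth <- c(-tang[2], tang[1])
  # displacement purely along the tangent is removed entirely
  ref <- cfg
  disp <- cfg
  disp[i, ] <- cfg[i, ] + 0.05 * tang
  slid <- slide_semilandmarks(disp, ref, sliders)
  expect_equal(slid[i, ], ref[i, ], tolerance = 1e-12)
  # purely orthogonal displacement is untouched
  disp[i, ] <- cfg[i, ] + 0.05 * orth
  slid <- slide_semilandmarks(disp, ref, sliders)
  expect_equal(slid[i, ], disp[i, ], tolerance = 1e-12)
})

test_that("post-slide residual equals a 2000-point 1-D grid minimum per slider", {
  withr::with_seed(11, {
    for (case in 1:5) {
      k <- 12
      ref <- random_config(k, seed = 20 + case)$coords
      cfg <- ref + matrix(rnorm(2 * k, 0, 0.04), k)
      sliders <- skatemorph:::make_sliders(k)
      slid <- slide_semilandmarks(cfg, ref, sliders)
      for (r in seq_len(nrow(sliders))) {
        i <- sliders[r, 2]
        tang <- cfg[sliders[r, 3], ] - cfg[sliders[r, 1], ]
        tang <- tang / sqrt(sum(tang^2))
        ts <- seq(-0.2, 0.2, length.out = 2000)
        cand <- outer(ts, tang)
        d2 <- (cfg[i, 1] + cand[, 1] - ref[i, 1])^2 +
          (cfg[i, 2] + cand[, 2] - ref[i, 2])^2
        expect_lt(abs(sum((slid[i, ] - ref[i, ])^2) - min(d2)), 1e-6)
      }
    }
  })
})

test_that("sliding never increases distance to the reference", {
  withr::with_seed(3, {
    for (case in 1:10) {
      k <- 20
      ref <- random_config(k, seed = 30 + case)$coords
      cfg <- ref + matrix(rnorm(2 * k, 0, 0.05), k)
      sliders <- skatemorph:::make_sliders(k)
      slid <- slide_semilandmarks(cfg, ref, sliders)
      expect_lte(procrustes_distance(slid, ref),
                 procrustes_distance(cfg, ref) + 1e-12)
    }
  })
})

test_that("GPA satisfies the aligned-sample contract", {
  sim <- simulate_interspecific(synthetic_spec(seed = 6, n_species = 10))
  al <- gpa(sim$configs, sliders = sim$sliders)
  expect_true(al$converged)
  n <- dim(al$shapes)[3]
  for (i in seq_len(n)) {
    expect_lt(max(abs(colMeans(al$shapes[, , i]))), 1e-9)
    expect_lt(abs(sqrt(sum(al$shapes[, , i]^2)) - 1), 1e-9)
  }
  # consensus is the re-scaled coordinate-wise mean
  m <- skatemorph:::center_scale(apply(al$shapes, c(1, 2), mean))
  m <- m %*% skatemorph:::optimal_rotation(m, al$consensus)
  expect_lt(procrustes_distance(m, al$consensus), 1e-7)
})

test_that("GPA of copies of one shape collapses to it; two shapes are equidistant", {
  base <- random_config(18, seed = 9)$coords
  copies <- lapply(1:5, function(i)
    landmark_config(similarity_transform(base, i, 0.5 + i, c(i, -i)),
                    paste0("c", i)))
  al <- gpa(copies)
  for (i in 1:5)
    expect_lt(procrustes_distance(al$shapes[, , i], al$consensus), 1e-9)
  # two distinct shapes: consensus equidistant from both
  two <- list(random_config(18, seed = 1), random_config(18, seed = 2))
  al2 <- gpa(two)
  d1 <- procrustes_distance(al2$shapes[, , 1], al2$consensus)
  d2 <- procrustes_distance(al2$shapes[, , 2], al2$consensus)
  expect_equal(d1, d2, tolerance = 1e-9)
})

test_that("GPA consensus is stable under input-order permutation", {
  sim <- simulate_interspecific(synthetic_spec(seed = 12, n_species = 10))
  arr <- skatemorph:::configs_to_array(sim$configs)
  a <- gpa(arr, sliders = sim$sliders)
  perm <- c(7:20, 1:6)
  b <- gpa(arr[, , perm], sliders = sim$sliders)
  cc <- b$consensus %*% skatemorph:::optimal_rotation(b$consensus, a$consensus)
  expect_lt(procrustes_distance(cc, a$consensus), 1e-6)
})

test_that("procrustes_distance matches analytic values, the oracle, and metric axioms", {
  expect_equal(procrustes_distance(rbind(c(0, 0), c(1, 0), c(0, 1)),
                                   rbind(c(0, 0), c(1, 0), c(0, 1))), 0)
  a <- rbind(c(0, 0), c(1, 0), c(2, 2))
  b <- rbind(c(0, 0), c(1, 1), c(2, 2))
  expect_equal(procrustes_distance(a, b), 1.0, tolerance = 1e-12)
  withr::with_seed(4, {
    for (i in 1:5) {
      x <- matrix(rnorm(70), 35); y <- matrix(rnorm(70), 35)
      z <- matrix(rnorm(70), 35)
      expect_equal(procrustes_distance(x, y), pd_oracle(x, y),
                   tolerance = 1e-12)
      expect_equal(procrustes_distance(x, y), procrustes_distance(y, x))
      expect_lte(procrustes_distance(x, z),
                 procrustes_distance(x, y) + procrustes_distance(y, z) + 1e-12)
    }
  })
})

test_that("shape PCA reproduces a brute-force eigendecomposition", {
  sim <- simulate_interspecific(synthetic_spec(seed = 21, n_species = 20))
  al <- gpa(sim$configs, sliders = sim$sliders)
  p <- shape_pca(al)
  X <- t(apply(al$shapes, 3, as.vector))
  Xc <- sweep(X, 2, colMeans(X))
  ev <- eigen(cov(Xc), symmetric = TRUE)$values
  ev <- ev[ev > ev[1] * 1e-12]
  expect_equal(p$eigenvalues, ev[seq_along(p$eigenvalues)], tolerance = 1e-9)
  expect_equal(sum(p$proportion_variance), 1, tolerance = 1e-9)
  expect_lt(max(abs(crossprod(p$loadings) - diag(ncol(p$loadings)))), 1e-9)
  # reconstruction and zero-mean scores
  expect_lt(max(abs(Xc - p$scores %*% t(p$loadings))), 1e-8)
  expect_lt(max(abs(colMeans(p$scores))), 1e-9)
  # total variance identity with mean squared distance to the sample mean
  n <- nrow(X)
  msd <- mean(apply(Xc, 1, function(r) sum(r^2)))
  expect_equal(sum(p$eigenvalues), msd * n / (n - 1), tolerance = 1e-9)
})

test_that("degenerate PCA inputs behave as documented", {
  base <- random_config(12, seed = 2)$coords
  X <- rbind(as.vector(base), as.vector(base), as.vector(base))
  p <- shape_pca(X)
  expect_length(p$eigenvalues, 0)
  expect_equal(ncol(p$scores), 0)
  # two distinct shapes plus midpoint: exactly one axis, proportion 1
  a <- as.vector(base); b <- as.vector(random_config(12, seed = 3)$coords)
  p2 <- shape_pca(rbind(a, b, (a + b) / 2))
  expect_length(p2$eigenvalues, 1)
  expect_equal(p2$proportion_variance, 1, tolerance = 1e-9)
  expect_error(shape_pca(rbind(a, b)), "at least 3")
})

test_that("PC-extreme shapes follow the linear reconstruction", {
  sim <- simulate_interspecific(synthetic_spec(seed = 23, n_species = 8))
  al <- gpa(sim$configs, sliders = sim$sliders)
  p <- shape_pca(al)
  lo <- shape_at_pc_extreme(p, 2, "min")
  hi <- shape_at_pc_extreme(p, 2, "max")
  smin <- min(p$scores[, 2]); smax <- max(p$scores[, 2])
  expect_equal(as.vector(hi) - as.vector(lo),
               (smax - smin) * p$loadings[, 2], tolerance = 1e-12)
  # projecting the extreme shape back recovers the requested score
  sc <- sum((as.vector(hi) - p$mean) * p$loadings[, 2])
  expect_equal(sc, smax, tolerance = 1e-10)
  expect_error(shape_at_pc_extreme(p, 200), "out of range")
})
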