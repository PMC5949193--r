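# Shape model (Procrustes + PCA), patch appearance model, and the
# inverse compositional fitters.

rand_shape <- function(seed) {
  set.seed(seed)
  landmark_template()$points * 30 + matrix(rnorm(32, 0, 1.5), 16, 2)
}

test_that("generalized Procrustes aligns similarity-transformed shapes", {
  A <- rand_shape(1)
  gp <- generalized_procrustes(list(A, A))
  expect_lt(max(abs(gp$aligned[[1]] - gp$aligned[[2]])), 1e-12)
  expect_lt(max(abs(gp$mean_shape - gp$aligned[[1]])), 1e-9)
  expect_lt(abs(sum(colMeans(gp$mean_shape))), 1e-12)
  expect_equal(sqrt(sum(gp$mean_shape^2)), 1)

  th <- 0.7; s <- 1.8
  R <- s * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  B <- sweep(A %*% t(R), 2, c(12, -4), "+")
  gp2 <- generalized_procrustes(list(A, B))
  expect_lt(max(abs(gp2$aligned[[1]] - gp2$aligned[[2]])), 1e-8)

  expect_error(generalized_procrustes(list(A)), "at least 2")
  expect_error(generalized_procrustes(list(matrix(1, 4, 2), matrix(2, 4, 2))),
               "degenerate")
})

test_that("Procrustes mean matches a brute-force alternating oracle", {
  shapes <- list(rbind(c(0, 0), c(2, 0), c(2, 1), c(0, 1)),
                 rbind(c(0, 0), c(2.2, 0.1), c(2.1, 1.2), c(-0.1, 0.9)),
                 rbind(c(0.1, -0.1), c(1.9, 0), c(2, 0.8), c(0, 1.1)))
  gp <- generalized_procrustes(shapes)

  # oracle: complex-regression similarity alignment, alternated to a
  # fixed point (independent of the SVD-rotation implementation)
  norm1 <- function(m) { m <- sweep(m, 2, colMeans(m)); m / sqrt(sum(m^2)) }
  zs <- lapply(shapes, function(m) {
    m <- norm1(m); complex(real = m[, 1], imaginary = m[, 2])
  })
  mu <- zs[[1]]
  for (it in 1:200) {
    al <- lapply(zs, function(z) {
      b <- sum(Conj(z) * mu) / sum(Mod(z)^2)
      (b / Mod(b)) * z                     # rotation only, unit scale kept
    })
    mu_new <- Reduce(`+`, al) / length(al)
    mu_new <- mu_new - mean(mu_new)
    mu_new <- mu_new / sqrt(sum(Mod(mu_new)^2))
    if (max(Mod(mu_new - mu)) < 1e-12) { mu <- mu_new; break }
    mu <- mu_new
  }
  oracle_mean <- cbind(Re(mu), Im(mu))
  # the mean is defined up to rotation: align before comparing
  zo <- complex(real = oracle_mean[, 1], imaginary = oracle_mean[, 2])
  zg <- complex(real = gp$mean_shape[, 1], imaginary = gp$mean_shape[, 2])
  rot <- sum(Conj(zo) * zg) / sum(Mod(zo)^2)
  expect_lt(max(Mod(zo * rot - zg)), 1e-6)
})

test_that("the PCA shape model retains variance as specified", {
  A <- rand_shape(2)
  gp0 <- generalized_procrustes(list(A, A, A))
  sm0 <- build_shape_model(gp0$aligned)
  expect_equal(ncol(sm0$eigenvectors), 0L)
  expect_true(all(sm0$eigenvalues <= 1e-12))

  # rank-1 variation: one mode parallel to the perturbation
  dirv <- matrix(rnorm(32), 16, 2); dirv <- dirv / sqrt(sum(dirv^2))
  shapes <- lapply(seq(-2, 2, length.out = 9), function(a) A + a * dirv)
  gp1 <- generalized_procrustes(shapes)
  sm1 <- build_shape_model(gp1$aligned, var_retained = 0.95)
  expect_equal(ncol(sm1$eigenvectors), 1L)

  # completeness: any training shape reconstructed with all components
  shapes2 <- lapply(1:8, rand_shape)
  gp2 <- generalized_procrustes(shapes2)
  X <- t(sapply(gp2$aligned, function(m) as.numeric(t(m))))
  sm2 <- build_shape_model(gp2$aligned, var_retained = 1)
  mu <- sm2$mean_shape
  for (i in c(1, 5)) {
    v <- X[i, ] - mu
    rec <- sm2$eigenvectors %*% crossprod(sm2$eigenvectors, v)
    expect_lt(max(abs(rec - v)), 1e-8)
  }
  # orthonormality and ordering
  G <- sm2$eigenvectors
  expect_lt(max(abs(crossprod(G) - diag(ncol(G)))), 1e-8)
  expect_true(all(diff(sm2$eigenvalues) <= 1e-12))
})

test_that("shape eigen-decomposition matches a brute-force covariance solve", {
  shapes <- lapply(1:6, rand_shape)
  gp <- generalized_procrustes(shapes)
  sm <- build_shape_model(gp$aligned, var_retained = 1)
  X <- t(sapply(gp$aligned, function(m) as.numeric(t(m))))
  C <- cov(X)
  ev <- eigen(C, symmetric = TRUE)
  k <- sum(sm$eigenvalues > 1e-8)   # compare the well-determined modes
  expect_equal(sm$eigenvalues[seq_len(k)], ev$values[seq_len(k)],
               tolerance = 1e-8)
  for (j in seq_len(k))
    expect_lt(abs(abs(sum(sm$eigenvectors[, j] * ev$vectors[, j])) - 1), 1e-8)
})

test_that("appearance model degenerates correctly on identical data", {
  ph <- generate_phantom(phantom_spec(seed = 4))
  pair <- list(image = ph$image, landmarks = ph$vertebrae[[2]]$landmarks)
  m <- suppressWarnings(build_appearance_model(list(pair, pair, pair),
                                               scales = 1.0))
  expect_true(all(vapply(m$levels, function(l)
    length(l$eigenvalues) == 0L || all(l$eigenvalues <= 1e-12), TRUE)))

  # constant image: every mean patch is constant (zero after z-scoring)
  flat <- gray_image(matrix(100, 64, 64))
  lm <- landmark_set(landmark_template()$points * 30 + 15)
  mc <- suppressWarnings(build_appearance_model(
    list(list(image = flat, landmarks = lm),
         list(image = flat, landmarks = lm)), scales = 1.0))
  expect_lt(max(abs(mc$levels[[1]]$mean)), 1e-9)

  expect_error(build_appearance_model(list(pair), patch_shape = c(16, 17)),
               "odd")
})

test_that("shape perturbation is seeded and has the stated magnitude", {
  gt <- landmark_set(landmark_template()$points * 40 + 30)
  none <- perturb_shape(gt, list(trans_frac = 0, scale_sigma = 0,
                                 rot_deg = 0), seed = 1)
  expect_equal(none$points, gt$points)
  expect_equal(perturb_shape(gt, seed = 9)$points,
               perturb_shape(gt, seed = 9)$points)

  # translation-only: mean displacement is the Rayleigh mean
  diag_len <- sqrt(sum((apply(gt$points, 2, max) -
                        apply(gt$points, 2, min))^2))
  sigma_t <- 0.05 * diag_len
  disp <- vapply(1:1000, function(s) {
    p <- perturb_shape(gt, list(trans_frac = 0.05, scale_sigma = 0,
                                rot_deg = 0), seed = s)
    mean(sqrt(rowSums((p$points - gt$points)^2)))
  }, 0)
  expect_lt(abs(mean(disp) - sigma_t * sqrt(pi / 2)) / (sigma_t * sqrt(pi / 2)),
            0.10)
})

test_that("fitting is exact on its own training datum and respects budgets", {
  ph <- generate_phantom(phantom_spec(seed = 8))
  pair <- list(image = ph$image, landmarks = ph$vertebrae[[3]]$landmarks)
  model <- suppressWarnings(train_aam(list(pair, pair), scales = 1.0))
  gt <- pair$landmarks

  fit0 <- fit_aam(ph$image, model, gt, algorithm = "WIC", n_iterations = 25)
  expect_lte(fit0$costs[1], 1e-6)
  expect_lte(vbseg:::point_to_point_error(fit0$final, gt), 0.5)

  frozen <- fit_aam(ph$image, model, gt, algorithm = "POIC",
                    n_iterations = 0)
  expect_equal(frozen$final$points, gt$points)
  expect_length(frozen$shapes, 1L)
})

test_that("fitting is deterministic and records every iteration", {
  fx <- aam_fixture()
  item <- fx$test[[4]]
  init <- perturb_shape(item$landmarks, seed = 21)
  for (alg in c("POIC", "SIC", "AIC", "MAIC", "WIC")) {
    f1 <- fit_aam(item$image, fx$model, init, algorithm = alg,
                  n_iterations = 10)
    f2 <- fit_aam(item$image, fx$model, init, algorithm = alg,
                  n_iterations = 10)
    expect_identical(f1$final$points, f2$final$points)
    expect_length(f1$shapes, 11L)
    expect_true(all(is.finite(f1$costs)))
    expect_equal(f1$shapes[[1]], init$points)
  }
})

test_that("perturbed initializations converge for POIC and WIC", {
  fx <- aam_fixture()
  errs <- sapply(seq_along(fx$test), function(i) {
    item <- fx$test[[i]]
    init <- perturb_shape(item$landmarks, seed = vbseg:::derive_seed(13, i))
    e0 <- vbseg:::point_to_point_error(init, item$landmarks)
    sapply(c(POIC = "POIC", WIC = "WIC"), function(alg) {
      fit <- fit_aam(item$image, fx$model, init, algorithm = alg)
      vbseg:::point_to_point_error(fit$final, item$landmarks) / e0
    })
  })
  expect_lt(mean(errs["POIC", ]), 0.5)
  expect_lt(mean(errs["WIC", ]), 0.5)
})

test_that("model serialization round-trips to identical fits", {
  fx <- aam_fixture()
  f <- withr::local_tempfile(fileext = ".json")
  save_aam(fx$model, f)
  back <- load_aam(f)
  item <- fx$test[[2]]
  init <- perturb_shape(item$landmarks, seed = 31)
  f1 <- fit_aam(item$image, fx$model, init)
  f2 <- fit_aam(item$image, back, init)
  expect_identical(f1$final$points, f2$final$points)
  expect_identical(f1$costs, f2$costs)
})

test_that("compare_algorithms equals the direct composition for one pass", {
  fx <- aam_fixture()
  items <- fx$test[1:2]
  cmp <- compare_algorithms(items, fx$model, algorithms = "WIC",
                            n_passes = 1, n_iterations = 5, seed = 7)
  # direct recomputation with the same derived seeds
  ff <- sapply(seq_along(items), function(i) {
    item <- items[[i]]
    init <- perturb_shape(item$landmarks,
                          seed = vbseg:::derive_seed(7, 1 * 1000L + i))
    fit <- fit_aam(item$image, fx$model, init, algorithm = "WIC",
                   n_iterations = 5)
    sapply(fit$shapes, function(s) {
      m <- rasterize(catmull_rom_closed(s), dim(item$image$pixels),
                     item$image$spacing)
      fractions(m, item$mask)$FF
    })
  })
  expect_equal(subset(cmp$per_iteration, algorithm == "WIC")$FF,
               rowMeans(ff), tolerance = 1e-12)

  cmp2 <- compare_algorithms(items, fx$model, algorithms = "WIC",
                             n_passes = 1, n_iterations = 5, seed = 7)
  expect_identical(cmp$per_iteration, cmp2$per_iteration)
})
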