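# Thin-plate-spline augmentation and harmonic inpainting.

test_that("TPS interpolates control points exactly and handles affine maps", {
  src <- rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10))

  w_id <- fit_tps(src, src)
  expect_lt(max(abs(tps_apply(w_id, rbind(c(3, 7), c(5, 5)) ) -
                    rbind(c(3, 7), c(5, 5)))), 1e-9)
  expect_lt(w_id$bending_energy, 1e-12)
  expect_lt(max(abs(w_id$W)), 1e-10)

  shift <- matrix(c(3, -2), 4, 2, byrow = TRUE)
  w_t <- fit_tps(src, src + shift)
  q <- matrix(runif(20, -5, 15), 10, 2)
  expect_lt(max(abs(tps_apply(w_t, q) - (q + rep(c(3, -2), each = 10)))), 1e-8)
  expect_lt(w_t$bending_energy, 1e-10)

  # interpolation property for a generic warp
  set.seed(4)
  tgt <- src + matrix(rnorm(8), 4, 2)
  w_g <- fit_tps(src, tgt)
  expect_lt(max(abs(tps_apply(w_g, src) - tgt)), 1e-6)
  expect_gte(w_g$bending_energy, 0)
})

test_that("TPS square-to-kite warp matches an independent dense solve", {
  src <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  tgt <- rbind(c(0, 0), c(1, -0.2), c(1.3, 1), c(-0.1, 1.2))
  w <- fit_tps(src, tgt)

  # oracle: assemble and solve the TPS system independently
  U <- function(r) ifelse(r == 0, 0, r^2 * log(r))
  K <- U(as.matrix(dist(src)))
  P <- cbind(1, src)
  L <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
  sol <- solve(L, rbind(tgt, matrix(0, 3, 2)))
  centroid <- matrix(colMeans(src), 1, 2)
  d <- sqrt(rowSums(sweep(src, 2, centroid)^2))
  expected <- cbind(1, centroid) %*% sol[5:7, ] + matrix(U(d), 1) %*% sol[1:4, ]
  expect_lt(max(abs(tps_apply(w, centroid) - expected)), 1e-8)
})

test_that("degenerate TPS control points raise a singular-system error", {
  line <- cbind(0:3, 0:3)
  expect_error(fit_tps(line, line + 1), "singular")
  dup <- rbind(c(0, 0), c(0, 0), c(1, 1), c(2, 0))
  expect_error(fit_tps(dup, dup), "singular")
})

test_that("image warping is exact for identity/translation and deterministic", {
  ph <- generate_phantom(phantom_spec(shape = c(64L, 64L), n_vertebrae = 1L,
                                      seed = 3))
  img <- ph$image
  lm <- ph$vertebrae[[1]]$landmarks
  src <- rbind(c(5, 5), c(58, 5), c(58, 58), c(5, 58), c(30, 30))

  out_id <- warp_image(img, lm, fit_tps(src, src))
  expect_lt(max(abs(out_id$image$pixels - img$pixels)), 1e-9)
  expect_lt(max(abs(out_id$landmarks$points - lm$points)), 1e-9)

  sh <- matrix(c(3, -2), 5, 2, byrow = TRUE)
  out_t <- warp_image(img, lm, fit_tps(src, src + sh))
  expect_lt(max(abs(out_t$landmarks$points - (lm$points +
             rep(c(3, -2), each = 16)))), 1e-6)
  # image content translated: compare interiors
  expect_lt(max(abs(out_t$image$pixels[20:50, 20:50] -
                    img$pixels[20:50 - (-2), 20:50 - 3])), 1e-6)

  set.seed(5)
  tgt <- src + matrix(rnorm(10, 0, 1.5), 5, 2)
  w <- fit_tps(src, tgt)
  a <- warp_image(img, lm, w)
  b <- warp_image(img, lm, w)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$landmarks$points, b$landmarks$points)
})

test_that("positive augmentation hits the requested count and seeds", {
  ph <- generate_phantom(phantom_spec(shape = c(64L, 64L), n_vertebrae = 1L,
                                      seed = 3))
  ann <- list(list(image = ph$image,
                   landmarks = ph$vertebrae[[1]]$landmarks))
  out <- generate_positives(ann, n_out = 10, seed = 2)
  expect_length(out, 10L)    # the 1-to-10 augmentation ratio

  none <- generate_positives(ann, n_out = 3,
                             jitter = list(sigma_px = 0, rot_deg = 0,
                                           scale = 0),
                             seed = 2)
  for (o in none) {
    expect_equal(o$image$pixels, ph$image$pixels)
    expect_equal(o$landmarks$points, ph$vertebrae[[1]]$landmarks$points)
  }

  again <- generate_positives(ann, n_out = 10, seed = 2)
  expect_identical(lapply(out, function(o) o$landmarks$points),
                   lapply(again, function(o) o$landmarks$points))
  expect_identical(lapply(out, function(o) o$image$pixels),
                   lapply(again, function(o) o$image$pixels))
  expect_error(generate_positives(list(), 5), "empty")
})

test_that("harmonic inpainting solves the Laplace problem", {
  img <- gray_image(matrix(runif(64, 10, 20), 8, 8))
  empty <- binary_mask(matrix(FALSE, 8, 8))
  expect_identical(inpaint(img, empty)$pixels, img$pixels)

  const <- gray_image(matrix(3, 8, 8))
  hole <- matrix(FALSE, 8, 8); hole[4:5, 4:5] <- TRUE
  expect_lt(max(abs(inpaint(const, binary_mask(hole))$pixels - 3)), 1e-6)

  # 2x2 hole: compare with the exact sparse Laplace solve
  set.seed(6)
  px <- matrix(runif(64, 0, 100), 8, 8)
  got <- inpaint(gray_image(px), binary_mask(hole), tol = 1e-8)$pixels
  idx <- which(hole)
  A <- matrix(0, 4, 4); b <- numeric(4)
  coords <- which(hole, arr.ind = TRUE)
  for (i in 1:4) {
    r <- coords[i, 1]; c <- coords[i, 2]
    nb <- rbind(c(r - 1, c), c(r + 1, c), c(r, c - 1), c(r, c + 1))
    A[i, i] <- 4
    for (j in seq_len(4)) {
      p <- nb[j, ]
      if (hole[p[1], p[2]]) {
        k <- which(coords[, 1] == p[1] & coords[, 2] == p[2])
        A[i, k] <- A[i, k] - 1
      } else b[i] <- b[i] + px[p[1], p[2]]
    }
  }
  exact <- solve(A, b)
  expect_lt(max(abs(got[idx] - exact)), 1e-3)

  # discrete maximum principle
  ring <- px[!hole]
  expect_true(all(got[idx] >= min(ring) - 1e-9 & got[idx] <= max(ring) + 1e-9))

  expect_error(inpaint(img, binary_mask(matrix(TRUE, 8, 8))), "entire image")
})

test_that("negative reconstruction removes detector responses", {
  model <- phantom_detector()
  it <- phantom_test_data()$items[[3]]
  boxes <- do.call(rbind, lapply(it$vertebrae, function(v)
    data.frame(x = v$box$x, y = v$box$y, width = v$box$width,
               height = v$box$height)))
  neg <- generate_negatives(list(it$image), list(boxes), seed = 11)[[1]]
  raw_before <- detect(it$image, model, min_neighbors = 1)
  raw_after <- detect(neg, model, min_neighbors = 1)
  hits_in_boxes <- function(d) {
    if (!nrow(d)) return(0L)
    sum(apply(vapply(seq_len(nrow(boxes)), function(i)
      vbseg:::box_iou(boxes[i, ], d), numeric(nrow(d))), 1, max) >= 0.3)
  }
  expect_lt(hits_in_boxes(raw_after), hits_in_boxes(raw_before))

  # no boxes: image untouched; same seed: identical output
  same <- generate_negatives(list(it$image), list(boxes[0, ]), seed = 11)[[1]]
  expect_identical(same$pixels, it$image$pixels)
  again <- generate_negatives(list(it$image), list(boxes), seed = 11)[[1]]
  expect_identical(neg$pixels, again$pixels)
})
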