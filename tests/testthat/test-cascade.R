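# Integral images, Haar features, AdaBoost stages, cascade training and
# multi-scale detection.

test_that("integral image rectangle sums match brute force", {
  ii <- integral_image(matrix(1, 4, 4))
  expect_equal(ii$ii[5, 5], 16)

  one <- integral_image(matrix(3.5, 2, 2))
  expect_equal(one$ii[2, 2], 3.5)

  set.seed(1)
  px <- matrix(rnorm(64), 8, 8)
  ii <- integral_image(px)
  for (x in 0:7) for (y in 0:7)
    for (w in 1:(8 - x)) for (h in 1:(8 - y))
      expect_equal(vbseg:::rect_sum(ii$ii, x, y, w, h),
                   brute_rect_sum(px, x, y, w, h), tolerance = 1e-9)
})

test_that("Haar features are zero on constants and variance-normalized", {
  pool <- haar_feature_pool(c(24L, 24L), stride = 6L, tilted = TRUE)
  expect_true(all(vbseg:::HAAR_KINDS %in% unique(pool$kind)))
  win <- bounding_box(0, 0, 24, 24)
  ii_const <- integral_image(matrix(42, 24, 24))
  for (i in seq_len(min(nrow(pool), 50)))
    expect_equal(eval_feature(pool[i, ], ii_const, win), 0)

  # edge_v on a left-0 / right-1 step: hand value from brute-force sums
  step <- matrix(0, 24, 24); step[, 13:24] <- 1
  iis <- integral_image(step)
  f <- data.frame(kind = "edge_v", x = 0, y = 0, w = 24, h = 24)
  raw <- brute_rect_sum(step, 0, 0, 12, 24) - brute_rect_sum(step, 12, 0, 12, 24)
  expect_equal(eval_feature(f, iis, win), raw / sd_pop(step))

  # affine intensity invariance
  set.seed(2)
  px <- matrix(rnorm(576), 24, 24)
  r1 <- eval_feature(f, integral_image(px), win)
  r2 <- eval_feature(f, integral_image(3 * px + 17), win)
  expect_equal(r1, r2, tolerance = 1e-9)

  expect_error(eval_feature(f, iis, bounding_box(10, 10, 24, 24)),
               "out of image bounds")
})

test_that("AdaBoost stage separates a separable toy with one stump", {
  # single informative feature: positives > 0, negatives < 0
  resp <- cbind(c(1, 2, 3, -1, -2, -3), c(0.1, -0.2, 0.3, 0.2, -0.1, 0.3))
  labels <- c(1, 1, 1, -1, -1, -1)
  feats <- data.frame(kind = "edge_v", x = 0, y = 0, w = 4, h = 4)[c(1, 1), ]
  stage <- train_stage(feats, NULL, labels, rep(1 / 6, 6),
                       params = list(max_stumps = 5, min_hit_rate = 0.99,
                                     max_false_alarm = 0.5,
                                     window = c(4L, 4L)),
                       responses = resp)
  expect_equal(nrow(stage$stumps), 1L)
  expect_equal(stage$hit_rate, 1)
  expect_equal(stage$false_alarm, 0)
  expect_equal(sum(stage$weights), 1, tolerance = 1e-12)
})

test_that("stump selection and weight update match the exhaustive oracle", {
  # 4 samples, one inseparable: feature 1 = (1, 2, 3, 4), labels (+,+,-,+)
  resp <- cbind(c(1, 2, 3, 4), c(0.5, 1.5, 2.5, 3.5))
  labels <- c(1L, 1L, -1L, 1L)
  w <- rep(0.25, 4)

  # oracle: enumerate every feature, midpoint threshold and polarity
  best <- list(err = Inf)
  for (f in 1:2) {
    v <- resp[, f]
    thrs <- c(min(v) - 1, sort(v)[-length(v)] + diff(sort(v)) / 2)
    for (thr in thrs) for (pol in c(-1, 1)) {
      pred <- ifelse(pol * (v - thr) > 0, 1L, -1L)
      err <- sum(w[pred != labels])
      if (err < best$err) best <- list(err = err, f = f, thr = thr, pol = pol)
    }
  }
  ord <- apply(resp, 2, order) - 1L
  storage.mode(ord) <- "integer"
  st <- vbseg:::cpp_best_stump(resp, ord, w, labels)
  expect_equal(st$error, best$err, tolerance = 1e-12)

  # updated weights from the chosen stump equal the hand update
  alpha <- 0.5 * log((1 - st$error) / st$error)
  pred <- ifelse(st$polarity * (resp[, st$feature] - st$threshold) > 0, 1L, -1L)
  w_new <- w * exp(alpha * (pred != labels))
  w_new <- w_new / sum(w_new)
  stage <- train_stage(NULL, NULL, labels, w,
                       params = list(max_stumps = 1, min_hit_rate = 0.75,
                                     max_false_alarm = 0.5,
                                     window = c(4L, 4L)),
                       responses = resp)
  expect_equal(stage$weights, w_new, tolerance = 1e-12)
})

test_that("unlearnable stages raise a training error", {
  # both features are pure noise w.r.t. labels (symmetric XOR-like setup)
  resp <- cbind(c(0, 0, 1, 1), c(0, 1, 0, 1))
  labels <- c(1L, -1L, -1L, 1L)
  expect_error(
    train_stage(NULL, NULL, labels, rep(0.25, 4),
                params = list(max_stumps = 3, min_hit_rate = 0.9,
                              max_false_alarm = 0.5, window = c(4L, 4L)),
                responses = resp),
    "unlearnable")
})

test_that("cascade training logs meet the hit-rate target and is deterministic", {
  model <- phantom_detector()
  for (lg in model$meta$log)
    expect_gte(lg$hit_rate, model$meta$params$min_hit_rate)

  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  save_cascade(model, f1)
  tr <- detector_training_set(phantom_train_data())
  model2 <- suppressWarnings(
    train_cascade(tr$positives, tr$negatives, params = list(seed = 1)))
  save_cascade(model2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))

  # serialization round trip preserves behaviour
  back <- load_cascade(f1)
  it <- phantom_test_data()$items[[1]]
  expect_equal(detect(it$image, back), detect(it$image, model))
})

test_that("cumulative false alarm on random negatives decays with stages", {
  model <- phantom_detector()
  tr <- detector_training_set(phantom_train_data())
  set.seed(42)
  neg <- tr$negatives[[1]]$pixels
  crops <- vapply(1:500, function(i) {
    y <- sample.int(nrow(neg) - 24L, 1L); x <- sample.int(ncol(neg) - 24L, 1L)
    as.numeric(neg[y:(y + 23L), x:(x + 23L)])
  }, numeric(576))
  rate <- mean(vbseg:::cascade_accept(model, crops))
  expect_lte(rate, model$meta$params$max_false_alarm^length(model$stages))
})

test_that("detection finds phantom vertebrae and respects the contracts", {
  model <- phantom_detector()
  blank <- gray_image(matrix(5, 120, 120))
  expect_equal(nrow(detect(blank, model)), 0L)

  it <- phantom_test_data()$items[[1]]
  d3 <- detect(it$image, model, min_neighbors = 3)
  d1 <- detect(it$image, model, min_neighbors = 1)
  expect_gte(nrow(d1), nrow(d3))   # min_neighbors is a monotone filter

  # every ground-truth vertebra recovered at IoU >= 0.5
  for (v in it$vertebrae)
    expect_gte(max(vbseg:::box_iou(v$box, d3)), 0.5)
})

test_that("detection is translation-covariant up to the scan step", {
  model <- phantom_detector()
  it <- phantom_test_data()$items[[2]]
  px <- it$image$pixels
  shift <- 2L
  px2 <- px
  px2[(shift + 1):nrow(px), (shift + 1):ncol(px)] <-
    px[1:(nrow(px) - shift), 1:(ncol(px) - shift)]
  d1 <- filter_by_size(detect(it$image, model))
  d2 <- filter_by_size(detect(gray_image(px2, it$image$spacing), model))
  expect_equal(nrow(d1), nrow(d2))
  d1 <- d1[order(d1$y), ]; d2 <- d2[order(d2$y), ]
  expect_lt(max(abs(d2$x - d1$x - shift)), 4)
  expect_lt(max(abs(d2$y - d1$y - shift)), 4)
})

test_that("the size filter removes area outliers only", {
  expect_equal(nrow(filter_by_size(tibble::tibble(
    x = numeric(0), y = numeric(0), width = numeric(0),
    height = numeric(0), score = numeric(0)))), 0L)

  boxes <- tibble::tibble(x = c(0, 50, 100, 150), y = 0,
                          width = c(10, 11, 9, 20),
                          height = c(10, 10, 10, 20), score = 1)
  kept <- filter_by_size(boxes)           # areas 100, 110, 90, 400
  expect_equal(nrow(kept), 3L)
  expect_false(400 %in% (kept$width * kept$height))

  same <- tibble::tibble(x = c(0, 30, 60), y = 0, width = 10, height = 10,
                         score = 1)
  expect_equal(filter_by_size(same), same)

  two <- boxes[1:2, ]
  expect_equal(filter_by_size(two), two)  # < 3 boxes: unchanged
})
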