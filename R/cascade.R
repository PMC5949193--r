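# Vertebra detection: integral images, extended Haar-like features,
# AdaBoost stages, attentional cascade, multi-scale sliding-window
# detection and the size-constraint post-filter.

HAAR_KINDS <- c("edge_h", "edge_v", "line_h", "line_v",
                "center_surround", "tilted_edge")

#' Integral image (summed-area tables)
#'
#' Returns padded cumulative-sum tables of the image and of its square,
#' so any rectangle sum costs four lookups. Entry `(r+1, c+1)` equals the
#' sum over pixel rows `0..r-? ` -- concretely `ii[r+1, c+1]` is the sum
#' of pixels in rows `0..r`, columns `0..c` (0-based).
#'
#' @param image a [gray_image()] or numeric matrix.
#' @return list with `ii` and `ii2`, each `(nrow+1) x (ncol+1)`.
#' @export
integral_image <- function(image) {
  px <- if (inherits(image, "gray_image")) image$pixels else as.matrix(image)
  pad <- function(m) {
    out <- matrix(0, nrow(m) + 1, ncol(m) + 1)
    out[-1, -1] <- t(apply(apply(m, 2, cumsum), 1, cumsum))
    out
  }
  list(ii = pad(px), ii2 = pad(px^2))
}

# sum over rows [y, y+h), cols [x, x+w) (0-based) from a padded table
rect_sum <- function(ii, x, y, w, h) {
  ii[y + h + 1, x + w + 1] - ii[y + 1, x + w + 1] -
    ii[y + h + 1, x + 1] + ii[y + 1, x + 1]
}

#' Enumerate the Haar-like feature pool for a detection window
#'
#' Six kinds of zero-sum weighted rectangle combinations: horizontal and
#' vertical two-rectangle edges, three-rectangle lines, a
#' center-surround, and (optionally) a diagonally offset rectangle pair
#' standing in for 45-degree structure. Positions are subsampled on a
#' stride grid to bound training cost.
#'
#' @param win window size `c(h, w)` in pixels.
#' @param stride position grid stride in pixels.
#' @param tilted include the diagonal-pair kind.
#' @return data.frame with columns `kind, x, y, w, h` (window-relative,
#'   0-based).
#' @export
haar_feature_pool <- function(win = c(24L, 24L), stride = 3L, tilted = FALSE) {
  win_h <- win[1]; win_w <- win[2]
  sizes4 <- seq(4L, 24L, by = 4L)
  sizes6 <- seq(6L, 24L, by = 6L)
  kinds <- list(
    edge_h = list(w = sizes4, h = sizes4),
    edge_v = list(w = sizes4, h = sizes4),
    line_h = list(w = sizes4, h = sizes6),
    line_v = list(w = sizes6, h = sizes4),
    center_surround = list(w = sizes4, h = sizes4)
  )
  if (tilted) kinds$tilted_edge <- list(w = sizes4, h = sizes4)
  out <- list()
  for (kn in names(kinds)) {
    for (w in kinds[[kn]]$w) for (h in kinds[[kn]]$h) {
      if (w > win_w || h > win_h) next
      xs <- seq(0L, win_w - w, by = stride)
      ys <- seq(0L, win_h - h, by = stride)
      g <- expand.grid(x = xs, y = ys)
      out[[length(out) + 1L]] <- data.frame(kind = kn, x = g$x, y = g$y,
                                            w = w, h = h)
    }
  }
  do.call(rbind, out)
}

feats_to_matrix <- function(features) {
  m <- cbind(match(features$kind, HAAR_KINDS) - 1L,
             as.integer(features$x), as.integer(features$y),
             as.integer(features$w), as.integer(features$h))
  storage.mode(m) <- "integer"
  m
}

#' Evaluate one Haar feature on an image window
#'
#' The weighted rectangle sum is divided by the window's intensity
#' standard deviation (variance normalization); a zero-variance window
#' returns 0, and an affine intensity change leaves the response
#' unchanged.
#'
#' @param feature one row of [haar_feature_pool()] (or an equivalent
#'   one-row data.frame).
#' @param integral result of [integral_image()].
#' @param window a [bounding_box()] placing the detection window; its
#'   size must equal the window the feature pool was built for.
#' @return scalar response.
#' @export
eval_feature <- function(feature, integral, window) {
  ii <- integral$ii; ii2 <- integral$ii2
  nr <- nrow(ii) - 1L; nc <- ncol(ii) - 1L
  wx <- window$x; wy <- window$y; ww <- window$width; wh <- window$height
  if (wx < 0 || wy < 0 || wx + ww > nc || wy + wh > nr)
    stop("eval_feature: window out of image bounds")
  area <- ww * wh
  tot <- rect_sum(ii, wx, wy, ww, wh)
  tot2 <- rect_sum(ii2, wx, wy, ww, wh)
  v <- tot2 / area - (tot / area)^2
  if (v <= 1e-12) return(0)
  fx <- wx + feature$x; fy <- wy + feature$y
  fw <- feature$w; fh <- feature$h
  raw <- switch(as.character(feature$kind),
    edge_h = rect_sum(ii, fx, fy, fw, fh / 2) -
             rect_sum(ii, fx, fy + fh / 2, fw, fh / 2),
    edge_v = rect_sum(ii, fx, fy, fw / 2, fh) -
             rect_sum(ii, fx + fw / 2, fy, fw / 2, fh),
    line_h = rect_sum(ii, fx, fy, fw, fh) -
             3 * rect_sum(ii, fx, fy + fh / 3, fw, fh / 3),
    line_v = rect_sum(ii, fx, fy, fw, fh) -
             3 * rect_sum(ii, fx + fw / 3, fy, fw / 3, fh),
    center_surround = rect_sum(ii, fx, fy, fw, fh) -
             4 * rect_sum(ii, fx + fw / 4, fy + fh / 4, fw / 2, fh / 2),
    tilted_edge = rect_sum(ii, fx, fy, fw / 2, fh / 2) -
             rect_sum(ii, fx + fw / 2, fy + fh / 2, fw / 2, fh / 2),
    stop("eval_feature: unknown kind ", feature$kind))
  raw / sqrt(v)
}

#' Train one boosted stage with discrete AdaBoost over decision stumps
#'
#' Iteratively picks the stump minimizing weighted error (exhaustive over
#' features and thresholds), updates weights
#' `w <- w * exp(alpha * [misclassified])` and renormalizes. Stumps are
#' added until the stage reaches `min_hit_rate` with training false
#' alarm `<= max_false_alarm` (the stage threshold is lowered to meet
#' the hit rate) or `max_stumps` is hit.
#'
#' @param features feature pool data.frame.
#' @param samples `(win_h*win_w) x n` matrix of window crops, or `NULL`
#'   when `responses` is given.
#' @param labels integer vector in `{-1, +1}`.
#' @param weights sample weights summing to 1.
#' @param params list: `max_stumps`, `min_hit_rate`, `max_false_alarm`,
#'   `window`.
#' @param responses optional precomputed `n x F` response matrix.
#' @return An object of class `boosted_stage`.
#' @export
train_stage <- function(features, samples, labels, weights,
                        params = list(max_stumps = 25L, min_hit_rate = 0.995,
                                      max_false_alarm = 0.5,
                                      window = c(24L, 24L)),
                        responses = NULL) {
  labels <- as.integer(labels)
  if (!any(labels > 0) || !any(labels < 0))
    stop("train_stage: need at least one positive and one negative sample")
  if (is.null(responses)) {
    responses <- cpp_feature_responses(samples, params$window[1],
                                       params$window[2],
                                       feats_to_matrix(features))
  }
  n <- nrow(responses)
  w <- weights / sum(weights)
  ord <- apply(responses, 2, order) - 1L
  storage.mode(ord) <- "integer"
  stumps <- list()
  scores <- numeric(n)
  stage_threshold <- 0
  hit <- 0; fa <- 1
  pos <- labels > 0
  repeat {
    st <- cpp_best_stump(responses, ord, w, labels)
    if (st$error >= 0.5 - 1e-9) {
      if (!length(stumps)) stop("train_stage: unlearnable stage ",
                                "(no stump beats weighted error 0.5)")
      break
    }
    err <- max(st$error, 1e-10)
    alpha <- 0.5 * log((1 - err) / err)
    v <- responses[, st$feature]
    pred <- ifelse(st$polarity * (v - st$threshold) > 0, 1L, -1L)
    stumps[[length(stumps) + 1L]] <-
      data.frame(feature = st$feature, threshold = st$threshold,
                 polarity = st$polarity, left = -alpha, right = alpha,
                 alpha = alpha)
    scores <- scores + alpha * pred
    mis <- pred != labels
    w <- w * exp(alpha * mis)
    w <- w / sum(w)
    # pick the highest threshold still meeting the hit-rate target
    ps <- sort(scores[pos])
    k <- max(1L, floor((1 - params$min_hit_rate) * length(ps)) + 1L)
    stage_threshold <- ps[k] - 1e-9
    hit <- mean(scores[pos] >= stage_threshold)
    fa <- mean(scores[!pos] >= stage_threshold)
    if ((hit >= params$min_hit_rate && fa <= params$max_false_alarm) ||
        length(stumps) >= params$max_stumps) break
  }
  structure(list(stumps = do.call(rbind, stumps),
                 stage_threshold = stage_threshold,
                 hit_rate = hit, false_alarm = fa,
                 weights = w),
            class = "boosted_stage")
}

stage_scores <- function(stage, responses) {
  s <- numeric(nrow(responses))
  for (i in seq_len(nrow(stage$stumps))) {
    st <- stage$stumps[i, ]
    v <- responses[, st$feature]
    s <- s + ifelse(st$polarity * (v - st$threshold) > 0, st$right, st$left)
  }
  s
}

# accepted-by-all-stages flag for window crops (samples: npix x n);
# only the features referenced by stumps are evaluated
cascade_accept <- function(model, samples) {
  used <- sort(unique(unlist(lapply(model$stages,
                                    function(s) s$stumps$feature))))
  remap <- match(seq_len(nrow(model$features)), used)
  feats <- feats_to_matrix(model$features[used, , drop = FALSE])
  resp <- cpp_feature_responses(samples, model$window[1], model$window[2],
                                feats)
  keep <- rep(TRUE, ncol(samples))
  for (stage in model$stages) {
    if (!any(keep)) break
    st <- stage$stumps
    st$feature <- remap[st$feature]
    s <- stage_scores(list(stumps = st), resp)
    keep <- keep & (s >= stage$stage_threshold)
  }
  keep
}

crop_resize <- function(px, x, y, w, h, out_h, out_w) {
  x0 <- max(0L, as.integer(round(x))); y0 <- max(0L, as.integer(round(y)))
  x1 <- min(ncol(px), x0 + as.integer(round(w)))
  y1 <- min(nrow(px), y0 + as.integer(round(h)))
  sub <- px[(y0 + 1):y1, (x0 + 1):x1, drop = FALSE]
  cpp_resize_bilinear(sub, out_h, out_w)
}

#' Train an attentional cascade of boosted classifiers
#'
#' Stage `k` trains on all positives plus negatives still accepted by
#' stages `1..k-1`, mined by seeded random window sampling from the
#' negative images. Training stops early (with a warning) when no false
#' positives can be mined; the per-stage hit/false-alarm log is kept in
#' the model metadata.
#'
#' @param positives list of window-sized crops (matrices or
#'   [gray_image()]s); larger crops are resampled to the window.
#' @param negatives list of negative sources, each either a vertebra-free
#'   image (matrix or [gray_image()]) or a `list(image =, avoid =)` pair
#'   whose `avoid` boxes (data.frame `x, y, width, height`) mark object
#'   locations that mined windows must not overlap (IoU < 0.2) --
#'   allowing annotated originals to serve as hard-negative sources.
#' @param params list: `n_stages`, `min_hit_rate`, `max_false_alarm`,
#'   `window = c(h, w)`, `feature_stride`, `max_stumps`, `tilted`,
#'   `n_neg`, `seed`.
#' @return An object of class `cascade_model`.
#' @export
train_cascade <- function(positives, negatives, params = list()) {
  p <- modifyList(list(n_stages = 12L, min_hit_rate = 0.995,
                       max_false_alarm = 0.5, window = c(24L, 24L),
                       feature_stride = 3L, max_stumps = 25L,
                       tilted = FALSE, n_neg = NULL, seed = 1L), params)
  win_h <- p$window[1]; win_w <- p$window[2]
  as_px <- function(im) if (inherits(im, "gray_image")) im$pixels else as.matrix(im)
  pos_mat <- vapply(positives, function(im) {
    m <- as_px(im)
    if (!all(dim(m) == c(win_h, win_w)))
      m <- cpp_resize_bilinear(m, win_h, win_w)
    as.numeric(m)
  }, numeric(win_h * win_w))
  neg_px <- lapply(negatives, function(n) {
    if (is.list(n) && !inherits(n, "gray_image") && !is.null(n$image))
      list(px = as_px(n$image), avoid = n$avoid)
    else list(px = as_px(n), avoid = NULL)
  })
  n_pos <- ncol(pos_mat)
  n_neg <- if (is.null(p$n_neg)) max(2L * n_pos, 200L) else p$n_neg

  features <- haar_feature_pool(c(win_h, win_w), stride = p$feature_stride,
                                tilted = p$tilted)
  feats <- feats_to_matrix(features)
  set.seed(p$seed)

  model <- structure(list(window = c(win_h, win_w), features = features,
                          stages = list(),
                          meta = list(n_pos = n_pos, n_neg = n_neg,
                                      params = p, log = list())),
                     class = "cascade_model")

  sample_neg_window <- function() {
    for (try in 1:20) {
      i <- sample.int(length(neg_px), 1L)
      m <- neg_px[[i]]$px
      smax <- min(nrow(m) / win_h, ncol(m) / win_w)
      s <- runif(1, 1, max(1, min(smax, 2.5)))
      h <- floor(win_h * s); w <- floor(win_w * s)
      y <- sample.int(nrow(m) - h + 1L, 1L) - 1L
      x <- sample.int(ncol(m) - w + 1L, 1L) - 1L
      av <- neg_px[[i]]$avoid
      if (!is.null(av) && nrow(av) &&
          max(box_iou(list(x = x, y = y, width = w, height = h), av)) >= 0.2)
        next
      return(as.numeric(crop_resize(m, x, y, w, h, win_h, win_w)))
    }
    # fall back to the first unconstrained source
    m <- neg_px[[1]]$px
    as.numeric(crop_resize(m, 0, 0, win_w, win_h, win_h, win_w))
  }

  mine_negatives <- function(n_needed, budget = 50L * n_needed) {
    out <- matrix(0, win_h * win_w, 0)
    tried <- 0L
    batch <- max(256L, n_needed)
    while (ncol(out) < n_needed && tried < budget) {
      cand <- vapply(seq_len(batch), function(i) sample_neg_window(),
                     numeric(win_h * win_w))
      tried <- tried + batch
      keep <- if (length(model$stages)) cascade_accept(model, cand)
              else rep(TRUE, ncol(cand))
      if (any(keep)) out <- cbind(out, cand[, keep, drop = FALSE])
      else if (tried >= 10L * batch && ncol(out) == 0L) break
    }
    if (ncol(out) > n_needed) out <- out[, seq_len(n_needed), drop = FALSE]
    out
  }

  for (k in seq_len(p$n_stages)) {
    neg_mat <- mine_negatives(n_neg)
    if (ncol(neg_mat) == 0L) {
      warning("train_cascade: no false positives minable after stage ",
              k - 1L, "; stopping early")
      break
    }
    samples <- cbind(pos_mat, neg_mat)
    labels <- c(rep(1L, n_pos), rep(-1L, ncol(neg_mat)))
    weights <- rep(1 / length(labels), length(labels))
    stage <- train_stage(features, samples, labels, weights,
                         params = list(max_stumps = p$max_stumps,
                                       min_hit_rate = p$min_hit_rate,
                                       max_false_alarm = p$max_false_alarm,
                                       window = c(win_h, win_w)))
    stage$weights <- NULL
    model$stages[[k]] <- stage
    model$meta$log[[k]] <- list(stage = k, n_stumps = nrow(stage$stumps),
                                hit_rate = stage$hit_rate,
                                false_alarm = stage$false_alarm,
                                n_neg_mined = ncol(neg_mat))
  }
  if (!length(model$stages))
    stop("train_cascade: no stage could be trained")
  model
}

#' @export
print.cascade_model <- function(x, ...) {
  cat(sprintf("<cascade_model %dx%d window, %d stages, %d stumps>\n",
              x$window[1], x$window[2], length(x$stages),
              sum(vapply(x$stages, function(s) nrow(s$stumps), 0L))))
  invisible(x)
}

flatten_stages <- function(model) {
  sizes <- vapply(model$stages, function(s) nrow(s$stumps), 0L)
  all_st <- do.call(rbind, lapply(model$stages, `[[`, "stumps"))
  list(sizes = as.integer(sizes),
       thr = vapply(model$stages, `[[`, 0, "stage_threshold"),
       feat = as.integer(all_st$feature),
       sthr = all_st$threshold,
       pol = as.integer(all_st$polarity),
       left = all_st$left, right = all_st$right)
}

box_iou <- function(b1, b2) {
  x1 <- pmax(b1$x, b2$x); y1 <- pmax(b1$y, b2$y)
  x2 <- pmin(b1$x + b1$width, b2$x + b2$width)
  y2 <- pmin(b1$y + b1$height, b2$y + b2$height)
  inter <- pmax(0, x2 - x1) * pmax(0, y2 - y1)
  union <- b1$width * b1$height + b2$width * b2$height - inter
  ifelse(union > 0, inter / union, 0)
}

#' Multi-scale sliding-window detection
#'
#' Runs the cascade over an image pyramid (powers of `scale_factor`),
#' maps accepted windows back to original coordinates, groups raw hits
#' whose IoU is at least 0.3 by connected components, discards groups
#' with fewer than `min_neighbors` raw hits, and reports each surviving
#' group's mean box with the raw-hit count as score.
#'
#' @param image a [gray_image()].
#' @param model a [train_cascade()] model.
#' @param scale_factor pyramid scale step (> 1).
#' @param step_px sliding-window step at each level.
#' @param min_neighbors minimum raw hits per reported detection.
#' @return tibble with columns `x, y, width, height, score` (possibly
#'   zero rows).
#' @export
detect <- function(image, model, scale_factor = 1.1, step_px = 2L,
                   min_neighbors = 3L) {
  stopifnot(inherits(image, "gray_image"), inherits(model, "cascade_model"))
  px <- image$pixels
  win_h <- model$window[1]; win_w <- model$window[2]
  if (nrow(px) < win_h || ncol(px) < win_w)
    stop("detect: image smaller than the detection window")
  feats <- feats_to_matrix(model$features)
  fl <- flatten_stages(model)
  raw <- list()
  s <- 1
  repeat {
    nr <- round(nrow(px) / s); nc <- round(ncol(px) / s)
    if (nr < win_h || nc < win_w) break
    scaled <- if (s == 1) px else cpp_resize_bilinear(px, nr, nc)
    hits <- cpp_scan_cascade(scaled, win_h, win_w, as.integer(step_px),
                             feats, fl$feat, fl$sthr, fl$pol,
                             fl$left, fl$right, fl$sizes, fl$thr)
    if (nrow(hits)) {
      sc <- (nrow(px) - 1) / max(nr - 1, 1)   # actual realized scale
      raw[[length(raw) + 1L]] <-
        data.frame(x = hits[, 1] * sc, y = hits[, 2] * sc,
                   width = win_w * sc, height = win_h * sc)
    }
    s <- s * scale_factor
  }
  empty <- tibble::tibble(x = numeric(0), y = numeric(0),
                          width = numeric(0), height = numeric(0),
                          score = numeric(0))
  if (!length(raw)) return(empty)
  rb <- do.call(rbind, raw)
  n <- nrow(rb)
  # union-find over the IoU >= 0.3 graph
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (i in seq_len(n)) {
    iou <- box_iou(rb[i, ], rb)
    for (j in which(iou >= 0.3)) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  comp <- vapply(seq_len(n), find, 0L)
  out <- lapply(split(seq_len(n), comp), function(idx) {
    if (length(idx) < min_neighbors) return(NULL)
    data.frame(x = mean(rb$x[idx]), y = mean(rb$y[idx]),
               width = mean(rb$width[idx]), height = mean(rb$height[idx]),
               score = length(idx))
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(empty)
  tibble::as_tibble(out[order(out$y, out$x), , drop = FALSE])
}

#' Remove size outliers among detections
#'
#' Keeps boxes whose area lies within `[0.5, 2]` times the median area.
#' With fewer than 3 boxes the input is returned unchanged.
#'
#' @param detections tibble from [detect()].
#' @return filtered tibble.
#' @export
filter_by_size <- function(detections) {
  if (is.null(detections) || nrow(detections) < 3L) return(detections)
  area <- detections$width * detections$height
  m <- stats::median(area)
  detections[area >= 0.5 * m & area <= 2.0 * m, , drop = FALSE]
}

#' Save / load a cascade model as a JSON container
#'
#' @param model a `cascade_model`.
#' @param path file path.
#' @return `load_cascade` returns the model; `save_cascade` the path,
#'   invisibly.
#' @export
save_cascade <- function(model, path) {
  stopifnot(inherits(model, "cascade_model"))
  obj <- list(
    container = "vbseg-cascade", version = 1L,
    window = model$window,
    features = as.list(model$features),
    stages = lapply(model$stages, function(s)
      list(stumps = as.list(s$stumps), stage_threshold = s$stage_threshold,
           hit_rate = s$hit_rate, false_alarm = s$false_alarm)),
    meta = model$meta[c("n_pos", "n_neg")],
    params = model$meta$params[c("n_stages", "min_hit_rate",
                                 "max_false_alarm", "feature_stride",
                                 "seed")])
  save_model_json(obj, path)
}

#' @rdname save_cascade
#' @export
load_cascade <- function(path) {
  obj <- load_model_json(path)
  if (!identical(obj$container, "vbseg-cascade"))
    stop("load_cascade: not a cascade model container: ", path)
  structure(list(
    window = as.integer(unlist(obj$window)),
    features = as.data.frame(obj$features, stringsAsFactors = FALSE),
    stages = lapply(obj$stages, function(s)
      structure(list(stumps = as.data.frame(s$stumps),
                     stage_threshold = s$stage_threshold,
                     hit_rate = s$hit_rate, false_alarm = s$false_alarm),
                class = "boosted_stage")),
    meta = list(n_pos = obj$meta$n_pos, n_neg = obj$meta$n_neg,
                params = obj$params)),
    class = "cascade_model")
}
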