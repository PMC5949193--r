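# Shared fixtures and independent oracles. Heavy artifacts (the phantom
# training set, the trained detector, the AAM fixture) are built once
# per test run and cached.

.vbseg_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .vbseg_cache))
    assign(name, force(expr), envir = .vbseg_cache)
  get(name, envir = .vbseg_cache)
}

phantom_train_data <- function() {
  cached("train50", generate_dataset(50, phantom_spec(), seed = 11))
}

phantom_test_data <- function() {
  cached("test10", generate_dataset(10, phantom_spec(), seed = 99))
}

phantom_detector <- function() {
  cached("detector", {
    tr <- detector_training_set(phantom_train_data())
    suppressWarnings(
      train_cascade(tr$positives, tr$negatives, params = list(seed = 1)))
  })
}

aam_fixture <- function() {
  cached("aam", {
    ds <- generate_dataset(12, phantom_spec(), seed = 11)
    pairs <- dataset_pairs(ds)
    model <- suppressWarnings(train_aam(pairs[1:40]))
    list(model = model, train = pairs[1:40], test = pairs[41:60])
  })
}

# ---- minimal explicit-VR little-endian DICOM writer (fixtures only) ---

dcm_w_u16 <- function(x) as.raw(c(x %% 256, x %/% 256))
dcm_w_u32 <- function(x) as.raw(c(x %% 256, (x %/% 256) %% 256,
                                  (x %/% 65536) %% 256,
                                  (x %/% 16777216) %% 256))

dcm_elem <- function(group, elem, vr, bytes) {
  if (length(bytes) %% 2L == 1L) bytes <- c(bytes, as.raw(0x20))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(dcm_w_u16(group), dcm_w_u16(elem), charToRaw(vr), as.raw(c(0, 0)),
      dcm_w_u32(length(bytes)), bytes)
  } else {
    c(dcm_w_u16(group), dcm_w_u16(elem), charToRaw(vr),
      dcm_w_u16(length(bytes)), bytes)
  }
}

write_mini_dicom <- function(path, pixels, spacing = NULL,
                             slope = NULL, intercept = NULL) {
  pixels <- as.matrix(pixels)
  body <- c(
    dcm_elem(0x0002, 0x0010, "UI",
             charToRaw("1.2.840.10008.1.2.1")),
    dcm_elem(0x0028, 0x0010, "US", dcm_w_u16(nrow(pixels))),
    dcm_elem(0x0028, 0x0011, "US", dcm_w_u16(ncol(pixels))))
  if (!is.null(spacing))
    body <- c(body, dcm_elem(0x0028, 0x0030, "DS",
                             charToRaw(paste(spacing, collapse = "\\"))))
  body <- c(body,
    dcm_elem(0x0028, 0x0100, "US", dcm_w_u16(16)),
    dcm_elem(0x0028, 0x0103, "US", dcm_w_u16(0)))
  if (!is.null(intercept))
    body <- c(body, dcm_elem(0x0028, 0x1052, "DS",
                             charToRaw(as.character(intercept))))
  if (!is.null(slope))
    body <- c(body, dcm_elem(0x0028, 0x1053, "DS",
                             charToRaw(as.character(slope))))
  pix <- writeBin(as.integer(t(pixels)), raw(), size = 2, endian = "little")
  body <- c(body, dcm_elem(0x7fe0, 0x0010, "OW", pix))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128), charToRaw("DICM"), body), con)
  invisible(path)
}

# ---- independent oracles ----------------------------------------------

sd_pop <- function(x) sqrt(mean(x^2) - mean(x)^2)

square_mask <- function(nr, nc, r0, c0, h, w) {
  m <- matrix(FALSE, nr, nc)
  m[(r0 + 1):(r0 + h), (c0 + 1):(c0 + w)] <- TRUE
  binary_mask(m)
}

brute_rect_sum <- function(px, x, y, w, h) {
  sum(px[(y + 1):(y + h), (x + 1):(x + w)])
}

# direct (slow) selective Gaussian for cross-checking the compiled path
selective_gaussian_oracle <- function(px, tol, sigma) {
  nr <- nrow(px); nc <- ncol(px)
  rad <- max(1, ceiling(3 * sigma))
  out <- px
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    v0 <- px[r, c]
    sw <- 0; sv <- 0; any_n <- FALSE
    for (dr in -rad:rad) for (dc in -rad:rad) {
      rr <- r + dr; cc <- c + dc
      if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
      if (dr == 0 && dc == 0) next
      if (abs(px[rr, cc] - v0) < tol[r, c]) {
        w <- exp(-0.5 * (dr^2 + dc^2) / sigma^2)
        sw <- sw + w; sv <- sv + w * px[rr, cc]
        any_n <- TRUE
      }
    }
    if (any_n) out[r, c] <- (sv + v0) / (sw + 1)
  }
  out
}

# even-odd point-in-polygon with the same "crossings at x <= c" rule
point_in_polygon_oracle <- function(poly, r, c) {
  n <- nrow(poly)
  cnt <- 0L
  for (i in seq_len(n)) {
    j <- i %% n + 1L
    y1 <- poly[i, 2]; y2 <- poly[j, 2]
    if ((y1 > r) == (y2 > r)) next
    xc <- poly[i, 1] + (r - y1) * (poly[j, 1] - poly[i, 1]) / (y2 - y1)
    if (xc <= c) cnt <- cnt + 1L
  }
  cnt %% 2L == 1L
}

# from-scratch two-way ANOVA ICC oracle (explicit sums of squares)
icc_oracle <- function(x, y) {
  n <- length(x); k <- 2
  dat <- cbind(x, y)
  gm <- mean(dat)
  ss_row <- k * sum((rowMeans(dat) - gm)^2)
  ss_col <- n * sum((colMeans(dat) - gm)^2)
  ss_tot <- sum((dat - gm)^2)
  ss_err <- ss_tot - ss_row - ss_col
  msr <- ss_row / (n - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  msc <- ss_col / (k - 1)
  list(single = (msr - mse) / (msr + (k - 1) * mse),
       average = (msr - mse) / msr,
       single_agreement = (msr - mse) / (msr + (k - 1) * mse +
                                         k / n * (msc - mse)))
}

box_list <- function(b) list(x = b$x, y = b$y, width = b$width,
                             height = b$height)

detection_stats <- function(items, model, min_neighbors = 3L) {
  tot <- 0L; found <- 0L; fp <- 0L
  for (it in items) {
    det <- filter_by_size(detect(it$image, model,
                                 min_neighbors = min_neighbors))
    gtb <- lapply(it$vertebrae, function(v) v$box)
    for (g in gtb) {
      tot <- tot + 1L
      if (nrow(det) && max(vbseg:::box_iou(g, det)) >= 0.5)
        found <- found + 1L
    }
    if (nrow(det)) {
      best <- apply(vapply(gtb, function(g) vbseg:::box_iou(g, det),
                           numeric(nrow(det))), 1, max)
      fp <- fp + sum(best < 0.5)
    }
  }
  list(recall = found / tot, fp_per_image = fp / length(items),
       n_vertebrae = tot)
}
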