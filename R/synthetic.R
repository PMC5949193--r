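# Seeded spine-slice phantom generator: a gently curved column of bright
# vertebral bodies over darker discs and background, a bright fat band
# at the skin side, a multiplicative exponential bias field, additive
# Gaussian noise, and exact per-vertebra ground truth (16-point landmark
# sets, bounding boxes, body masks).

#' The 16-point vertebral body landmark template (unit frame)
#'
#' Four rounded-corner points plus three equally spaced points per edge
#' of the body outline, ordered clockwise from the anterior-superior
#' corner. The centroid sits at (0.5, 0.5). This fixed ordering is the
#' template convention used by the shape model and the contour module.
#'
#' @param corner_inset how far (unit frame) the corner points are pulled
#'   inward along both axes, producing the rounded-corner look.
#' @return A [landmark_set()] in the unit square frame.
#' @export
landmark_template <- function(corner_inset = 0.05) {
  ci <- corner_inset
  e <- c(0.275, 0.5, 0.725)
  pts <- rbind(
    c(ci, ci),                            # anterior-superior corner
    cbind(e, 0),                          # superior edge
    c(1 - ci, ci),                        # posterior-superior corner
    cbind(1, e),                          # posterior edge
    c(1 - ci, 1 - ci),                    # posterior-inferior corner
    cbind(rev(e), 1),                     # inferior edge
    c(ci, 1 - ci),                        # anterior-inferior corner
    cbind(0, rev(e)))                     # anterior edge
  landmark_set(pts, frame = "unit-template")
}

#' Phantom specification
#'
#' Defaults emulate a sagittal lumbar slice at desk scale: a 256 x 256
#' grid at 0.7 mm/px with five bright vertebral bodies (about
#' 34 x 26 px) stacked along a gently curved column, darker
#' intervertebral discs, a spinal-canal band, a bright subcutaneous fat
#' band at the left border, an exponential depth bias and additive
#' Gaussian noise.
#'
#' @param shape image `c(nrow, ncol)`.
#' @param n_vertebrae number of bodies.
#' @param vert_size `c(h, w)` body size in px.
#' @param jitter per-vertebra similarity jitter:
#'   `trans_px`, `rot_deg`, `scale`.
#' @param tps_sigma smooth boundary deformation amplitude in px.
#' @param bias_lam exponential bias decay per mm of depth.
#' @param noise_sigma additive Gaussian noise sd (intensity units).
#' @param levels named intensities: `body, disc, canal, fat, background`.
#' @param spacing pixel spacing `(row_mm, col_mm)`.
#' @param skin_offset_px column where the fat band (skin) starts.
#' @param fat_width_px width of the fat band.
#' @param seed integer; fully determines the phantom.
#' @return list of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(256L, 256L), n_vertebrae = 5L,
                         vert_size = c(26L, 34L),
                         jitter = list(trans_px = 2, rot_deg = 4,
                                       scale = 0.06),
                         tps_sigma = 1.0, bias_lam = 0.006,
                         noise_sigma = 6,
                         levels = list(body = 200, disc = 110, canal = 70,
                                       fat = 240, background = 40, air = 5),
                         spacing = c(0.7, 0.7), skin_offset_px = 10L,
                         fat_width_px = 8L, seed = 1L) {
  if (levels$body <= levels$background)
    stop("phantom_spec: body level must exceed background")
  structure(list(shape = as.integer(shape), n_vertebrae = as.integer(n_vertebrae),
                 vert_size = vert_size, jitter = jitter,
                 tps_sigma = tps_sigma, bias_lam = bias_lam,
                 noise_sigma = noise_sigma, levels = levels,
                 spacing = spacing, skin_offset_px = as.integer(skin_offset_px),
                 fat_width_px = as.integer(fat_width_px),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# similarity pose of a centered point set
pose_points <- function(pts, rot_rad, scale, center) {
  R <- scale * matrix(c(cos(rot_rad), sin(rot_rad),
                        -sin(rot_rad), cos(rot_rad)), 2, 2)
  sweep(pts %*% t(R), 2, center, "+")
}

#' Generate one spine phantom with ground truth
#'
#' @param spec a [phantom_spec()].
#' @return list with `image` (a [gray_image()]) and `vertebrae`, a list
#'   of per-vertebra `list(box, landmarks, mask)` ground-truth entries.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  nr <- spec$shape[1]; nc <- spec$shape[2]
  vh <- spec$vert_size[1]; vw <- spec$vert_size[2]
  margin <- max(20, vh)
  pitch <- (nr - 2 * margin) / max(spec$n_vertebrae - 1L, 1L)
  if (nr < 2 * margin || (spec$n_vertebrae > 1L && pitch < vh + 4))
    stop("generate_phantom: vertebrae do not fit in the image")
  lv <- spec$levels

  # gently curved column axis
  amp <- runif(1, 4, 10)
  phase <- runif(1, 0, 2 * pi)
  cx0 <- 0.42 * nc
  axis_x <- function(y) cx0 + amp * sin(2 * pi * y / nr * 0.8 + phase)

  img <- matrix(lv$background, nr, nc)
  cols0 <- matrix(rep(0:(nc - 1), each = nr), nr, nc)
  rows0 <- matrix(rep(0:(nr - 1), times = nc), nr, nc)

  # dark air outside the skin, bright fat band at the skin (left) side
  air <- if (is.null(lv$air)) 5 else lv$air
  img[cols0 < spec$skin_offset_px] <- air
  fat_cols <- cols0 >= spec$skin_offset_px &
              cols0 < spec$skin_offset_px + spec$fat_width_px
  img[fat_cols] <- lv$fat

  # spinal canal: darker band trailing the bodies
  canal_x <- axis_x(rows0) + vw / 2 + 6
  img[cols0 >= canal_x & cols0 <= canal_x + 10] <- lv$canal

  tmpl <- landmark_template()$points
  centers_y <- margin + (seq_len(spec$n_vertebrae) - 1L) * pitch
  vertebrae <- vector("list", spec$n_vertebrae)

  # discs midway between bodies
  if (spec$n_vertebrae > 1L) {
    for (i in seq_len(spec$n_vertebrae - 1L)) {
      my <- (centers_y[i] + centers_y[i + 1L]) / 2
      mx <- axis_x(my)
      a <- 0.42 * vw; b <- 0.30 * (pitch - vh)
      inside <- ((cols0 - mx) / a)^2 + ((rows0 - my) / max(b, 2))^2 <= 1
      img[inside] <- lv$disc
    }
  }

  for (i in seq_len(spec$n_vertebrae)) {
    cy <- centers_y[i] + runif(1, -spec$jitter$trans_px, spec$jitter$trans_px)
    cx <- axis_x(cy) + runif(1, -spec$jitter$trans_px, spec$jitter$trans_px)
    rot <- runif(1, -spec$jitter$rot_deg, spec$jitter$rot_deg) * pi / 180
    sc <- 1 + runif(1, -spec$jitter$scale, spec$jitter$scale)

    local <- sweep(tmpl, 2, c(0.5, 0.5)) %*% diag(c(vw, vh))
    if (spec$tps_sigma > 0) {
      g <- as.matrix(expand.grid(x = c(-0.6, 0, 0.6) * vw,
                                 y = c(-0.6, 0, 0.6) * vh))
      disp <- matrix(rnorm(nrow(g) * 2, 0, spec$tps_sigma), ncol = 2)
      w <- fit_tps(g, g + disp, reg = 1e-6)
      local <- tps_apply(w, local)
    }
    pts <- pose_points(local, rot, sc, c(cx, cy))
    lm <- landmark_set(pts, frame = sprintf("phantom-%d-v%d", spec$seed, i))

    ctr <- catmull_rom_closed(lm, alpha = 0.5, samples_per_segment = 20L)
    mask <- rasterize(ctr, c(nr, nc), spacing = spec$spacing)
    shade <- runif(1, -6, 6)
    img[mask$pixels] <- lv$body + shade

    xr <- range(pts[, 1]); yr <- range(pts[, 2])
    box <- bounding_box(x = xr[1] - 2, y = yr[1] - 2,
                        width = diff(xr) + 4, height = diff(yr) + 4)
    vertebrae[[i]] <- list(box = box, landmarks = lm, mask = mask)
  }

  # multiplicative exponential bias in depth from the skin boundary
  if (spec$bias_lam != 0) {
    d <- pmax(cols0 - spec$skin_offset_px, 0) * spec$spacing[2]
    img <- img * exp(-spec$bias_lam * d)
  }
  if (spec$noise_sigma > 0)
    img <- img + matrix(rnorm(nr * nc, 0, spec$noise_sigma), nr, nc)
  img <- pmax(img, 0)

  list(image = gray_image(img, spacing = spec$spacing,
                          source_id = sprintf("phantom-seed-%d", spec$seed)),
       vertebrae = vertebrae)
}

derive_seed <- function(master, i) {
  as.integer((as.numeric(master) * 10007 + i * 7919) %% 2147483647)
}

#' Generate a phantom dataset
#'
#' Per-image seeds are derived from the master seed, so the same master
#' seed reproduces the dataset exactly. When `dir` is given, images
#' (PNG), landmark files (PTS), masks (PNG) and a JSON manifest are
#' written; otherwise everything stays in memory.
#'
#' @param n_images number of phantoms.
#' @param spec a [phantom_spec()] used as the per-image template (its
#'   seed field is overridden per image).
#' @param seed master seed.
#' @param dir optional output directory.
#' @return list with `items` (each `list(image, vertebrae, seed)`) and
#'   `manifest` (data.frame of per-image records).
#' @export
generate_dataset <- function(n_images, spec = phantom_spec(), seed = 11L,
                             dir = NULL) {
  items <- vector("list", n_images)
  recs <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    s <- spec
    s$seed <- derive_seed(seed, i)
    ph <- generate_phantom(s)
    ph$seed <- s$seed
    items[[i]] <- ph
    recs[[i]] <- data.frame(id = i, seed = s$seed,
                            n_vertebrae = length(ph$vertebrae))
  }
  manifest <- do.call(rbind, recs)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    files <- vector("list", n_images)
    for (i in seq_len(n_images)) {
      base <- file.path(dir, sprintf("phantom_%03d", i))
      write_image_png(items[[i]]$image, paste0(base, ".png"))
      for (j in seq_along(items[[i]]$vertebrae)) {
        v <- items[[i]]$vertebrae[[j]]
        write_pts(v$landmarks, sprintf("%s_v%02d.pts", base, j))
        write_mask(v$mask, sprintf("%s_v%02d_mask.png", base, j))
      }
    }
    jsonlite::write_json(
      list(container = "vbseg-dataset", master_seed = seed,
           n_images = n_images,
           images = lapply(seq_len(n_images), function(i)
             list(id = i, seed = manifest$seed[i],
                  image = sprintf("phantom_%03d.png", i),
                  n_vertebrae = manifest$n_vertebrae[i]))),
      file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  }
  list(items = items, manifest = manifest, master_seed = seed)
}

#' Split a dataset into disjoint train/test parts by image
#'
#' Splitting is always by image, never by vertebra, so vertebrae of one
#' phantom can never leak across the split.
#'
#' @param dataset a [generate_dataset()] result.
#' @param test_frac fraction of images held out.
#' @param seed split seed.
#' @return list with `train` and `test` datasets and the index vectors.
#' @export
split_dataset <- function(dataset, test_frac = 0.2, seed = 1L) {
  n <- length(dataset$items)
  set.seed(seed)
  n_test <- max(1L, round(test_frac * n))
  test_idx <- sort(sample.int(n, n_test))
  list(train = list(items = dataset$items[-test_idx]),
       test = list(items = dataset$items[test_idx]),
       train_idx = setdiff(seq_len(n), test_idx), test_idx = test_idx)
}

#' Flatten a dataset into per-vertebra training pairs
#'
#' @param dataset a [generate_dataset()] result (or `list(items = ...)`).
#' @return list of `list(image, landmarks, box, mask)` records, one per
#'   vertebra.
#' @export
dataset_pairs <- function(dataset) {
  out <- list()
  for (it in dataset$items)
    for (v in it$vertebrae)
      out[[length(out) + 1L]] <- list(image = it$image,
                                      landmarks = v$landmarks,
                                      box = v$box, mask = v$mask)
  out
}
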