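# Training-data synthesis: thin-plate-spline positive augmentation and
# inpainting-based negative reconstruction.

tps_kernel <- function(r) {
  u <- r^2 * log(r)
  u[r == 0] <- 0
  u
}

#' Fit a thin-plate-spline warp between paired control points
#'
#' Solves the standard TPS linear system with kernel
#' `U(r) = r^2 * log(r)` (`U(0) = 0`); `reg` adds `lambda * I` to the
#' kernel block (relaxing exact interpolation). With `reg = 0` the warp
#' maps each source control point to its target exactly and the bending
#' energy is zero iff the warp is affine.
#'
#' @param source_pts,target_pts `n x 2` matrices of `(x, y)` points,
#'   `n >= 3`, sources not collinear.
#' @param reg non-negative regularization added to the kernel block.
#' @return An object of class `tps_warp` with the affine part, the
#'   radial coefficients and the bending energy.
#' @export
fit_tps <- function(source_pts, target_pts, reg = 0) {
  S <- as.matrix(source_pts); T_ <- as.matrix(target_pts)
  if (nrow(S) != nrow(T_) || ncol(S) != 2L || ncol(T_) != 2L)
    stop("fit_tps: source and target must be equal-size n x 2 matrices")
  n <- nrow(S)
  if (n < 3L) stop("fit_tps: at least 3 control points are required")
  D <- as.matrix(stats::dist(S))
  K <- tps_kernel(D) + diag(reg, n)
  P <- cbind(1, S)
  Lmat <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
  rhs <- rbind(T_, matrix(0, 3, 2))
  sol <- tryCatch(solve(Lmat, rhs), error = function(e)
    stop("fit_tps: singular TPS system (collinear or duplicate source ",
         "points with reg = 0)"))
  W <- sol[1:n, , drop = FALSE]
  A <- sol[(n + 1):(n + 3), , drop = FALSE]
  be <- sum(diag(t(W) %*% K %*% W))
  structure(list(source = S, target = T_, W = W, A = A,
                 bending_energy = max(be, 0), reg = reg),
            class = "tps_warp")
}

#' @export
print.tps_warp <- function(x, ...) {
  cat(sprintf("<tps_warp %d control points, bending energy %.4g>\n",
              nrow(x$source), x$bending_energy))
  invisible(x)
}

#' Evaluate a TPS warp at arbitrary points
#'
#' @param warp a [fit_tps()] object.
#' @param pts `m x 2` matrix of `(x, y)` points.
#' @return `m x 2` matrix of warped points.
#' @export
tps_apply <- function(warp, pts) {
  Q <- as.matrix(pts)
  if (is.null(dim(Q))) Q <- matrix(Q, ncol = 2)
  # distances from every query to every source control point
  D <- sqrt(outer(Q[, 1], warp$source[, 1], "-")^2 +
            outer(Q[, 2], warp$source[, 2], "-")^2)
  U <- tps_kernel(D)
  cbind(1, Q) %*% warp$A + U %*% warp$W
}

#' Warp an image and its landmarks with a fitted TPS
#'
#' The image is resampled by backward mapping (the inverse deformation is
#' approximated by a TPS fitted on the swapped control points) using the
#' cubic-convolution interpolator; landmarks are mapped forward.
#'
#' @param image a [gray_image()].
#' @param landmarks a [landmark_set()] (or NULL).
#' @param warp a [fit_tps()] object.
#' @return list with warped `image` and `landmarks`.
#' @export
warp_image <- function(image, landmarks, warp) {
  stopifnot(inherits(image, "gray_image"), inherits(warp, "tps_warp"))
  inv <- fit_tps(warp$target, warp$source, reg = warp$reg)
  nr <- nrow(image$pixels); nc <- ncol(image$pixels)
  grid <- cbind(rep(0:(nc - 1), each = nr), rep(0:(nr - 1), times = nc))
  src <- tps_apply(inv, grid)
  v <- cpp_interp_cubic(image$pixels, src[, 1], src[, 2], -0.5)
  v <- pmin(pmax(v, min(image$pixels)), max(image$pixels))
  out_img <- gray_image(matrix(v, nr, nc), spacing = image$spacing,
                        source_id = image$source_id)
  out_lm <- NULL
  if (!is.null(landmarks)) {
    stopifnot(inherits(landmarks, "landmark_set"))
    out_lm <- landmark_set(tps_apply(warp, landmarks$points),
                           frame = landmarks$frame)
  }
  list(image = out_img, landmarks = out_lm)
}

#' Generate artificial positive examples by TPS jitter
#'
#' Cycles through the annotated inputs, samples per-landmark Gaussian
#' control displacements plus a global rotation/scale jitter, and emits
#' warped crops with their warped landmark sets. Exactly `n_out` items
#' are produced; the whole procedure is seeded.
#'
#' @param annotated list of `list(image =, landmarks =)` pairs.
#' @param n_out number of outputs.
#' @param jitter list: `sigma_px` (per-landmark Gaussian displacement,
#'   default 2\% of image width), `rot_deg`, `scale`.
#' @param seed integer seed.
#' @return list of `list(image =, landmarks =, origin =)` items.
#' @export
generate_positives <- function(annotated, n_out,
                               jitter = list(sigma_px = NULL, rot_deg = 8,
                                             scale = 0.10),
                               seed = 1L) {
  if (!length(annotated)) stop("generate_positives: empty input")
  set.seed(seed)
  out <- vector("list", n_out)
  for (i in seq_len(n_out)) {
    src <- annotated[[(i - 1L) %% length(annotated) + 1L]]
    img <- src$image; lm <- src$landmarks
    sig <- jitter$sigma_px
    if (is.null(sig)) sig <- 0.02 * ncol(img$pixels)
    ctr <- colMeans(lm$points)
    th <- runif(1, -jitter$rot_deg, jitter$rot_deg) * pi / 180
    sc <- 1 + runif(1, -jitter$scale, jitter$scale)
    R <- sc * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    tgt <- sweep(sweep(lm$points, 2, ctr) %*% t(R), 2, ctr, "+")
    tgt <- tgt + matrix(rnorm(32, 0, sig), 16, 2)
    if (sig == 0 && jitter$rot_deg == 0 && jitter$scale == 0) {
      out[[i]] <- list(image = img, landmarks = lm, origin = i)
      next
    }
    w <- fit_tps(lm$points, tgt, reg = 1e-8)
    wr <- warp_image(img, lm, w)
    out[[i]] <- list(image = wr$image, landmarks = wr$landmarks, origin = i)
  }
  out
}

#' Harmonic (diffusion) inpainting
#'
#' Replaces the masked pixels by the solution of the discrete Laplace
#' equation with boundary values taken from the unmasked neighbours
#' (Gauss-Seidel relaxation until the residual drops below `tol` or
#' `10 * |mask|` iterations). Unmasked pixels are untouched; the filled
#' region obeys the discrete maximum principle.
#'
#' @param image a [gray_image()].
#' @param mask a [binary_mask()] (TRUE = pixels to fill) of equal shape.
#' @param tol relaxation stopping tolerance.
#' @return An inpainted [gray_image()].
#' @export
inpaint <- function(image, mask, tol = 1e-4) {
  stopifnot(inherits(image, "gray_image"), inherits(mask, "binary_mask"))
  if (!all(dim(image$pixels) == dim(mask$pixels)))
    stop("inpaint: mask shape mismatch")
  nmask <- sum(mask$pixels)
  if (nmask == length(mask$pixels))
    stop("inpaint: mask covers the entire image")
  if (nmask == 0L) return(image)
  out <- cpp_inpaint(image$pixels, mask$pixels, tol, 10L * nmask)
  gray_image(out, spacing = image$spacing, source_id = image$source_id)
}

#' Reconstruct vertebra-free negative images
#'
#' Each vertebra bounding box (dilated by 10\%) is inpainted out of its
#' image, yielding full background reconstructions for negative mining.
#'
#' @param images list of [gray_image()]s.
#' @param vertebra_boxes list (parallel to `images`) of box data.frames
#'   with columns `x, y, width, height`.
#' @param seed unused randomness guard kept for manifest provenance.
#' @return list of reconstructed [gray_image()]s.
#' @export
generate_negatives <- function(images, vertebra_boxes, seed = 1L) {
  stopifnot(length(images) == length(vertebra_boxes))
  lapply(seq_along(images), function(i) {
    img <- images[[i]]
    boxes <- vertebra_boxes[[i]]
    if (is.null(boxes) || nrow(boxes) == 0L) return(img)
    m <- matrix(FALSE, nrow(img$pixels), ncol(img$pixels))
    for (j in seq_len(nrow(boxes))) {
      b <- boxes[j, ]
      dx <- 0.05 * b$width; dy <- 0.05 * b$height
      x0 <- max(0, floor(b$x - dx)); y0 <- max(0, floor(b$y - dy))
      x1 <- min(ncol(m) - 1, ceiling(b$x + b$width + dx))
      y1 <- min(nrow(m) - 1, ceiling(b$y + b$height + dy))
      m[(y0 + 1):(y1 + 1), (x0 + 1):(x1 + 1)] <- TRUE
    }
    inpaint(img, binary_mask(m, img$spacing))
  })
}
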