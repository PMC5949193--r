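# Initial filtration: cubic-spline upsampling, exponential
# intensity-inhomogeneity (IIH) correction anchored on the fat-skin
# boundary, and selective Gaussian denoising.

#' Upsample an image by separable cubic convolution
#'
#' Interpolation uses the Keys cubic-convolution kernel (parameter `a`,
#' `-0.5` giving the Catmull-Rom member with linear precision and a sharp
#' high-frequency response). Output intensities are clipped to the input
#' range; spacing is divided by the factor.
#'
#' @param image a [gray_image()].
#' @param factor integer upsampling factor, >= 1.
#' @param a cubic kernel parameter.
#' @return A [gray_image()] of `factor`-times the size.
#' @export
upsample <- function(image, factor, a = -0.5) {
  stopifnot(inherits(image, "gray_image"))
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L)
    stop("upsample: factor must be an integer >= 1")
  if (factor == 1L) return(image)
  nr <- nrow(image$pixels) * factor
  nc <- ncol(image$pixels) * factor
  # output pixel k sits at input coordinate k / factor
  xs <- rep((seq_len(nc) - 1) / factor, each = nr)
  ys <- rep((seq_len(nr) - 1) / factor, times = nc)
  v <- cpp_interp_cubic(image$pixels, xs, ys, a)
  v <- pmin(pmax(v, min(image$pixels)), max(image$pixels))
  gray_image(matrix(v, nr, nc), spacing = image$spacing / factor,
             source_id = image$source_id)
}

#' Detect the skin boundary and build a depth map
#'
#' Scanning inward from the configured lateral side, the boundary of each
#' row is the first column whose intensity exceeds the given quantile of
#' that row. The boundary is smoothed by a running median and converted
#' into a per-pixel inward depth map in millimetres.
#'
#' @param image a [gray_image()] with a bright fat band near one border.
#' @param side `"left"` or `"right"`: which border carries the skin.
#' @param quantile row-intensity quantile defining "bright" (default 0.90).
#' @param smooth_window running-median window (rows) for the boundary.
#' @return list with `boundary` (per-row boundary column, 0-based) and
#'   `depth_map` (matrix of inward distances in mm, >= 0).
#' @export
detect_skin_boundary <- function(image, side = c("left", "right"),
                                 quantile = 0.90, smooth_window = 11L) {
  stopifnot(inherits(image, "gray_image"))
  side <- match.arg(side)
  px <- image$pixels
  nr <- nrow(px); nc <- ncol(px)
  bound <- rep(NA_real_, nr)
  for (r in seq_len(nr)) {
    row <- px[r, ]
    thr <- stats::quantile(row, quantile, names = FALSE)
    idx <- if (side == "left") which(row > thr) else rev(which(row > thr))
    if (length(idx)) bound[r] <- idx[1] - 1
  }
  if (all(is.na(bound)))
    stop("detect_skin_boundary: no row exceeds the brightness quantile; ",
         "supply a manual depth origin")
  if (anyNA(bound)) {
    # borrow the nearest detected row
    ok <- which(!is.na(bound))
    for (r in which(is.na(bound)))
      bound[r] <- bound[ok[which.min(abs(ok - r))]]
  }
  if (smooth_window > 1L && nr >= 3L) {
    k <- min(as.integer(smooth_window), nr)
    if (k %% 2L == 0L) k <- k - 1L
    if (k >= 3L) bound <- stats::runmed(bound, k, endrule = "median")
  }
  col_mm <- image$spacing[2]
  cols <- matrix(rep(0:(nc - 1), each = nr), nr, nc)
  d <- if (side == "left") (cols - bound) else (bound - cols)
  depth <- pmax(d, 0) * col_mm
  list(boundary = as.numeric(bound), depth_map = depth)
}

#' Exponential intensity-inhomogeneity gain
#'
#' Multiplicative bias model `b(d) = exp(-lam * d)` where `d` is the
#' inward depth from the skin boundary in millimetres: observed intensity
#' is true intensity times `b(d)`.
#'
#' @param I0 reference (zero-depth) intensity, > 0.
#' @param lam decay rate per mm.
#' @param depth_map per-pixel depth in mm.
#' @return An object of class `exponential_gain`.
#' @export
exponential_gain <- function(I0, lam, depth_map) {
  if (!is.finite(lam)) stop("exponential_gain: lam must be finite")
  if (!is.finite(I0) || I0 <= 0) stop("exponential_gain: I0 must be > 0")
  if (any(depth_map < 0)) stop("exponential_gain: depth_map must be >= 0")
  structure(list(I0 = I0, lam = lam, depth_map = depth_map),
            class = "exponential_gain")
}

#' @export
print.exponential_gain <- function(x, ...) {
  cat(sprintf("<exponential_gain I0 = %.4g, lam = %.5g /mm>\n", x$I0, x$lam))
  invisible(x)
}

#' Fit the exponential gain from an image and its depth map
#'
#' Least-squares line fit of `log(intensity)` against depth over the
#' foreground (pixels above the global Otsu threshold): the slope is
#' `-lam`, the intercept `log(I0)`.
#'
#' Pixels shallower than `min_depth_mm` are excluded from the fit: the
#' subcutaneous fat band that anchors the depth origin is a different
#' tissue class than the deep structures of interest and would otherwise
#' bias the slope.
#'
#' @param image a [gray_image()].
#' @param depth_map depth matrix from [detect_skin_boundary()].
#' @param min_foreground minimum number of foreground pixels required.
#' @param min_depth_mm shallowest depth admitted to the fit.
#' @return An [exponential_gain()].
#' @export
fit_exponential_gain <- function(image, depth_map, min_foreground = 100L,
                                 min_depth_mm = 5) {
  stopifnot(inherits(image, "gray_image"))
  px <- image$pixels
  if (!all(dim(px) == dim(depth_map)))
    stop("fit_exponential_gain: depth_map shape mismatch")
  thr <- otsu_threshold(px)
  fg <- which(px > thr & px > 0 & depth_map >= min_depth_mm)
  if (length(fg) < min_foreground)
    fg <- which(px > thr & px > 0)   # shallow images: use everything
  if (length(fg) < min_foreground)
    stop("fit_exponential_gain: only ", length(fg),
         " foreground pixels (need >= ", min_foreground, ")")
  d <- depth_map[fg]
  logi <- log(px[fg])
  fit <- stats::lm.fit(cbind(1, d), logi)
  b <- fit$coefficients
  exponential_gain(I0 = exp(b[1]), lam = -b[2], depth_map = depth_map)
}

# Otsu's between-class-variance threshold on a 256-bin histogram.
otsu_threshold <- function(px) {
  rng <- range(px)
  if (diff(rng) <= 0) return(rng[1])
  h <- tabulate(pmin(pmax(floor((px - rng[1]) / diff(rng) * 256) + 1, 1), 256),
                nbins = 256)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(256))
  mu_t <- mu[256]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  k <- which.max(sigma_b)
  rng[1] + k / 256 * diff(rng)
}

#' Correct intensity inhomogeneity with a fitted exponential gain
#'
#' Divides by the bias field (multiplies by `exp(lam * d)`) and rescales
#' so the output mean equals the input mean. Shape and spacing preserved.
#'
#' @param image a [gray_image()].
#' @param gain an [exponential_gain()] fitted on the same geometry.
#' @return A corrected [gray_image()].
#' @export
correct_iih <- function(image, gain) {
  stopifnot(inherits(image, "gray_image"), inherits(gain, "exponential_gain"))
  if (!all(dim(image$pixels) == dim(gain$depth_map)))
    stop("correct_iih: gain fitted on a different geometry")
  out <- image$pixels * exp(gain$lam * gain$depth_map)
  m_in <- mean(image$pixels); m_out <- mean(out)
  if (m_out > 0) out <- out * (m_in / m_out)
  gray_image(out, spacing = image$spacing, source_id = image$source_id)
}

#' Selective Gaussian denoising with a depth-scaled intensity window
#'
#' Each pixel becomes the Gaussian-weighted mean of itself and the
#' neighbours whose absolute intensity difference from it is below
#' `edge_threshold * exp(lam * d)` -- the tolerance widens with depth to
#' follow the noise amplification introduced by IIH correction. Pixels
#' with no qualifying neighbour are unchanged, so strong edges survive.
#'
#' @param image a [gray_image()].
#' @param gain optional [exponential_gain()]; `NULL` uses a flat window.
#' @param sigma_px Gaussian spatial sigma in pixels (> 0).
#' @param edge_threshold base intensity tolerance.
#' @return A denoised [gray_image()].
#' @export
selective_gaussian <- function(image, gain = NULL, sigma_px = 2,
                               edge_threshold = 20) {
  stopifnot(inherits(image, "gray_image"))
  if (sigma_px <= 0) stop("selective_gaussian: sigma_px must be > 0")
  tol <- if (is.null(gain)) {
    matrix(edge_threshold, nrow(image$pixels), ncol(image$pixels))
  } else {
    edge_threshold * exp(gain$lam * gain$depth_map)
  }
  out <- cpp_selective_gaussian(image$pixels, tol, sigma_px)
  gray_image(out, spacing = image$spacing, source_id = image$source_id)
}

#' Run the full initial-filtration chain
#'
#' Upsampling, skin-boundary depth estimation, exponential IIH fit and
#' correction, then selective Gaussian denoising. Steps degrade
#' gracefully: if the gain cannot be estimated the image passes through
#' with a flat denoising window.
#'
#' @param image a [gray_image()].
#' @param config named list of parameters (see [default_config()],
#'   section `preprocess`).
#' @return list with the filtered `image`, the `gain` (or NULL) and the
#'   skin `boundary` (or NULL).
#' @export
preprocess_image <- function(image, config = default_config()$preprocess) {
  img <- upsample(image, config$upsample_factor, a = config$kernel_a)
  gain <- NULL; boundary <- NULL
  sk <- tryCatch(detect_skin_boundary(img, side = config$skin_side,
                                      quantile = config$quantile),
                 error = function(e) NULL)
  if (!is.null(sk)) {
    boundary <- sk$boundary
    gain <- tryCatch(fit_exponential_gain(img, sk$depth_map),
                     error = function(e) NULL)
    if (!is.null(gain)) img <- correct_iih(img, gain)
  }
  img <- selective_gaussian(img, gain, sigma_px = config$sigma_px,
                            edge_threshold = config$edge_threshold)
  list(image = img, gain = gain, boundary = boundary)
}
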