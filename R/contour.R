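# Closed centripetal Catmull-Rom interpolation of the 16 landmarks,
# rasterization to a mask, and area measurement.

#' Closed Catmull-Rom contour through control points
#'
#' Interpolates a closed C1 curve through the control points using the
#' recursive Barry-Goldman pyramid with knot increments
#' `t[i+1] - t[i] = ||P[i+1] - P[i]||^alpha`; `alpha = 0.5` is the
#' centripetal parameterization, which avoids cusps and
#' self-intersections for reasonable control polygons. End tangents wrap
#' cyclically. Consecutive duplicate control points are collapsed with a
#' warning.
#'
#' @param points a [landmark_set()] or an `n x 2` matrix (`n >= 4`
#'   distinct points).
#' @param alpha knot exponent (0.5 = centripetal).
#' @param samples_per_segment dense samples per control-point segment.
#' @return An object of class `vb_contour` with fields `control`,
#'   `alpha`, `samples_per_segment`, `knots` (cumulative, length n+1)
#'   and `polyline` (closed: first row equals last row).
#' @export
catmull_rom_closed <- function(points, alpha = 0.5, samples_per_segment = 20L) {
  P <- if (inherits(points, "landmark_set")) points$points else as.matrix(points)
  if (ncol(P) != 2L) stop("catmull_rom_closed: points must be n x 2")
  # collapse consecutive duplicates (cyclically)
  n0 <- nrow(P)
  keep <- c(TRUE, rowSums((P[-1, , drop = FALSE] -
                           P[-n0, , drop = FALSE])^2) > 0)
  if (nrow(P) > 1L && all(P[1, ] == P[nrow(P), ])) keep[nrow(P)] <- FALSE
  if (!all(keep)) {
    warning("catmull_rom_closed: collapsed ", sum(!keep),
            " duplicate control point(s)")
    P <- P[keep, , drop = FALSE]
  }
  n <- nrow(P)
  if (n < 4L) stop("catmull_rom_closed: need at least 4 distinct points")
  idx <- function(i) ((i - 1L) %% n) + 1L
  seg_len <- vapply(seq_len(n), function(i)
    sqrt(sum((P[idx(i + 1L), ] - P[i, ])^2)), 0)
  dts <- seg_len^alpha
  knots <- c(0, cumsum(dts))

  m <- as.integer(samples_per_segment)
  poly <- matrix(0, n * m + 1L, 2L)
  row <- 1L
  for (i in seq_len(n)) {
    P0 <- P[idx(i - 1L), ]; P1 <- P[i, ]
    P2 <- P[idx(i + 1L), ]; P3 <- P[idx(i + 2L), ]
    dt0 <- dts[idx(i - 1L)]; dt1 <- dts[i]; dt2 <- dts[idx(i + 1L)]
    t0 <- 0; t1 <- dt0; t2 <- dt0 + dt1; t3 <- dt0 + dt1 + dt2
    u <- t1 + (seq_len(m) - 1L) / m * (t2 - t1)
    for (j in seq_len(m)) {
      t <- u[j]
      A1 <- (t1 - t) / (t1 - t0) * P0 + (t - t0) / (t1 - t0) * P1
      A2 <- (t2 - t) / (t2 - t1) * P1 + (t - t1) / (t2 - t1) * P2
      A3 <- (t3 - t) / (t3 - t2) * P2 + (t - t2) / (t3 - t2) * P3
      B1 <- (t2 - t) / (t2 - t0) * A1 + (t - t0) / (t2 - t0) * A2
      B2 <- (t3 - t) / (t3 - t1) * A2 + (t - t1) / (t3 - t1) * A3
      poly[row, ] <- (t2 - t) / (t2 - t1) * B1 + (t - t1) / (t2 - t1) * B2
      row <- row + 1L
    }
  }
  poly[row, ] <- poly[1L, ]   # close the curve
  structure(list(control = P, alpha = alpha, samples_per_segment = m,
                 knots = knots, polyline = poly),
            class = "vb_contour")
}

#' @export
print.vb_contour <- function(x, ...) {
  cat(sprintf("<vb_contour %d control pts, alpha %.2f, %d samples>\n",
              nrow(x$control), x$alpha, nrow(x$polyline)))
  invisible(x)
}

seg_intersects <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
   ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
}

#' Test a contour polyline for self-intersection
#'
#' Pairwise segment check over the dense polyline, excluding adjacent
#' segments (which share an endpoint).
#'
#' @param contour a [catmull_rom_closed()] contour.
#' @return logical scalar.
#' @export
self_intersects <- function(contour) {
  stopifnot(inherits(contour, "vb_contour"))
  poly <- contour$polyline
  n <- nrow(poly) - 1L   # closed: last row repeats the first
  a <- poly[seq_len(n), , drop = FALSE]
  b <- poly[c(seq_len(n - 1L) + 1L, 1L), , drop = FALSE]
  for (i in seq_len(n - 2L)) {
    js <- seq.int(i + 2L, n)
    if (i == 1L) js <- js[js != n]   # segment n is adjacent to segment 1
    if (!length(js)) next
    # vectorized proper-crossing test of segment i against segments js
    p1 <- a[i, ]; p2 <- b[i, ]
    q1 <- a[js, , drop = FALSE]; q2 <- b[js, , drop = FALSE]
    d1 <- (q2[, 1] - q1[, 1]) * (p1[2] - q1[, 2]) -
          (q2[, 2] - q1[, 2]) * (p1[1] - q1[, 1])
    d2 <- (q2[, 1] - q1[, 1]) * (p2[2] - q1[, 2]) -
          (q2[, 2] - q1[, 2]) * (p2[1] - q1[, 1])
    d3 <- (p2[1] - p1[1]) * (q1[, 2] - p1[2]) -
          (p2[2] - p1[2]) * (q1[, 1] - p1[1])
    d4 <- (p2[1] - p1[1]) * (q2[, 2] - p1[2]) -
          (p2[2] - p1[2]) * (q2[, 1] - p1[1])
    hit <- ((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &
           ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0))
    if (any(hit)) return(TRUE)
  }
  FALSE
}

#' Rasterize a contour to a binary mask
#'
#' Pixel-center-in-polygon with the even-odd rule over the sampled
#' polyline; the contour is clipped to the image bounds. A contour
#' entirely outside the grid yields an empty mask with a warning.
#'
#' @param contour a [catmull_rom_closed()] contour.
#' @param shape `c(nrow, ncol)` of the target grid.
#' @param spacing pixel spacing to attach to the mask.
#' @return A [binary_mask()].
#' @export
rasterize <- function(contour, shape, spacing = c(1, 1)) {
  stopifnot(inherits(contour, "vb_contour"))
  poly <- contour$polyline
  poly <- poly[-nrow(poly), , drop = FALSE]
  if (all(poly[, 1] < 0) || all(poly[, 1] > shape[2] - 1) ||
      all(poly[, 2] < 0) || all(poly[, 2] > shape[1] - 1)) {
    warning("rasterize: contour entirely outside the image")
    return(binary_mask(matrix(FALSE, shape[1], shape[2]), spacing))
  }
  m <- cpp_rasterize_polygon(poly[, 1], poly[, 2],
                             as.integer(shape[1]), as.integer(shape[2]))
  binary_mask(m, spacing)
}

#' Enclosed area in square millimetres
#'
#' For a contour the shoelace formula on the dense polyline; for a mask
#' the foreground pixel count. Both are scaled by the pixel spacing
#' product.
#'
#' @param x a `vb_contour`, a [binary_mask()], or an `n x 2` matrix
#'   taken as a closed polygon.
#' @param spacing `(row_mm, col_mm)`; for masks the mask's own spacing
#'   is used when omitted.
#' @return area in mm^2.
#' @export
area_mm2 <- function(x, spacing = NULL) {
  if (inherits(x, "vb_contour")) {
    if (is.null(spacing)) spacing <- c(1, 1)
    p <- x$polyline
    n <- nrow(p) - 1L
    xs <- p[seq_len(n), 1]; ys <- p[seq_len(n), 2]
    xs2 <- c(xs[-1], xs[1]); ys2 <- c(ys[-1], ys[1])
    abs(sum(xs * ys2 - xs2 * ys)) / 2 * spacing[1] * spacing[2]
  } else if (inherits(x, "binary_mask")) {
    if (is.null(spacing)) spacing <- x$spacing
    sum(x$pixels) * spacing[1] * spacing[2]
  } else if (is.matrix(x) && ncol(x) == 2L) {
    if (is.null(spacing)) spacing <- c(1, 1)
    xs <- x[, 1]; ys <- x[, 2]
    xs2 <- c(xs[-1], xs[1]); ys2 <- c(ys[-1], ys[1])
    abs(sum(xs * ys2 - xs2 * ys)) / 2 * spacing[1] * spacing[2]
  } else stop("area_mm2: need a vb_contour, binary_mask or n x 2 matrix")
}
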