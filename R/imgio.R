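# Image, landmark and mask containers plus on-disk formats.
#
# Spatial convention used by every module in the package:
# x = column index, y = row index, both 0-based, pixel centers at integer
# coordinates. Masks are pixel sets on the same grid.

#' Grayscale image with physical pixel spacing
#'
#' @param pixels numeric matrix of non-negative finite intensities
#'   (rows = y, columns = x).
#' @param spacing numeric length-2 vector `(row_mm, col_mm)`: physical
#'   size of one pixel in millimetres.
#' @param source_id free-text provenance tag.
#' @return An object of class `gray_image` with fields `pixels`,
#'   `spacing`, `source_id`.
#' @export
gray_image <- function(pixels, spacing = c(1, 1), source_id = "") {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  if (nrow(pixels) < 2L || ncol(pixels) < 2L)
    stop("gray_image: pixels must have at least 2 rows and 2 columns")
  if (!all(is.finite(pixels)))
    stop("gray_image: intensities must be finite")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 2L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("gray_image: spacing must be two positive numbers (row_mm, col_mm)")
  structure(list(pixels = pixels, spacing = spacing,
                 source_id = as.character(source_id)[1]),
            class = "gray_image")
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image %d x %d px, spacing %.4g x %.4g mm, range [%.4g, %.4g]>\n",
              nrow(x$pixels), ncol(x$pixels), x$spacing[1], x$spacing[2],
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.gray_image <- function(x) dim(x$pixels)

#' Ordered 16-point vertebral body outline
#'
#' @param points 16 x 2 numeric matrix of `(x, y)` subpixel coordinates in
#'   the fixed template ordering (clockwise from the anterior-superior
#'   corner).
#' @param frame identifier of the image the coordinates live in.
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(points, frame = "") {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (nrow(points) != 16L || ncol(points) != 2L)
    stop("landmark_set: exactly 16 (x, y) points are required, got ",
         nrow(points), " x ", ncol(points))
  if (!all(is.finite(points)))
    stop("landmark_set: coordinates must be finite")
  colnames(points) <- c("x", "y")
  structure(list(points = points, frame = as.character(frame)[1]),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  ctr <- colMeans(x$points)
  cat(sprintf("<landmark_set 16 pts, centroid (%.2f, %.2f), frame '%s'>\n",
              ctr[1], ctr[2], x$frame))
  invisible(x)
}

#' Axis-aligned detection box
#'
#' @param x,y top-left corner (pixels, 0-based).
#' @param width,height box size in pixels (> 0).
#' @param score detection score (raw-hit count for grouped detections).
#' @return An object of class `bounding_box`.
#' @export
bounding_box <- function(x, y, width, height, score = NA_real_) {
  if (width <= 0 || height <= 0)
    stop("bounding_box: width and height must be positive")
  structure(list(x = as.numeric(x), y = as.numeric(y),
                 width = as.numeric(width), height = as.numeric(height),
                 score = as.numeric(score)),
            class = "bounding_box")
}

#' Binary mask on an image grid
#'
#' @param pixels logical matrix (TRUE = foreground).
#' @param spacing as in [gray_image()].
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(pixels, spacing = c(1, 1)) {
  pixels <- as.matrix(pixels)
  if (!is.logical(pixels)) {
    storage.mode(pixels) <- "double"
    pixels <- pixels != 0
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 2L || any(spacing <= 0))
    stop("binary_mask: spacing must be two positive numbers")
  structure(list(pixels = pixels, spacing = spacing), class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask %d x %d px, %d foreground>\n",
              nrow(x$pixels), ncol(x$pixels), sum(x$pixels)))
  invisible(x)
}

# ---- DICOM -------------------------------------------------------------

dcm_read_n <- function(con, n) {
  b <- readBin(con, "raw", n)
  if (length(b) < n) stop("unexpected end of file")
  b
}

dcm_u16 <- function(b) as.integer(b[1]) + 256L * as.integer(b[2])
dcm_u32 <- function(b) sum(as.numeric(b) * 256^(0:3))

#' Read a single-frame DICOM slice
#'
#' Minimal reader for uncompressed single-frame DICOM files (explicit or
#' implicit VR, little endian). Pixel values are rescaled by
#' RescaleSlope/RescaleIntercept when present; pixel spacing is taken
#' from PixelSpacing and defaults to `(1, 1)` mm with a warning when the
#' tag is absent.
#'
#' @param path path to the DICOM file.
#' @return A [gray_image()].
#' @export
read_dicom_slice <- function(path) {
  if (!file.exists(path)) stop("read_dicom_slice: no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  ok <- tryCatch({
    readBin(con, "raw", 128)
    magic <- readBin(con, "raw", 4)
    identical(rawToChar(magic), "DICM")
  }, error = function(e) FALSE)
  if (!ok)
    stop("read_dicom_slice: not a DICOM file (missing DICM magic): ", path)

  tags <- list()
  explicit <- TRUE
  repeat {
    hdr <- readBin(con, "raw", 8)
    if (length(hdr) < 8) break
    group <- dcm_u16(hdr[1:2]); elem <- dcm_u16(hdr[3:4])
    vr <- rawToChar(hdr[5:6])
    if (explicit && grepl("^[A-Z]{2}$", vr)) {
      if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
        len <- dcm_u32(dcm_read_n(con, 4))
      } else {
        len <- dcm_u16(hdr[7:8])
      }
    } else {
      # implicit VR: bytes 5..8 are the 32-bit length
      vr <- NA_character_
      len <- dcm_u32(hdr[5:8])
    }
    if (!is.finite(len) || len > 2^30) stop("read_dicom_slice: corrupt length")
    val <- if (len > 0) dcm_read_n(con, len) else raw(0)
    key <- sprintf("%04x,%04x", group, elem)
    tags[[key]] <- list(vr = vr, bytes = val)
    if (group == 0x7fe0 && elem == 0x0010) break
    # after the group-0002 meta header the main data set may switch VR mode
    if (group == 0x0002 && elem == 0x0010) {
      ts <- sub("\\s+$", "", rawToChar(val))
      explicit <- !identical(ts, "1.2.840.10008.1.2")
    }
  }

  get_str <- function(key) {
    t <- tags[[key]]
    if (is.null(t)) return(NULL)
    sub("\\s+$", "", rawToChar(t$bytes))
  }
  get_num <- function(key) {
    s <- get_str(key)
    if (is.null(s) || !nzchar(s)) return(NULL)
    as.numeric(strsplit(s, "\\\\")[[1]])
  }
  get_u16val <- function(key) {
    t <- tags[[key]]
    if (is.null(t)) return(NULL)
    dcm_u16(t$bytes)
  }

  rows <- get_u16val("0028,0010"); cols <- get_u16val("0028,0011")
  pix <- tags[["7fe0,0010"]]
  if (is.null(rows) || is.null(cols) || is.null(pix))
    stop("read_dicom_slice: missing Rows/Columns/PixelData in ", path)
  bits <- get_u16val("0028,0100"); if (is.null(bits)) bits <- 16L
  signed <- identical(get_u16val("0028,0103"), 1L)
  nbytes <- bits %/% 8L
  if (!nbytes %in% c(1L, 2L))
    stop("read_dicom_slice: unsupported BitsAllocated ", bits)
  n <- rows * cols
  if (length(pix$bytes) < n * nbytes)
    stop("read_dicom_slice: pixel data truncated in ", path)
  vals <- readBin(pix$bytes, "integer", n = n, size = nbytes,
                  signed = if (nbytes == 2L) signed else FALSE,
                  endian = "little")
  if (nbytes == 2L && !signed && any(vals < 0)) vals <- vals + 65536
  # DICOM stores rows contiguously
  m <- matrix(as.numeric(vals), nrow = rows, ncol = cols, byrow = TRUE)

  slope <- get_num("0028,1053"); intercept <- get_num("0028,1052")
  if (!is.null(slope)) m <- m * slope[1]
  if (!is.null(intercept)) m <- m + intercept[1]

  spacing <- get_num("0028,0030")
  if (is.null(spacing) || length(spacing) != 2L) {
    warning("read_dicom_slice: PixelSpacing absent in ", path,
            "; defaulting to (1, 1) mm")
    spacing <- c(1, 1)
  }
  gray_image(m, spacing = spacing, source_id = path)
}

# ---- PTS landmark files ------------------------------------------------

#' Read / write PTS landmark files
#'
#' Plain-text landmark format: `version: 1`, `n_points: 16`, then the 16
#' `x y` coordinate lines between `{` and `}`. Write and read are exact
#' inverses to below 1e-9.
#'
#' @param path file path.
#' @param landmarks a [landmark_set()].
#' @return `read_pts` returns a [landmark_set()]; `write_pts` returns
#'   `path` invisibly.
#' @export
read_pts <- function(path) {
  if (!file.exists(path)) stop("read_pts: no such file: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  if (length(lines) < 4L || !grepl("^version:", lines[1]) ||
      !grepl("^n_points:", lines[2]))
    stop("read_pts: malformed PTS header in ", path)
  np <- suppressWarnings(as.integer(sub("^n_points:\\s*", "", lines[2])))
  if (is.na(np)) stop("read_pts: malformed n_points header in ", path)
  if (np != 16L)
    stop("read_pts: n_points must be 16, found ", np, " in ", path)
  open_i <- which(lines == "{")[1]
  close_i <- which(lines == "}")[1]
  if (is.na(open_i) || is.na(close_i) || close_i <= open_i)
    stop("read_pts: missing brace block in ", path)
  body <- lines[(open_i + 1):(close_i - 1)]
  if (length(body) != np)
    stop("read_pts: expected ", np, " coordinate lines, found ",
         length(body), " in ", path)
  toks <- strsplit(body, "\\s+")
  if (any(lengths(toks) != 2L))
    stop("read_pts: each coordinate line must hold two tokens in ", path)
  vals <- suppressWarnings(as.numeric(unlist(toks)))
  if (any(is.na(vals)))
    stop("read_pts: non-numeric coordinate token in ", path)
  landmark_set(matrix(vals, ncol = 2, byrow = TRUE), frame = path)
}

#' @rdname read_pts
#' @export
write_pts <- function(landmarks, path) {
  stopifnot(inherits(landmarks, "landmark_set"))
  p <- landmarks$points
  lines <- c("version: 1",
             sprintf("n_points: %d", nrow(p)),
             "{",
             sprintf("%.12g %.12g", p[, 1], p[, 2]),
             "}")
  writeLines(lines, path)
  invisible(path)
}

# ---- PNG images and masks ---------------------------------------------

#' Read / write grayscale PNG images
#'
#' Intensities are mapped to/from the 16-bit PNG range; `write_image_png`
#' scales by the image maximum (recorded losslessly only up to that
#' quantization, which is ample for 8-16 bit pipelines).
#'
#' @param path file path.
#' @param image a [gray_image()].
#' @param spacing spacing to attach on read (PNG carries none).
#' @return `read_image_png` returns a [gray_image()].
#' @export
read_image_png <- function(path, spacing = c(1, 1)) {
  a <- tryCatch(png::readPNG(path), error = function(e)
    stop("read_image_png: cannot read PNG: ", path, " (", conditionMessage(e), ")"))
  if (length(dim(a)) == 3L) a <- a[, , 1]
  gray_image(a * 65535, spacing = spacing, source_id = path)
}

#' @rdname read_image_png
#' @export
write_image_png <- function(image, path) {
  stopifnot(inherits(image, "gray_image"))
  m <- image$pixels
  mx <- max(m)
  if (mx > 0) m <- m / mx
  png::writePNG(m, path)
  invisible(path)
}

#' Read / write binary masks as 8-bit PNG
#'
#' Nonzero pixels are foreground; the round trip is lossless.
#'
#' @param path file path.
#' @param mask a [binary_mask()].
#' @param spacing spacing to attach on read.
#' @return `read_mask` returns a [binary_mask()].
#' @export
read_mask <- function(path, spacing = c(1, 1)) {
  a <- tryCatch(png::readPNG(path), error = function(e)
    stop("read_mask: cannot read PNG: ", path, " (", conditionMessage(e), ")"))
  if (length(dim(a)) == 3L) a <- a[, , 1]
  binary_mask(a > 0, spacing = spacing)
}

#' @rdname read_mask
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "binary_mask"))
  png::writePNG(mask$pixels * 1.0, path)
  invisible(path)
}

# ---- JSON model container ---------------------------------------------

# Numeric blocks are embedded as base64 little-endian doubles so model
# files stay portable, diffable and free of binary-serialization hazards.

enc_block <- function(x) {
  d <- dim(x)
  list(dim = if (is.null(d)) length(x) else d,
       data = jsonlite::base64_enc(writeBin(as.numeric(x), raw(),
                                            size = 8, endian = "little")))
}

dec_block <- function(b) {
  v <- readBin(jsonlite::base64_dec(b$data), "double",
               n = prod(unlist(b$dim)), size = 8, endian = "little")
  d <- unlist(b$dim)
  if (length(d) > 1L) dim(v) <- d
  v
}

save_model_json <- function(obj, path) {
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = FALSE)
  invisible(path)
}

load_model_json <- function(path) {
  if (!file.exists(path)) stop("load_model_json: no such file: ", path)
  jsonlite::read_json(path, simplifyVector = TRUE,
                      simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
}
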