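# Patch-based Active Appearance Model: Procrustes + PCA shape model,
# per-landmark patch appearance model, and inverse compositional
# Lucas-Kanade fitting (POIC, SIC, AIC, MAIC, WIC variants).

#' Generalized Procrustes alignment of landmark shapes
#'
#' Iterative similarity alignment: each shape is translated to zero
#' centroid and scaled to unit norm, then rotated onto the current mean
#' by least squares; the mean is renormalized and the loop repeats until
#' it moves by less than `tol` or `max_iter` rounds.
#'
#' @param shapes list of [landmark_set()]s or `n x 2` matrices (>= 2).
#' @param tol convergence tolerance on the mean shape.
#' @param max_iter iteration cap.
#' @return list with `aligned` (list of matrices), `mean_shape`
#'   (zero-centroid, unit-norm matrix) and `scales` (original centroid
#'   sizes).
#' @export
generalized_procrustes <- function(shapes, tol = 1e-7, max_iter = 100L) {
  if (length(shapes) < 2L)
    stop("generalized_procrustes: need at least 2 shapes")
  mats <- lapply(shapes, function(s)
    if (inherits(s, "landmark_set")) s$points else as.matrix(s))
  scales <- numeric(length(mats))
  norm_shape <- function(m) {
    m <- sweep(m, 2, colMeans(m))
    s <- sqrt(sum(m^2))
    if (s < 1e-12) stop("generalized_procrustes: degenerate ",
                        "(all-coincident) shape")
    list(m = m / s, s = s)
  }
  for (i in seq_along(mats)) {
    ns <- norm_shape(mats[[i]])
    mats[[i]] <- ns$m; scales[i] <- ns$s
  }
  rotate_onto <- function(m, ref) {
    sv <- svd(t(m) %*% ref)
    R <- sv$u %*% t(sv$v)
    if (det(R) < 0) {           # keep orientation (no reflections)
      sv$v[, 2] <- -sv$v[, 2]
      R <- sv$u %*% t(sv$v)
    }
    m %*% R
  }
  mean_s <- mats[[1]]
  for (it in seq_len(max_iter)) {
    mats <- lapply(mats, rotate_onto, ref = mean_s)
    new_mean <- Reduce(`+`, mats) / length(mats)
    new_mean <- sweep(new_mean, 2, colMeans(new_mean))
    new_mean <- new_mean / sqrt(sum(new_mean^2))
    delta <- sqrt(sum((new_mean - mean_s)^2))
    mean_s <- new_mean
    if (delta < tol) break
  }
  list(aligned = mats, mean_shape = mean_s, scales = scales)
}

# shapes vectorized as (x1, y1, x2, y2, ...)
vec_shape <- function(m) as.numeric(t(m))
unvec_shape <- function(v) matrix(v, ncol = 2, byrow = TRUE)

#' Build a PCA shape model from aligned shapes
#'
#' Eigen-decomposition of the covariance of the aligned shape vectors;
#' the smallest number of leading components whose cumulative variance
#' reaches `var_retained` is kept.
#'
#' @param aligned list of aligned shape matrices (from
#'   [generalized_procrustes()]).
#' @param var_retained fraction of variance to keep.
#' @return An object of class `shape_model` with `mean_shape` (32-vector),
#'   `eigenvectors` (32 x k, orthonormal), `eigenvalues` (descending).
#' @export
build_shape_model <- function(aligned, var_retained = 0.95) {
  if (length(aligned) < 2L) stop("build_shape_model: need >= 2 shapes")
  X <- t(vapply(aligned, vec_shape, numeric(2L * nrow(aligned[[1]]))))
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  C <- crossprod(Xc) / (nrow(X) - 1L)
  e <- eigen(C, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  k <- if (sum(vals) <= 1e-12) 0L else {
    cum <- cumsum(vals) / sum(vals)
    which(cum >= var_retained)[1]
  }
  structure(list(mean_shape = mu,
                 eigenvectors = if (k > 0) e$vectors[, seq_len(k), drop = FALSE]
                                else matrix(0, length(mu), 0),
                 eigenvalues = if (k > 0) vals[seq_len(k)] else numeric(0)),
            class = "shape_model")
}

#' @export
print.shape_model <- function(x, ...) {
  cat(sprintf("<shape_model %d landmarks, %d modes>\n",
              length(x$mean_shape) / 2, ncol(x$eigenvectors)))
  invisible(x)
}

# exact landmark scale factors used when an image is resized to (nr2, nc2)
resize_factors <- function(dim_in, dim_out) {
  fy <- if (dim_in[1] > 1) (dim_out[1] - 1) / (dim_in[1] - 1) else 1
  fx <- if (dim_in[2] > 1) (dim_out[2] - 1) / (dim_in[2] - 1) else 1
  c(fy = fy, fx = fx)
}

# z-score each patch column (its own mean/sd), sd floored for flat patches
zscore_patches <- function(P) {
  mu <- colMeans(P)
  sdv <- sqrt(pmax(colMeans(P^2) - mu^2, 0))
  sdv[sdv < 1e-8] <- 1
  sweep(sweep(P, 2, mu), 2, sdv, "/")
}

sample_appearance <- function(px, pts, ph, pw) {
  P <- cpp_extract_patches(px, pts[, 1], pts[, 2], ph, pw)
  as.numeric(zscore_patches(P))
}

#' Build a patch appearance model (with its shape model) from data
#'
#' For each pyramid scale the training images are resized, 17 x 17 (by
#' default) patches are sampled at the ground-truth landmarks with
#' bilinear subpixel interpolation (edge replication near borders, with
#' a warning), z-scored per landmark and concatenated into one
#' appearance vector; PCA keeps `var_retained` of the variance. The
#' shape model comes from generalized Procrustes + PCA on the landmark
#' sets.
#'
#' @param dataset list of `list(image =, landmarks =)` pairs.
#' @param patch_shape `c(h, w)`, both odd.
#' @param var_retained appearance variance fraction to keep.
#' @param var_shape shape variance fraction to keep.
#' @param scales pyramid downscale factors, finest (1.0) last.
#' @return An object of class `aam_model`.
#' @export
build_appearance_model <- function(dataset, patch_shape = c(17L, 17L),
                                   var_retained = 0.90, var_shape = 0.95,
                                   scales = c(0.5, 1.0)) {
  if (!length(dataset)) stop("build_appearance_model: empty dataset")
  ph <- as.integer(patch_shape[1]); pw <- as.integer(patch_shape[2])
  if (ph %% 2L == 0L || pw %% 2L == 0L)
    stop("build_appearance_model: patch_shape must be odd in both dims")
  shapes <- lapply(dataset, `[[`, "landmarks")
  gp <- generalized_procrustes(shapes)
  sm <- build_shape_model(gp$aligned, var_retained = var_shape)
  ref_scale <- mean(gp$scales)

  warned <- FALSE
  levels <- lapply(scales, function(sg) {
    X <- vapply(dataset, function(d) {
      px <- d$image$pixels
      din <- dim(px)
      dout <- pmax(round(din * sg), 2L)
      f <- resize_factors(din, dout)
      spx <- if (all(din == dout)) px else cpp_resize_bilinear(px, dout[1], dout[2])
      pts <- cbind(d$landmarks$points[, 1] * f["fx"],
                   d$landmarks$points[, 2] * f["fy"])
      if (!warned &&
          (any(pts[, 1] < pw %/% 2) || any(pts[, 2] < ph %/% 2) ||
           any(pts[, 1] > dout[2] - 1 - pw %/% 2) ||
           any(pts[, 2] > dout[1] - 1 - ph %/% 2))) {
        warning("build_appearance_model: landmark close to border; ",
                "patches padded by edge replication")
        warned <<- TRUE
      }
      sample_appearance(spx, pts, ph, pw)
    }, numeric(ph * pw * length(shapes[[1]]$points) / 2))
    mu <- rowMeans(X)
    Xc <- X - mu
    k_max <- min(nrow(Xc), ncol(Xc) - 1L)
    if (ncol(Xc) < 2L || sum(Xc^2) <= 1e-12) {
      basis <- matrix(0, length(mu), 0)
      vals <- numeric(0)
    } else {
      sv <- svd(Xc, nu = min(k_max, ncol(Xc)), nv = 0)
      vals <- (sv$d^2 / (ncol(Xc) - 1L))[seq_len(ncol(sv$u))]
      keep <- vals > 1e-12
      vals <- vals[keep]
      basis <- sv$u[, keep, drop = FALSE]
      if (length(vals)) {
        cum <- cumsum(vals) / sum(vals)
        k <- which(cum >= var_retained)[1]
        basis <- basis[, seq_len(k), drop = FALSE]
        vals <- vals[seq_len(k)]
      }
    }
    list(scale = sg, mean = mu, basis = basis, eigenvalues = vals)
  })

  structure(list(shape = sm, ref_scale = ref_scale,
                 patch_shape = c(ph, pw), scales = scales,
                 levels = levels,
                 n_landmarks = nrow(shapes[[1]]$points)),
            class = "aam_model")
}

#' Train an AAM from (image, landmarks) pairs
#'
#' Convenience wrapper around [build_appearance_model()].
#'
#' @param dataset list of `list(image =, landmarks =)` pairs.
#' @param ... forwarded to [build_appearance_model()].
#' @return An `aam_model`.
#' @export
train_aam <- function(dataset, ...) build_appearance_model(dataset, ...)

#' @export
print.aam_model <- function(x, ...) {
  cat(sprintf(paste0("<aam_model %d landmarks, %d shape modes, ",
                     "%s appearance modes, patches %dx%d, scales %s>\n"),
              x$n_landmarks, ncol(x$shape$eigenvectors),
              paste(vapply(x$levels, function(l) ncol(l$basis), 0L),
                    collapse = "/"),
              x$patch_shape[1], x$patch_shape[2],
              paste(x$scales, collapse = ", ")))
  invisible(x)
}

#' Randomly perturb a ground-truth shape (similarity jitter)
#'
#' Seeded similarity perturbation used to produce fitting
#' initializations: Gaussian translation with sd equal to `trans_frac`
#' of the shape's bounding-box diagonal on each axis, Gaussian rotation
#' (sd `rot_deg` degrees) and Gaussian scale (sd `scale_sigma`) about
#' the centroid.
#'
#' @param gt a [landmark_set()].
#' @param noise list: `trans_frac`, `scale_sigma`, `rot_deg`.
#' @param seed integer seed.
#' @return A perturbed [landmark_set()].
#' @export
perturb_shape <- function(gt, noise = list(trans_frac = 0.05,
                                           scale_sigma = 0.02, rot_deg = 3),
                          seed = 1L) {
  stopifnot(inherits(gt, "landmark_set"))
  set.seed(seed)
  p <- gt$points
  diag_len <- sqrt(sum((apply(p, 2, max) - apply(p, 2, min))^2))
  tx <- rnorm(1, 0, noise$trans_frac * diag_len)
  ty <- rnorm(1, 0, noise$trans_frac * diag_len)
  th <- rnorm(1, 0, noise$rot_deg * pi / 180)
  sc <- 1 + rnorm(1, 0, noise$scale_sigma)
  ctr <- colMeans(p)
  R <- sc * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  landmark_set(sweep(sweep(p, 2, ctr) %*% t(R), 2, ctr + c(tx, ty), "+"),
               frame = gt$frame)
}

# ---- fitting -----------------------------------------------------------

# landmark positions from params: L_i = M(q) (B_i + (V b)_i) + t
shape_from_params <- function(q, b, base, V) {
  m <- base
  if (length(b)) m <- m + unvec_shape(V %*% b)
  M <- matrix(c(1 + q[1], q[2], -q[2], 1 + q[1]), 2, 2)
  sweep(m %*% t(M), 2, q[3:4], "+")
}

# project landmarks to (q, b): similarity by complex regression, then
# shape coefficients on the residual (clamped to 3 sd)
params_from_shape <- function(pts, base, V, lam) {
  ctr <- colMeans(pts)
  Yc <- sweep(pts, 2, ctr)
  zB <- complex(real = base[, 1], imaginary = base[, 2])
  zY <- complex(real = Yc[, 1], imaginary = Yc[, 2])
  beta <- sum(Conj(zB) * zY) / sum(Mod(zB)^2)
  q <- c(Re(beta) - 1, Im(beta), ctr)
  b <- numeric(ncol(V))
  if (ncol(V)) {
    Minv <- solve(matrix(c(1 + q[1], q[2], -q[2], 1 + q[1]), 2, 2))
    res <- Yc %*% t(Minv) - base
    b <- as.numeric(crossprod(V, vec_shape(res))) / colSums(V^2)
    b <- pmin(pmax(b, -3 * sqrt(lam)), 3 * sqrt(lam))
  }
  list(q = q, b = b)
}

# gradients of a concatenated patch vector: list(gx, gy) per pixel
patch_gradients <- function(v, ph, pw, L) {
  gx <- numeric(length(v)); gy <- numeric(length(v))
  np <- ph * pw
  for (l in seq_len(L)) {
    m <- matrix(v[(l - 1) * np + seq_len(np)], ph, pw)
    dx <- m; dy <- m
    dx[, 2:(pw - 1)] <- (m[, 3:pw] - m[, 1:(pw - 2)]) / 2
    dx[, 1] <- m[, 2] - m[, 1]; dx[, pw] <- m[, pw] - m[, pw - 1]
    dy[2:(ph - 1), ] <- (m[3:ph, ] - m[1:(ph - 2), ]) / 2
    dy[1, ] <- m[2, ] - m[1, ]; dy[ph, ] <- m[ph, ] - m[ph - 1, ]
    gx[(l - 1) * np + seq_len(np)] <- as.numeric(dx)
    gy[(l - 1) * np + seq_len(np)] <- as.numeric(dy)
  }
  list(gx = gx, gy = gy)
}

# contract per-pixel gradients with landmark-motion derivatives:
# J[pix, param] = gx * dLx/dp + gy * dLy/dp
build_jacobian <- function(g, base, V, ph, pw) {
  L <- nrow(base)
  np_pix <- ph * pw
  k <- ncol(V)
  J <- matrix(0, np_pix * L, 4L + k)
  for (l in seq_len(L)) {
    idx <- (l - 1) * np_pix + seq_len(np_pix)
    gx <- g$gx[idx]; gy <- g$gy[idx]
    J[idx, 1] <- gx * base[l, 1] + gy * base[l, 2]          # scale-like
    J[idx, 2] <- -gx * base[l, 2] + gy * base[l, 1]          # rotation-like
    J[idx, 3] <- gx                                          # tx
    J[idx, 4] <- gy                                          # ty
    if (k) {
      vx <- V[2 * l - 1, , drop = FALSE]
      vy <- V[2 * l, , drop = FALSE]
      J[idx, 4 + seq_len(k)] <- gx %o% as.numeric(vx) + gy %o% as.numeric(vy)
    }
  }
  J
}

pinv_solve <- function(H, g, cutoff = 1e-10) {
  e <- eigen(H, symmetric = TRUE)
  keep <- e$values > cutoff * max(e$values, cutoff)
  if (!any(keep)) return(numeric(length(g)))
  e$vectors[, keep, drop = FALSE] %*%
    ((crossprod(e$vectors[, keep, drop = FALSE], g)) / e$values[keep])
}

AAM_ALGORITHMS <- c("POIC", "SIC", "AIC", "MAIC", "WIC")

#' Fit an AAM to an image by inverse compositional Lucas-Kanade
#'
#' Coarse-to-fine over the model's pyramid scales. At each iteration,
#' patches are sampled at the current landmarks and the appearance
#' residual drives a Gauss-Newton update of the shape parameters
#' (global similarity + shape modes). Variants:
#' \describe{
#'   \item{POIC}{project-out: shape step in the appearance-orthogonal
#'     complement, template-gradient Jacobian precomputed.}
#'   \item{SIC}{simultaneous: joint Gauss-Newton over shape and
#'     appearance parameters, Jacobian rebuilt from the current
#'     reconstruction.}
#'   \item{AIC}{alternating: shape step against the residual of the
#'     previous appearance estimate, then the appearance is re-solved.}
#'   \item{MAIC}{AIC with the appearance update applied before the
#'     residual used by the shape step is recomputed.}
#'   \item{WIC}{Wiberg: appearance parameters eliminated in closed form
#'     each iteration, shape step on the projected residual with the
#'     reconstruction-gradient Jacobian.}
#' }
#' The Gauss-Newton step is damped by 0.5 (up to 4 halvings) when the
#' cost increases; degenerate Hessians are handled by an eigenvalue
#' pseudo-inverse with cutoff 1e-10. Iterations are split evenly across
#' scales with the remainder given to the finest scale. Landmarks
#' leaving the image are clamped to the border and the fit is flagged
#' unconverged.
#'
#' @param image a [gray_image()].
#' @param model an `aam_model`.
#' @param init a [landmark_set()] initialization (inside the image).
#' @param algorithm one of `"POIC", "SIC", "AIC", "MAIC", "WIC"`.
#' @param n_iterations total iteration budget (default 25).
#' @param n_shape,n_appearance optional caps on the number of shape /
#'   appearance modes used.
#' @return An object of class `aam_fit` with `shapes` (list of
#'   `n_iterations + 1` landmark matrices at full-image scale, entry 1 =
#'   initialization), `costs`, `final` ([landmark_set()]) and
#'   `converged`.
#' @export
fit_aam <- function(image, model, init, algorithm = "WIC",
                    n_iterations = 25L, n_shape = NULL, n_appearance = NULL) {
  stopifnot(inherits(image, "gray_image"), inherits(model, "aam_model"),
            inherits(init, "landmark_set"))
  algorithm <- match.arg(algorithm, AAM_ALGORITHMS)
  ph <- model$patch_shape[1]; pw <- model$patch_shape[2]
  L <- model$n_landmarks
  mu <- unvec_shape(model$shape$mean_shape)
  Phi <- model$shape$eigenvectors
  lam <- model$shape$eigenvalues
  if (!is.null(n_shape) && ncol(Phi) > n_shape) {
    Phi <- Phi[, seq_len(n_shape), drop = FALSE]
    lam <- lam[seq_len(n_shape)]
  }
  din <- dim(image$pixels)

  n_scales <- length(model$scales)
  iters <- rep(n_iterations %/% n_scales, n_scales)
  iters[n_scales] <- iters[n_scales] + n_iterations %% n_scales

  shapes <- vector("list", n_iterations + 1L)
  costs <- numeric(n_iterations + 1L)
  shapes[[1L]] <- init$points
  cur_full <- init$points
  converged <- TRUE
  it_global <- 1L

  for (si in seq_len(n_scales)) {
    lev <- model$levels[[si]]
    sg <- lev$scale
    dout <- pmax(round(din * sg), 2L)
    f <- resize_factors(din, dout)
    px <- if (all(din == dout)) image$pixels
          else cpp_resize_bilinear(image$pixels, dout[1], dout[2])
    fmean <- mean(f)
    base <- mu * model$ref_scale * fmean
    V <- Phi * model$ref_scale * fmean
    A <- lev$basis
    if (!is.null(n_appearance) && ncol(A) > n_appearance)
      A <- A[, seq_len(n_appearance), drop = FALSE]
    xbar <- lev$mean
    g0 <- patch_gradients(xbar, ph, pw, L)
    J0 <- build_jacobian(g0, base, V, ph, pw)
    AtJ0 <- if (ncol(A)) crossprod(A, J0) else NULL
    Jk <- NULL
    if (algorithm %in% c("SIC", "WIC") && ncol(A)) {
      Jk <- lapply(seq_len(ncol(A)), function(k)
        build_jacobian(patch_gradients(A[, k], ph, pw, L), base, V, ph, pw))
    }
    Jpo <- if (ncol(A)) J0 - A %*% AtJ0 else J0
    Hpo <- crossprod(Jpo)

    cur <- cbind(cur_full[, 1] * f["fx"], cur_full[, 2] * f["fy"])
    pr <- params_from_shape(cur, base, V, lam)
    q <- pr$q; b <- pr$b
    c_app <- NULL

    sample_res <- function(q, b) {
      pts <- shape_from_params(q, b, base, V)
      clamped <- FALSE
      if (any(pts[, 1] < 0) || any(pts[, 1] > dout[2] - 1) ||
          any(pts[, 2] < 0) || any(pts[, 2] > dout[1] - 1)) {
        pts[, 1] <- pmin(pmax(pts[, 1], 0), dout[2] - 1)
        pts[, 2] <- pmin(pmax(pts[, 2], 0), dout[1] - 1)
        clamped <- TRUE
      }
      x <- sample_appearance(px, pts, ph, pw)
      r0 <- x - xbar
      cc <- if (ncol(A)) as.numeric(crossprod(A, r0)) else numeric(0)
      res <- if (ncol(A)) r0 - A %*% cc else r0
      list(pts = pts, r0 = r0, c = cc, cost = sum(res^2), clamped = clamped)
    }

    st <- sample_res(q, b)
    if (st$clamped) converged <- FALSE
    if (si == 1L) costs[1L] <- st$cost
    if (is.null(c_app)) c_app <- st$c

    for (k in seq_len(iters[si])) {
      r0 <- st$r0
      dp <- switch(algorithm,
        POIC = {
          r_perp <- if (ncol(A)) r0 - A %*% (crossprod(A, r0)) else r0
          pinv_solve(Hpo, crossprod(Jpo, r_perp))
        },
        AIC = {
          r <- if (ncol(A)) r0 - A %*% c_app else r0
          pinv_solve(crossprod(J0), crossprod(J0, r))
        },
        MAIC = {
          c_app <- st$c
          r <- if (ncol(A)) r0 - A %*% c_app else r0
          pinv_solve(crossprod(J0), crossprod(J0, r))
        },
        SIC = {
          cc <- st$c
          Js <- J0
          if (length(Jk))
            for (m in seq_along(Jk)) Js <- Js + cc[m] * Jk[[m]]
          Jfull <- cbind(Js, A)
          r <- if (ncol(A)) r0 - A %*% cc else r0
          d <- pinv_solve(crossprod(Jfull), crossprod(Jfull, r))
          d[seq_len(4L + length(b))]
        },
        WIC = {
          cc <- st$c
          Js <- J0
          if (length(Jk))
            for (m in seq_along(Jk)) Js <- Js + cc[m] * Jk[[m]]
          Jp <- if (ncol(A)) Js - A %*% crossprod(A, Js) else Js
          r <- if (ncol(A)) r0 - A %*% cc else r0
          pinv_solve(crossprod(Jp), crossprod(Jp, r))
        })
      dp <- as.numeric(dp)
      step <- 1
      for (h in 0:4) {
        q_new <- q - step * dp[1:4]
        b_new <- b
        if (length(b)) {
          b_new <- b - step * dp[4 + seq_along(b)]
          b_new <- pmin(pmax(b_new, -3 * sqrt(lam)), 3 * sqrt(lam))
        }
        st_new <- sample_res(q_new, b_new)
        if (st_new$cost <= st$cost || h == 4L) break
        step <- step / 2
      }
      q <- q_new; b <- b_new; st <- st_new
      if (algorithm == "AIC") c_app <- st$c
      if (st$clamped) converged <- FALSE
      cur_full <- cbind(st$pts[, 1] / f["fx"], st$pts[, 2] / f["fy"])
      it_global <- it_global + 1L
      shapes[[it_global]] <- cur_full
      costs[it_global] <- st$cost
    }
  }
  if (n_iterations == 0L) {
    shapes <- shapes[1L]
    costs <- costs[1L]
  }
  structure(list(shapes = shapes, costs = costs,
                 final = landmark_set(cur_full, frame = init$frame),
                 converged = converged, algorithm = algorithm),
            class = "aam_fit")
}

#' @export
print.aam_fit <- function(x, ...) {
  cat(sprintf("<aam_fit %s, %d iterations, final cost %.4g, converged %s>\n",
              x$algorithm, length(x$shapes) - 1L,
              x$costs[length(x$costs)], x$converged))
  invisible(x)
}

# mean Euclidean distance between corresponding landmarks
point_to_point_error <- function(a, b) {
  pa <- if (inherits(a, "landmark_set")) a$points else a
  pb <- if (inherits(b, "landmark_set")) b$points else b
  mean(sqrt(rowSums((pa - pb)^2)))
}

#' Compare fitting algorithms over repeated perturbed initializations
#'
#' For each pass, every test item gets a fresh seeded perturbed
#' initialization; each algorithm is fitted from the same
#' initialization; per-iteration masks (via the closed Catmull-Rom
#' contour) are scored against the ground-truth mask with TPF/FNF/FF.
#'
#' @param test_pairs list of `list(image =, landmarks =, mask =)` items.
#' @param model an `aam_model`.
#' @param algorithms character vector of fitter names.
#' @param n_passes perturbation repeats.
#' @param n_iterations iterations per fit.
#' @param noise perturbation parameters for [perturb_shape()].
#' @param seed master seed.
#' @return list with `per_iteration` (tibble: algorithm, iteration,
#'   mean TPF/FNF/FF) and `final` (tibble in the layout
#'   mean +/- halfwidth with sigma columns, one row per algorithm).
#' @export
compare_algorithms <- function(test_pairs, model,
                               algorithms = AAM_ALGORITHMS,
                               n_passes = 100L, n_iterations = 25L,
                               noise = list(trans_frac = 0.05,
                                            scale_sigma = 0.02, rot_deg = 3),
                               seed = 1L) {
  n_it <- n_iterations + 1L
  acc <- lapply(algorithms, function(a)
    list(tpf = matrix(NA_real_, 0, n_it), fnf = matrix(NA_real_, 0, n_it),
         ff = matrix(NA_real_, 0, n_it)))
  names(acc) <- algorithms
  for (p in seq_len(n_passes)) {
    for (i in seq_along(test_pairs)) {
      item <- test_pairs[[i]]
      init <- perturb_shape(item$landmarks, noise,
                            seed = derive_seed(seed, p * 1000L + i))
      for (a in algorithms) {
        fit <- fit_aam(item$image, model, init, algorithm = a,
                       n_iterations = n_iterations)
        row <- vapply(fit$shapes, function(s) {
          ctr <- catmull_rom_closed(s)
          m <- rasterize(ctr, dim(item$image$pixels), item$image$spacing)
          fr <- fractions(m, item$mask)
          c(fr$TPF, fr$FNF, fr$FF)
        }, numeric(3))
        acc[[a]]$tpf <- rbind(acc[[a]]$tpf, row[1, ])
        acc[[a]]$fnf <- rbind(acc[[a]]$fnf, row[2, ])
        acc[[a]]$ff <- rbind(acc[[a]]$ff, row[3, ])
      }
    }
  }
  per_it <- do.call(rbind, lapply(algorithms, function(a)
    data.frame(algorithm = a, iteration = 0:(n_it - 1L),
               TPF = colMeans(acc[[a]]$tpf), FNF = colMeans(acc[[a]]$fnf),
               FF = colMeans(acc[[a]]$ff))))
  final <- do.call(rbind, lapply(algorithms, function(a) {
    lastc <- n_it
    s_tpf <- summarize_ci(acc[[a]]$tpf[, lastc])
    s_fnf <- summarize_ci(acc[[a]]$fnf[, lastc])
    s_ff <- summarize_ci(acc[[a]]$ff[, lastc])
    data.frame(algorithm = a,
               TPF = s_tpf$mean, TPF_hw = s_tpf$halfwidth,
               FNF = s_fnf$mean, FNF_hw = s_fnf$halfwidth,
               FF = s_ff$mean, FF_hw = s_ff$halfwidth,
               sigma_TPF = s_tpf$sigma, sigma_FNF = s_fnf$sigma,
               sigma_FF = s_ff$sigma, n = s_ff$n)
  }))
  list(per_iteration = tibble::as_tibble(per_it),
       final = tibble::as_tibble(final))
}

#' Save / load an AAM model as a JSON container
#'
#' Numeric blocks are embedded as base64 doubles, so a save/load round
#' trip reproduces fitting results exactly.
#'
#' @param model an `aam_model`.
#' @param path file path.
#' @return `load_aam` returns the model; `save_aam` the path, invisibly.
#' @export
save_aam <- function(model, path) {
  stopifnot(inherits(model, "aam_model"))
  obj <- list(
    container = "vbseg-aam", version = 1L,
    n_landmarks = model$n_landmarks,
    ref_scale = model$ref_scale,
    patch_shape = model$patch_shape,
    scales = model$scales,
    shape = list(mean_shape = enc_block(model$shape$mean_shape),
                 eigenvectors = enc_block(model$shape$eigenvectors),
                 eigenvalues = enc_block(model$shape$eigenvalues)),
    levels = lapply(model$levels, function(l)
      list(scale = l$scale, mean = enc_block(l$mean),
           basis = enc_block(l$basis), eigenvalues = enc_block(l$eigenvalues))))
  save_model_json(obj, path)
}

#' @rdname save_aam
#' @export
load_aam <- function(path) {
  obj <- load_model_json(path)
  if (!identical(obj$container, "vbseg-aam"))
    stop("load_aam: not an AAM model container: ", path)
  sm <- structure(list(mean_shape = dec_block(obj$shape$mean_shape),
                       eigenvectors = as.matrix(dec_block(obj$shape$eigenvectors)),
                       eigenvalues = dec_block(obj$shape$eigenvalues)),
                  class = "shape_model")
  if (is.null(dim(sm$eigenvectors)))
    sm$eigenvectors <- matrix(sm$eigenvectors, length(sm$mean_shape), 0)
  structure(list(shape = sm, ref_scale = obj$ref_scale,
                 patch_shape = as.integer(unlist(obj$patch_shape)),
                 scales = as.numeric(unlist(obj$scales)),
                 levels = lapply(obj$levels, function(l)
                   list(scale = l$scale, mean = dec_block(l$mean),
                        basis = as.matrix(dec_block(l$basis)),
                        eigenvalues = dec_block(l$eigenvalues))),
                 n_landmarks = obj$n_landmarks),
            class = "aam_model")
}
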