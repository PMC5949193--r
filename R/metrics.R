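# Segmentation evaluation: overlap fractions, per-iteration convergence
# tables, the mean +/- halfwidth summary convention, intraclass
# correlation coefficients, and k-fold cross-validation.

#' Overlap fractions between an automatic and a reference mask
#'
#' With reference area `A_T` (expert) and segmented area `A_S`
#' (computer): `A_TP = A_S intersect A_T`, `A_FN = A_T \ A_S`,
#' `A_FP = A_S \ A_T`, and
#' \deqn{TPF = 100 A_{TP}/A_T, \quad FNF = 100 A_{FN}/A_T, \quad
#'       FF = 100 (1 - (A_{FP}+A_{FN})/A_T).}
#' `TPF + FNF = 100` exactly; `FF <= TPF`, with equality iff no false
#' positives; `FF` may be negative for gross over-segmentation and is
#' reported unclamped.
#'
#' @param a_S automatic segmentation, a [binary_mask()].
#' @param a_T reference (expert) segmentation, same shape, nonempty.
#' @return list of class `fraction_report` with pixel counts `a_T, a_S,
#'   a_TP, a_FN, a_FP` and percentages `TPF, FNF, FF`.
#' @export
fractions <- function(a_S, a_T) {
  stopifnot(inherits(a_S, "binary_mask"), inherits(a_T, "binary_mask"))
  if (!all(dim(a_S$pixels) == dim(a_T$pixels)))
    stop("fractions: mask shapes differ")
  nT <- sum(a_T$pixels)
  if (nT == 0L) stop("fractions: empty reference mask (A_T); ",
                     "the fractions are undefined")
  nTP <- sum(a_S$pixels & a_T$pixels)
  nFN <- nT - nTP
  nFP <- sum(a_S$pixels & !a_T$pixels)
  structure(list(a_T = nT, a_S = sum(a_S$pixels), a_TP = nTP,
                 a_FN = nFN, a_FP = nFP,
                 TPF = 100 * nTP / nT,
                 FNF = 100 * nFN / nT,
                 FF = 100 * (1 - (nFP + nFN) / nT)),
            class = "fraction_report")
}

#' @export
print.fraction_report <- function(x, ...) {
  cat(sprintf("<fractions TPF %.2f  FNF %.2f  FF %.2f (A_T = %d px)>\n",
              x$TPF, x$FNF, x$FF, x$a_T))
  invisible(x)
}

#' Mean, standard deviation and normal-approximation halfwidth
#'
#' The summary convention used throughout the result tables: the mean is
#' reported as `mean +/- halfwidth` where
#' `halfwidth = z * sigma / sqrt(n)` with `sigma` the n-1 standard
#' deviation and `z = 1.96` at the default `alpha = 0.05`.
#'
#' @param values numeric vector.
#' @param alpha significance level.
#' @return list of class `summary_stat`: `mean`, `sigma`, `halfwidth`,
#'   `n`.
#' @export
summarize_ci <- function(values, alpha = 0.05) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 1L) stop("summarize_ci: no finite values")
  z <- if (isTRUE(all.equal(alpha, 0.05))) 1.96 else qnorm(1 - alpha / 2)
  s <- if (n > 1L) stats::sd(values) else 0
  structure(list(mean = mean(values), sigma = s,
                 halfwidth = z * s / sqrt(n), n = n),
            class = "summary_stat")
}

#' @export
print.summary_stat <- function(x, ...) {
  cat(sprintf("%.2f ± %.2f (sigma %.2f, n %d)\n",
              x$mean, x$halfwidth, x$sigma, x$n))
  invisible(x)
}

#' Per-iteration convergence table against reference masks
#'
#' Each recorded shape of a fit is interpolated with the closed
#' centripetal Catmull-Rom contour, rasterized, and scored against every
#' reference mask; the last column is the arithmetic mean across
#' references. Iteration indexing starts at 0 (the initialization).
#'
#' @param shapes list of per-iteration landmark matrices (entry 1 =
#'   iteration 0), e.g. `fit$shapes` from [fit_aam()].
#' @param reference_masks list of [binary_mask()]s (one per expert).
#' @param shape image `c(nrow, ncol)`.
#' @param spacing pixel spacing.
#' @return tibble with columns `iteration`, per-reference
#'   `TPF_k, FNF_k, FF_k`, and `TPF_mean, FNF_mean, FF_mean`.
#' @export
convergence_table <- function(shapes, reference_masks, shape,
                              spacing = c(1, 1)) {
  n_ref <- length(reference_masks)
  rows <- lapply(seq_along(shapes), function(i) {
    ctr <- catmull_rom_closed(shapes[[i]])
    m <- rasterize(ctr, shape, spacing)
    vals <- lapply(reference_masks, function(ref) fractions(m, ref))
    out <- list(iteration = i - 1L)
    for (k in seq_len(n_ref)) {
      out[[paste0("TPF_", k)]] <- vals[[k]]$TPF
      out[[paste0("FNF_", k)]] <- vals[[k]]$FNF
      out[[paste0("FF_", k)]] <- vals[[k]]$FF
    }
    out$TPF_mean <- mean(vapply(vals, `[[`, 0, "TPF"))
    out$FNF_mean <- mean(vapply(vals, `[[`, 0, "FNF"))
    out$FF_mean <- mean(vapply(vals, `[[`, 0, "FF"))
    as.data.frame(out)
  })
  tibble::as_tibble(do.call(rbind, rows))
}

#' Intraclass correlation of two raters (two-way models)
#'
#' Two-way ANOVA mean squares over subjects x raters. The default
#' `"consistency"` model gives ICC(C,1) (and ICC(C,k) for average
#' measures); `"agreement"` gives ICC(A,1)/ICC(A,k). Confidence bounds
#' at level `alpha` come from the F distribution (exact for the
#' consistency model; the agreement bounds use the same F interval
#' applied to the consistency statistic, adequate for paired raters).
#'
#' @param x,y equal-length (>= 3) measurement vectors of the two raters.
#' @param model `"consistency"` (default) or `"agreement"`.
#' @param alpha significance level for the confidence interval.
#' @return list of class `icc_result`: `single`, `average`, `ci_low`,
#'   `ci_high` (single measures), `model`.
#' @export
icc_pair <- function(x, y, model = c("consistency", "agreement"),
                     alpha = 0.05) {
  model <- match.arg(model)
  if (length(x) != length(y)) stop("icc_pair: unequal lengths")
  n <- length(x)
  if (n < 3L) stop("icc_pair: need at least 3 subjects")
  dat <- cbind(x, y)
  k <- 2L
  gm <- mean(dat)
  row_m <- rowMeans(dat)
  col_m <- colMeans(dat)
  SSR <- k * sum((row_m - gm)^2)
  SSC <- n * sum((col_m - gm)^2)
  SST <- sum((dat - gm)^2)
  SSE <- SST - SSR - SSC
  MSR <- SSR / (n - 1)
  MSC <- SSC / (k - 1)
  MSE <- SSE / ((n - 1) * (k - 1))
  if (MSR <= 1e-15)
    stop("icc_pair: zero between-subject variance; ICC undefined")
  if (model == "consistency") {
    single <- (MSR - MSE) / (MSR + (k - 1) * MSE)
    average <- (MSR - MSE) / MSR
  } else {
    single <- (MSR - MSE) / (MSR + (k - 1) * MSE + k / n * (MSC - MSE))
    average <- (MSR - MSE) / (MSR + (MSC - MSE) / n)
  }
  # F-based interval for single measures
  Fobs <- MSR / MSE
  df1 <- n - 1; df2 <- (n - 1) * (k - 1)
  FL <- Fobs / stats::qf(1 - alpha / 2, df1, df2)
  FU <- Fobs * stats::qf(1 - alpha / 2, df2, df1)
  ci_low <- (FL - 1) / (FL + k - 1)
  ci_high <- (FU - 1) / (FU + k - 1)
  structure(list(single = single, average = average,
                 ci_low = ci_low, ci_high = ci_high, model = model),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("<icc (%s) single %.4f [%.4f, %.4f], average %.4f>\n",
              x$model, x$single, x$ci_low, x$ci_high, x$average))
  invisible(x)
}

#' Pairwise ICC matrices over a rater-by-subject table
#'
#' Computes [icc_pair()] for every unordered rater pair and the
#' per-rater mean of off-diagonal entries (the r-bar summary).
#'
#' @param areas numeric matrix, raters in rows, subjects in columns;
#'   rater names taken from rownames.
#' @param model passed to [icc_pair()].
#' @return list with `single` and `average` (symmetric matrices with NA
#'   diagonal) and `r_bar` (named vector of row means).
#' @export
icc_matrix <- function(areas, model = "consistency") {
  r <- nrow(areas)
  if (r < 2L) stop("icc_matrix: need at least 2 raters")
  nm <- rownames(areas)
  if (is.null(nm)) nm <- paste0("rater", seq_len(r))
  single <- matrix(NA_real_, r, r, dimnames = list(nm, nm))
  average <- matrix(NA_real_, r, r, dimnames = list(nm, nm))
  for (i in seq_len(r - 1L)) for (j in (i + 1L):r) {
    icc <- icc_pair(areas[i, ], areas[j, ], model = model)
    single[i, j] <- single[j, i] <- icc$single
    average[i, j] <- average[j, i] <- icc$average
  }
  r_bar <- rowMeans(single, na.rm = TRUE)
  list(single = single, average = average, r_bar = r_bar)
}

#' Seeded k-fold index split
#'
#' Shuffles `1..n_items` with the given seed and deals the items into
#' `k` folds whose sizes differ by at most 1; folds are disjoint and
#' cover all items.
#'
#' @param n_items number of items.
#' @param k number of folds.
#' @param seed integer seed.
#' @return list of `k` integer index vectors.
#' @export
kfold_split <- function(n_items, k = 10L, seed = 1L) {
  if (k < 2L) stop("kfold_split: k must be at least 2")
  if (k > n_items) stop("kfold_split: more folds than items")
  set.seed(seed)
  idx <- sample.int(n_items)
  fold_of <- rep(seq_len(k), length.out = n_items)
  lapply(seq_len(k), function(f) sort(idx[fold_of == f]))
}

#' k-fold cross-validation of the AAM segmentation stage
#'
#' For each fold the AAM is trained on the complement images' vertebrae
#' and fitted on the held-out fold's vertebrae from seeded perturbed
#' ground-truth initializations; the reference mask is the rasterized
#' ground-truth Catmull-Rom contour. Splitting is by image, never by
#' vertebra. Per-fold TPF/FNF/FF are summarized with the
#' mean +/- halfwidth convention; the mean row is the arithmetic mean of
#' the fold statistics.
#'
#' @param dataset a [generate_dataset()] result (or compatible list with
#'   `items`).
#' @param k number of folds (>= 2; `k = 1` is rejected since the train
#'   set would be empty).
#' @param seed master seed (drives both the split and the
#'   perturbations).
#' @param algorithm fitter passed to [fit_aam()].
#' @param n_iterations iterations per fit.
#' @param noise perturbation parameters for [perturb_shape()].
#' @param aam_args extra arguments to [train_aam()].
#' @return tibble in the k-fold table layout: columns `fold` (1..k then
#'   `"Mean"`), `TPF, TPF_hw, FNF, FNF_hw, FF, FF_hw, sigma_TPF,
#'   sigma_FNF, sigma_FF, n`.
#' @export
crossval <- function(dataset, k = 10L, seed = 1L, algorithm = "WIC",
                     n_iterations = 25L,
                     noise = list(trans_frac = 0.05, scale_sigma = 0.02,
                                  rot_deg = 3),
                     aam_args = list()) {
  items <- dataset$items
  if (k < 2L)
    stop("crossval: k must be at least 2 (k = 1 leaves no training set)")
  folds <- kfold_split(length(items), k = k, seed = seed)
  fold_rows <- vector("list", k)
  for (f in seq_len(k)) {
    test_idx <- folds[[f]]
    train_pairs <- dataset_pairs(list(items = items[-test_idx]))
    test_pairs <- dataset_pairs(list(items = items[test_idx]))
    model <- do.call(train_aam, c(list(train_pairs), aam_args))
    vals <- vapply(seq_along(test_pairs), function(i) {
      item <- test_pairs[[i]]
      init <- perturb_shape(item$landmarks, noise,
                            seed = derive_seed(seed, f * 100000L + i))
      fit <- fit_aam(item$image, model, init, algorithm = algorithm,
                     n_iterations = n_iterations)
      ref <- rasterize(catmull_rom_closed(item$landmarks),
                       dim(item$image$pixels), item$image$spacing)
      m <- rasterize(catmull_rom_closed(fit$final),
                     dim(item$image$pixels), item$image$spacing)
      fr <- fractions(m, ref)
      c(fr$TPF, fr$FNF, fr$FF)
    }, numeric(3))
    s_tpf <- summarize_ci(vals[1, ]); s_fnf <- summarize_ci(vals[2, ])
    s_ff <- summarize_ci(vals[3, ])
    fold_rows[[f]] <- data.frame(
      fold = as.character(f),
      TPF = s_tpf$mean, TPF_hw = s_tpf$halfwidth,
      FNF = s_fnf$mean, FNF_hw = s_fnf$halfwidth,
      FF = s_ff$mean, FF_hw = s_ff$halfwidth,
      sigma_TPF = s_tpf$sigma, sigma_FNF = s_fnf$sigma,
      sigma_FF = s_ff$sigma, n = s_ff$n)
  }
  tab <- do.call(rbind, fold_rows)
  mean_row <- tab[1, ]
  mean_row$fold <- "Mean"
  for (col in setdiff(names(tab), "fold"))
    mean_row[[col]] <- mean(tab[[col]])
  tibble::as_tibble(rbind(tab, mean_row))
}
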