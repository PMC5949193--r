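# End-to-end orchestration: read -> filter -> detect -> AAM segment ->
# interpolate -> evaluate, plus the thin command-line front-end.

#' Default run configuration
#'
#' Nested parameter list for every stage. Unknown keys are rejected by
#' [validate_config()]; every pipeline run persists its resolved
#' configuration next to its outputs.
#'
#' @return named nested list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    log_level = "info",
    preprocess = list(upsample_factor = 2L, kernel_a = -0.5,
                      skin_side = "left", quantile = 0.90,
                      sigma_px = 2, edge_threshold = 20),
    cascade = list(n_stages = 12L, min_hit_rate = 0.995,
                   max_false_alarm = 0.5, window = c(24L, 24L),
                   feature_stride = 3L, max_stumps = 25L, tilted = FALSE),
    detect = list(scale_factor = 1.1, step_px = 2L, min_neighbors = 3L),
    aam = list(algorithm = "WIC", n_iterations = 25L,
               patch_shape = c(17L, 17L), var_appearance = 0.90,
               var_shape = 0.95, scales = c(0.5, 1.0)),
    contour = list(alpha = 0.5, samples_per_segment = 20L),
    perturb = list(trans_frac = 0.05, scale_sigma = 0.02, rot_deg = 3)
  )
}

#' Validate and merge a run configuration
#'
#' Merges `config` over [default_config()], rejecting keys that the
#' defaults do not know (typo protection).
#'
#' @param config partial nested list.
#' @return the merged configuration.
#' @export
validate_config <- function(config = list()) {
  def <- default_config()
  check <- function(given, ref, path = "") {
    for (nm in names(given)) {
      if (!nm %in% names(ref))
        stop("validate_config: unknown key '", path, nm, "'")
      if (is.list(ref[[nm]]) && !is.null(names(ref[[nm]])) &&
          is.list(given[[nm]]))
        check(given[[nm]], ref[[nm]], paste0(path, nm, "."))
    }
  }
  check(config, def)
  modifyList(def, config)
}

# mean shape placed into a detection box (deployment-mode initialization)
init_from_box <- function(model, box, fill = 0.8) {
  mu <- unvec_shape(model$shape$mean_shape)
  bb_w <- diff(range(mu[, 1])); bb_h <- diff(range(mu[, 2]))
  s <- fill * min(box$width / bb_w, box$height / bb_h)
  ctr <- c(box$x + box$width / 2, box$y + box$height / 2)
  landmark_set(sweep(mu * s, 2, ctr, "+"), frame = "box-init")
}

#' Run the full segmentation pipeline on one image
#'
#' Preprocess, detect, size-filter, then for each detected box
#' initialize the AAM from the box-aligned mean shape (deployment mode)
#' or from a perturbed ground-truth shape (evaluation mode), fit,
#' interpolate the final landmarks with the closed centripetal
#' Catmull-Rom contour and rasterize the mask. When reference masks are
#' supplied, TPF/FNF/FF are reported per vertebra. Deterministic given
#' the configuration and seed.
#'
#' @param image a [gray_image()].
#' @param detector a `cascade_model`.
#' @param aam_model an `aam_model`.
#' @param config configuration (merged through [validate_config()]).
#' @param gt_landmarks optional list of ground-truth [landmark_set()]s
#'   (enables evaluation-mode initialization).
#' @param reference_masks optional list of [binary_mask()]s parallel to
#'   `gt_landmarks` for scoring.
#' @param mode `"deploy"` or `"evaluation"`.
#' @return list with `image` (preprocessed), `boxes`, `vertebrae` (per
#'   box: `landmarks`, `contour`, `mask`, `fit`), and `metrics` (tibble
#'   or NULL).
#' @export
pipeline_run <- function(image, detector, aam_model, config = list(),
                         gt_landmarks = NULL, reference_masks = NULL,
                         mode = c("deploy", "evaluation")) {
  mode <- match.arg(mode)
  if (is.null(detector) || is.null(aam_model))
    stop("pipeline_run: detector and AAM model are required")
  cfg <- validate_config(config)
  pre <- preprocess_image(image, cfg$preprocess)
  img <- pre$image
  f <- cfg$preprocess$upsample_factor

  boxes <- detect(img, detector, scale_factor = cfg$detect$scale_factor,
                  step_px = cfg$detect$step_px,
                  min_neighbors = cfg$detect$min_neighbors)
  boxes <- filter_by_size(boxes)
  if (nrow(boxes) == 0L)
    warning("pipeline_run: detector found no vertebrae")

  vertebrae <- list()
  metrics <- NULL
  if (mode == "evaluation" && !is.null(gt_landmarks)) {
    inits <- lapply(seq_along(gt_landmarks), function(i) {
      gt <- gt_landmarks[[i]]
      scaled <- landmark_set(gt$points * f, frame = gt$frame)
      perturb_shape(scaled, cfg$perturb,
                    seed = derive_seed(cfg$seed, i))
    })
  } else {
    inits <- lapply(seq_len(nrow(boxes)), function(i)
      init_from_box(aam_model, boxes[i, ]))
  }
  rows <- list()
  for (i in seq_along(inits)) {
    fit <- fit_aam(img, aam_model, inits[[i]],
                   algorithm = cfg$aam$algorithm,
                   n_iterations = cfg$aam$n_iterations)
    ctr <- catmull_rom_closed(fit$final, alpha = cfg$contour$alpha,
                              samples_per_segment = cfg$contour$samples_per_segment)
    mask <- rasterize(ctr, dim(img$pixels), img$spacing)
    vertebrae[[i]] <- list(landmarks = fit$final, contour = ctr,
                           mask = mask, fit = fit)
    if (!is.null(reference_masks) && i <= length(reference_masks)) {
      ref <- reference_masks[[i]]
      if (!all(dim(ref$pixels) == dim(mask$pixels))) {
        # references live on the original grid; rescale the mask back
        small <- rasterize(
          catmull_rom_closed(landmark_set(fit$final$points / f)),
          dim(ref$pixels), ref$spacing)
        fr <- fractions(small, ref)
      } else fr <- fractions(mask, ref)
      rows[[length(rows) + 1L]] <-
        data.frame(vertebra = i, TPF = fr$TPF, FNF = fr$FNF, FF = fr$FF)
    }
  }
  if (length(rows)) metrics <- tibble::as_tibble(do.call(rbind, rows))
  list(image = img, boxes = boxes, vertebrae = vertebrae,
       metrics = metrics, config = cfg)
}

# ---- command-line front end -------------------------------------------

cli_parse <- function(args) {
  if (!length(args)) stop("usage: vbseg <subcommand> [--key value ...]")
  cmd <- args[[1]]
  rest <- args[-1]
  opts <- list()
  i <- 1L
  while (i <= length(rest)) {
    key <- rest[[i]]
    if (!startsWith(key, "--"))
      stop("vbseg_cli: expected --key, got '", key, "'")
    opts[[substring(key, 3)]] <- rest[[i + 1L]]
    i <- i + 2L
  }
  list(cmd = cmd, opts = opts)
}

cli_num <- function(opts, key, default) {
  if (is.null(opts[[key]])) default else as.numeric(opts[[key]])
}

write_resolved_config <- function(cfg, out_dir) {
  jsonlite::write_json(cfg, file.path(out_dir, "resolved_config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Command-line entry point
#'
#' Thin dispatcher behind the `vbseg` Rscript front-end
#' (`inst/cli/vbseg.R`). Subcommands: `synth` (phantom dataset),
#' `train-detector`, `detect`, `train-aam`, `segment`, `evaluate`,
#' `crossval`. Global flags: `--config cfg.yaml` (nested run
#' configuration, validated against [default_config()]), `--seed`,
#' `--out`. Every run writes its resolved configuration next to its
#' outputs, so results are reproducible from the persisted config.
#'
#' @param args character vector of command-line arguments.
#' @return invisibly, the subcommand's result.
#' @export
vbseg_cli <- function(args) {
  p <- cli_parse(args)
  opts <- p$opts
  seed <- as.integer(cli_num(opts, "seed", 1))
  out <- opts[["out"]]
  user_cfg <- list()
  if (!is.null(opts[["config"]])) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("vbseg_cli: the yaml package is required for --config")
    user_cfg <- yaml::read_yaml(opts[["config"]])
  }
  cfg <- validate_config(modifyList(user_cfg, list(seed = seed)))
  switch(p$cmd,
    synth = {
      if (is.null(out)) stop("synth: --out DIR is required")
      n <- as.integer(cli_num(opts, "n", 10))
      dir.create(out, recursive = TRUE, showWarnings = FALSE)
      ds <- generate_dataset(n, phantom_spec(), seed = seed, dir = out)
      write_resolved_config(cfg, out)
      invisible(ds)
    },
    `train-detector` = {
      if (is.null(opts[["data"]]) || is.null(out))
        stop("train-detector: --data DIR(seed spec: 'n:seed') and --out FILE required")
      spec <- strsplit(opts[["data"]], ":")[[1]]
      ds <- generate_dataset(as.integer(spec[1]), phantom_spec(),
                             seed = as.integer(spec[2]))
      tr <- detector_training_set(ds)
      model <- train_cascade(tr$positives, tr$negatives,
                             params = c(cfg$cascade, list(seed = seed)))
      save_cascade(model, out)
      invisible(model)
    },
    detect = {
      if (is.null(opts[["image"]]) || is.null(opts[["model"]]) || is.null(out))
        stop("detect: --image --model --out required")
      img <- read_image_png(opts[["image"]])
      model <- load_cascade(opts[["model"]])
      boxes <- filter_by_size(detect(img, model))
      jsonlite::write_json(as.data.frame(boxes), out, digits = NA)
      invisible(boxes)
    },
    `train-aam` = {
      if (is.null(opts[["data"]]) || is.null(out))
        stop("train-aam: --data 'n:seed' and --out FILE required")
      spec <- strsplit(opts[["data"]], ":")[[1]]
      ds <- generate_dataset(as.integer(spec[1]), phantom_spec(),
                             seed = as.integer(spec[2]))
      model <- train_aam(dataset_pairs(ds))
      save_aam(model, out)
      invisible(model)
    },
    segment = {
      if (is.null(opts[["image"]]) || is.null(opts[["detector"]]) ||
          is.null(opts[["aam"]]) || is.null(out))
        stop("segment: --image --detector --aam --out required")
      img <- read_image_png(opts[["image"]])
      res <- pipeline_run(img, load_cascade(opts[["detector"]]),
                          load_aam(opts[["aam"]]), config = cfg)
      dir.create(out, recursive = TRUE, showWarnings = FALSE)
      jsonlite::write_json(
        list(boxes = as.data.frame(res$boxes),
             landmarks = lapply(res$vertebrae, function(v)
               unname(as.data.frame(v$landmarks$points)))),
        file.path(out, "result.json"), digits = NA)
      for (i in seq_along(res$vertebrae))
        write_mask(res$vertebrae[[i]]$mask,
                   file.path(out, sprintf("mask_%02d.png", i)))
      write_resolved_config(res$config, out)
      invisible(res)
    },
    evaluate = {
      if (is.null(opts[["pred"]]) || is.null(opts[["ref"]]) || is.null(out))
        stop("evaluate: --pred MASK --ref MASK --out FILE required")
      fr <- fractions(read_mask(opts[["pred"]]), read_mask(opts[["ref"]]))
      utils::write.csv(data.frame(TPF = fr$TPF, FNF = fr$FNF, FF = fr$FF),
                       out, row.names = FALSE)
      invisible(fr)
    },
    crossval = {
      if (is.null(opts[["data"]]) || is.null(out))
        stop("crossval: --data 'n:seed' and --out FILE required")
      spec <- strsplit(opts[["data"]], ":")[[1]]
      ds <- generate_dataset(as.integer(spec[1]), phantom_spec(),
                             seed = as.integer(spec[2]))
      k <- as.integer(cli_num(opts, "k", 5))
      tab <- crossval(ds, k = k, seed = seed,
                      n_iterations = as.integer(cli_num(opts, "iterations", 25)))
      utils::write.csv(as.data.frame(tab), out, row.names = FALSE)
      invisible(tab)
    },
    stop("vbseg_cli: unknown subcommand '", p$cmd, "'"))
}

#' Build detector training material from a phantom dataset
#'
#' Positive crops are the ground-truth vertebra boxes; negatives are the
#' same images with every vertebra inpainted away (background
#' reconstruction).
#'
#' @param dataset a [generate_dataset()] result.
#' @param inpaint_negatives reconstruct negatives by inpainting (TRUE)
#'   or reuse images without modification.
#' @return list with `positives` (crop matrices) and `negatives`
#'   ([gray_image()]s).
#' @export
detector_training_set <- function(dataset, inpaint_negatives = TRUE) {
  positives <- list()
  images <- list()
  boxes_per_image <- list()
  for (it in dataset$items) {
    px <- it$image$pixels
    bx <- do.call(rbind, lapply(it$vertebrae, function(v)
      data.frame(x = v$box$x, y = v$box$y, width = v$box$width,
                 height = v$box$height)))
    for (v in it$vertebrae) {
      b <- v$box
      positives[[length(positives) + 1L]] <-
        crop_resize(px, b$x, b$y, b$width, b$height, 24L, 24L)
    }
    images[[length(images) + 1L]] <- it$image
    boxes_per_image[[length(boxes_per_image) + 1L]] <- bx
  }
  negatives <- if (inpaint_negatives)
    generate_negatives(images, boxes_per_image)
  else list()
  # annotated originals double as hard-negative sources: mined windows
  # must keep clear of the ground-truth boxes
  hard <- lapply(seq_along(images), function(i)
    list(image = images[[i]], avoid = boxes_per_image[[i]]))
  list(positives = positives, negatives = c(negatives, hard))
}
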