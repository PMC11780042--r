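# Pipeline orchestration: configuration, training of the three models,
# end-to-end inference and the evaluation protocol over a dataset.

#' Pipeline configuration
#'
#' `default_config()` returns the standard clinical configuration: 1 mm
#' isotropic resampling; maximum-intensity sagittal projection over the
#' central half of the right-left extent; localization windows
#' [1000, 2000], [400, 500], [800, 1900] on a 128 x 256 grid with Gaussian
#' sigma 15; L1 segmentation window [-1024, 500] and L3 windows
#' [-1024, 2048], [-190, -30], [40, 100] on a 512 grid; 5-fold
#' cross-validation. `phantom_scale_config()` adapts grid-dependent entries
#' to the reduced-resolution phantoms (2 mm voxels, 96 slice grid) while
#' keeping every window, sigma and the projection geometry identical.
#'
#' @return a nested list of configuration entries.
#' @export
default_config <- function() {
  list(
    iso_spacing = 1,
    projection = list(mode = "mip", slab_frac = 0.5),
    sigma = 15,
    loc_windows = list(c(1000, 2000), c(400, 500), c(800, 1900)),
    loc_grid = c(128L, 256L),
    l1_window = c(-1024, 500),
    l3_windows = list(c(-1024, 2048), c(-190, -30), c(40, 100)),
    seg_grid = 512L,
    postprocess = list(modal_iterations = 0L),
    k = 5L,
    model = list(loc_base = 6L, seg_base = 8L),
    training = list(lr_loc = 1e-3, lr_seg = 3e-4, batch = 8L,
                    epochs_loc = 60L, epochs_seg = 40L,
                    patience = 10L, validation_frac = 0.1, dice_weight = 1,
                    seed = 42L)
  )
}

#' @rdname default_config
#' @export
phantom_scale_config <- function() {
  cfg <- default_config()
  cfg$iso_spacing <- 2
  cfg$seg_grid <- 96L
  # halve the projection grid and sigma together (same angular extent) so a
  # tiny localizer trains on one CPU in minutes
  cfg$loc_grid <- c(64L, 128L)
  cfg$sigma <- 7.5
  cfg$model$loc_base <- 4L
  cfg$training$epochs_loc <- 30L
  cfg$training$patience <- 8L
  # at this region size single-pixel boundary errors are proportionally
  # large, so the optional modal post-processing is enabled
  cfg$postprocess$modal_iterations <- 1L
  cfg
}

#' Read / write a configuration as YAML
#'
#' @param config a configuration list.
#' @param path YAML file path.
#' @return `config_load` returns the configuration list.
#' @export
config_save <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname config_save
#' @export
config_load <- function(path) {
  yaml::read_yaml(path)
}

# ---- localization stage -----------------------------------------------------

# Projection record + windowed channels for one volume.
project_volume <- function(vol, config) {
  iso <- resample_isotropic(vol, config$iso_spacing)
  proj <- sagittal_project(iso, mode = config$projection$mode,
                           slab_frac = config$projection$slab_frac)
  ch <- window_channels(proj$img, config$loc_windows)
  rec <- resize_to_grid(ch, proj$spacing, shape = config$loc_grid,
                        subject = vol$subject)
  list(iso = iso, record = rec)
}

# Ground-truth centre of an annotation in projection-grid pixels.
center_to_px <- function(record, center, spacing) {
  mm <- c(center[2] * spacing[2], center[3] * spacing[3])  # (AP, SI) mm
  mm_to_px(record, mm)[1, ]
}

#' Build one localization training example
#'
#' Projects the volume, composes the window channels and renders the
#' Gaussian heatmap target from the annotated centres.
#'
#' @param vol a [ct_volume()]; @param ann its [annotation()].
#' @param config pipeline configuration.
#' @return list with `x` (input array), `y` (target heatmap array), `record`
#'   and `iso`.
#' @export
localization_example <- function(vol, ann, config = default_config()) {
  pr <- project_volume(vol, config)
  p1 <- center_to_px(pr$record, ann$l1_center, vol$spacing)
  p3 <- center_to_px(pr$record, ann$l3_center, vol$spacing)
  hm <- make_target(rbind(p1, p3), shape = config$loc_grid, sigma = config$sigma)
  y <- hm$values
  dim(y) <- c(dim(y), 1L)
  list(x = pr$record$channels, y = y, record = pr$record, iso = pr$iso)
}

#' Train the vertebra localization model
#'
#' @param dataset list of subjects, each a list with `volume` and
#'   `annotation` (the format produced by [generate_dataset()]).
#' @param config pipeline configuration.
#' @param verbose print per-epoch losses.
#' @return a trained `bodycomp_cnn` heatmap model.
#' @export
train_localizer <- function(dataset, config = phantom_scale_config(),
                            verbose = FALSE) {
  exs <- lapply(dataset, function(s)
    localization_example(s$volume, s$annotation, config))
  tr <- config$training
  model <- build_multiresunet(c(config$loc_grid, length(config$loc_windows)),
                              base = config$model$loc_base, seed = tr$seed)
  cnn_fit(model, lapply(exs, `[[`, "x"), lapply(exs, `[[`, "y"),
          epochs = tr$epochs_loc, batch = tr$batch, lr = tr$lr_loc,
          validation_frac = tr$validation_frac, patience = tr$patience,
          seed = tr$seed + 1L, verbose = verbose)
}

#' Locate the L1 and L3 slices of a volume
#'
#' @param model trained heatmap model.
#' @param vol a [ct_volume()].
#' @param config pipeline configuration.
#' @return list with `pred` (a `center_prediction` in the isotropic frame),
#'   `heatmap`, `record` and `iso`.
#' @export
predict_centers <- function(model, vol, config = phantom_scale_config()) {
  pr <- project_volume(vol, config)
  hm <- predict(model, pr$record$channels)
  pred <- extract_centers(hm, pr$record, pr$iso, sigma = config$sigma)
  list(pred = pred, heatmap = hm, record = pr$record, iso = pr$iso)
}

# ---- segmentation stage -----------------------------------------------------

one_hot <- function(labels, n_classes) {
  y <- array(0, c(dim(labels), n_classes))
  for (c in seq_len(n_classes)) y[, , c] <- labels == (c - 1L)
  y
}

# Pad/crop a ground-truth mask with the same geometry extract_axial_slice
# uses for the HU slice (background outside).
pad_mask_to_grid <- function(mask, grid) {
  d <- dim(mask$labels)
  out <- matrix(0L, grid, grid)
  src <- pmin(d, grid)
  off_in <- floor((d - src) / 2)
  off_out <- floor((grid - src) / 2)
  out[off_out[1] + seq_len(src[1]), off_out[2] + seq_len(src[2])] <-
    mask$labels[off_in[1] + seq_len(src[1]), off_in[2] + seq_len(src[2])]
  label_mask(out, mask$level, mask$classes)
}

seg_example <- function(vol, ann, level, config) {
  iso <- resample_isotropic(vol, config$iso_spacing)
  center <- if (level == "L1") ann$l1_center else ann$l3_center
  # slice index in the isotropic frame
  k <- round(center[3] * vol$spacing[3] / config$iso_spacing)
  sl <- extract_axial_slice(iso, k, level, grid = config$seg_grid)
  x <- if (level == "L1") preprocess_l1(sl, config$l1_window)
       else preprocess_l3(sl, config$l3_windows)
  mask <- pad_mask_to_grid(if (level == "L1") ann$l1_mask else ann$l3_mask,
                           config$seg_grid)
  list(x = x, y = one_hot(mask$labels, length(mask$classes)),
       mask = mask, slice = sl)
}

#' Train a per-level segmentation U-Net
#'
#' @param dataset list of subjects with `volume` and `annotation`.
#' @param level "L1" or "L3".
#' @param config pipeline configuration.
#' @param verbose print per-epoch losses.
#' @return a trained `bodycomp_cnn` segmentation model.
#' @export
train_segmenter <- function(dataset, level, config = phantom_scale_config(),
                            verbose = FALSE) {
  classes <- level_classes(level)
  exs <- lapply(dataset, function(s)
    seg_example(s$volume, s$annotation, level, config))
  tr <- config$training
  n_ch <- if (level == "L1") 1L else length(config$l3_windows)
  ys <- lapply(exs, `[[`, "y")
  priors <- colMeans(do.call(rbind, lapply(ys, function(y) apply(y, 3, mean))))
  model <- build_unet(c(config$seg_grid, config$seg_grid, n_ch),
                      n_classes = length(classes),
                      base = config$model$seg_base,
                      level = level, classes = classes, seed = tr$seed + 2L,
                      class_priors = pmax(priors, 1e-4))
  cnn_fit(model, lapply(exs, `[[`, "x"), ys,
          epochs = tr$epochs_seg, batch = tr$batch, lr = tr$lr_seg,
          dice_weight = tr$dice_weight,
          validation_frac = tr$validation_frac, patience = tr$patience,
          seed = tr$seed + 3L, verbose = verbose)
}

# ---- end-to-end -------------------------------------------------------------

#' Run the full pipeline on one volume
#'
#' Localizes the L1/L3 slices, segments them and quantifies the seven
#' body-composition indices. A localization failure propagates as a
#' `bodycomp_detection_failure` error rather than a silent fallback.
#'
#' @param vol a [ct_volume()].
#' @param models list with `localizer`, `l1`, `l3` trained models.
#' @param config pipeline configuration.
#' @param debug_dir if non-NULL, intermediate artifacts (projection record,
#'   heatmap, slices, masks) are saved there as RDS/NIfTI.
#' @return list with `centers` (a `center_prediction`), `l1_mask`, `l3_mask`
#'   (predicted [label_mask()]s) and `report` (an `index_report`).
#' @export
run_pipeline <- function(vol, models, config = phantom_scale_config(),
                         debug_dir = NULL) {
  stopifnot(inherits(models$localizer, "bodycomp_cnn"),
            identical(models$l1$manifest$level, "L1"),
            identical(models$l3$manifest$level, "L3"))
  if (!identical(as.integer(models$localizer$input_shape[1:2]),
                 as.integer(config$loc_grid)))
    stop("localizer grid does not match configuration")
  if (models$l1$input_shape[1] != config$seg_grid)
    stop("segmentation grid does not match configuration")
  loc <- predict_centers(models$localizer, vol, config)
  iso <- loc$iso
  sl1 <- extract_axial_slice(iso, loc$pred$l1$slice, "L1", grid = config$seg_grid)
  sl3 <- extract_axial_slice(iso, loc$pred$l3$slice, "L3", grid = config$seg_grid)
  m1 <- predict_mask(models$l1, preprocess_l1(sl1, config$l1_window))
  m3 <- predict_mask(models$l3, preprocess_l3(sl3, config$l3_windows))
  it <- config$postprocess$modal_iterations
  if (!is.null(it) && it > 0) {
    m1 <- smooth_mask(m1, it)
    m3 <- smooth_mask(m3, it)
  }
  report <- compute_report(m1, sl1$hu, m3, sl3$hu, iso$spacing[1:2],
                           subject = vol$subject)
  if (!is.null(debug_dir)) {
    dir.create(debug_dir, recursive = TRUE, showWarnings = FALSE)
    saveRDS(list(record = loc$record, heatmap = loc$heatmap,
                 slices = list(L1 = sl1, L3 = sl3),
                 masks = list(L1 = m1, L3 = m3)),
            file.path(debug_dir, paste0(vol$subject, "_intermediates.rds")))
  }
  list(centers = loc$pred, l1_mask = m1, l3_mask = m3, report = report)
}

#' Ground-truth index report of an annotated subject
#'
#' Computes the seven indices from the annotated masks and the HU content of
#' the true L1/L3 slices, on the same isotropic grid the pipeline segments.
#'
#' @param subject a list with `volume` and `annotation`.
#' @param config pipeline configuration.
#' @return an `index_report`.
#' @export
reference_report <- function(subject, config = phantom_scale_config()) {
  e1 <- seg_example(subject$volume, subject$annotation, "L1", config)
  e3 <- seg_example(subject$volume, subject$annotation, "L3", config)
  compute_report(e1$mask, e1$slice$hu, e3$mask, e3$slice$hu,
                 e1$slice$spacing, subject = subject$volume$subject)
}

#' Evaluate trained models over an annotated dataset
#'
#' Applies the full evaluation protocol: per-case localization errors (SI mm
#' and slices), per-class Dice of the masks predicted at the true slices,
#' and predicted-vs-reference index reports from the end-to-end pipeline.
#'
#' @param models list with `localizer`, `l1`, `l3`.
#' @param dataset list of subjects with `volume` and `annotation`.
#' @param config pipeline configuration.
#' @return list with data.frames `localization`, `dice`, `indices`.
#' @export
evaluate_pipeline <- function(models, dataset, config = phantom_scale_config()) {
  loc_rows <- list(); dice_rows <- list(); idx_rows <- list()
  for (s in dataset) {
    vol <- s$volume; ann <- s$annotation
    out <- run_pipeline(vol, models, config)
    iso <- resample_isotropic(vol, config$iso_spacing)
    # localization error against the annotation mapped into the iso frame
    truth_iso <- annotation(
      ann$l1_center * vol$spacing / config$iso_spacing,
      ann$l3_center * vol$spacing / config$iso_spacing,
      subject = ann$subject)
    err <- localization_error(out$centers, truth_iso, iso)
    loc_rows[[vol$subject]] <- data.frame(subject = vol$subject, t(err))
    # Dice at the true slices (segmentation quality in isolation)
    e1 <- seg_example(vol, ann, "L1", config)
    e3 <- seg_example(vol, ann, "L3", config)
    p1 <- predict_mask(models$l1, e1$x)
    p3 <- predict_mask(models$l3, e3$x)
    it <- config$postprocess$modal_iterations
    if (!is.null(it) && it > 0) {
      p1 <- smooth_mask(p1, it)
      p3 <- smooth_mask(p3, it)
    }
    dice_rows[[vol$subject]] <- data.frame(
      subject = vol$subject,
      trabecular = vdsc(p1, e1$mask, "trabecular"),
      cortical = vdsc(p1, e1$mask, "cortical"),
      sma = vdsc(p3, e3$mask, "sma"),
      vat = vdsc(p3, e3$mask, "vat"),
      sat = vdsc(p3, e3$mask, "sat"))
    ref <- compute_report(e1$mask, e1$slice$hu, e3$mask, e3$slice$hu,
                          e1$slice$spacing, subject = vol$subject)
    pred_df <- as.data.frame(out$report)
    ref_df <- as.data.frame(ref)
    idx_rows[[vol$subject]] <- data.frame(
      subject = vol$subject, index = index_names,
      pred = unlist(pred_df[index_names], use.names = FALSE),
      truth = unlist(ref_df[index_names], use.names = FALSE))
  }
  list(localization = do.call(rbind, c(loc_rows, make.row.names = FALSE)),
       dice = do.call(rbind, c(dice_rows, make.row.names = FALSE)),
       indices = do.call(rbind, c(idx_rows, make.row.names = FALSE)))
}

#' Train the three pipeline models with k-fold cross-validation
#'
#' Trains the localizer and both U-Nets inside each fold, evaluates on the
#' held-out fold, aggregates fold metrics as mean +/- sd, and finally
#' retrains all models on the complete dataset.
#'
#' @param dataset list of subjects with `volume` and `annotation`.
#' @param config pipeline configuration (`config$k` folds).
#' @return list with `folds`, `aggregate`, `assignments` and `final` (the
#'   model set trained on all subjects).
#' @export
train_all <- function(dataset, config = phantom_scale_config()) {
  if (length(dataset) < config$k)
    stop("dataset smaller than k = ", config$k)
  train_fn <- function(train_set) {
    list(localizer = train_localizer(train_set, config),
         l1 = train_segmenter(train_set, "L1", config),
         l3 = train_segmenter(train_set, "L3", config))
  }
  metric_fn <- function(models, test_set) {
    ev <- evaluate_pipeline(models, test_set, config)
    pres <- vapply(split(ev$indices, ev$indices$index),
                   function(d) mean(pre(d$pred, d$truth)), 0)
    c(mae_l1 = mean(ev$localization$l1_mm),
      mae_l3 = mean(ev$localization$l3_mm),
      dice_trabecular = mean(ev$dice$trabecular),
      dice_cortical = mean(ev$dice$cortical),
      dice_sma = mean(ev$dice$sma),
      dice_vat = mean(ev$dice$vat),
      dice_sat = mean(ev$dice$sat),
      mean_pre = mean(pres))
  }
  kfold_harness(dataset, k = config$k, seed = config$training$seed,
                train_fn = train_fn, metric_fn = metric_fn, final_fit = TRUE)
}
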