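#' Preprocess one slide into quality-filtered, normalized tile features
#'
#' Tessellates the annotated slide, applies \code{\link{qc_tile}} to every
#' candidate tile, estimates the slide's stain profile from a pixel sample
#' of the accepted tiles, normalizes each accepted tile to the reference
#' profile and featurizes it for the backbone.  Optionally writes the
#' normalized tiles as PNG.
#'
#' @param image \code{height x width x 3} slide array in \[0, 1\].
#' @param annotation The slide's \code{"tumor_annotation"}.
#' @param tile_edge Tile edge in pixels (default 512).
#' @param min_tumor_fraction Tumor-fraction retention threshold
#'   (default 0.5).
#' @param backbone \code{\link{backbone_spec}} used for featurization.
#' @param target Reference stain profile (default
#'   \code{\link{default_stain_profile}()}).
#' @param normalize Apply stain normalization (default \code{TRUE}).
#' @param tile_dir Optional directory to write normalized tiles as PNG.
#' @param qc_args Named list of \code{\link{qc_tile}} threshold overrides.
#' @return List with \code{manifest} (one row per candidate tile:
#'   \code{slide_id, grid_row, grid_col, tumor_fraction, qc_status,
#'   tile_path}) and \code{features} (matrix over accepted tiles, rows
#'   matching \code{which(manifest$qc_status == "accept")}).
#' @export
prep_slide <- function(image, annotation, tile_edge = 512,
                       min_tumor_fraction = 0.5,
                       backbone = backbone_spec(),
                       target = default_stain_profile(), normalize = TRUE,
                       tile_dir = NULL, qc_args = list()) {
  specs <- tessellate(image, annotation, tile_edge, min_tumor_fraction)
  if (nrow(specs) == 0)
    return(list(manifest = cbind(specs, qc_status = character(0),
                                 tile_path = character(0)),
                features = NULL))
  tiles <- lapply(seq_len(nrow(specs)),
                  function(i) extract_tile(image, specs[i, ]))
  qc <- lapply(tiles, function(t) do.call(qc_tile, c(list(t), qc_args)))
  status <- vapply(qc, function(d)
    if (d$accept) "accept" else paste0("reject:", d$reason), character(1))
  accepted <- which(status == "accept")
  feats <- NULL
  paths <- rep(NA_character_, nrow(specs))
  if (length(accepted)) {
    if (normalize) {
      profile <- estimate_stains(sample_tile_pixels(tiles[accepted]))
      tiles[accepted] <- lapply(tiles[accepted], normalize_stain,
                                source = profile, target = target)
    }
    feats <- featurize_tiles(tiles[accepted], backbone)
    if (!is.null(tile_dir))
      paths[accepted] <- vapply(accepted, function(i)
        write_tile_png(tiles[[i]], tile_dir, specs$slide_id[i],
                       specs$grid_row[i], specs$grid_col[i]), character(1))
  }
  manifest <- cbind(specs, qc_status = status, tile_path = paths,
                    stringsAsFactors = FALSE)
  list(manifest = manifest, features = feats)
}

# Deterministic pixel sample (strided) across tiles, shaped as an n x 1 x 3
# image for stain estimation.
sample_tile_pixels <- function(tiles, n_per_tile = 4096) {
  px <- lapply(tiles, function(t) {
    t <- tile_unit_scale(t)
    v <- cbind(as.vector(t[, , 1]), as.vector(t[, , 2]), as.vector(t[, , 3]))
    step <- max(1, floor(nrow(v) / n_per_tile))
    v[seq(1, nrow(v), by = step), , drop = FALSE]
  })
  v <- do.call(rbind, px)
  array(v, c(nrow(v), 1, 3))
}

#' Run the end-to-end synthetic cross-validation experiment
#'
#' Generates a seeded pseudo-slide cohort, preprocesses every slide into
#' normalized tile features, plans a stratified patient-level K-fold
#' cross-validation, trains the tile classifier on class-balanced training
#' tiles of each fold, aggregates validation tile predictions to slide
#' calls, and evaluates slide-level metrics per fold with Student-t
#' summaries plus a pooled confusion matrix and pooled AUROC.
#'
#' @param seed Master seed for cohort generation, fold planning, balancing
#'   and training.
#' @param n_luminal,n_basal Slides per class (default 12 + 12, the smoke
#'   cohort).
#' @param width,height Slide dimensions (default 3072 x 2048).
#' @param tile_edge Tile edge (default 512).
#' @param n_folds,n_repetitions Cross-validation shape (default 3 x 1).
#' @param backbone,config Classifier specification.
#' @param verbose Print per-slide progress.
#' @return A \code{"histotype_experiment"} list: \code{manifest},
#'   \code{plan}, \code{slide_predictions} (per repetition, pooled over
#'   folds), \code{fold_metrics}, \code{summary} (per repetition),
#'   \code{confusion} (per repetition), \code{auroc_pooled} (per
#'   repetition), and \code{cohort}.
#' @export
run_cv_experiment <- function(seed = 7, n_luminal = 12, n_basal = 12,
                              width = 3072, height = 2048, tile_edge = 512,
                              n_folds = 3, n_repetitions = 1,
                              backbone = backbone_spec(),
                              config = train_config(),
                              verbose = FALSE) {
  cohort <- gen_cohort(n_luminal, n_basal, 0, seed = seed,
                       width = width, height = height)
  manifest <- list(); feats <- list()
  for (i in seq_len(nrow(cohort$slides))) {
    sl <- realize_slide(cohort, i)
    prep <- prep_slide(sl$image, sl$annotation, tile_edge,
                       backbone = backbone)
    m <- prep$manifest
    m$patient_id <- cohort$slides$patient_id[i]
    m$label <- cohort$slides$label[i]
    acc <- m$qc_status == "accept"
    manifest[[i]] <- m[acc, , drop = FALSE]
    feats[[i]] <- prep$features
    if (verbose)
      message(sprintf("slide %s: %d/%d tiles accepted",
                      cohort$slides$slide_id[i], sum(acc), nrow(m)))
    rm(sl, prep)
  }
  manifest <- do.call(rbind, manifest)
  features <- do.call(rbind, feats)
  manifest$row_id <- seq_len(nrow(manifest))
  plan <- plan_folds(manifest, n_folds, n_repetitions, seed,
                     stratify = TRUE)
  truth_by_slide <- unique(manifest[, c("slide_id", "label")])
  fold_metrics <- list(); slide_preds <- list()
  summaries <- list(); confusions <- list(); auroc_pooled <- numeric()
  for (rep in seq_len(n_repetitions)) {
    rep_preds <- list()
    for (fold in seq_len(n_folds)) {
      rows <- fold_rows(plan, manifest, rep, fold)
      train_bal <- balance_training_tiles(manifest[rows$train, , drop = FALSE],
                                          derive_seed(seed, rep * 100 + fold))
      cfg <- config
      cfg$seed <- derive_seed(seed, rep * 1000 + fold)
      model <- tile_classifier(train_bal,
                               features = features[train_bal$row_id, ,
                                                   drop = FALSE],
                               backbone = backbone, config = cfg)
      val <- manifest[rows$validation, , drop = FALSE]
      p <- predict_tiles(model, features[val$row_id, , drop = FALSE],
                         features = TRUE)
      sp <- aggregate_slides(cbind(val[, c("slide_id", "grid_row",
                                           "grid_col")], p))
      sp$truth <- truth_by_slide$label[match(sp$slide_id,
                                             truth_by_slide$slide_id)]
      sp$repetition <- rep; sp$fold <- fold
      rep_preds[[fold]] <- sp
      m <- classification_metrics(sp$truth, sp$label,
                                  scores = sp$p_wsi_basal)
      fold_metrics[[length(fold_metrics) + 1L]] <-
        data.frame(repetition = rep, fold = fold, as.data.frame(m))
    }
    pooled <- do.call(rbind, rep_preds)
    slide_preds[[rep]] <- pooled
    rep_fm <- do.call(rbind,
                      fold_metrics[vapply(fold_metrics,
                                          function(f) f$repetition == rep,
                                          logical(1))])
    summaries[[rep]] <- summarize_fold_metrics(rep_fm)
    confusions[[rep]] <- confusion_concat(
      data.frame(slide_id = pooled$slide_id, truth = pooled$truth,
                 predicted = pooled$label))
    auroc_pooled[rep] <- auroc(pooled$p_wsi_basal, pooled$truth)
  }
  structure(list(cohort = cohort, manifest = manifest, plan = plan,
                 slide_predictions = slide_preds,
                 fold_metrics = do.call(rbind, fold_metrics),
                 summary = summaries, confusion = confusions,
                 auroc_pooled = auroc_pooled,
                 backbone = backbone, config = config, seed = seed),
            class = "histotype_experiment")
}

#' @export
print.histotype_experiment <- function(x, ...) {
  cat("Synthetic cross-validation experiment (seed ", x$seed, ")\n",
      sep = "")
  cat("  slides: ", nrow(x$cohort$slides), ", accepted tiles: ",
      nrow(x$manifest), "\n", sep = "")
  for (rep in seq_along(x$summary)) {
    cat("  repetition ", rep, " (pooled slide-level AUROC ",
        round(x$auroc_pooled[rep], 3), "):\n", sep = "")
    s <- x$summary[[rep]]
    for (i in seq_len(nrow(s)))
      cat(sprintf("    %-9s %.3f (95%% CI %.3f-%.3f)\n", s$metric[i],
                  s$mean[i], s$ci_low[i], s$ci_high[i]))
  }
  invisible(x)
}

#' Read or write a tile manifest CSV
#'
#' @param manifest Manifest data frame.
#' @param path CSV path.
#' @return \code{path} (write) or the manifest data frame (read).
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
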