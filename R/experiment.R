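#' Experiment configuration
#'
#' One nested configuration drives the whole protocol: synthetic cohort
#' generation, tiling, augmentation, backbone, patch training, U-Net,
#' region training, evaluation, fold count and the global seed. Values may
#' be given as a YAML file or a nested list; unspecified keys take the
#' desk-scale defaults below (a 20+20 slide training cohort of 512 px slides
#' with 64 px tiles, heterogeneity 0.3 at smoothness 3, a 4+4 test cohort
#' from the shifted scanner domain, patches resized to 32 and cropped to 28,
#' slim backbone at width 1/4, 5 patch epochs at lr 0.01, depth-2 U-Net for
#' 30 epochs at lr 0.01, 5 folds).
#'
#' @param config path to a YAML file, or a nested list of overrides, or
#'   NULL for pure defaults.
#' @param ... top-level overrides applied after `config` (e.g. `seed = 3`).
#' @return object of class `experiment_config`.
#' @export
experiment_config <- function(config = NULL, ...) {
  defaults <- list(
    synth = list(n_pos = 20, n_neg = 20, n_test_pos = 4, n_test_neg = 4,
                 slide_px = 512, tile_px = 64, het_rate = 0.3,
                 het_smooth = 3, train_domain = "scannerA",
                 test_domain = "scannerB"),
    tile = list(patch_dim = 64, min_ratio = 0.9, resize = 32),
    augment = list(crop_px = 28, jitter_low = 0.6, jitter_high = 1.4,
                   flip_prob = 0.5),
    backbone = list(preset = "resnet18_slim", width = 0.25),
    patch_train = list(epochs = 5, lr = 0.01, drop_epochs = c(10, 20),
                       drop_factor = 5, batch = 32, momentum = 0.9,
                       wd = 5e-4),
    unet = list(depth = 2, base = 16),
    region_train = list(epochs = 30, lr = 0.01, momentum = 0.9, wd = 5e-4),
    eval = list(n_boot = 500, alpha = 0.05),
    k = 5,
    seed = 0
  )
  user <- if (is.character(config)) yaml::read_yaml(config)
          else if (is.list(config)) config else list()
  cfg <- merge_config(defaults, user)
  cfg <- merge_config(cfg, list(...))
  structure(cfg, class = "experiment_config")
}

merge_config <- function(base, over) {
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], over[[nm]])
    else base[[nm]] <- over[[nm]]
  }
  base
}

config_hash <- function(cfg) {
  f <- tempfile(fileext = ".yaml")
  yaml::write_yaml(unclass(cfg), f)
  h <- unname(tools::md5sum(f))
  unlink(f)
  h
}

#' Generate the training and test cohorts of an experiment
#'
#' Training slides come from `synth$train_domain`, test slides from
#' `synth$test_domain` (emulating two scanner platforms); seeds are derived
#' from the global seed, with disjoint slide-id prefixes.
#'
#' @param cfg an [experiment_config()].
#' @param out_dir optional directory for images/masks/manifests.
#' @return list with `train` and `test` cohorts (each as returned by
#'   [generate_cohort()]).
#' @export
generate_experiment_cohorts <- function(cfg, out_dir = NULL) {
  sp <- synthetic_spec(slide_px = cfg$synth$slide_px,
                       tile_px = cfg$synth$tile_px,
                       heterogeneity_rate = cfg$synth$het_rate,
                       heterogeneity_smoothness = cfg$synth$het_smooth,
                       seed = cfg$seed)
  train <- generate_cohort(cfg$synth$n_pos, cfg$synth$n_neg, sp,
                           domain = cfg$synth$train_domain,
                           seed = derive_seed(cfg$seed, 1),
                           out_dir = if (!is.null(out_dir))
                             file.path(out_dir, "train"),
                           prefix = "tr")
  test <- generate_cohort(cfg$synth$n_test_pos, cfg$synth$n_test_neg, sp,
                          domain = cfg$synth$test_domain,
                          seed = derive_seed(cfg$seed, 2),
                          out_dir = if (!is.null(out_dir))
                            file.path(out_dir, "test"),
                          prefix = "te")
  list(train = train, test = test)
}

tile_records <- function(records, cfg) {
  tiles <- lapply(records, function(s)
    tile_slide(s, cfg$tile$patch_dim, cfg$tile$min_ratio, cfg$tile$resize))
  names(tiles) <- vapply(records, `[[`, character(1), "slide_id")
  tiles
}

# gather all patch records of the named slides into one patch_set
patches_for <- function(tiles, slide_ids) {
  as_patch_set(do.call(c, lapply(tiles[slide_ids], `[[`, "patches")))
}

# per-slide global feature maps under a given patch model
build_gmaps <- function(model, tiles, slide_ids, depth) {
  lapply(slide_ids, function(id) {
    ps <- patches_for(tiles, id)
    feats <- extract_patch_features(model, ps)
    assemble_global_features(feats, tiles[[id]]$grid, ps$grid_row,
                             ps$grid_col, depth = depth)
  })
}

#' Run the K-fold cross-validation protocol
#'
#' Trains K model pairs (patch classifier + region model), each validating
#' on one fold of the training slides and training on the rest. Slide-level
#' splitting is enforced throughout. When `out_dir` is given, completed fold
#' bundles are cached there (keyed by the configuration hash) and reused on
#' re-runs with unchanged inputs; fold assignments, per-epoch histories and
#' a run manifest (config, hash, seeds, versions) are also written.
#'
#' @param records list of training `slide_record`s (or a manifest path /
#'   data.frame accepted by [load_cohort()]).
#' @param cfg an [experiment_config()].
#' @param out_dir optional run directory.
#' @param verbose print per-fold progress.
#' @return object of class `cv_run`: `cfg`, `folds`, `tiles`, `bundles`
#'   (list of k, each with `patch_model`, `region_model`, `val_slides`).
#' @export
run_cross_validation <- function(records, cfg = experiment_config(),
                                 out_dir = NULL, verbose = TRUE) {
  if (is.character(records) || is.data.frame(records))
    records <- load_cohort(records)$records
  ids <- vapply(records, `[[`, character(1), "slide_id")
  if (anyDuplicated(ids)) stop("duplicate slide ids in training cohort")
  names(records) <- ids
  manifest <- data.frame(slide_id = ids,
                         label = vapply(records, `[[`, character(1),
                                        "label"),
                         stringsAsFactors = FALSE)
  hash <- config_hash(cfg)
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)

  tiles <- tile_records(records, cfg)
  folds <- make_slide_folds(manifest, k = cfg$k,
                            seed = derive_seed(cfg$seed, 10))
  rotations <- fold_rotations(folds)
  aug <- augment_config(crop_px = cfg$augment$crop_px,
                        jitter_range = c(cfg$augment$jitter_low,
                                         cfg$augment$jitter_high),
                        flip_prob = cfg$augment$flip_prob)
  bb <- backbone_config(cfg$backbone$preset,
                        width_multiplier = cfg$backbone$width)
  uc <- unet_config(in_channels = bb$feature_dim, depth = cfg$unet$depth,
                    base_channels = cfg$unet$base)

  bundles <- vector("list", cfg$k)
  for (kk in seq_len(cfg$k)) {
    cache_file <- if (!is.null(out_dir))
      file.path(out_dir, sprintf("bundle_%d.rds", kk))
    if (!is.null(cache_file) && file.exists(cache_file)) {
      cached <- readRDS(cache_file)
      if (identical(cached$hash, hash)) {
        if (verbose) message("fold ", kk, ": cache hit, skipping training")
        bundles[[kk]] <- cached
        next
      }
    }
    rot <- rotations[[kk]]
    if (verbose)
      message(sprintf("fold %d/%d: %d train / %d val slides", kk, cfg$k,
                      length(rot$train), length(rot$val)))
    pm <- train_patch_classifier(
      patches_for(tiles, rot$train), patches_for(tiles, rot$val),
      backbone = bb,
      cfg = patch_train_config(epochs = cfg$patch_train$epochs,
                               lr = cfg$patch_train$lr,
                               lr_drop_epochs = cfg$patch_train$drop_epochs,
                               lr_drop_factor = cfg$patch_train$drop_factor,
                               batch_size = cfg$patch_train$batch,
                               momentum = cfg$patch_train$momentum,
                               weight_decay = cfg$patch_train$wd,
                               seed = derive_seed(cfg$seed, 100 + kk)),
      augment = aug)
    gm_train <- build_gmaps(pm, tiles, rot$train, cfg$unet$depth)
    gm_val <- build_gmaps(pm, tiles, rot$val, cfg$unet$depth)
    lab_of <- function(id) records[[id]]$label
    rm_ <- train_region_model(
      gm_train, vapply(rot$train, lab_of, character(1)),
      gm_val, vapply(rot$val, lab_of, character(1)),
      unet = uc,
      cfg = region_train_config(epochs = cfg$region_train$epochs,
                                lr = cfg$region_train$lr,
                                momentum = cfg$region_train$momentum,
                                weight_decay = cfg$region_train$wd,
                                seed = derive_seed(cfg$seed, 200 + kk)))
    bundles[[kk]] <- list(patch_model = pm, region_model = rm_,
                          val_slides = rot$val, fold = kk, hash = hash)
    if (!is.null(cache_file)) saveRDS(bundles[[kk]], cache_file)
  }

  run <- structure(list(cfg = cfg, folds = folds, tiles = tiles,
                        bundles = bundles, train_ids = ids, hash = hash),
                   class = "cv_run")
  if (!is.null(out_dir)) {
    utils::write.table(folds$assignment, file.path(out_dir, "folds.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (kk in seq_len(cfg$k)) {
      utils::write.table(bundles[[kk]]$patch_model$history,
                         file.path(out_dir,
                                   sprintf("history_patch_%d.tsv", kk)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(bundles[[kk]]$region_model$history,
                         file.path(out_dir,
                                   sprintf("history_region_%d.tsv", kk)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    mf <- tempfile()
    utils::write.table(manifest, mf, sep = "\t", row.names = FALSE)
    yaml::write_yaml(list(config = unclass(cfg), config_hash = hash,
                          seed = cfg$seed, n_slides = length(records),
                          input_manifest_md5 = unname(tools::md5sum(mf)),
                          package = as.character(utils::packageVersion("histocorr")),
                          r_version = R.version.string),
                     file.path(out_dir, "run_manifest.yaml"))
    unlink(mf)
  }
  run
}

#' Evaluate trained models on a held-out test cohort
#'
#' Tiles the test slides, scores every tumor patch with each fold's patch
#' classifier (independent variant) and region model (region-correlation
#' variant), forms the 5-model ensemble by posterior averaging, aggregates
#' patch posteriors to slide posteriors by the tumor-patch mean, and
#' reports AUC (with bootstrap CI) and threshold-0.5 metrics at both the
#' patch and slide level.
#'
#' @param run a `cv_run` from [run_cross_validation()].
#' @param test_records list of test `slide_record`s; slide ids must be
#'   disjoint from the training cohort.
#' @param out_dir optional directory for the report tables and probability
#'   map renders.
#' @return list with `reports` (one data.frame row per level x variant x
#'   model), `slide_table` (per-slide posteriors), `patch_probs`
#'   (per-model and ensemble patch posteriors with labels), `maps`
#'   (per-slide ensemble `probability_map`s, both variants).
#' @export
run_test_evaluation <- function(run, test_records, out_dir = NULL) {
  cfg <- run$cfg
  test_ids <- vapply(test_records, `[[`, character(1), "slide_id")
  assert_slide_disjoint(run$train_ids, test_ids)
  names(test_records) <- test_ids
  tiles <- tile_records(test_records, cfg)
  kept <- test_ids[vapply(tiles, function(t) length(t$patches) > 0,
                          logical(1))]
  ps <- patches_for(tiles, kept)
  y_patch <- ps$label == "POS"
  slide_lab <- vapply(test_records[kept], `[[`, character(1), "label")
  M <- length(run$bundles)

  p_ind <- vector("list", M)
  p_reg <- vector("list", M)
  for (m in seq_len(M)) {
    pm <- run$bundles[[m]]$patch_model
    rmod <- run$bundles[[m]]$region_model
    p_ind[[m]] <- predict_patch_probabilities(pm, ps)
    gmaps <- build_gmaps(pm, tiles, kept, cfg$unet$depth)
    names(gmaps) <- kept
    p_reg[[m]] <- numeric(length(y_patch))
    for (id in kept) {
      pmap <- predict_probability_map(rmod, gmaps[[id]])
      sel <- which(ps$slide_id == id)
      p_reg[[m]][sel] <- pmap$probs[cbind(ps$grid_row[sel] + 1L,
                                          ps$grid_col[sel] + 1L)]
    }
  }
  ens_ind <- ensemble_average(p_ind)
  ens_reg <- ensemble_average(p_reg)

  slide_prob <- function(p) vapply(kept, function(id)
    slide_probability(p[ps$slide_id == id]), numeric(1))

  rows <- list()
  add_row <- function(scores, labels, level, variant, model) {
    r <- metrics_report(scores, labels, n_boot = cfg$eval$n_boot,
                        alpha = cfg$eval$alpha,
                        seed = derive_seed(cfg$seed, 300), level = level,
                        variant = variant)
    r$model <- model
    rows[[length(rows) + 1]] <<- r
  }
  for (m in seq_len(M)) {
    add_row(p_ind[[m]], y_patch, "patch", "independent", m)
    add_row(p_reg[[m]], y_patch, "patch", "region", m)
    add_row(slide_prob(p_ind[[m]]), slide_lab, "slide", "independent", m)
    add_row(slide_prob(p_reg[[m]]), slide_lab, "slide", "region", m)
  }
  add_row(ens_ind, y_patch, "patch", "ensemble_independent", 0)
  add_row(ens_reg, y_patch, "patch", "ensemble_region", 0)
  add_row(slide_prob(ens_ind), slide_lab, "slide", "ensemble_independent", 0)
  add_row(slide_prob(ens_reg), slide_lab, "slide", "ensemble_region", 0)
  reports <- do.call(rbind, rows)

  slide_table <- data.frame(slide_id = kept, label = slide_lab,
                            p_independent = slide_prob(ens_ind),
                            p_region = slide_prob(ens_reg),
                            stringsAsFactors = FALSE)
  maps <- lapply(kept, function(id) {
    sel <- which(ps$slide_id == id)
    list(independent = stitch_probability_map(ens_ind[sel], tiles[[id]]$grid,
                                              ps$grid_row[sel],
                                              ps$grid_col[sel]),
         region = stitch_probability_map(ens_reg[sel], tiles[[id]]$grid,
                                         ps$grid_row[sel],
                                         ps$grid_col[sel]))
  })
  names(maps) <- kept

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(reports, file.path(out_dir, "reports.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(slide_table, file.path(out_dir, "slide_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    # ROC point tables for the ensemble variants
    roc_sets <- list(
      patch_ensemble_independent = list(ens_ind, y_patch),
      patch_ensemble_region = list(ens_reg, y_patch),
      slide_ensemble_independent = list(slide_prob(ens_ind), slide_lab),
      slide_ensemble_region = list(slide_prob(ens_reg), slide_lab))
    for (nm in names(roc_sets))
      utils::write.table(roc_curve(roc_sets[[nm]][[1]], roc_sets[[nm]][[2]]),
                         file.path(out_dir, paste0("roc_", nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    for (id in kept) {
      render_probability_map(maps[[id]]$independent,
                             file.path(out_dir,
                                       paste0(id, "_independent.png")))
      render_probability_map(maps[[id]]$region,
                             file.path(out_dir, paste0(id, "_region.png")))
    }
  }
  list(reports = reports, slide_table = slide_table,
       patch_probs = list(independent = p_ind, region = p_reg,
                          ensemble_independent = ens_ind,
                          ensemble_region = ens_reg, labels = y_patch,
                          slide_id = ps$slide_id),
       maps = maps)
}

#' Run the full experiment end to end
#'
#' Synthesizes the training and test cohorts, runs the K-fold
#' cross-validation, and evaluates on the domain-shifted test cohort.
#'
#' @param cfg an [experiment_config()].
#' @param out_dir optional run directory.
#' @param verbose print progress.
#' @return list with `run` (the `cv_run`), `evaluation` (see
#'   [run_test_evaluation()]), and `cohorts`.
#' @export
run_experiment <- function(cfg = experiment_config(), out_dir = NULL,
                           verbose = TRUE) {
  cohorts <- generate_experiment_cohorts(cfg, out_dir = out_dir)
  run <- run_cross_validation(cohorts$train$records, cfg,
                              out_dir = out_dir, verbose = verbose)
  evaluation <- run_test_evaluation(run, cohorts$test$records,
                                    out_dir = if (!is.null(out_dir))
                                      file.path(out_dir, "test_eval"))
  list(run = run, evaluation = evaluation, cohorts = cohorts)
}
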