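#' Pipeline configuration
#'
#' Assembles and validates the configuration driving [run_pipeline()].
#' Defaults mirror the published workflow: 8 mm FWHM smoothing, 2 mm
#' isotropic grid, ROI definition at FDR q < 0.01 with cluster extent > 500
#' voxels (18-connectivity), 64 gray levels, correlation filter at |r| > 0.1,
#' t screen at p < 0.005, 0.7/0.3 stratified split, linear SVM (C = 1) under
#' 5-fold CV repeated 100 times with age/sex residualization.
#'
#' @param simulate `NULL`, or a list of [cohort_spec()] arguments (plus
#'   optional `write_volumes = TRUE/FALSE`) to generate a synthetic cohort.
#' @param paths List with `manifest`, `atlas`, `lookup` when reading an
#'   existing cohort from disk (ignored when simulating).
#' @param preprocessing List: `fwhm` (mm, default 8; 0 disables), `iso_mm`.
#' @param roi List: `q`, `min_cluster`, `connectivity`, `min_overlap`,
#'   `reference_id` (atlas id of the SUVR reference region; defaults to the
#'   simulated reference), `task` (group pair defining the ROI contrast;
#'   defaults to the classification task).
#' @param features List: `n_levels`.
#' @param selection List: `r_max`, `p_max`, `seed`.
#' @param classification List: `train_frac`, `k_folds`, `n_reps`, `cost`,
#'   `covariate_mode`, `covariates`, `seed`.
#' @param task Group pair to classify (positive class first).
#' @param group_col Label column for the task (default `"group"`; use
#'   `"tau_status"` / `"apoe_status"` for subgroup tasks).
#' @param models Subset of `c("radiomics", "suvr", "clinical")`.
#' @param seed Master seed; stage seeds default to values derived from it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(simulate = list(),
                            paths = NULL,
                            preprocessing = list(),
                            roi = list(),
                            features = list(),
                            selection = list(),
                            classification = list(),
                            task = c("AD", "NC"),
                            group_col = "group",
                            models = c("radiomics", "suvr", "clinical"),
                            seed = 1) {
  seed <- as.integer(seed)
  cfg <- list(
    simulate = simulate,
    paths = paths,
    # simulated cohorts emulate already-preprocessed (smoothed, normalized)
    # PET, so smoothing defaults off for them; volumes read from disk get
    # the standard 8 mm kernel
    preprocessing = modifyList(
      list(fwhm = if (is.null(simulate)) 8 else 0, iso_mm = 2),
      preprocessing),
    roi = modifyList(list(q = 0.01, min_cluster = 500, connectivity = 18,
                          min_overlap = 64, reference_id = NULL,
                          task = NULL, fallback = "atlas"), roi),
    features = modifyList(list(n_levels = 64), features),
    selection = modifyList(list(r_max = 0.1, p_max = 0.005,
                                seed = derive_seed(seed, 101)), selection),
    classification = modifyList(
      list(train_frac = 0.7, k_folds = 5, n_reps = 100, cost = 1,
           covariate_mode = "residualize", covariates = c("age", "sex"),
           seed = derive_seed(seed, 202)),
      classification),
    task = task, group_col = group_col, models = models, seed = seed
  )
  stopifnot(cfg$roi$q > 0, cfg$roi$q < 1, cfg$roi$min_cluster >= 1,
            cfg$features$n_levels >= 2,
            cfg$selection$r_max > 0, cfg$selection$r_max <= 1,
            cfg$selection$p_max > 0, cfg$selection$p_max < 1,
            cfg$classification$train_frac > 0,
            cfg$classification$train_frac < 1,
            length(task) == 2)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys map to [pipeline_config()] arguments; unspecified values
#' keep their defaults.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), names(formals(pipeline_config)))]
  do.call(pipeline_config, args)
}

#' Run the full analysis pipeline
#'
#' Executes the staged workflow: (optional) cohort simulation, smoothing and
#' resampling, ROI definition on training subjects only, feature extraction,
#' feature selection on training rows, and classification of the configured
#' models through one shared harness. All artifacts (ROI map, feature and
#' SUVR tables, selection result, evaluation reports, a seed log) are written
#' under `out_dir` when given; re-running an identical config reproduces them
#' bit for bit.
#'
#' @param config A `pipeline_config`.
#' @param out_dir Run directory, or `NULL` to skip writing artifacts.
#' @return (Invisibly) list with `reports` (named `eval_report`s), `rois`,
#'   `selection`, `split`, `tables`, `config`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  # --- stage: cohort ---------------------------------------------------
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    write_vols <- isTRUE(sim_args$write_volumes)
    sim_args$write_volumes <- NULL
    if (is.null(sim_args$seed)) sim_args$seed <- config$seed
    spec <- do.call(cohort_spec, sim_args)
    cohort <- generate_cohort(
      spec,
      out_dir = if (write_vols && !is.null(out_dir)) {
        file.path(out_dir, "cohort")
      } else NULL
    )
    if (is.null(config$roi$reference_id)) {
      config$roi$reference_id <- spec$reference_region
    }
  } else {
    manifest <- readr::read_tsv(config$paths$manifest, show_col_types = FALSE)
    atlas <- read_label_map(config$paths$atlas, config$paths$lookup)
    cohort <- list(manifest = manifest, atlas = atlas, spec = NULL)
  }
  manifest <- cohort$manifest
  atlas <- cohort$atlas

  # --- stage: preprocess ------------------------------------------------
  pre <- config$preprocessing
  if (!all(abs(atlas$spacing - pre$iso_mm) < 1e-9)) {
    atlas <- resample_isotropic(atlas, pre$iso_mm)
  }
  preprocess_fn <- function(v) {
    if (!all(abs(v$spacing - pre$iso_mm) < 1e-9)) {
      v <- resample_isotropic(v, pre$iso_mm)
    }
    if (pre$fwhm > 0) v <- gaussian_smooth(v, fwhm_mm = pre$fwhm) else v
  }
  vols <- purrr::map(seq_len(nrow(manifest)),
                     function(i) preprocess_fn(manifest_volume(manifest[i, ])))
  manifest$volume <- vols

  # --- stage: split (before ROI definition: leakage guard) --------------
  cls <- config$classification
  task <- config$task
  split_plan <- make_split(manifest, task = task,
                           train_frac = cls$train_frac,
                           seed = cls$seed, group_col = config$group_col)

  # --- stage: ROI definition on training subjects only ------------------
  roi_cfg <- config$roi
  roi_task <- roi_cfg$task
  if (is.null(roi_task)) {
    roi_task <- if (config$group_col == "group") task else {
      grp <- unique(manifest$group)
      ctrl <- if (!is.null(cohort$spec)) cohort$spec$control_group else
        grp[length(grp)]
      c(setdiff(grp, ctrl)[1], ctrl)
    }
  }
  heldout_ids <- split_plan$id[split_plan$role != "train"]
  roi_rows <- manifest$group %in% roi_task & !(manifest$id %in% heldout_ids)
  if ("cohort" %in% names(manifest)) {
    roi_rows <- roi_rows & manifest$cohort != "external"
  }
  roi_manifest <- manifest[roi_rows, ]
  grp_a <- roi_manifest$volume[roi_manifest$group == roi_task[1]]
  grp_b <- roi_manifest$volume[roi_manifest$group == roi_task[2]]
  exclude <- if (!is.null(roi_cfg$reference_id)) roi_cfg$reference_id else
    integer()
  rois <- define_rois(grp_a, grp_b, atlas, q = roi_cfg$q,
                      min_cluster = roi_cfg$min_cluster,
                      connectivity = roi_cfg$connectivity,
                      min_overlap = roi_cfg$min_overlap,
                      exclude = exclude, fallback = roi_cfg$fallback)

  # --- stage: feature extraction ---------------------------------------
  tables <- list()
  if ("radiomics" %in% config$models) {
    tables$radiomics <- feature_table(manifest, rois,
                                      n_levels = config$features$n_levels)
  }
  if ("suvr" %in% config$models) {
    if (is.null(roi_cfg$reference_id)) {
      stop("SUVR model needs roi$reference_id", call. = FALSE)
    }
    ref_mask <- mask_from_labels(atlas, roi_cfg$reference_id)
    tables$suvr <- suvr_table(manifest, rois, ref_mask)
  }
  if ("clinical" %in% config$models) {
    tables$clinical <- clinical_table(manifest)
  }

  # --- stage: selection (radiomics only, training rows only) ------------
  selection <- NULL
  sel_features <- list()
  if ("radiomics" %in% config$models) {
    train_tbl <- tables$radiomics[
      tables$radiomics$id %in% split_plan$id[split_plan$role == "train"], ]
    train_tbl$label <- split_plan$label[match(train_tbl$id, split_plan$id)]
    usable <- feature_columns(train_tbl)
    usable <- usable[!vapply(usable, function(f) anyNA(train_tbl[[f]]),
                             logical(1))]
    selection <- select_features(train_tbl, features = usable,
                                 group_col = "label",
                                 groups = task,
                                 r_max = config$selection$r_max,
                                 p_max = config$selection$p_max,
                                 seed = config$selection$seed)
    sel_features$radiomics <- selection$kept
  }
  sel_features$suvr <- if ("suvr" %in% config$models) {
    feature_columns(tables$suvr)
  }
  sel_features$clinical <- if ("clinical" %in% config$models) "clinical__mmse"

  # --- stage: classification (shared harness) ---------------------------
  reports <- list()
  for (model in config$models) {
    reports[[model]] <- classify_features(
      tables[[model]], split_plan, features = sel_features[[model]],
      covariates = cls$covariates, covariate_mode = cls$covariate_mode,
      k_folds = cls$k_folds, n_reps = cls$n_reps, cost = cls$cost,
      seed = cls$seed, model_name = model
    )
  }

  # --- artifacts ---------------------------------------------------------
  if (!is.null(out_dir)) {
    write_roi_set(rois, file.path(out_dir, "rois.nii.gz"))
    if (!is.null(selection)) {
      write_selection(selection, file.path(out_dir, "selection.json"))
    }
    for (nm in names(tables)) {
      tbl <- tables[[nm]]
      tbl$volume <- NULL
      readr::write_csv(tbl, file.path(out_dir, paste0("features_", nm,
                                                      ".csv")))
    }
    readr::write_tsv(tibble::as_tibble(split_plan),
                     file.path(out_dir, "split.tsv"))
    for (nm in names(reports)) {
      write_eval_report(reports[[nm]], file.path(out_dir,
                                                 paste0("report_", nm)))
    }
    readr::write_csv(report_table(reports),
                     file.path(out_dir, "report_table.csv"))
    jsonlite::write_json(
      list(seed = config$seed, selection_seed = config$selection$seed,
           classification_seed = config$classification$seed,
           task = config$task, models = config$models,
           thresholds = list(q = roi_cfg$q,
                             min_cluster = roi_cfg$min_cluster,
                             connectivity = roi_cfg$connectivity,
                             r_max = config$selection$r_max,
                             p_max = config$selection$p_max,
                             n_levels = config$features$n_levels,
                             fwhm = pre$fwhm, iso_mm = pre$iso_mm)),
      file.path(out_dir, "run_log.json"), auto_unbox = TRUE, pretty = TRUE,
      digits = NA)
  }
  invisible(list(reports = reports, rois = rois, selection = selection,
                 split = split_plan, tables = tables, config = config))
}
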