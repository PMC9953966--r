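#' Voxelwise two-sample t-test
#'
#' Pooled-variance (Student) two-sample t per in-mask voxel, two-sided p from
#' the t distribution with `n1 + n2 - 2` degrees of freedom. Voxels with zero
#' pooled variance get `t = 0`, `p = 1`. A Welch variant is available for
#' sensitivity analyses.
#'
#' @param group_a,group_b Lists of [pet_volume()]s with identical geometry
#'   (at least two per group). The sign convention is `mean(a) - mean(b)`.
#' @param mask A [pet_mask()] restricting the analysis (default: all voxels).
#' @param var_equal Pooled variance if `TRUE` (default), Welch otherwise.
#' @return A `stat_map`: list with 3D arrays `t` and `p` (NA outside the
#'   mask), `df`, and the analysis `mask`.
#' @export
voxelwise_ttest <- function(group_a, group_b, mask = NULL, var_equal = TRUE) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("need at least two volumes per group", call. = FALSE)
  }
  ref <- group_a[[1]]
  for (v in c(group_a, group_b)) check_geometry(ref, v, "group volumes")
  d <- dim(ref$data)
  if (is.null(mask)) {
    mask <- pet_mask(array(TRUE, dim = d), spacing = ref$spacing)
  }
  check_geometry(ref, mask, "volumes and mask")
  idx <- which(mask$data)
  A <- vapply(group_a, function(v) v$data[idx], numeric(length(idx)))
  B <- vapply(group_b, function(v) v$data[idx], numeric(length(idx)))
  n1 <- ncol(A); n2 <- ncol(B)
  m1 <- rowMeans(A); m2 <- rowMeans(B)
  v1 <- rowSums((A - m1)^2) / (n1 - 1)
  v2 <- rowSums((B - m2)^2) / (n2 - 1)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
    tt <- ifelse(se > 0, (m1 - m2) / se, 0)
    pp <- ifelse(se > 0, 2 * stats::pt(-abs(tt), df), 1)
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df_w <- se^4 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    tt <- ifelse(se > 0, (m1 - m2) / se, 0)
    pp <- ifelse(se > 0, 2 * stats::pt(-abs(tt), ifelse(se > 0, df_w, 1)), 1)
    df <- df_w
  }
  t_arr <- array(NA_real_, dim = d); t_arr[idx] <- tt
  p_arr <- array(NA_real_, dim = d); p_arr[idx] <- pp
  structure(list(t = t_arr, p = p_arr, df = df, mask = mask,
                 spacing = ref$spacing),
            class = "stat_map")
}

#' Benjamini-Hochberg p-value cutoff
#'
#' Returns the largest ordered p-value `p_(k)` with `p_(k) <= k * q / m`
#' (the BH step-up boundary); voxels with `p <= cutoff` are the BH
#' rejections at FDR level `q`. Returns `NA` when nothing is rejected.
#'
#' @param p_values Numeric vector of p-values (the in-mask voxels).
#' @param q FDR level in (0, 1), default 0.01.
#' @return Scalar cutoff, or `NA_real_` if there are no rejections.
#' @export
fdr_cutoff <- function(p_values, q = 0.01) {
  p_values <- p_values[!is.na(p_values)]
  if (length(p_values) == 0) stop("no p-values supplied", call. = FALSE)
  stopifnot(q > 0, q < 1)
  m <- length(p_values)
  ps <- sort(p_values)
  ok <- ps <= seq_len(m) * q / m
  if (!any(ok)) return(NA_real_)
  ps[max(which(ok))]
}

#' Cluster-extent filtering of a significance mask
#'
#' Labels connected components of the mask and keeps those with strictly
#' more than `min_voxels` voxels (matching the convention "cluster size >
#' 500"). Default connectivity 18 (faces + edges), the common neuroimaging
#' choice; 6 and 26 available.
#'
#' @param sig A [pet_mask()] of suprathreshold voxels.
#' @param min_voxels Minimum cluster size; components of exactly this size
#'   are removed (strict `>`). Default 500.
#' @param connectivity 6, 18 or 26.
#' @return Filtered [pet_mask()].
#' @export
cluster_filter <- function(sig, min_voxels = 500, connectivity = 18) {
  stopifnot(inherits(sig, "pet_mask"), min_voxels >= 1,
            connectivity %in% c(6, 18, 26))
  grid <- array(as.integer(sig$data), dim = dim(sig$data))
  lab <- label_components_cpp(grid, as.integer(connectivity), FALSE)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes > min_voxels)
  pet_mask(array(lab %in% keep, dim = dim(sig$data)), spacing = sig$spacing)
}

#' Map surviving voxels to atlas regions
#'
#' For every atlas label, the candidate ROI is the intersection of the label
#' with the surviving mask; it is retained when the overlap reaches
#' `min_overlap` voxels (so texture matrices are well populated). Set
#' `full_label = TRUE` to use whole atlas regions touched by the mask
#' instead of intersections.
#'
#' @param surviving A [pet_mask()] (e.g. from [cluster_filter()]).
#' @param lm A [label_map()] with matching geometry.
#' @param min_overlap Minimum intersection size in voxels (default 64).
#' @param full_label Use the whole atlas region instead of the intersection.
#' @param stat Optional [voxelwise_ttest()] `stat_map` used to record each
#'   region's peak |t|.
#' @return An `roi_set`: tibble with columns `region_id`, `region_name`,
#'   `n_voxels`, `peak_t` and a list-column `voxels` of linear voxel
#'   indices; grid geometry in attributes.
#' @export
map_to_atlas <- function(surviving, lm, min_overlap = 64, full_label = FALSE,
                         stat = NULL) {
  stopifnot(inherits(surviving, "pet_mask"), inherits(lm, "label_map"))
  check_geometry(surviving, lm, "mask and atlas")
  rows <- purrr::map(lm$lookup$label_id, function(id) {
    in_label <- lm$labels == id
    inter <- in_label & surviving$data
    n <- sum(inter)
    if (n < min_overlap) return(NULL)
    vox <- if (full_label) which(in_label) else which(inter)
    peak <- if (!is.null(stat)) {
      tv <- stat$t[vox]
      tv <- tv[!is.na(tv)]
      if (length(tv)) max(abs(tv)) else NA_real_
    } else NA_real_
    tibble::tibble(
      region_id = id,
      region_name = lm$lookup$region_name[match(id, lm$lookup$label_id)],
      n_voxels = length(vox), peak_t = peak, voxels = list(vox)
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(region_id = integer(), region_name = character(),
                          n_voxels = integer(), peak_t = numeric(),
                          voxels = list())
  }
  structure(out, class = c("roi_set", class(out)),
            grid_dim = dim(lm$labels), spacing = lm$spacing,
            thresholds = list(min_overlap = min_overlap,
                              full_label = full_label))
}

#' Define disease-related ROIs from a training set
#'
#' The full ROI-definition stage: voxelwise pooled-variance t-test between
#' the two training groups inside the atlas foreground, BH-FDR threshold at
#' level `q`, cluster-extent filtering (strict `> min_cluster` voxels), and
#' mapping of the surviving voxels to atlas regions. This must be run on
#' training subjects only; the pipeline orchestrator enforces that.
#'
#' If no cluster survives (e.g. a null cohort) and `fallback = "atlas"`
#' (default), the full parcellation (minus the reference region, if
#' `exclude` is given) is returned with a warning so downstream stages can
#' still run; `fallback = "none"` returns the empty set.
#'
#' @param group_a,group_b Lists of training [pet_volume()]s (patients first).
#' @param atlas A [label_map()].
#' @param q FDR level (default 0.01).
#' @param min_cluster Cluster-extent threshold in voxels (default 500).
#' @param connectivity Cluster connectivity (default 18).
#' @param min_overlap Minimum ROI-atlas intersection (default 64 voxels).
#' @param exclude Label ids never used as ROIs (e.g. the reference region).
#' @param fallback `"atlas"` or `"none"`; see above.
#' @return An `roi_set` (see [map_to_atlas()]) with a `provenance` attribute
#'   recording all thresholds.
#' @export
define_rois <- function(group_a, group_b, atlas, q = 0.01, min_cluster = 500,
                        connectivity = 18, min_overlap = 64,
                        exclude = integer(), fallback = c("atlas", "none")) {
  fallback <- match.arg(fallback)
  keep_ids <- setdiff(atlas$lookup$label_id, exclude)
  brain <- mask_from_labels(atlas, keep_ids)
  stat <- voxelwise_ttest(group_a, group_b, mask = brain)
  cutoff <- fdr_cutoff(stat$p[brain$data], q = q)
  sig <- array(FALSE, dim = dim(stat$p))
  if (!is.na(cutoff)) {
    sig[brain$data] <- stat$p[brain$data] <= cutoff
  }
  surv <- cluster_filter(pet_mask(sig, spacing = atlas$spacing),
                         min_voxels = min_cluster,
                         connectivity = connectivity)
  rois <- map_to_atlas(surv, lm = subset_label_map(atlas, keep_ids),
                       min_overlap = min_overlap, stat = stat)
  if (nrow(rois) == 0 && fallback == "atlas") {
    warning("no cluster survived FDR + extent thresholding; ",
            "falling back to the full atlas parcellation", call. = FALSE)
    all_mask <- mask_from_labels(atlas, keep_ids)
    rois <- map_to_atlas(all_mask, lm = subset_label_map(atlas, keep_ids),
                         min_overlap = min_overlap, stat = stat)
  }
  attr(rois, "provenance") <- list(
    q = q, min_cluster = min_cluster, connectivity = connectivity,
    min_overlap = min_overlap, fdr_cutoff = cutoff,
    df = stat$df, fallback_used = is.na(cutoff) || sum(surv$data) == 0
  )
  rois
}

subset_label_map <- function(lm, ids) {
  labels <- lm$labels
  labels[!(labels %in% ids)] <- 0L
  label_map(labels, spacing = lm$spacing,
            lookup = lm$lookup[lm$lookup$label_id %in% ids, ])
}

#' Serialize an ROI set
#'
#' Writes the ROI voxels as one NIfTI label map, a TSV table
#' (`region_id`, `region_name`, `n_voxels`, `peak_t`) and a JSON sidecar
#' with the thresholds used.
#'
#' @param rois An `roi_set`.
#' @param path Output NIfTI path; the TSV/JSON take the same stem.
#' @return `path`, invisibly.
#' @export
write_roi_set <- function(rois, path) {
  d <- attr(rois, "grid_dim")
  labels <- array(0L, dim = d)
  for (i in seq_len(nrow(rois))) {
    labels[rois$voxels[[i]]] <- rois$region_id[i]
  }
  lm <- label_map(labels, spacing = attr(rois, "spacing"),
                  lookup = rois[, c("region_id", "region_name")] |>
                    stats::setNames(c("label_id", "region_name")))
  write_volume(lm, path, datatype = "int16")
  stem <- sub("\\.nii(\\.gz)?$", "", path)
  readr::write_tsv(
    tibble::as_tibble(rois)[, c("region_id", "region_name", "n_voxels", "peak_t")],
    paste0(stem, "_rois.tsv")
  )
  prov <- attr(rois, "provenance")
  if (!is.null(prov)) {
    jsonlite::write_json(prov, paste0(stem, "_provenance.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(path)
}
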