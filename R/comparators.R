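#' ROI SUVR values for one subject
#'
#' Standardized uptake value ratio: mean uptake in each ROI divided by the
#' mean uptake in the reference region (cerebellum in the real analysis).
#' Invariant to global multiplicative intensity rescaling.
#'
#' @param pet A [pet_volume()].
#' @param rois An `roi_set`.
#' @param reference A [pet_mask()] of the reference region.
#' @return Named numeric vector, one SUVR per ROI (`<ROI>__suvr`).
#' @export
compute_suvr <- function(pet, rois, reference) {
  stopifnot(inherits(pet, "pet_volume"), inherits(rois, "roi_set"),
            inherits(reference, "pet_mask"))
  check_geometry(pet, reference, "PET and reference mask")
  ref_vals <- pet$data[reference$data]
  if (length(ref_vals) == 0) stop("empty reference region", call. = FALSE)
  ref_mean <- mean(ref_vals)
  if (!is.finite(ref_mean) || ref_mean <= 0) {
    stop("reference region mean must be positive", call. = FALSE)
  }
  out <- vapply(seq_len(nrow(rois)), function(i) {
    mean(pet$data[rois$voxels[[i]]]) / ref_mean
  }, numeric(1))
  setNames(out, paste0(rois$region_name, "__suvr"))
}

#' SUVR feature table for a cohort
#'
#' One row per subject: metadata columns plus one SUVR per ROI, mirroring the
#' radiomics feature-table schema so both feed the identical classification
#' harness.
#'
#' @param cohort Cohort list or manifest tibble.
#' @param rois An `roi_set`.
#' @param reference Reference-region [pet_mask()].
#' @param preprocess Optional per-volume preprocessing function.
#' @return A tibble.
#' @export
suvr_table <- function(cohort, rois, reference, preprocess = NULL) {
  manifest <- if (is.data.frame(cohort)) cohort else cohort$manifest
  rows <- purrr::map(seq_len(nrow(manifest)), function(i) {
    v <- manifest_volume(manifest[i, ])
    if (!is.null(preprocess)) v <- preprocess(v)
    tibble::as_tibble_row(compute_suvr(v, rois, reference))
  })
  meta_cols <- intersect(
    c("id", "group", "age", "sex", "mmse", "tau_status", "apoe_status",
      "cohort"),
    names(manifest)
  )
  dplyr::bind_cols(manifest[, meta_cols], dplyr::bind_rows(rows))
}

#' Clinical-score feature table
#'
#' The MMSE-only comparator model: a single-feature table with the group
#' labels and covariates. Subjects missing the score are excluded with a
#' warning.
#'
#' @param manifest Manifest tibble with an `mmse` column.
#' @return A tibble with metadata columns and the feature column
#'   `clinical__mmse`.
#' @export
clinical_table <- function(manifest) {
  if (is.list(manifest) && !is.data.frame(manifest)) manifest <- manifest$manifest
  stopifnot("mmse" %in% names(manifest))
  missing <- is.na(manifest$mmse)
  if (any(missing)) {
    warning("excluding ", sum(missing), " subjects with missing MMSE: ",
            paste(manifest$id[missing], collapse = ", "), call. = FALSE)
    manifest <- manifest[!missing, ]
  }
  meta_cols <- intersect(
    c("id", "group", "age", "sex", "mmse", "tau_status", "apoe_status",
      "cohort"),
    names(manifest)
  )
  out <- manifest[, meta_cols]
  out$clinical__mmse <- as.numeric(manifest$mmse)
  out
}
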