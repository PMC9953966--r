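#' Integer-labeled atlas volumes
#'
#' A `label_map` assigns each voxel a non-negative integer region id
#' (0 = background) and carries a lookup table mapping every nonzero id to a
#' region name. Geometry must match the PET volumes it parcellates.
#'
#' @param labels 3D integer array of region ids (0 = background).
#' @param spacing Numeric length-3 voxel size in mm.
#' @param lookup A data frame with columns `label_id`, `region_name` covering
#'   every nonzero id, or `NULL` to auto-name regions `region_<id>`.
#' @return A `label_map` object.
#' @export
label_map <- function(labels, spacing = c(1, 1, 1), lookup = NULL) {
  if (!is.array(labels) || length(dim(labels)) != 3L) {
    stop("`labels` must be a 3D array", call. = FALSE)
  }
  storage.mode(labels) <- "integer"
  if (any(is.na(labels)) || any(labels < 0L)) {
    stop("labels must be non-negative integers", call. = FALSE)
  }
  ids <- sort(unique(as.vector(labels)))
  ids <- ids[ids != 0L]
  if (is.null(lookup)) {
    lookup <- tibble::tibble(
      label_id = ids,
      region_name = sprintf("region_%02d", ids)
    )
  } else {
    lookup <- tibble::as_tibble(lookup)
    stopifnot(all(c("label_id", "region_name") %in% names(lookup)))
    missing <- setdiff(ids, lookup$label_id)
    if (length(missing) > 0) {
      stop("lookup table misses label ids: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  spacing <- as.numeric(spacing)
  stopifnot(length(spacing) == 3L, all(spacing > 0))
  structure(list(labels = labels, spacing = spacing, lookup = lookup),
            class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  cat(sprintf("<label_map> %s voxels @ %s mm, %d regions\n",
              paste(dim(x$labels), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              nrow(x$lookup)))
  invisible(x)
}

#' Read a label map with its lookup table
#'
#' @param path NIfTI file of integer labels.
#' @param lookup_path Optional 2-column TSV (`label_id`, `region_name`).
#' @return A [label_map()].
#' @export
read_label_map <- function(path, lookup_path = NULL) {
  v <- read_volume(path)
  labels <- round(v$data)
  storage.mode(labels) <- "integer"
  lookup <- NULL
  if (!is.null(lookup_path)) {
    lookup <- readr::read_tsv(lookup_path, show_col_types = FALSE)
  }
  label_map(labels, spacing = v$spacing, lookup = lookup)
}

#' Write a label map and its lookup TSV
#'
#' @param lm A [label_map()].
#' @param path Output NIfTI path.
#' @param lookup_path Optional TSV path for the lookup table.
#' @return `path`, invisibly.
#' @export
write_label_map <- function(lm, path, lookup_path = NULL) {
  write_volume(lm, path, datatype = "int16")
  if (!is.null(lookup_path)) {
    readr::write_tsv(lm$lookup, lookup_path)
  }
  invisible(path)
}

#' Boolean masks over a volume grid
#'
#' @param data 3D logical array.
#' @param spacing Numeric length-3 voxel size in mm.
#' @return A `pet_mask` object.
#' @export
pet_mask <- function(data, spacing = c(1, 1, 1)) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("`data` must be a 3D array", call. = FALSE)
  }
  storage.mode(data) <- "logical"
  if (any(is.na(data))) stop("mask may not contain NA", call. = FALSE)
  structure(list(data = data, spacing = as.numeric(spacing)),
            class = "pet_mask")
}

#' @export
print.pet_mask <- function(x, ...) {
  cat(sprintf("<pet_mask> %s voxels @ %s mm, %d set\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              sum(x$data)))
  invisible(x)
}

#' Build a mask from atlas labels
#'
#' @param lm A [label_map()].
#' @param ids Nonempty vector of label ids, all present in the lookup table.
#' @return A [pet_mask()] true exactly where `lm` takes a value in `ids`.
#' @export
mask_from_labels <- function(lm, ids) {
  stopifnot(inherits(lm, "label_map"))
  if (length(ids) == 0) stop("`ids` must be nonempty", call. = FALSE)
  ids <- as.integer(ids)
  unknown <- setdiff(ids, lm$lookup$label_id)
  if (length(unknown) > 0) {
    stop("unknown label ids: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  pet_mask(array(lm$labels %in% ids, dim = dim(lm$labels)),
           spacing = lm$spacing)
}

#' Number of voxels set in a mask
#' @param mask A [pet_mask()].
#' @return Integer count.
#' @export
mask_count <- function(mask) {
  stopifnot(inherits(mask, "pet_mask"))
  sum(mask$data)
}
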