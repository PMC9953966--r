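# The 43-feature texture bank: 3 histogram + 9 GLCM + 13 GLRLM + 13 GLSZM +
# 5 NGTDM features per quantized ROI. Matrices are accumulated in C++ over
# the voxel grid (13 unique directions for GLCM/GLRLM, 26-connected zones
# for GLSZM, 26-neighborhoods for NGTDM); the feature formulas live here.
#
# Degenerate-value policy: single-level or single-voxel ROIs never produce
# NaN. GLCM with no pairs -> energy 1, others 0; zero-variance moments and
# correlations map to 0; the NGTDM coarseness denominator carries a 1e-6
# guard (the formula diverges on constant ROIs).

texture_feature_names <- function() {
  c(
    paste0("hist_", c("variance", "skewness", "kurtosis")),
    paste0("glcm_", c("energy", "contrast", "entropy", "homogeneity",
                      "correlation", "sum_average", "variance",
                      "dissimilarity", "autocorrelation")),
    paste0("glrlm_", c("sre", "lre", "gln", "rln", "rp", "lgre", "hgre",
                       "srlge", "srhge", "lrlge", "lrhge", "glv", "rlv")),
    paste0("glszm_", c("sze", "lze", "gln", "zsn", "zp", "lgze", "hgze",
                       "szlge", "szhge", "lzlge", "lzhge", "glv", "zsv")),
    paste0("ngtdm_", c("coarseness", "contrast", "busyness", "complexity",
                       "strength"))
  )
}

#' Histogram moments of a quantized ROI
#'
#' Variance, skewness and kurtosis (biased moment estimators; kurtosis is
#' non-excess) of the gray-level values. Zero-variance ROIs map skewness and
#' kurtosis to 0.
#'
#' @param levels Integer vector or array of gray levels (0 = outside ROI for
#'   arrays).
#' @return Named numeric of length 3.
#' @export
histogram_features <- function(levels) {
  x <- as.numeric(levels[levels > 0])
  n <- length(x)
  if (n == 0) stop("empty ROI", call. = FALSE)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  if (m2 == 0) {
    return(c(hist_variance = 0, hist_skewness = 0, hist_kurtosis = 0))
  }
  c(hist_variance = m2,
    hist_skewness = mean((x - mu)^3) / m2^1.5,
    hist_kurtosis = mean((x - mu)^4) / m2^2)
}

#' Gray-level co-occurrence matrix and its 9 features
#'
#' Co-occurrences at Chebyshev distance 1, accumulated over the 13 unique 3D
#' directions into one symmetric matrix (pairs counted only when both voxels
#' are in the ROI), normalized to probabilities. Entropy uses log2 with
#' `0 * log 0 := 0`.
#'
#' @param levels 3D integer array, 1..Ng in the ROI, 0 outside.
#' @param n_levels Number of gray levels Ng.
#' @return List with `matrix` (normalized Ng x Ng) and `features`
#'   (named, length 9).
#' @export
compute_glcm <- function(levels, n_levels) {
  M <- glcm_counts_cpp(levels, as.integer(n_levels))
  M <- M + t(M)
  total <- sum(M)
  feats <- setNames(numeric(9), paste0(
    "glcm_", c("energy", "contrast", "entropy", "homogeneity", "correlation",
               "sum_average", "variance", "dissimilarity", "autocorrelation")))
  if (total == 0) {
    feats["glcm_energy"] <- 1
    return(list(matrix = M, features = feats))
  }
  P <- M / total
  ng <- nrow(P)
  I <- matrix(seq_len(ng), ng, ng)
  J <- t(I)
  px <- rowSums(P)
  mu <- sum(seq_len(ng) * px)
  sg2 <- sum((seq_len(ng) - mu)^2 * px)
  plog <- ifelse(P > 0, P * log2(P), 0)
  feats["glcm_energy"] <- sum(P^2)
  feats["glcm_contrast"] <- sum((I - J)^2 * P)
  feats["glcm_entropy"] <- -sum(plog)
  feats["glcm_homogeneity"] <- sum(P / (1 + abs(I - J)))
  feats["glcm_correlation"] <- if (sg2 > 0) {
    sum((I - mu) * (J - mu) * P) / sg2
  } else 0
  feats["glcm_sum_average"] <- sum((I + J) * P)
  feats["glcm_variance"] <- sum((I - mu)^2 * P)
  feats["glcm_dissimilarity"] <- sum(abs(I - J) * P)
  feats["glcm_autocorrelation"] <- sum(I * J * P)
  list(matrix = P, features = feats)
}

# shared small-to-large emphasis formulas for GLRLM / GLSZM
rl_features <- function(M, prefix, n_voxels) {
  ng <- nrow(M); rmax <- ncol(M)
  nr <- sum(M)
  nm <- paste0(prefix, "_",
               if (prefix == "glrlm") {
                 c("sre", "lre", "gln", "rln", "rp", "lgre", "hgre", "srlge",
                   "srhge", "lrlge", "lrhge", "glv", "rlv")
               } else {
                 c("sze", "lze", "gln", "zsn", "zp", "lgze", "hgze", "szlge",
                   "szhge", "lzlge", "lzhge", "glv", "zsv")
               })
  feats <- setNames(numeric(13), nm)
  if (nr == 0) return(feats)
  i <- matrix(seq_len(ng), ng, rmax)
  r <- matrix(seq_len(rmax), ng, rmax, byrow = TRUE)
  P <- M / nr
  feats[1] <- sum(M / r^2) / nr                      # short emphasis
  feats[2] <- sum(M * r^2) / nr                      # long emphasis
  feats[3] <- sum(rowSums(M)^2) / nr                 # gray-level nonuniformity
  feats[4] <- sum(colSums(M)^2) / nr                 # length nonuniformity
  feats[5] <- nr / n_voxels                          # run/zone percentage
  feats[6] <- sum(M / i^2) / nr
  feats[7] <- sum(M * i^2) / nr
  feats[8] <- sum(M / (i^2 * r^2)) / nr
  feats[9] <- sum(M * i^2 / r^2) / nr
  feats[10] <- sum(M * r^2 / i^2) / nr
  feats[11] <- sum(M * i^2 * r^2) / nr
  mu_i <- sum(i * P)
  mu_r <- sum(r * P)
  feats[12] <- sum((i - mu_i)^2 * P)                 # gray-level variance
  feats[13] <- sum((r - mu_r)^2 * P)                 # length variance
  feats
}

#' Gray-level run-length matrix and its 13 features
#'
#' Maximal constant-level runs along each of the 13 unique 3D directions,
#' merged into one Ng x Rmax matrix; runs are truncated at the ROI boundary.
#' The run percentage denominator is the total voxel count times 13 (each
#' voxel takes part in one run per direction).
#'
#' @inheritParams compute_glcm
#' @return List with `matrix` (counts, trailing empty columns trimmed) and
#'   `features` (named, length 13).
#' @export
compute_glrlm <- function(levels, n_levels) {
  M <- glrlm_counts_cpp(levels, as.integer(n_levels))
  n_vox <- sum(levels > 0)
  used <- which(colSums(M) > 0)
  if (length(used) > 0) M <- M[, seq_len(max(used)), drop = FALSE]
  feats <- rl_features(M, "glrlm", n_voxels = 13 * n_vox)
  list(matrix = M, features = feats)
}

#' Gray-level size-zone matrix and its 13 features
#'
#' Zones are 26-connected components of equal gray level within the ROI;
#' the matrix counts zones by level and size. Direction-free.
#'
#' @inheritParams compute_glcm
#' @return List with `matrix` and `features` (named, length 13).
#' @export
compute_glszm <- function(levels, n_levels) {
  lab <- label_components_cpp(levels, 26L, TRUE)
  n_vox <- sum(levels > 0)
  if (n_vox == 0) stop("empty ROI", call. = FALSE)
  zones <- tabulate(lab[lab > 0L])
  zone_level <- levels[match(seq_along(zones), lab)]
  zmax <- max(zones)
  M <- matrix(0, n_levels, zmax)
  for (k in seq_along(zones)) {
    M[zone_level[k], zones[k]] <- M[zone_level[k], zones[k]] + 1
  }
  feats <- rl_features(M, "glszm", n_voxels = n_vox)
  list(matrix = M, features = feats)
}

#' Neighborhood gray-tone difference features
#'
#' For every voxel with at least one in-ROI neighbor (26-neighborhood), the
#' absolute difference between its level and the mean level of those
#' neighbors is accumulated per level; coarseness, contrast, busyness,
#' complexity and strength follow the Amadasun-King definitions with a 1e-6
#' guard on diverging denominators.
#'
#' @inheritParams compute_glcm
#' @return List with `table` (per-level counts `n_i` and sums `s_i`) and
#'   `features` (named, length 5).
#' @export
compute_ngtdm <- function(levels, n_levels) {
  A <- ngtdm_accum_cpp(levels, as.integer(n_levels))
  n_i <- A[, 1]; s_i <- A[, 2]
  N <- sum(n_i)
  feats <- setNames(numeric(5), paste0(
    "ngtdm_", c("coarseness", "contrast", "busyness", "complexity",
                "strength")))
  if (N == 0) {
    feats["ngtdm_coarseness"] <- 1 / 1e-6
    return(list(table = A, features = feats))
  }
  p_i <- n_i / N
  act <- which(p_i > 0)
  ngp <- length(act)
  eps <- 1e-6
  feats["ngtdm_coarseness"] <- 1 / (sum(p_i * s_i) + eps)
  if (ngp > 1) {
    grid <- expand.grid(i = act, j = act)
    pij <- p_i[grid$i] * p_i[grid$j]
    dij <- grid$i - grid$j
    feats["ngtdm_contrast"] <- (sum(pij * dij^2) / (ngp * (ngp - 1))) *
      (sum(s_i) / N)
    denom <- sum(abs(grid$i * p_i[grid$i] - grid$j * p_i[grid$j]))
    feats["ngtdm_busyness"] <- if (denom > 0) sum(p_i * s_i) / denom else 0
    feats["ngtdm_complexity"] <- sum(abs(dij) *
      (p_i[grid$i] * s_i[grid$i] + p_i[grid$j] * s_i[grid$j]) /
      (p_i[grid$i] + p_i[grid$j])) / N
    feats["ngtdm_strength"] <-
      sum((p_i[grid$i] + p_i[grid$j]) * dij^2) / (sum(s_i) + eps)
  }
  list(table = A, features = feats)
}

#' All 43 texture-bank features of one quantized ROI
#'
#' @param levels 3D integer array (1..Ng in ROI, 0 outside).
#' @param n_levels Gray-level count Ng.
#' @return Named numeric vector of length 43.
#' @export
roi_feature_vector <- function(levels, n_levels) {
  out <- c(
    histogram_features(levels),
    compute_glcm(levels, n_levels)$features,
    compute_glrlm(levels, n_levels)$features,
    compute_glszm(levels, n_levels)$features,
    compute_ngtdm(levels, n_levels)$features
  )
  stopifnot(length(out) == 43, all(is.finite(out)))
  out
}

#' Extract the per-ROI feature bank for one subject
#'
#' Per ROI: (optionally) resample the PET volume to an isotropic grid,
#' Lloyd-Max quantize the within-ROI intensities to `n_levels` gray levels,
#' and compute all 43 features. ROIs smaller than `min_voxels` yield missing
#' features with a warning. Feature names follow
#' `"<ROIname>__<family>_<feature>"`.
#'
#' @param pet A [pet_volume()] with geometry matching the ROI set.
#' @param rois An `roi_set` from [map_to_atlas()] / [define_rois()].
#' @param n_levels Gray levels for quantization (default 64).
#' @param iso_mm Target isotropic spacing; when the volume is already on an
#'   isotropic grid at this spacing (the usual case) no resampling happens.
#'   `NULL` skips resampling entirely.
#' @param min_voxels ROIs below this size give NA features (default 27).
#' @return Named numeric vector of length `43 * nrow(rois)`.
#' @export
extract_features <- function(pet, rois, n_levels = 64, iso_mm = NULL,
                             min_voxels = 27) {
  stopifnot(inherits(pet, "pet_volume"), inherits(rois, "roi_set"))
  if (!is.null(iso_mm) && !all(abs(pet$spacing - iso_mm) < 1e-9)) {
    stop("volume spacing differs from iso_mm; resample volumes and atlas ",
         "together with resample_isotropic() before defining ROIs",
         call. = FALSE)
  }
  if (!identical(dim(pet$data), attr(rois, "grid_dim"))) {
    stop("volume geometry does not match the ROI set", call. = FALSE)
  }
  fam_names <- texture_feature_names()
  out <- purrr::map(seq_len(nrow(rois)), function(i) {
    vox <- rois$voxels[[i]]
    if (length(vox) < min_voxels) {
      warning("ROI ", rois$region_name[i], " below ", min_voxels,
              " voxels; features set to NA", call. = FALSE)
      return(setNames(rep(NA_real_, 43),
                      paste0(rois$region_name[i], "__", fam_names)))
    }
    qa <- quantized_roi_array(pet, vox, n_levels = n_levels)
    fv <- roi_feature_vector(qa$levels, qa$n_levels)
    setNames(fv, paste0(rois$region_name[i], "__", names(fv)))
  })
  unlist(out)
}

#' Build the cohort feature table
#'
#' One row per manifest subject: id, group, covariates, then the
#' `43 * nrow(rois)` radiomics features. Rows are extracted independently,
#' so the table is deterministic and free of train/test leakage (quantizers
#' are per subject and per ROI).
#'
#' @param cohort A cohort list (`manifest`, `atlas`) from [generate_cohort()],
#'   or any manifest tibble with `volume` or `path` columns.
#' @param rois An `roi_set`.
#' @param n_levels Gray levels (default 64).
#' @param preprocess Optional function applied to each volume before
#'   extraction (e.g. `function(v) gaussian_smooth(v, 8)`).
#' @return A tibble: `id`, `group`, `age`, `sex`, `mmse`, `tau_status`,
#'   `apoe_status`, `cohort`, then feature columns.
#' @export
feature_table <- function(cohort, rois, n_levels = 64, preprocess = NULL) {
  manifest <- if (is.data.frame(cohort)) cohort else cohort$manifest
  feats <- purrr::map(seq_len(nrow(manifest)), function(i) {
    v <- manifest_volume(manifest[i, ])
    if (!is.null(preprocess)) v <- preprocess(v)
    tibble::as_tibble_row(extract_features(v, rois, n_levels = n_levels))
  })
  meta_cols <- intersect(
    c("id", "group", "age", "sex", "mmse", "tau_status", "apoe_status",
      "cohort"),
    names(manifest)
  )
  dplyr::bind_cols(manifest[, meta_cols], dplyr::bind_rows(feats))
}

#' Names of the feature columns of a feature table
#' @param table A feature table.
#' @return Character vector of `<ROI>__<family>_<feature>` columns.
#' @export
feature_columns <- function(table) {
  grep("__", names(table), value = TRUE, fixed = TRUE)
}
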