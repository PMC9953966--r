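#' Specification of a synthetic PET cohort
#'
#' Defines the statistical skeleton the analysis assumes: two (or more)
#' diagnostic groups whose patient members carry a regional mean-uptake shift
#' and a regional texture (spatial-correlation-length) change against a
#' smooth Gaussian-random-field background, an unaffected reference region
#' (cerebellum stand-in), demographic covariates with mild global effects on
#' uptake, clinical scores, optional tau-positivity / ApoE-carrier subgroup
#' labels tied to signal amplitude, and an optional site-shifted external
#' cohort.
#'
#' All downstream stages are exercised against cohorts generated from this
#' object; generation is fully deterministic given `seed`.
#'
#' @param n_per_group Subjects per group (default 60).
#' @param groups Ordered group names; the last is the control group.
#' @param grid_dim Output grid (default `c(64, 64, 64)`).
#' @param spacing Voxel size mm (default 2 mm isotropic).
#' @param n_regions Atlas parcel count including the reference region
#'   (default 61 = 60 + reference).
#' @param affected_regions Region ids carrying group effects (default 1:12).
#' @param mean_shift Uptake increase in affected regions for patients, in
#'   units of the noise SD (default 2).
#' @param texture_effect Extra correlation FWHM (mm) of the within-ROI noise
#'   field for patients (default 4; 0 disables the texture difference).
#' @param background_fwhm Correlation FWHM (mm) of the background field
#'   (default 4).
#' @param baseline_uptake Mean uptake inside the brain (default 5).
#' @param noise_sd Marginal SD of the background field (default 1).
#' @param age_effect,sex_effect Global uptake slope per year of age and
#'   offset for male sex (defaults 0: demographics do not drive uptake;
#'   set nonzero to give covariate adjustment something to remove).
#' @param mmse_mean,mmse_sd Named per-group MMSE means/SDs; defaults follow
#'   typical AD (24.0 +/- 3.3) and control (29.1 +/- 1.2) cohorts.
#' @param subgroup_model List with tau-positivity and ApoE-carrier base
#'   rates and the amplitude multipliers applied to negative/non-carrier
#'   patients (`tau_rate`, `tau_amp`, `apoe_rate`, `apoe_amp`).
#' @param n_external_per_group Subjects per group in a site-shifted external
#'   test cohort (default 0 = none).
#' @param site_shift Named vector `c(scale =, offset =)` applied to external
#'   volumes (default 1.1 and 0.5).
#' @param seed Integer RNG seed (default 1).
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_per_group = 60,
                        groups = c("AD", "NC"),
                        grid_dim = c(64, 64, 64),
                        spacing = c(2, 2, 2),
                        n_regions = 61,
                        affected_regions = 1:12,
                        mean_shift = 2,
                        texture_effect = 4,
                        background_fwhm = 4,
                        baseline_uptake = 5,
                        noise_sd = 1,
                        age_effect = 0,
                        sex_effect = 0,
                        mmse_mean = NULL,
                        mmse_sd = NULL,
                        subgroup_model = list(tau_rate = 0.5, tau_amp = 0.3,
                                              apoe_rate = 0.5, apoe_amp = 0.6),
                        n_external_per_group = 0,
                        site_shift = c(scale = 1.1, offset = 0.5),
                        seed = 1) {
  stopifnot(n_per_group >= 2, length(groups) >= 2, n_regions >= 2)
  reference_region <- n_regions
  if (reference_region %in% affected_regions) {
    stop("the reference region (id ", reference_region,
         ") cannot be an affected region", call. = FALSE)
  }
  if (any(affected_regions < 1 | affected_regions >= n_regions)) {
    stop("affected_regions must be ids in 1..(n_regions - 1)", call. = FALSE)
  }
  stopifnot(is.finite(mean_shift), is.finite(texture_effect),
            texture_effect >= 0, background_fwhm > 0, noise_sd > 0)
  control <- groups[length(groups)]
  if (is.null(mmse_mean)) {
    mmse_mean <- setNames(c(rep(24.0, length(groups) - 1), 29.1), groups)
    if (length(groups) == 3) mmse_mean[2] <- 27.9
  }
  if (is.null(mmse_sd)) {
    mmse_sd <- setNames(c(rep(3.3, length(groups) - 1), 1.2), groups)
    if (length(groups) == 3) mmse_sd[2] <- 1.9
  }
  structure(list(
    n_per_group = as.integer(n_per_group), groups = groups,
    control_group = control,
    grid_dim = as.integer(grid_dim), spacing = as.numeric(spacing),
    n_regions = as.integer(n_regions),
    reference_region = as.integer(reference_region),
    affected_regions = as.integer(affected_regions),
    mean_shift = mean_shift, texture_effect = texture_effect,
    background_fwhm = background_fwhm, baseline_uptake = baseline_uptake,
    noise_sd = noise_sd, age_effect = age_effect, sex_effect = sex_effect,
    mmse_mean = mmse_mean, mmse_sd = mmse_sd,
    subgroup_model = subgroup_model,
    n_external_per_group = as.integer(n_external_per_group),
    site_shift = site_shift, seed = as.integer(seed)
  ), class = "cohort_spec")
}

# Deterministic per-subject sub-seed, kept below 2^31.
derive_seed <- function(base, i) {
  as.integer((abs(as.double(base)) %% 1000003 * 1009 + i * 7919) %% 2147483629 + 1)
}

#' Generate a phantom atlas
#'
#' Parcellates an ellipsoidal "brain" into `n_regions` contiguous Voronoi
#' cells of seeded points (three Lloyd relaxation sweeps even out cell
#' sizes). The cell with the lowest centroid along the third axis is
#' relabeled to the last id and plays the unaffected reference region
#' (cerebellum stand-in). Deterministic given `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @return A [label_map()] with `n_regions` nonzero labels.
#' @export
generate_atlas <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  d <- spec$grid_dim
  ctr <- (d + 1) / 2
  semi <- d * c(0.44, 0.42, 0.40)
  ix <- seq_len(d[1]); iy <- seq_len(d[2]); iz <- seq_len(d[3])
  X <- array(rep(ix, times = d[2] * d[3]), dim = d)
  Y <- array(rep(rep(iy, each = d[1]), times = d[3]), dim = d)
  Z <- array(rep(iz, each = d[1] * d[2]), dim = d)
  inside <- ((X - ctr[1]) / semi[1])^2 + ((Y - ctr[2]) / semi[2])^2 +
    ((Z - ctr[3]) / semi[3])^2 <= 1
  vox <- cbind(X[inside], Y[inside], Z[inside])
  if (nrow(vox) < 64 * spec$n_regions) {
    stop("grid too small for ", spec$n_regions,
         " regions of >= 64 voxels", call. = FALSE)
  }
  seeds <- withr::with_seed(spec$seed, {
    vox[sample.int(nrow(vox), spec$n_regions), , drop = FALSE]
  })
  assign_cells <- function(pts) {
    best <- rep(Inf, nrow(vox)); lab <- integer(nrow(vox))
    for (k in seq_len(nrow(pts))) {
      d2 <- (vox[, 1] - pts[k, 1])^2 + (vox[, 2] - pts[k, 2])^2 +
        (vox[, 3] - pts[k, 3])^2
      upd <- d2 < best
      best[upd] <- d2[upd]; lab[upd] <- k
    }
    lab
  }
  lab <- assign_cells(seeds)
  for (it in 1:3) {
    for (k in seq_len(nrow(seeds))) {
      m <- lab == k
      if (any(m)) seeds[k, ] <- colMeans(vox[m, , drop = FALSE])
    }
    lab <- assign_cells(seeds)
  }
  sizes <- tabulate(lab, nbins = spec$n_regions)
  if (any(sizes < 64)) {
    stop("atlas generation produced a region below 64 voxels; ",
         "reduce n_regions or enlarge the grid", call. = FALSE)
  }
  # reference = lowest cell along z (inferior stand-in)
  zc <- vapply(seq_len(spec$n_regions),
               function(k) mean(vox[lab == k, 3]), numeric(1))
  ref <- which.min(zc)
  if (ref != spec$n_regions) {
    lab[lab == ref] <- -1L
    lab[lab == spec$n_regions] <- ref
    lab[lab == -1L] <- spec$n_regions
  }
  labels <- array(0L, dim = d)
  labels[inside] <- lab
  lookup <- tibble::tibble(
    label_id = seq_len(spec$n_regions),
    region_name = c(sprintf("region_%02d", seq_len(spec$n_regions - 1)),
                    "reference_cerebellum")
  )
  label_map(labels, spacing = spec$spacing, lookup = lookup)
}

# Smoothed-white-noise Gaussian random field with unit marginal SD
# (interior-voxel normalization is analytic, not empirical).
grf_field <- function(grid_dim, spacing, fwhm_mm) {
  noise <- array(rnorm(prod(grid_dim)), dim = grid_dim)
  v <- gaussian_smooth(pet_volume(noise, spacing), fwhm_mm = fwhm_mm)
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / spacing
  sdf <- 1
  for (axis in 1:3) {
    radius <- max(1L, ceiling(4 * sigma_vox[axis]))
    taps <- stats::dnorm(seq(-radius, radius), sd = sigma_vox[axis])
    taps <- taps / sum(taps)
    sdf <- sdf * sqrt(sum(taps^2))
  }
  v$data / sdf
}

#' Generate one synthetic subject volume
#'
#' Background: unit-SD Gaussian random field (correlation FWHM
#' `background_fwhm`) scaled by `noise_sd`, plus a constant brain baseline
#' and mild global age/sex effects. Patients (any non-control group) receive
#' `mean_shift * amplitude * noise_sd` added inside the affected regions and,
#' when `texture_effect > 0`, a smoother noise field blended into those
#' regions (blend weight `sqrt(min(amplitude, 1))`), which changes local
#' correlation length with little change to the regional mean. The reference
#' region never receives a group effect. External-cohort volumes get the
#' multiplicative + additive site shift. Deterministic given the subject's
#' `seed` (derived from the cohort seed and subject index).
#'
#' @param spec A [cohort_spec()].
#' @param record One manifest row (list or 1-row data frame) with fields
#'   `group`, `age`, `sex`, `amplitude`, `cohort`, `seed`.
#' @param atlas The [label_map()] from [generate_atlas()].
#' @return A [pet_volume()].
#' @export
generate_subject_volume <- function(spec, record, atlas) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(atlas, "label_map"))
  record <- as.list(record)
  if (!identical(dim(atlas$labels), spec$grid_dim)) {
    stop("atlas geometry does not match the cohort spec", call. = FALSE)
  }
  brain <- atlas$labels > 0L
  affected <- array(atlas$labels %in% spec$affected_regions,
                    dim = spec$grid_dim)
  is_patient <- record$group != spec$control_group
  amp <- if (is.null(record$amplitude)) 1 else record$amplitude
  withr::with_seed(as.integer(record$seed), {
    field <- grf_field(spec$grid_dim, spec$spacing, spec$background_fwhm)
    if (is_patient && spec$texture_effect > 0 && amp > 0) {
      tex <- grf_field(spec$grid_dim, spec$spacing,
                       spec$background_fwhm + spec$texture_effect)
      w <- sqrt(min(amp, 1))
      field[affected] <- sqrt(1 - w^2) * field[affected] + w * tex[affected]
    }
    vol <- spec$baseline_uptake +
      spec$age_effect * (record$age - 72) +
      spec$sex_effect * (record$sex == "M") +
      spec$noise_sd * field
    if (is_patient) {
      vol[affected] <- vol[affected] + spec$mean_shift * amp * spec$noise_sd
    }
    vol[!brain] <- 0
    if (identical(record$cohort, "external")) {
      v <- vol
      v[brain] <- spec$site_shift[["scale"]] * v[brain] +
        spec$site_shift[["offset"]]
      vol <- v
    }
    pet_volume(vol, spacing = spec$spacing)
  })
}

sample_manifest <- function(spec) {
  n_dis <- spec$n_per_group * length(spec$groups)
  n_ext <- spec$n_external_per_group * length(spec$groups)
  group_of <- c(rep(spec$groups, each = spec$n_per_group),
                rep(spec$groups, each = spec$n_external_per_group))
  rows <- purrr::map(seq_len(n_dis + n_ext), function(i) {
    ext <- i > n_dis
    group <- group_of[i]
    sseed <- derive_seed(spec$seed, i)
    is_patient <- group != spec$control_group
    withr::with_seed(sseed, {
      age <- round(rnorm(1, 72, 7))
      sex <- if (runif(1) < 0.5) "M" else "F"
      mmse <- round(rnorm(1, spec$mmse_mean[[group]], spec$mmse_sd[[group]]))
      mmse <- min(max(mmse, 0), 30)
      sg <- spec$subgroup_model
      tau <- if (is_patient) {
        if (runif(1) < sg$tau_rate) "+" else "-"
      } else NA_character_
      apoe <- if (is_patient) {
        if (runif(1) < sg$apoe_rate) "carrier" else "non-carrier"
      } else NA_character_
      amp <- 1
      if (is_patient) {
        if (identical(tau, "-")) amp <- amp * sg$tau_amp
        if (identical(apoe, "non-carrier")) amp <- amp * sg$apoe_amp
      }
      tibble::tibble(
        id = sprintf("sub-%04d", i), group = group, age = age, sex = sex,
        mmse = mmse, tau_status = tau, apoe_status = apoe,
        amplitude = amp,
        cohort = if (ext) "external" else "discovery",
        seed = sseed
      )
    })
  })
  dplyr::bind_rows(rows)
}

#' Generate a full synthetic cohort
#'
#' Produces the atlas, one volume per subject, and the subject manifest.
#' With `out_dir = NULL` the volumes are kept in memory (manifest gains a
#' `volume` list-column); otherwise NIfTI volumes, the atlas + lookup table,
#' a `manifest.tsv` and a JSON generation log (with the seed) are written.
#'
#' @param spec A [cohort_spec()].
#' @param out_dir Output directory, or `NULL` for an in-memory cohort.
#' @return A list with elements `manifest` (tibble), `atlas` ([label_map()])
#'   and `spec`.
#' @export
generate_cohort <- function(spec, out_dir = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  atlas <- generate_atlas(spec)
  manifest <- sample_manifest(spec)
  vols <- purrr::map(seq_len(nrow(manifest)), function(i) {
    generate_subject_volume(spec, manifest[i, ], atlas)
  })
  if (is.null(out_dir)) {
    manifest$volume <- vols
  } else {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    if (file.access(out_dir, mode = 2) != 0) {
      stop("output directory is not writable: ", out_dir, call. = FALSE)
    }
    write_label_map(atlas, file.path(out_dir, "atlas.nii.gz"),
                    file.path(out_dir, "atlas_lookup.tsv"))
    manifest$path <- file.path(out_dir, paste0(manifest$id, ".nii.gz"))
    purrr::walk2(vols, manifest$path, write_volume)
    readr::write_tsv(manifest, file.path(out_dir, "manifest.tsv"))
    jsonlite::write_json(
      list(seed = spec$seed, n_per_group = spec$n_per_group,
           groups = spec$groups, mean_shift = spec$mean_shift,
           texture_effect = spec$texture_effect),
      file.path(out_dir, "generation_log.json"),
      auto_unbox = TRUE, pretty = TRUE
    )
  }
  list(manifest = manifest, atlas = atlas, spec = spec)
}

#' Fetch a subject volume from a cohort manifest row
#'
#' Reads from `path` or takes the in-memory `volume` column.
#' @param row One manifest row.
#' @return A [pet_volume()].
#' @export
manifest_volume <- function(row) {
  if (!is.null(row$volume)) {
    v <- row$volume
    if (is.list(v) && !inherits(v, "pet_volume")) v <- v[[1]]
    return(v)
  }
  read_volume(row$path)
}
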