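# texture_features: Lloyd-Max quantization and the 43-feature bank

test_that("lloyd_max_quantize recovers the analytic uniform solution", {
  withr::with_seed(51, x <- runif(1e4))
  q <- lloyd_max_quantize(x, n_levels = 4)
  expect_equal(q$boundaries, c(0.25, 0.5, 0.75), tolerance = 0.02)
  expect_equal(q$centroids, c(0.125, 0.375, 0.625, 0.875), tolerance = 0.02)
  expect_false(q$degenerate)
})

test_that("lloyd_max_quantize is exact on Ng-point discrete support", {
  x <- rep(c(-3, 0.5, 2, 10), times = c(7, 3, 9, 5))
  q <- lloyd_max_quantize(x, n_levels = 4)
  expect_equal(sort(q$centroids), c(-3, 0.5, 2, 10))
  expect_equal(q$mse, 0)
  # each mass is its own level, in order
  expect_identical(q$levels, rep(1:4, times = c(7, 3, 9, 5)))
})

test_that("lloyd_max_quantize flags constant input as degenerate", {
  q <- lloyd_max_quantize(rep(2.5, 100), n_levels = 8)
  expect_true(q$degenerate)
  expect_true(all(q$levels == 1L))
})

test_that("lloyd_max_quantize never increases MSE across iterations", {
  withr::with_seed(53, x <- c(rnorm(500), rnorm(300, 5), runif(200, -4, 0)))
  for (ng in c(2, 8, 32)) {
    q <- lloyd_max_quantize(x, n_levels = ng)
    expect_equal(q$mse, mean((x - q$centroids[q$levels])^2),
                 tolerance = 1e-4)
    # the fixed point beats the quantile initialization
    init <- quantile(x, (seq_len(ng) - 0.5) / ng, type = 8, names = FALSE)
    b0 <- (init[-1] + init[-ng]) / 2
    lv0 <- findInterval(x, b0) + 1L
    expect_lte(q$mse, mean((x - init[lv0])^2) + 1e-12)
  }
})

test_that("histogram features match hand-derived moments", {
  # two levels, equal counts: var .25, skew 0, kurtosis 1
  lv <- array(rep(c(1L, 2L), 8), c(4, 2, 2))
  h <- histogram_features(lv)
  expect_equal(unname(h), c(0.25, 0, 1))
  # symmetric histogram -> zero skewness
  lv2 <- array(rep(c(1L, 2L, 2L, 3L), 4), c(4, 2, 2))
  expect_equal(unname(histogram_features(lv2)["hist_skewness"]), 0,
               tolerance = 1e-12)
  # single level degenerates to zeros
  expect_equal(unname(histogram_features(array(3L, c(2, 2, 2)))), c(0, 0, 0))
})

test_that("GLCM of a constant ROI is the single-cell matrix", {
  lv <- array(2L, c(3, 3, 3))
  g <- compute_glcm(lv, 4)
  f <- g$features
  expect_equal(unname(f["glcm_energy"]), 1)
  expect_equal(unname(f["glcm_contrast"]), 0)
  expect_equal(unname(f["glcm_entropy"]), 0)
  expect_equal(unname(f["glcm_homogeneity"]), 1)
  expect_equal(sum(g$matrix > 0), 1)
})

test_that("GLCM matches exhaustive pair enumeration on the 2x2x1 example", {
  lv <- array(c(1L, 3L, 2L, 4L), c(2, 2, 1))   # [[1,2],[3,4]] in x-y
  got <- compute_glcm(lv, 4)$features
  want <- oracle_glcm_features(lv, 4)
  expect_close(got, want, tol = 1e-12)
})

test_that("alternating two-level line: maximal contrast, correlation -1", {
  line <- alternating_line(8)
  f <- compute_glcm(line, 2)$features
  expect_equal(unname(f["glcm_contrast"]), 1)     # every pair differs by 1
  expect_equal(unname(f["glcm_correlation"]), -1, tolerance = 1e-9)
  # contrast is maximal among random two-level images of the same size
  withr::with_seed(55, {
    for (i in 1:20) {
      rnd <- array(sample(1:2, 8, TRUE), c(8, 1, 1))
      expect_lte(compute_glcm(rnd, 2)$features["glcm_contrast"],
                 f["glcm_contrast"])
    }
  })
})

test_that("single-voxel ROI degenerates to energy 1, others 0", {
  lv <- array(0L, c(3, 3, 3)); lv[2, 2, 2] <- 1L
  f <- compute_glcm(lv, 4)$features
  expect_equal(unname(f["glcm_energy"]), 1)
  expect_true(all(f[setdiff(names(f), "glcm_energy")] == 0))
})

test_that("GLRLM hand count: constant 4x1x1 line merged over 13 directions", {
  lv <- array(2L, c(4, 1, 1))
  g <- compute_glrlm(lv, 3)
  # one run of length 4 along x; 4 runs of length 1 in each of the other 12
  expect_equal(g$matrix[2, 4], 1)
  expect_equal(g$matrix[2, 1], 48)
  expect_equal(sum(g$matrix), 49)
  expect_equal(unname(g$features["glrlm_lre"]),
               (48 * 1 + 1 * 16) / 49)
  # run-voxel bookkeeping: runs x lengths = 13 * voxels
  expect_equal(sum(g$matrix %*% seq_len(ncol(g$matrix))), 13 * 4)
})

test_that("alternating line has only unit runs: SRE = LRE = RP = 1", {
  f <- compute_glrlm(alternating_line(9), 2)$features
  expect_equal(unname(f["glrlm_sre"]), 1)
  expect_equal(unname(f["glrlm_lre"]), 1)
  expect_equal(unname(f["glrlm_rp"]), 1)
})

test_that("GLSZM of a constant ROI is one zone: ZP = 1/V", {
  lv <- array(3L, c(3, 3, 2))
  f <- compute_glszm(lv, 4)$features
  expect_equal(unname(f["glszm_zp"]), 1 / 18)
  expect_equal(unname(f["glszm_lze"]), 18^2)
})

test_that("GLSZM zone bookkeeping: zone sizes sum to the voxel count", {
  for (seed in 1:5) {
    lv <- random_levels(c(5, 4, 3), ng = 3, seed = seed)
    M <- compute_glszm(lv, 3)$matrix
    expect_equal(sum(M %*% seq_len(ncol(M))), sum(lv > 0))
  }
})

test_that("NGTDM constant ROI hits the guarded coarseness ceiling", {
  f <- compute_ngtdm(array(2L, c(3, 3, 3)), 4)$features
  expect_equal(unname(f["ngtdm_coarseness"]), 1e6)
  expect_equal(unname(f["ngtdm_contrast"]), 0)
})

test_that("all families match the brute-force oracles on random ROIs", {
  for (seed in 1:12) {
    ng <- c(3, 4, 6)[seed %% 3 + 1]
    lv <- random_levels(c(4, 4, 4), ng = ng, p_roi = 0.8, seed = 60 + seed)
    got <- roi_feature_vector(lv, ng)
    want <- oracle_feature_vector(lv, ng)
    expect_identical(names(got), names(want))
    expect_close(got, want, tol = 1e-10)
  }
})

test_that("features are invariant to translating the ROI inside the grid", {
  lv <- random_levels(c(4, 4, 4), ng = 4, seed = 71)
  pad <- array(0L, c(8, 8, 8))
  pad[2:5, 3:6, 4:7] <- lv
  expect_equal(roi_feature_vector(pad, 4), roi_feature_vector(lv, 4))
})

test_that("quantized features are invariant to affine intensity rescaling", {
  withr::with_seed(73, {
    vol <- pet_volume(array(rnorm(10 * 10 * 10, 5), c(10, 10, 10)))
  })
  vox <- which(array(seq_len(1000), c(10, 10, 10)) %% 3 != 0)[1:200]
  q1 <- quantized_roi_array(vol, vox, n_levels = 8)
  vol2 <- pet_volume(2.7 * vol$data + 13)
  q2 <- quantized_roi_array(vol2, vox, n_levels = 8)
  expect_identical(q1$levels, q2$levels)
  expect_equal(roi_feature_vector(q1$levels, 8),
               roi_feature_vector(q2$levels, 8))
})

test_that("extract_features emits 43 named features per ROI", {
  spec <- tiny_spec(n_per_group = 4, mean_shift = 2, seed = 77)
  cohort <- generate_cohort(spec)
  man <- cohort$manifest
  rois <- define_rois(man$volume[man$group == "AD"],
                      man$volume[man$group == "NC"],
                      cohort$atlas, min_cluster = 60,
                      exclude = spec$reference_region,
                      fallback = "atlas") |> suppressWarnings()
  fv <- extract_features(man$volume[[1]], rois)
  expect_equal(length(fv), 43 * nrow(rois))
  expect_true(all(grepl("^[^_]+.*__(hist|glcm|glrlm|glszm|ngtdm)_", names(fv))))
  per_roi <- table(sub("__.*$", "", names(fv)))
  expect_true(all(per_roi == 43))
  families <- table(sub("_.*$", "", sub("^.*__", "", names(fv)))) / nrow(rois)
  expect_equal(as.vector(families[c("hist", "glcm", "glrlm", "glszm",
                                    "ngtdm")]),
               c(3, 9, 13, 13, 5))
})

test_that("feature_table binds subjects x features with metadata", {
  spec <- tiny_spec(n_per_group = 3, mean_shift = 2, seed = 79)
  cohort <- generate_cohort(spec)
  man <- cohort$manifest
  rois <- suppressWarnings(
    define_rois(man$volume[man$group == "AD"],
                man$volume[man$group == "NC"],
                cohort$atlas, min_cluster = 60,
                exclude = spec$reference_region))
  tab <- feature_table(man, rois)
  expect_s3_class(tab, "tbl_df")
  expect_equal(nrow(tab), nrow(man))
  expect_true(all(c("id", "group", "age", "sex", "mmse") %in% names(tab)))
  expect_equal(length(feature_columns(tab)), 43 * nrow(rois))
})

test_that("extract_features warns and yields NA on undersized ROIs", {
  vol <- pet_volume(array(1, c(6, 6, 6)) + array(runif(216), c(6, 6, 6)))
  rois <- tibble::tibble(region_id = 1L, region_name = "tiny",
                         n_voxels = 8L, peak_t = 1,
                         voxels = list(1:8))
  attr(rois, "grid_dim") <- c(6L, 6L, 6L)
  attr(rois, "spacing") <- c(1, 1, 1)
  class(rois) <- c("roi_set", class(rois))
  expect_warning(fv <- extract_features(vol, rois, min_voxels = 27), "below")
  expect_true(all(is.na(fv)))
})
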