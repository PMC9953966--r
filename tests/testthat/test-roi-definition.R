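# roi_definition: voxelwise t-test, FDR cutoff, cluster filter, atlas mapping

make_vols <- function(values_per_subject, dim3 = c(3, 3, 3)) {
  lapply(values_per_subject, function(v) pet_volume(array(v, dim3)))
}

test_that("voxelwise_ttest matches the hand-computed pooled t", {
  # per-voxel samples a = {1,2,3}, b = {4,5,6}: t = -3.674, p = 0.0214
  a <- make_vols(list(1, 2, 3))
  b <- make_vols(list(4, 5, 6))
  mask <- pet_mask(array(TRUE, c(3, 3, 3)))
  sm <- voxelwise_ttest(a, b, mask)
  expect_equal(sm$t[1, 1, 1], -3.674235, tolerance = 1e-6)
  expect_equal(sm$p[1, 1, 1], 0.02131164, tolerance = 1e-6)
  expect_equal(sm$df, 4)
  # agrees with stats::t.test at every voxel
  ref <- t.test(c(1, 2, 3), c(4, 5, 6), var.equal = TRUE)
  expect_equal(sm$p[2, 2, 2], ref$p.value, tolerance = 1e-12)
})

test_that("voxelwise_ttest maps zero-variance voxels to t = 0, p = 1", {
  a <- make_vols(list(2, 2, 2))
  b <- make_vols(list(2, 2, 2))
  mask <- pet_mask(array(TRUE, c(3, 3, 3)))
  sm <- voxelwise_ttest(a, b, mask)
  expect_true(all(sm$t == 0))
  expect_true(all(sm$p == 1))
})

test_that("voxelwise_ttest agrees with per-voxel t.test on random data", {
  withr::with_seed(41, {
    a <- make_vols(lapply(1:5, function(i) array(rnorm(27), c(3, 3, 3))))
    b <- make_vols(lapply(1:6, function(i) array(rnorm(27), c(3, 3, 3))))
  })
  mask <- pet_mask(array(TRUE, c(3, 3, 3)))
  sm <- voxelwise_ttest(a, b, mask)
  for (v in c(1, 14, 27)) {
    xa <- vapply(a, function(x) x$data[v], numeric(1))
    xb <- vapply(b, function(x) x$data[v], numeric(1))
    ref <- t.test(xa, xb, var.equal = TRUE)
    expect_equal(sm$t[v], unname(ref$statistic), tolerance = 1e-10)
    expect_equal(sm$p[v], ref$p.value, tolerance = 1e-10)
  }
})

test_that("fdr_cutoff reproduces the Benjamini-Hochberg threshold", {
  # hand example, m = 5, q = 0.05: sorted p (.001,.008,.039,.041,.09);
  # largest k with p(k) <= 0.05 k/5: k=2 (.008 <= .02); k=3 fails
  # (.039 > .03); k=4 passes (.041 > .04? no, fails); cutoff = .008
  p <- c(0.041, 0.008, 0.09, 0.001, 0.039)
  expect_equal(fdr_cutoff(p, q = 0.05), 0.008)
  # no rejections
  expect_true(is.na(fdr_cutoff(c(0.5, 0.9, 0.7), q = 0.05)))
  # everything rejected
  expect_equal(fdr_cutoff(c(1e-5, 2e-5), q = 0.05), 2e-5)
})

test_that("fdr_cutoff equals the O(m^2) oracle on random draws", {
  withr::with_seed(43, {
    for (i in 1:50) {
      m <- sample(3:60, 1)
      p <- runif(m)^sample(1:3, 1)
      q <- runif(1, 0.005, 0.2)
      got <- fdr_cutoff(p, q)
      want <- oracle_bh_cutoff(p, q)
      if (is.na(want)) expect_true(is.na(got)) else expect_equal(got, want)
    }
  })
})

test_that("cluster_filter keeps strictly larger than min_voxels only", {
  sig <- array(FALSE, c(12, 12, 12))
  sig[1:5, 1:5, 1:4] <- TRUE            # 100 voxels
  sig[9:12, 9:12, 9:12] <- TRUE         # 64 voxels
  m <- pet_mask(sig)
  out <- cluster_filter(m, min_voxels = 64, connectivity = 18)$data
  expect_true(all(out[1:5, 1:5, 1:4]))
  expect_false(any(out[9:12, 9:12, 9:12]))   # exactly 64 -> dropped (strict)
  out2 <- cluster_filter(m, min_voxels = 63, connectivity = 18)$data
  expect_true(all(out2[9:12, 9:12, 9:12]))
})

test_that("18- and 26-connectivity differ on a corner-touching pair", {
  sig <- array(FALSE, c(4, 4, 4))
  sig[1:2, 1:2, 1:2] <- TRUE            # 8 voxels
  sig[3, 3, 3] <- TRUE                  # touches only at a corner
  # corner neighbor joins under 26- but not 18-connectivity
  out18 <- cluster_filter(pet_mask(sig), min_voxels = 8,
                          connectivity = 18)$data
  out26 <- cluster_filter(pet_mask(sig), min_voxels = 8,
                          connectivity = 26)$data
  expect_false(any(out18))              # components of size 8 and 1
  expect_true(all(out26[sig]))          # one component of size 9
})

test_that("connected-component labeling matches the oracle on random masks", {
  withr::with_seed(47, {
    for (conn in c(6L, 18L, 26L)) {
      g <- array(as.integer(runif(9 * 9 * 9) < 0.4), c(9, 9, 9))
      got <- tauradiomics:::label_components_cpp(g, conn, FALSE)
      want <- oracle_components(g, conn, same_value = FALSE)
      # same partition: component sizes agree and co-membership agrees
      expect_equal(sort(tabulate(got[got > 0])),
                   sort(tabulate(want[want > 0])))
      expect_equal(length(unique(paste(got, want)[g > 0])),
                   max(want))
    }
  })
})

test_that("map_to_atlas honors the minimum-overlap rule", {
  labs <- array(0L, c(10, 10, 10))
  labs[1:5, 1:5, 1:4] <- 1L     # 100 voxels
  labs[6:10, 1:5, 1:4] <- 2L    # 100 voxels
  lm <- label_map(labs)
  surv <- array(FALSE, c(10, 10, 10))
  surv[labs == 1L] <- TRUE                        # full region 1
  surv[6:10, 1:4, 1:3] <- TRUE                    # 60 voxels of region 2
  surviving <- pet_mask(surv)
  stat <- list(t = array(1, c(10, 10, 10)), p = array(0, c(10, 10, 10)))
  rois <- map_to_atlas(surviving, lm, min_overlap = 64, stat = stat)
  expect_equal(rois$region_id, 1L)
  expect_equal(rois$n_voxels, 100L)
  rois2 <- map_to_atlas(surviving, lm, min_overlap = 60, stat = stat)
  expect_setequal(rois2$region_id, c(1L, 2L))
})

test_that("define_rois recovers injected regions without false positives", {
  spec <- tiny_spec(n_per_group = 40, mean_shift = 2, seed = 29)
  cohort <- generate_cohort(spec)
  man <- cohort$manifest
  is_a <- man$group == spec$groups[1]
  rois <- define_rois(man$volume[is_a], man$volume[!is_a], cohort$atlas,
                      min_cluster = 100, exclude = spec$reference_region)
  expect_setequal(rois$region_id, spec$affected_regions)
})

test_that("define_rois is invariant to subject order within groups", {
  spec <- tiny_spec(n_per_group = 20, mean_shift = 2, seed = 31)
  cohort <- generate_cohort(spec)
  man <- cohort$manifest
  a <- man$volume[man$group == "AD"]
  b <- man$volume[man$group == "NC"]
  r1 <- define_rois(a, b, cohort$atlas, min_cluster = 60,
                    exclude = spec$reference_region)
  r2 <- define_rois(rev(a), b[c(11:20, 1:10)], cohort$atlas, min_cluster = 60,
                    exclude = spec$reference_region)
  expect_identical(r1$region_id, r2$region_id)
  expect_identical(r1$voxels, r2$voxels)
})

test_that("define_rois on a null cohort falls back to the atlas with a warning", {
  spec <- tiny_spec(n_per_group = 8, mean_shift = 0, texture_effect = 0,
                    seed = 37)
  cohort <- generate_cohort(spec)
  man <- cohort$manifest
  is_a <- man$group == spec$groups[1]
  expect_warning(
    rois <- define_rois(man$volume[is_a], man$volume[!is_a], cohort$atlas,
                        exclude = spec$reference_region),
    "fall"
  )
  expect_setequal(rois$region_id, setdiff(1:spec$n_regions,
                                          spec$reference_region))
  r0 <- suppressWarnings(
    define_rois(man$volume[is_a], man$volume[!is_a], cohort$atlas,
                exclude = spec$reference_region, fallback = "none"))
  expect_equal(nrow(r0), 0)
})

test_that("write_roi_set produces NIfTI, TSV and provenance artifacts", {
  spec <- tiny_spec(n_per_group = 20, mean_shift = 2, seed = 31)
  cohort <- generate_cohort(spec)
  man <- cohort$manifest
  is_a <- man$group == spec$groups[1]
  rois <- define_rois(man$volume[is_a], man$volume[!is_a], cohort$atlas,
                      min_cluster = 60, exclude = spec$reference_region)
  stem <- file.path(withr::local_tempdir(), "rois.nii.gz")
  write_roi_set(rois, stem)
  expect_true(file.exists(stem))
  expect_true(file.exists(sub("\\.nii\\.gz$", "_rois.tsv", stem)))
  expect_true(file.exists(sub("\\.nii\\.gz$", "_provenance.json", stem)))
})
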