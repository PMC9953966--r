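# classification: splits, covariate adjustment, SVM harness, metrics, reports

sim_table <- function(n_per_group = 30, d = 0, p = 3, seed = 1,
                      groups = c("AD", "NC")) {
  withr::with_seed(seed, {
    n <- 2 * n_per_group
    X <- matrix(rnorm(n * p), n, p)
    X[seq_len(n_per_group), 1] <- X[seq_len(n_per_group), 1] + d
    colnames(X) <- paste0("roi", seq_len(p), "__f")
    tibble::tibble(
      id = sprintf("s%03d", seq_len(n)),
      group = rep(groups, each = n_per_group),
      age = round(rnorm(n, 72, 6)),
      sex = sample(c("M", "F"), n, TRUE),
      mmse = round(runif(n, 20, 30))
    ) |> dplyr::bind_cols(tibble::as_tibble(X))
  })
}

test_that("make_split stratifies 0.7/0.3 and sends externals to test", {
  tbl <- sim_table(20)
  tbl$cohort <- "discovery"
  tbl$cohort[c(1, 2, 39, 40)] <- "external"
  sp <- make_split(tbl, task = c("AD", "NC"), train_frac = 0.7, seed = 3)
  expect_setequal(sp$role, c("train", "validation", "test"))
  expect_true(all(sp$role[match(tbl$id[tbl$cohort == "external"], sp$id)] ==
                    "test"))
  disc <- sp[sp$id %in% tbl$id[tbl$cohort == "discovery"], ]
  for (g in c("AD", "NC")) {
    ids <- tbl$id[tbl$group == g & tbl$cohort == "discovery"]
    expect_equal(sum(disc$role == "train" & disc$label == g),
                 round(0.7 * length(ids)))
  }
  # deterministic in the seed
  sp2 <- make_split(tbl, task = c("AD", "NC"), train_frac = 0.7, seed = 3)
  expect_identical(sp, sp2)
  expect_false(identical(
    sp$role, make_split(tbl, task = c("AD", "NC"), seed = 4)$role))
})

test_that("make_split refuses tiny discovery cohorts", {
  tbl <- sim_table(2)
  expect_error(make_split(tbl, task = c("AD", "NC"), seed = 1), "subject")
})

test_that("covariate residualization removes a pure age effect", {
  withr::with_seed(103, {
    age <- round(rnorm(50, 72, 6))
    x <- cbind(f1 = 3 * age, f2 = rnorm(50))
    cov <- tibble::tibble(age = age, sex = sample(c("M", "F"), 50, TRUE))
  })
  fit <- tauradiomics:::fit_covariate_adjustment(x, cov)
  res <- tauradiomics:::apply_covariate_adjustment(fit, x, cov)
  expect_lt(max(abs(res[, "f1"])), 1e-8)
  # holdout rows use the training fit, not their own regression
  cov2 <- tibble::tibble(age = c(60, 90), sex = c("M", "F"))
  x2 <- cbind(f1 = c(100, 500), f2 = c(0, 0))
  res2 <- tauradiomics:::apply_covariate_adjustment(fit, x2, cov2)
  expect_equal(unname(res2[, "f1"]), c(100 - 3 * 60, 500 - 3 * 90),
               tolerance = 1e-6)
})

test_that("scaler is fit on training rows and applied elsewhere", {
  withr::with_seed(105, x <- matrix(rnorm(40, 5, 3), 20, 2))
  sc <- tauradiomics:::fit_scaler(x)
  z <- tauradiomics:::apply_scaler(sc, x)
  expect_equal(colMeans(z), c(0, 0), tolerance = 1e-12)
  expect_equal(apply(z, 2, sd), c(1, 1), tolerance = 1e-12)
})

test_that("binary_metrics matches a hand-counted confusion table", {
  scores <- c(2, 1, -1, 0.5, -2, -0.5)
  labels <- c("AD", "AD", "AD", "NC", "NC", "NC")
  m <- tauradiomics:::binary_metrics(scores, labels, positive = "AD")
  # predicted positive: scores > 0 -> AD,AD,NC predicted for first three
  expect_equal(m[["accuracy"]], 4 / 6)
  expect_equal(m[["sensitivity"]], 2 / 3)
  expect_equal(m[["specificity"]], 2 / 3)
})

test_that("roc_auc equals the Mann-Whitney statistic (pROC oracle)", {
  withr::with_seed(107, {
    scores <- c(rnorm(30, 1), rnorm(40))
    labels <- rep(c("AD", "NC"), c(30, 40))
  })
  got <- tauradiomics:::roc_auc(scores, labels, positive = "AD")
  want <- as.numeric(pROC::auc(pROC::roc(labels, scores, levels = c("NC", "AD"),
                                         direction = "<", quiet = TRUE)))
  expect_equal(got, want, tolerance = 1e-12)
  # ties handled by midranks
  expect_equal(tauradiomics:::roc_auc(c(1, 1), c("AD", "NC"), "AD"), 0.5)
})

test_that("repeated CV on separable data is perfect, with schedule determinism", {
  tbl <- sim_table(20, d = 8, seed = 109)
  sp <- make_split(tbl, task = c("AD", "NC"), seed = 7)
  rep1 <- classify_features(tbl, sp, n_reps = 5, seed = 11,
                            covariate_mode = "none")
  rep2 <- classify_features(tbl, sp, n_reps = 5, seed = 11,
                            covariate_mode = "none")
  expect_equal(rep1$summary, rep2$summary)
  s <- rep1$summary
  expect_equal(s$accuracy_mean[s$dataset == "cv"], 1)
  expect_equal(s$accuracy_mean[s$dataset == "validation"], 1)
  expect_equal(s$auc_median[s$dataset == "validation"], 1)
  # residualizing randomly correlated covariates may cost a little accuracy
  # but must stay near-perfect on clearly separable data
  rr <- classify_features(tbl, sp, n_reps = 5, seed = 11)
  expect_gt(rr$summary$accuracy_mean[rr$summary$dataset == "cv"], 0.85)
})

test_that("label-permuted data stays at chance", {
  tbl <- sim_table(30, d = 3, seed = 111)
  withr::with_seed(13, tbl$group <- sample(tbl$group))
  sp <- make_split(tbl, task = c("AD", "NC"), seed = 7)
  rep <- classify_features(tbl, sp, n_reps = 20, seed = 11)
  s <- rep$summary
  # the unbiased check is on the holdout; CV metrics on permuted labels
  # carry the usual pessimistic small-sample bias
  expect_gt(s$auc_median[s$dataset == "validation"], 0.25)
  expect_lt(s$auc_median[s$dataset == "validation"], 0.75)
  expect_gt(s$accuracy_mean[s$dataset == "validation"], 0.25)
  expect_lt(s$accuracy_mean[s$dataset == "validation"], 0.75)
})

test_that("covariate_mode append widens the design instead", {
  tbl <- sim_table(15, d = 2, seed = 113)
  sp <- make_split(tbl, task = c("AD", "NC"), seed = 7)
  r <- classify_features(tbl, sp, n_reps = 3, seed = 1,
                         covariate_mode = "append")
  expect_s3_class(r, "eval_report")
  r2 <- classify_features(tbl, sp, n_reps = 3, seed = 1,
                          covariate_mode = "none")
  expect_s3_class(r2, "eval_report")
})

test_that("single-class holdouts yield NA rates, not errors", {
  tbl <- sim_table(10, d = 6, seed = 115)
  m <- tauradiomics:::binary_metrics(c(1, 2), c("AD", "AD"), positive = "AD")
  expect_true(is.na(m[["specificity"]]))
  expect_equal(m[["sensitivity"]], 1)
})

test_that("eval_report exposes tidy, glance, report_table and autoplot", {
  tbl <- sim_table(15, d = 3, seed = 117)
  sp <- make_split(tbl, task = c("AD", "NC"), seed = 7)
  r <- classify_features(tbl, sp, n_reps = 4, seed = 1,
                         model_name = "radiomics")
  td <- tidy(r)
  expect_true(all(c("model", "dataset", "accuracy", "auc") %in% names(td)))
  expect_equal(sum(td$dataset == "cv"), 4)
  gl <- glance(r)
  expect_equal(nrow(gl), 1)
  expect_true("validation_accuracy_mean" %in% names(gl))
  rt <- report_table(r)
  expect_true(all(c("model", "dataset", "accuracy_mean") %in% names(rt)))
  p <- ggplot2::autoplot(r)
  expect_s3_class(p, "ggplot")
  rp <- roc_points(r, "validation")
  expect_true(all(diff(rp$fpr[rp$rep == 1]) >= 0))
  expect_true(all(rp$tpr >= 0 & rp$tpr <= 1))
})

test_that("write_eval_report emits JSON and per-repetition CSV", {
  tbl <- sim_table(15, d = 3, seed = 119)
  sp <- make_split(tbl, task = c("AD", "NC"), seed = 7)
  r <- classify_features(tbl, sp, n_reps = 3, seed = 1)
  stem <- file.path(withr::local_tempdir(), "report")
  write_eval_report(r, stem)
  j <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  expect_equal(j$positive, "AD")
  reps <- readr::read_csv(paste0(stem, "_reps.csv"), show_col_types = FALSE)
  expect_true(all(c("dataset", "accuracy", "auc") %in% names(reps)))
})
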