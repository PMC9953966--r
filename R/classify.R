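#' Stratified train/validation split with external-cohort isolation
#'
#' Subjects of the two task groups from the discovery cohort are split into
#' training and validation sets at `train_frac` / `1 - train_frac`,
#' stratified by group (the ratio is preserved within one subject). Subjects
#' with `cohort == "external"` are never assigned to train or validation:
#' they form the independent test set.
#'
#' @param manifest Manifest tibble (`id`, group column, optional `cohort`).
#' @param task Character of length 2: the group labels to classify; the
#'   first is the patient (positive) class.
#' @param train_frac Training fraction in (0, 1), default 0.7.
#' @param seed Integer seed.
#' @param group_col Label column (default `"group"`; use `"tau_status"` or
#'   `"apoe_status"` for subgroup tasks).
#' @return A `split_plan` tibble: `id`, `label`, `role` in
#'   train/validation/test, with the task recorded in attributes.
#' @export
make_split <- function(manifest, task, train_frac = 0.7, seed = 1,
                       group_col = "group") {
  stopifnot(length(task) == 2, train_frac > 0, train_frac < 1)
  lab <- manifest[[group_col]]
  keep <- !is.na(lab) & lab %in% task
  m <- manifest[keep, ]
  lab <- lab[keep]
  cohort <- if ("cohort" %in% names(m)) m$cohort else rep("discovery", nrow(m))
  dis <- cohort != "external"
  for (g in task) {
    if (sum(lab == g & dis) < 5) {
      stop("group '", g, "' has fewer than 5 discovery subjects; ",
           "cross-validation is infeasible", call. = FALSE)
    }
  }
  role <- rep("test", nrow(m))
  withr::with_seed(as.integer(seed), {
    for (g in task) {
      idx <- which(lab == g & dis)
      n_tr <- round(train_frac * length(idx))
      tr <- sample(idx, n_tr)
      role[tr] <- "train"
      role[setdiff(idx, tr)] <- "validation"
    }
  })
  out <- tibble::tibble(id = m$id, label = lab, role = role)
  structure(out, class = c("split_plan", class(out)),
            task = task, positive = task[1], train_frac = train_frac,
            seed = as.integer(seed), group_col = group_col)
}

#' Train-fit linear covariate adjustment
#'
#' Per feature, ordinary least squares against `[1, age, sex]` fitted on the
#' training rows; residuals are returned for the training rows and the same
#' fitted coefficients are applied to held-out rows (never refitted), which
#' keeps the adjustment leakage-free. Rank-deficient designs (e.g. a single
#' sex in training) drop the offending covariate with a warning.
#'
#' @param train_x Numeric matrix (training subjects x features).
#' @param train_cov Data frame with `age` (numeric) and `sex` (M/F) for the
#'   training rows.
#' @param apply_x,apply_cov Optional held-out rows to residualize with the
#'   training coefficients.
#' @return List with `train` (residualized training matrix), `applied`
#'   (residualized held-out matrix or NULL) and `fit` (the coefficients).
#' @export
adjust_covariates <- function(train_x, train_cov, apply_x = NULL,
                              apply_cov = NULL) {
  fit <- fit_covariate_adjustment(train_x, train_cov)
  list(
    train = apply_covariate_adjustment(fit, train_x, train_cov),
    applied = if (!is.null(apply_x)) {
      apply_covariate_adjustment(fit, apply_x, apply_cov)
    },
    fit = fit
  )
}

covariate_design <- function(cov) {
  D <- cbind(intercept = rep(1, nrow(cov)))
  if ("age" %in% names(cov)) D <- cbind(D, age = as.numeric(cov$age))
  if ("sex" %in% names(cov)) D <- cbind(D, sex = as.numeric(cov$sex == "M"))
  D
}

fit_covariate_adjustment <- function(train_x, train_cov) {
  D <- covariate_design(train_cov)
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    drop_cols <- colnames(D)[qrD$pivot[seq(qrD$rank + 1, ncol(D))]]
    warning("rank-deficient covariate design; dropping: ",
            paste(drop_cols, collapse = ", "), call. = FALSE)
    D <- D[, setdiff(colnames(D), drop_cols), drop = FALSE]
    qrD <- qr(D)
  }
  beta <- qr.coef(qrD, as.matrix(train_x))
  beta[is.na(beta)] <- 0
  structure(list(beta = beta, columns = colnames(D)),
            class = "covariate_fit")
}

apply_covariate_adjustment <- function(fit, x, cov) {
  D <- covariate_design(cov)[, fit$columns, drop = FALSE]
  as.matrix(x) - D %*% fit$beta
}

fit_scaler <- function(x) {
  mu <- colMeans(x)
  sdv <- apply(x, 2, sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  structure(list(center = mu, scale = sdv), class = "feature_scaler")
}

apply_scaler <- function(scaler, x) {
  sweep(sweep(as.matrix(x), 2, scaler$center), 2, scaler$scale, "/")
}

stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (g in unique(y)) {
    idx <- which(y == g)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep(seq_len(k), length.out = length(idx))[
      sample.int(length(idx))]
  }
  fold
}

balanced_weights <- function(y) {
  tab <- table(y)
  w <- length(y) / (length(tab) * tab)
  setNames(as.numeric(w), names(tab))
}

# Fit a linear SVM; returns the e1071 model plus the level order used for
# orienting decision values (positive class scores > 0).
fit_linear_svm <- function(x, y, positive, cost = 1) {
  y <- factor(y, levels = c(positive, setdiff(unique(as.character(y)),
                                              positive)))
  m <- e1071::svm(x = x, y = y, kernel = "linear", cost = cost,
                  scale = FALSE, class.weights = balanced_weights(y))
  m
}

svm_scores <- function(model, x, positive) {
  pr <- predict(model, x, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  first <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]][1]
  s <- as.numeric(dv[, 1])
  if (first != positive) s <- -s
  s
}

binary_metrics <- function(scores, labels, positive) {
  pred_pos <- scores > 0
  is_pos <- labels == positive
  acc <- mean(pred_pos == is_pos)
  sens <- if (any(is_pos)) mean(pred_pos[is_pos]) else NA_real_
  spec <- if (any(!is_pos)) mean(!pred_pos[!is_pos]) else NA_real_
  auc <- if (any(is_pos) && any(!is_pos)) {
    roc_auc(scores, labels, positive)
  } else NA_real_
  c(accuracy = acc, sensitivity = sens, specificity = spec, auc = auc)
}

#' Repeated stratified k-fold cross-validation of a linear SVM
#'
#' For each repetition a fresh stratified fold assignment is drawn; a linear
#' SVM (C = `cost`, balanced class weights) is fitted on k-1 folds and
#' evaluated on the remaining fold; the repetition's metrics are computed on
#' the pooled out-of-fold predictions. The fold models are retained so that
#' held-out sets can be scored per repetition (see [evaluate_holdout()]).
#'
#' @param x Numeric matrix (subjects x features), already adjusted/scaled.
#' @param y Label vector.
#' @param positive Positive (patient) class label.
#' @param k_folds Folds per repetition (default 5).
#' @param n_reps Repetitions (default 100).
#' @param cost SVM cost parameter (default 1).
#' @param seed Integer seed; the whole schedule is deterministic given it.
#' @return A `repeated_cv_fit`: list with `per_rep` metrics tibble and the
#'   per-repetition fold models.
#' @export
repeated_cv <- function(x, y, positive = NULL, k_folds = 5, n_reps = 100,
                        cost = 1, seed = 1) {
  x <- as.matrix(x)
  y <- as.character(y)
  if (is.null(positive)) positive <- y[1]
  if (length(unique(y)) != 2) stop("need exactly two classes", call. = FALSE)
  min_class <- min(table(y))
  if (min_class < k_folds) {
    k_folds <- max(2L, min_class)
  }
  reps <- withr::with_seed(as.integer(seed), {
    purrr::map(seq_len(n_reps), function(rep_i) {
      fold <- stratified_folds(y, k_folds)
      scores <- rep(NA_real_, length(y))
      models <- vector("list", k_folds)
      for (k in seq_len(k_folds)) {
        tr <- fold != k
        m <- fit_linear_svm(x[tr, , drop = FALSE], y[tr], positive, cost)
        scores[!tr] <- svm_scores(m, x[!tr, , drop = FALSE], positive)
        models[[k]] <- m
      }
      list(metrics = binary_metrics(scores, y, positive), models = models)
    })
  })
  per_rep <- dplyr::bind_rows(purrr::imap(reps, function(r, i) {
    tibble::as_tibble_row(c(rep = i, r$metrics))
  }))
  structure(list(per_rep = per_rep,
                 models = purrr::map(reps, "models"),
                 positive = positive, k_folds = k_folds,
                 n_reps = n_reps, cost = cost, seed = as.integer(seed)),
            class = "repeated_cv_fit")
}

#' Evaluate a repeated-CV fit on a held-out set
#'
#' Each repetition's fold models score the held-out subjects; their decision
#' values are averaged into one score per subject and repetition, from which
#' accuracy, sensitivity (positive = patient class), specificity and AUC are
#' computed. The mean and SD over repetitions mirror how validation/test
#' results are reported. Holdout sets containing a single class yield NA for
#' the undefined rate with a warning.
#'
#' @param fit A `repeated_cv_fit` from [repeated_cv()].
#' @param x Held-out feature matrix (same columns and adjustment as training).
#' @param y Held-out labels.
#' @return A tibble of per-repetition metrics, with the per-subject scores of
#'   each repetition in attribute `"scores"`.
#' @export
evaluate_holdout <- function(fit, x, y) {
  stopifnot(inherits(fit, "repeated_cv_fit"))
  x <- as.matrix(x)
  y <- as.character(y)
  if (length(unique(y)) < 2) {
    warning("holdout set contains a single class; sensitivity or ",
            "specificity undefined", call. = FALSE)
  }
  score_mat <- vapply(fit$models, function(models) {
    rowMeans(vapply(models, function(m) svm_scores(m, x, fit$positive),
                    numeric(nrow(x))))
  }, numeric(nrow(x)))
  per_rep <- dplyr::bind_rows(purrr::map(seq_along(fit$models), function(i) {
    tibble::as_tibble_row(c(rep = i,
                            binary_metrics(score_mat[, i], y, fit$positive)))
  }))
  attr(per_rep, "scores") <- score_mat
  attr(per_rep, "labels") <- y
  per_rep
}

#' Rank-based AUC
#'
#' Area under the ROC curve by the Mann-Whitney rank statistic with midranks
#' for ties: the probability that a random positive outranks a random
#' negative.
#'
#' @param scores Numeric decision values (higher = more positive).
#' @param labels Class labels.
#' @param positive Positive class label.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels, positive) {
  is_pos <- labels == positive
  n1 <- sum(is_pos); n0 <- sum(!is_pos)
  if (n1 == 0 || n0 == 0) stop("need both classes for AUC", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[is_pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Median and interquartile range of per-repetition AUCs
#'
#' @param aucs Numeric vector of per-repetition AUCs.
#' @return Tibble with `auc_median`, `auc_q25`, `auc_q75`.
#' @export
roc_summary <- function(aucs) {
  aucs <- aucs[!is.na(aucs)]
  if (length(aucs) == 0) stop("no AUCs supplied", call. = FALSE)
  qs <- quantile(aucs, c(0.25, 0.5, 0.75), names = FALSE)
  tibble::tibble(auc_median = qs[2], auc_q25 = qs[1], auc_q75 = qs[3])
}

#' Classify a feature table under the full evaluation harness
#'
#' The single code path used by the radiomics, SUVR and clinical models:
#' restrict to the split's subjects, residualize age/sex covariates with
#' training-fit coefficients (configurable), z-score with training-fit
#' scaling, run repeated stratified k-fold CV of a linear SVM on the training
#' set, and score the validation (and external test, if present) subjects
#' with every repetition's fold models.
#'
#' @param table Feature table (radiomics, SUVR or clinical schema).
#' @param split A `split_plan` from [make_split()].
#' @param features Feature columns (default: all `__` columns).
#' @param covariates Covariate columns used for adjustment (default
#'   `c("age", "sex")`; empty vector or `covariate_mode = "none"` disables).
#' @param covariate_mode `"residualize"` (default), `"append"` (covariates
#'   added as features) or `"none"`.
#' @param k_folds,n_reps,cost See [repeated_cv()].
#' @param seed Integer seed for the CV schedule.
#' @param model_name Label stored in the report (e.g. `"radiomics"`).
#' @return An `eval_report`; see [tidy.eval_report()] and
#'   [glance.eval_report()].
#' @export
classify_features <- function(table, split, features = NULL,
                              covariates = c("age", "sex"),
                              covariate_mode = c("residualize", "append",
                                                 "none"),
                              k_folds = 5, n_reps = 100, cost = 1, seed = 1,
                              model_name = "radiomics") {
  covariate_mode <- match.arg(covariate_mode)
  if (length(covariates) == 0) covariate_mode <- "none"
  if (is.null(features)) features <- feature_columns(table)
  positive <- attr(split, "positive")
  tbl <- dplyr::inner_join(table, split[, c("id", "label", "role")],
                           by = "id")
  bad <- vapply(features, function(f) anyNA(tbl[[f]]), logical(1))
  if (any(bad)) {
    warning("dropping ", sum(bad), " feature(s) with missing values",
            call. = FALSE)
    features <- features[!bad]
  }
  if (length(features) == 0) stop("no usable features", call. = FALSE)
  parts <- base::split(tbl, tbl$role)
  train <- parts$train
  if (is.null(train) || length(unique(train$label)) != 2) {
    stop("training set must contain both classes", call. = FALSE)
  }
  get_x <- function(df) as.matrix(df[, features, drop = FALSE])
  get_cov <- function(df) df[, intersect(covariates, names(df)), drop = FALSE]

  x_train <- get_x(train)
  fit_cov <- NULL
  if (covariate_mode == "residualize") {
    fit_cov <- fit_covariate_adjustment(x_train, get_cov(train))
    x_train <- apply_covariate_adjustment(fit_cov, x_train, get_cov(train))
  } else if (covariate_mode == "append") {
    x_train <- cbind(x_train, covariate_design(get_cov(train))[, -1,
                                                               drop = FALSE])
  }
  scaler <- fit_scaler(x_train)
  x_train <- apply_scaler(scaler, x_train)

  prep_holdout <- function(df) {
    x <- get_x(df)
    if (covariate_mode == "residualize") {
      x <- apply_covariate_adjustment(fit_cov, x, get_cov(df))
    } else if (covariate_mode == "append") {
      x <- cbind(x, covariate_design(get_cov(df))[, -1, drop = FALSE])
    }
    apply_scaler(scaler, x)
  }

  fit <- repeated_cv(x_train, train$label, positive = positive,
                     k_folds = k_folds, n_reps = n_reps, cost = cost,
                     seed = seed)
  per_rep <- dplyr::mutate(fit$per_rep, dataset = "cv", .before = 1)
  holdout_scores <- list()
  for (ds in c("validation", "test")) {
    df <- parts[[ds]]
    if (!is.null(df) && nrow(df) > 0) {
      ev <- evaluate_holdout(fit, prep_holdout(df), df$label)
      holdout_scores[[ds]] <- list(scores = attr(ev, "scores"),
                                   labels = df$label, id = df$id)
      per_rep <- dplyr::bind_rows(
        per_rep, dplyr::mutate(ev, dataset = ds, .before = 1))
    }
  }
  new_eval_report(per_rep, model_name = model_name,
                  task = attr(split, "task"), positive = positive,
                  n = table(tbl$role), seed = seed,
                  fitted = list(covariate_fit = fit_cov, scaler = scaler,
                                features = features, cv_fit_seed = seed,
                                cv_models = fit$models),
                  holdout_scores = holdout_scores)
}
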