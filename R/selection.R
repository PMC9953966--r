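#' Pairwise-correlation redundancy filter
#'
#' Implements the aggressive redundancy screen: when two feature columns
#' correlate with |Pearson r| above `r_max` (default 0.1), one of the pair is
#' removed at random. Features are scanned in a seeded-random order; each
#' incoming feature is tested against the currently kept set and every
#' conflicting pair is resolved by a seeded coin flip, so the result is
#' deterministic given `seed`. Constant columns cannot correlate and are
#' treated as |r| = 0 against everything.
#'
#' At 0.1 this filter is intentionally severe — with thousands of texture
#' features it yields kept sets of a few dozen.
#'
#' @param table Feature table (training rows only).
#' @param features Feature column names (default: all `__` columns).
#' @param r_max Absolute-correlation threshold, in (0, 1] (default 0.1).
#' @param seed Integer seed for scan order and coin flips.
#' @return A tibble with columns `feature`, `kept`, `reason`
#'   (`NA`/"correlation"), `statistic` (the offending |r|) and `partner`.
#' @export
correlation_filter <- function(table, features = NULL, r_max = 0.1, seed = 1) {
  stopifnot(r_max > 0, r_max <= 1, nrow(table) >= 2)
  if (is.null(features)) features <- feature_columns(table)
  X <- as.matrix(table[, features, drop = FALSE])
  sds <- apply(X, 2, sd)
  R <- suppressWarnings(abs(cor(X)))
  R[is.na(R)] <- 0            # constant columns: treat as uncorrelated
  diag(R) <- 0
  p <- length(features)
  withr::with_seed(as.integer(seed), {
    order_idx <- sample.int(p)
    kept <- integer(0)
    dropped <- integer(0)
    reason_partner <- character(p)
    reason_stat <- rep(NA_real_, p)
    for (f in order_idx) {
      conflicts <- kept[R[f, kept] > r_max]
      survived <- TRUE
      for (g in conflicts) {
        if (runif(1) < 0.5) {
          # drop the incoming feature
          dropped <- c(dropped, f)
          reason_partner[f] <- features[g]
          reason_stat[f] <- R[f, g]
          survived <- FALSE
          break
        } else {
          # drop the previously kept conflicting feature
          kept <- setdiff(kept, g)
          dropped <- c(dropped, g)
          reason_partner[g] <- features[f]
          reason_stat[g] <- R[f, g]
        }
      }
      if (survived) kept <- c(kept, f)
    }
    tibble::tibble(
      feature = features,
      kept = seq_len(p) %in% kept,
      reason = ifelse(seq_len(p) %in% dropped, "correlation", NA_character_),
      statistic = reason_stat,
      partner = ifelse(reason_partner == "", NA_character_, reason_partner)
    )
  })
}

#' Two-sample t-test feature screen
#'
#' Pooled-variance two-sided t per feature between the two groups on the
#' training rows; features with `p < p_max` (strict) are kept. No
#' multiplicity correction is applied at this stage. Features with zero
#' variance in both groups get `p = 1` and are dropped.
#'
#' @param table Feature table (training rows only).
#' @param features Feature column names.
#' @param group_col Name of the group label column (default `"group"`).
#' @param groups The two labels to compare (default: the two present).
#' @param p_max Significance threshold (default 0.005).
#' @return A tibble `feature`, `kept`, `statistic` (t), `p_value`.
#' @export
ttest_filter <- function(table, features = NULL, group_col = "group",
                         groups = NULL, p_max = 0.005) {
  stopifnot(p_max > 0, p_max < 1)
  if (is.null(features)) features <- feature_columns(table)
  g <- table[[group_col]]
  if (is.null(groups)) groups <- unique(g)
  stopifnot(length(groups) == 2)
  a <- table[g == groups[1], features, drop = FALSE]
  b <- table[g == groups[2], features, drop = FALSE]
  if (nrow(a) < 2 || nrow(b) < 2) {
    stop("both groups need at least two subjects", call. = FALSE)
  }
  res <- pooled_ttest_cols(as.matrix(a), as.matrix(b))
  tibble::tibble(
    feature = features,
    kept = res$p < p_max,
    statistic = res$t,
    p_value = res$p
  )
}

# column-wise pooled two-sample t (shared by ttest_filter and tests)
pooled_ttest_cols <- function(A, B) {
  n1 <- nrow(A); n2 <- nrow(B)
  m1 <- colMeans(A); m2 <- colMeans(B)
  v1 <- colSums(sweep(A, 2, m1)^2) / (n1 - 1)
  v2 <- colSums(sweep(B, 2, m2)^2) / (n2 - 1)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tt <- ifelse(se > 0, (m1 - m2) / se, 0)
  pp <- ifelse(se > 0, 2 * stats::pt(-abs(tt), n1 + n2 - 2), 1)
  list(t = tt, p = pp, df = n1 + n2 - 2)
}

#' Two-stage feature selection
#'
#' The fixed pipeline order: correlation redundancy filter
#' ([correlation_filter()]), then univariate t-test screen ([ttest_filter()])
#' on the survivors. Runs on training rows only. When no feature passes the
#' t screen (a null cohort), the single smallest-p survivor is retained with
#' a flag so the downstream classifier can still run at chance level.
#'
#' @param train Feature table restricted to training rows.
#' @param features Feature column names (default: all `__` columns).
#' @param group_col,groups Passed to [ttest_filter()].
#' @param r_max,p_max Thresholds (defaults 0.1 and 0.005).
#' @param seed Seed for the correlation filter's dedicated RNG stream.
#' @return A `selection_result`: list with `kept` (character), `dropped`
#'   (tibble: feature, reason, statistic), `thresholds`, `seed`,
#'   `fallback_used`.
#' @export
select_features <- function(train, features = NULL, group_col = "group",
                            groups = NULL, r_max = 0.1, p_max = 0.005,
                            seed = 1) {
  if (is.null(features)) features <- feature_columns(train)
  cf <- correlation_filter(train, features, r_max = r_max, seed = seed)
  surv <- cf$feature[cf$kept]
  tf <- ttest_filter(train, surv, group_col = group_col, groups = groups,
                     p_max = p_max)
  kept <- tf$feature[tf$kept]
  fallback <- FALSE
  if (length(kept) == 0) {
    kept <- tf$feature[which.min(tf$p_value)]
    fallback <- TRUE
  }
  dropped <- dplyr::bind_rows(
    cf |> dplyr::filter(!.data$kept) |>
      dplyr::transmute(feature = .data$feature, reason = "correlation",
                       statistic = .data$statistic),
    tf |> dplyr::filter(!.data$feature %in% .env$kept) |>
      dplyr::transmute(feature = .data$feature, reason = "ttest",
                       statistic = .data$p_value)
  )
  structure(list(
    kept = kept, dropped = dropped,
    ttest = tf,
    thresholds = list(r_max = r_max, p_max = p_max),
    seed = as.integer(seed), fallback_used = fallback
  ), class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf(
    "<selection_result> %d kept / %d dropped (|r| > %g: %d, t-test: %d)%s\n",
    length(x$kept), nrow(x$dropped), x$thresholds$r_max,
    sum(x$dropped$reason == "correlation"),
    sum(x$dropped$reason == "ttest"),
    if (x$fallback_used) " [fallback: best-p feature retained]" else ""
  ))
  invisible(x)
}

#' Serialize a selection result to JSON
#' @param sel A `selection_result`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_selection <- function(sel, path) {
  jsonlite::write_json(
    list(kept = sel$kept,
         dropped = sel$dropped,
         thresholds = sel$thresholds,
         seed = sel$seed,
         fallback_used = sel$fallback_used),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(path)
}
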