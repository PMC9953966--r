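# Small shared fixtures. All random content is generated under explicit
# seeds so every test is deterministic.

# random quantized ROI array: levels 1..ng inside, 0 outside a random mask
random_levels <- function(dim3 = c(4, 4, 4), ng = 4, p_roi = 0.85,
                          seed = 1) {
  withr::with_seed(seed, {
    lv <- array(sample.int(ng, prod(dim3), replace = TRUE), dim3)
    lv[runif(prod(dim3)) > p_roi] <- 0L
    if (all(lv == 0)) lv[1] <- 1L
    lv
  })
}

# 1D alternating two-level line embedded as an N x 1 x 1 array (the
# checkerboard pattern of a one-dimensional image)
alternating_line <- function(n = 8) {
  array(rep(c(1L, 2L), length.out = n), dim = c(n, 1, 1))
}

# small but fully functional cohort spec (fast to generate)
tiny_spec <- function(...) {
  args <- modifyList(
    list(n_per_group = 6, grid_dim = c(32, 32, 32), n_regions = 9,
         affected_regions = 1:2, seed = 7),
    list(...))
  do.call(cohort_spec, args)
}

# fast pipeline config over a tiny cohort
tiny_config <- function(simulate = list(), n_reps = 10, seed = 5, ...) {
  sim <- modifyList(
    list(n_per_group = 10, grid_dim = c(32, 32, 32), n_regions = 9,
         affected_regions = 1:2, seed = seed),
    simulate)
  pipeline_config(simulate = sim,
                  classification = list(n_reps = n_reps),
                  seed = seed, ...)
}
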