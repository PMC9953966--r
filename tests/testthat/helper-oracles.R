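# Independent brute-force oracles for the texture families, BH-FDR and
# connected components. Deliberately written in plain R with explicit loops,
# sharing no code with the package internals, so that agreement is evidence
# of correctness rather than of shared bugs. Degenerate-value conventions
# (0*log0, zero-variance maps to 0, the NGTDM 1e-6 guard) follow the
# documented package contracts, since those are definitional choices, not
# computations.

# all 26 neighbor offsets, and one representative per +/- direction pair
oracle_offsets26 <- function() {
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  as.matrix(g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ])
}

oracle_dirs13 <- function() {
  o <- oracle_offsets26()
  keep <- o[, 3] > 0 | (o[, 3] == 0 & o[, 2] > 0) |
    (o[, 3] == 0 & o[, 2] == 0 & o[, 1] > 0)
  o[keep, , drop = FALSE]
}

oracle_in_roi <- function(lv, x, y, z) {
  d <- dim(lv)
  x >= 1 && x <= d[1] && y >= 1 && y <= d[2] && z >= 1 && z <= d[3] &&
    lv[x, y, z] > 0
}

# ---- histogram ----------------------------------------------------------
oracle_histogram <- function(lv) {
  x <- as.numeric(lv[lv > 0])
  mu <- sum(x) / length(x)
  m2 <- sum((x - mu)^2) / length(x)
  if (m2 == 0) return(c(hist_variance = 0, hist_skewness = 0,
                        hist_kurtosis = 0))
  m3 <- sum((x - mu)^3) / length(x)
  m4 <- sum((x - mu)^4) / length(x)
  c(hist_variance = m2, hist_skewness = m3 / m2^(3 / 2),
    hist_kurtosis = m4 / m2^2)
}

# ---- GLCM ---------------------------------------------------------------
oracle_glcm_matrix <- function(lv, ng) {
  d <- dim(lv)
  M <- matrix(0, ng, ng)
  off <- oracle_offsets26()
  for (z in 1:d[3]) for (y in 1:d[2]) for (x in 1:d[1]) {
    if (lv[x, y, z] <= 0) next
    for (k in seq_len(nrow(off))) {
      nx <- x + off[k, 1]; ny <- y + off[k, 2]; nz <- z + off[k, 3]
      if (oracle_in_roi(lv, nx, ny, nz)) {
        M[lv[x, y, z], lv[nx, ny, nz]] <- M[lv[x, y, z], lv[nx, ny, nz]] + 1
      }
    }
  }
  M
}

oracle_glcm_features <- function(lv, ng) {
  M <- oracle_glcm_matrix(lv, ng)
  out <- c(glcm_energy = 1, glcm_contrast = 0, glcm_entropy = 0,
           glcm_homogeneity = 0, glcm_correlation = 0, glcm_sum_average = 0,
           glcm_variance = 0, glcm_dissimilarity = 0,
           glcm_autocorrelation = 0)
  tot <- sum(M)
  if (tot == 0) return(out)
  P <- M / tot
  mu <- 0; for (i in 1:ng) mu <- mu + i * sum(P[i, ])
  sg2 <- 0; for (i in 1:ng) sg2 <- sg2 + (i - mu)^2 * sum(P[i, ])
  e <- ct <- en <- hm <- cr <- sa <- va <- ds <- ac <- 0
  for (i in 1:ng) for (j in 1:ng) {
    p <- P[i, j]
    e <- e + p^2
    ct <- ct + (i - j)^2 * p
    if (p > 0) en <- en - p * log2(p)
    hm <- hm + p / (1 + abs(i - j))
    cr <- cr + (i - mu) * (j - mu) * p
    sa <- sa + (i + j) * p
    va <- va + (i - mu)^2 * p
    ds <- ds + abs(i - j) * p
    ac <- ac + i * j * p
  }
  c(glcm_energy = e, glcm_contrast = ct, glcm_entropy = en,
    glcm_homogeneity = hm,
    glcm_correlation = if (sg2 > 0) cr / sg2 else 0,
    glcm_sum_average = sa, glcm_variance = va, glcm_dissimilarity = ds,
    glcm_autocorrelation = ac)
}

# ---- shared run/zone feature formulas ----------------------------------
oracle_rl_features <- function(M, names13, n_voxels) {
  out <- setNames(numeric(13), names13)
  nr <- sum(M)
  if (nr == 0) return(out)
  ng <- nrow(M); rmax <- ncol(M)
  sre <- lre <- lgre <- hgre <- srlge <- srhge <- lrlge <- lrhge <- 0
  mu_i <- mu_r <- 0
  for (i in 1:ng) for (r in 1:rmax) {
    m <- M[i, r]
    if (m == 0) next
    sre <- sre + m / r^2;        lre <- lre + m * r^2
    lgre <- lgre + m / i^2;      hgre <- hgre + m * i^2
    srlge <- srlge + m / (i^2 * r^2); srhge <- srhge + m * i^2 / r^2
    lrlge <- lrlge + m * r^2 / i^2;   lrhge <- lrhge + m * i^2 * r^2
    mu_i <- mu_i + i * m / nr;   mu_r <- mu_r + r * m / nr
  }
  glv <- rlv <- 0
  for (i in 1:ng) for (r in 1:rmax) {
    glv <- glv + (i - mu_i)^2 * M[i, r] / nr
    rlv <- rlv + (r - mu_r)^2 * M[i, r] / nr
  }
  gln <- sum(sapply(1:ng, function(i) sum(M[i, ]))^2) / nr
  rln <- sum(sapply(1:rmax, function(r) sum(M[, r]))^2) / nr
  out[] <- c(sre / nr, lre / nr, gln, rln, nr / n_voxels, lgre / nr,
             hgre / nr, srlge / nr, srhge / nr, lrlge / nr, lrhge / nr,
             glv, rlv)
  out
}

# ---- GLRLM --------------------------------------------------------------
oracle_glrlm_matrix <- function(lv, ng) {
  d <- dim(lv)
  dirs <- oracle_dirs13()
  runs_i <- integer(0); runs_l <- integer(0)
  for (k in seq_len(nrow(dirs))) {
    dx <- dirs[k, 1]; dy <- dirs[k, 2]; dz <- dirs[k, 3]
    for (z in 1:d[3]) for (y in 1:d[2]) for (x in 1:d[1]) {
      v <- lv[x, y, z]
      if (v <= 0) next
      # run starts where the backward neighbor is absent or differs
      px <- x - dx; py <- y - dy; pz <- z - dz
      if (oracle_in_roi(lv, px, py, pz) && lv[px, py, pz] == v) next
      len <- 1
      nx <- x + dx; ny <- y + dy; nz <- z + dz
      while (oracle_in_roi(lv, nx, ny, nz) && lv[nx, ny, nz] == v) {
        len <- len + 1
        nx <- nx + dx; ny <- ny + dy; nz <- nz + dz
      }
      runs_i <- c(runs_i, v); runs_l <- c(runs_l, len)
    }
  }
  M <- matrix(0, ng, max(runs_l))
  for (q in seq_along(runs_i)) {
    M[runs_i[q], runs_l[q]] <- M[runs_i[q], runs_l[q]] + 1
  }
  M
}

oracle_glrlm_features <- function(lv, ng) {
  M <- oracle_glrlm_matrix(lv, ng)
  oracle_rl_features(
    M, paste0("glrlm_", c("sre", "lre", "gln", "rln", "rp", "lgre", "hgre",
                          "srlge", "srhge", "lrlge", "lrhge", "glv", "rlv")),
    n_voxels = 13 * sum(lv > 0))
}

# ---- connected components (used for GLSZM and cluster oracle) ----------
# iterative minimum-label propagation until fixpoint
oracle_components <- function(grid, connectivity = 26, same_value = TRUE) {
  d <- dim(grid)
  off <- oracle_offsets26()
  if (connectivity == 6) off <- off[rowSums(abs(off)) == 1, , drop = FALSE]
  if (connectivity == 18) off <- off[rowSums(abs(off)) <= 2, , drop = FALSE]
  lab <- array(0L, d)
  lab[grid > 0] <- seq_len(sum(grid > 0))
  idx <- which(grid > 0, arr.ind = TRUE)
  repeat {
    changed <- FALSE
    for (q in seq_len(nrow(idx))) {
      x <- idx[q, 1]; y <- idx[q, 2]; z <- idx[q, 3]
      for (k in seq_len(nrow(off))) {
        nx <- x + off[k, 1]; ny <- y + off[k, 2]; nz <- z + off[k, 3]
        if (!oracle_in_roi(grid, nx, ny, nz)) next
        if (same_value && grid[nx, ny, nz] != grid[x, y, z]) next
        if (lab[nx, ny, nz] < lab[x, y, z]) {
          lab[x, y, z] <- lab[nx, ny, nz]; changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  # renumber to 1..K
  u <- sort(unique(lab[lab > 0]))
  lab[lab > 0] <- match(lab[lab > 0], u)
  lab
}

# ---- GLSZM --------------------------------------------------------------
oracle_glszm_matrix <- function(lv, ng) {
  lab <- oracle_components(lv, 26, same_value = TRUE)
  k <- max(lab)
  sizes <- integer(k); lvl <- integer(k)
  for (z in seq_len(k)) {
    w <- which(lab == z)
    sizes[z] <- length(w)
    lvl[z] <- lv[w[1]]
  }
  M <- matrix(0, ng, max(sizes))
  for (z in seq_len(k)) M[lvl[z], sizes[z]] <- M[lvl[z], sizes[z]] + 1
  M
}

oracle_glszm_features <- function(lv, ng) {
  M <- oracle_glszm_matrix(lv, ng)
  oracle_rl_features(
    M, paste0("glszm_", c("sze", "lze", "gln", "zsn", "zp", "lgze", "hgze",
                          "szlge", "szhge", "lzlge", "lzhge", "glv", "zsv")),
    n_voxels = sum(lv > 0))
}

# ---- NGTDM --------------------------------------------------------------
oracle_ngtdm_features <- function(lv, ng) {
  d <- dim(lv)
  off <- oracle_offsets26()
  n_i <- numeric(ng); s_i <- numeric(ng)
  for (z in 1:d[3]) for (y in 1:d[2]) for (x in 1:d[1]) {
    v <- lv[x, y, z]
    if (v <= 0) next
    nb <- numeric(0)
    for (k in seq_len(nrow(off))) {
      nx <- x + off[k, 1]; ny <- y + off[k, 2]; nz <- z + off[k, 3]
      if (oracle_in_roi(lv, nx, ny, nz)) nb <- c(nb, lv[nx, ny, nz])
    }
    if (length(nb) > 0) {
      n_i[v] <- n_i[v] + 1
      s_i[v] <- s_i[v] + abs(v - sum(nb) / length(nb))
    }
  }
  out <- c(ngtdm_coarseness = 1e6, ngtdm_contrast = 0, ngtdm_busyness = 0,
           ngtdm_complexity = 0, ngtdm_strength = 0)
  N <- sum(n_i)
  if (N == 0) return(out)
  p_i <- n_i / N
  act <- which(p_i > 0)
  eps <- 1e-6
  out["ngtdm_coarseness"] <- 1 / (sum(p_i * s_i) + eps)
  if (length(act) > 1) {
    ctr <- bsy_den <- cpx <- str <- 0
    for (i in act) for (j in act) {
      ctr <- ctr + p_i[i] * p_i[j] * (i - j)^2
      bsy_den <- bsy_den + abs(i * p_i[i] - j * p_i[j])
      cpx <- cpx + abs(i - j) * (p_i[i] * s_i[i] + p_i[j] * s_i[j]) /
        (p_i[i] + p_i[j])
      str <- str + (p_i[i] + p_i[j]) * (i - j)^2
    }
    ngp <- length(act)
    out["ngtdm_contrast"] <- ctr / (ngp * (ngp - 1)) * sum(s_i) / N
    out["ngtdm_busyness"] <- if (bsy_den > 0) sum(p_i * s_i) / bsy_den else 0
    out["ngtdm_complexity"] <- cpx / N
    out["ngtdm_strength"] <- str / (sum(s_i) + eps)
  }
  out
}

# ---- full 43-feature oracle --------------------------------------------
oracle_feature_vector <- function(lv, ng) {
  c(oracle_histogram(lv), oracle_glcm_features(lv, ng),
    oracle_glrlm_features(lv, ng), oracle_glszm_features(lv, ng),
    oracle_ngtdm_features(lv, ng))
}

# ---- Benjamini-Hochberg cutoff, O(m^2) ---------------------------------
oracle_bh_cutoff <- function(p, q) {
  m <- length(p)
  best <- NA_real_
  for (i in seq_len(m)) {
    rank_i <- sum(p <= p[i])   # midless rank: count of values <= p[i]
    if (p[i] <= q * rank_i / m) {
      if (is.na(best) || p[i] > best) best <- p[i]
    }
  }
  best
}

# relative comparison helper: |a-b| <= tol * max(1, |b|)
expect_close <- function(a, b, tol = 1e-10) {
  expect_true(all(abs(a - b) <= tol * pmax(1, abs(b))),
              label = paste0("max rel err ",
                             format(max(abs(a - b) / pmax(1, abs(b))))))
}
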