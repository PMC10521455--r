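# Independent oracles and small generators used across the suite.

# All monotone, continuous warping paths from (1,1) to (n,m), as 2-row
# index matrices (row 1 = first-series index, row 2 = second-series index).
enumerate_warping_paths <- function(n, m) {
  out <- list()
  grow <- function(path) {
    i <- path[1L, ncol(path)]
    j <- path[2L, ncol(path)]
    if (i == n && j == m) {
      out[[length(out) + 1L]] <<- path
      return(invisible())
    }
    if (i < n && j < m) grow(cbind(path, c(i + 1L, j + 1L)))
    if (i < n) grow(cbind(path, c(i + 1L, j)))
    if (j < m) grow(cbind(path, c(i, j + 1L)))
  }
  grow(matrix(c(1L, 1L), 2L))
  out
}

# Step weights along a path: start cell then one weight per move.
path_weights <- function(path, weighting) {
  du <- diff(path[1L, ])
  dv <- diff(path[2L, ])
  if (weighting == "symmetric") c(2, du + dv) else c(1, du)
}

# Exhaustive-minimization DTW oracle for one pair of series.
dtw_oracle <- function(y, z, weighting = "symmetric") {
  paths <- enumerate_warping_paths(length(y), length(z))
  min(vapply(paths, function(p) {
    w <- path_weights(p, weighting)
    sum(abs(y[p[1L, ]] - z[p[2L, ]]) * w) / sum(w)
  }, numeric(1)))
}

# Exact two-sided signed-rank p-value by full 2^n sign enumeration.
wilcoxon_enum_oracle <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) return(1)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  ws <- vapply(0:(2^n - 1L), function(mask) {
    sum(r[as.logical(intToBits(mask))[seq_len(n)]])
  }, numeric(1))
  p_le <- mean(ws <= w_obs + 1e-9)
  p_ge <- mean(ws >= w_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# Best label agreement over all k! cluster relabellings (small k).
permutation_accuracy <- function(labels, truth) {
  k <- max(truth)
  perms <- if (k == 1L) list(1L) else asplit(permutations_of(k), 1L)
  max(vapply(perms, function(p) mean(p[labels] == truth), numeric(1)))
}

permutations_of <- function(k) {
  if (k == 1L) return(matrix(1L))
  sub <- permutations_of(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

# Sparse stable VAR(1) with planted off-diagonal edges; returns the
# coefficient matrix and a post-burn-in series.
gen_sparse_var <- function(seed, p = 20L, t_obs = 480L, n_edges = 10L,
                           noise_sd = 0.5) {
  set.seed(seed)
  A <- matrix(0, p, p)
  picked <- sample(which(row(A) != col(A)), n_edges)
  A[picked] <- sample(c(-1, 1), n_edges, replace = TRUE) * runif(n_edges, 0.4, 0.5)
  while (max(Mod(eigen(A, only.values = TRUE)$values)) >= 0.95) A <- A * 0.9
  x <- matrix(0, p, t_obs + 100L)
  for (t in seq_len(t_obs + 99L)) {
    x[, t + 1L] <- A %*% x[, t] + rnorm(p, sd = noise_sd)
  }
  list(A = A, x = x[, 100L + seq_len(t_obs), drop = FALSE])
}

# Precision of the top-n ranked lagged edges against the planted ones.
lagged_edge_precision <- function(A_true, x, n_top = 10L) {
  ids <- sprintf("v%02d", seq_len(nrow(x)))
  em <- expression_matrix(x, ids, seq_len(ncol(x)))
  P <- lagged_pcor_matrix(em)
  e <- top_edges(P, n_top = n_top, directed = TRUE)
  truth <- which(A_true != 0, arr.ind = TRUE)
  truth_keys <- paste(truth[, 2L], truth[, 1L])   # source, target
  est_keys <- paste(match(e$source, ids), match(e$target, ids))
  mean(est_keys %in% truth_keys)
}

# Small standardized expression fixture with two planted archetypes.
two_blob_matrix <- function(n_per = 50L, t_obs = 24L, noise_sd = 0.3,
                            seed = 1L) {
  tt <- seq_len(t_obs)
  a1 <- scale(sin(2 * pi * tt / t_obs))[, 1L]
  a2 <- -a1
  set.seed(seed)
  vals <- rbind(
    matrix(a1, n_per, t_obs, byrow = TRUE),
    matrix(a2, n_per, t_obs, byrow = TRUE)
  ) + matrix(rnorm(2 * n_per * t_obs, sd = noise_sd), 2L * n_per)
  list(
    em = expression_matrix(vals, sprintf("g%03d", seq_len(2L * n_per)), tt),
    labels = rep(1:2, each = n_per)
  )
}
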