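#' Fit a first-order vector autoregression
#'
#' Ordinary least squares fit of \eqn{y(t+1) = A\,y(t) + B + \epsilon(t)},
#' \eqn{\epsilon(t) \sim N(0, \Sigma)}, over the `p` selected genes:
#' `Y_future` (observations 2..T) is regressed on `Y_past` (1..T-1) with
#' intercept. `A[i, j]` is the lagged effect of gene `j` on gene `i`; a
#' nonzero entry encodes a directed arc `j -> i`. The residual covariance
#' uses denominator `T - 1 - (p + 1)` (samples minus parameters per
#' equation); when that is not positive the uncorrected residual second
#' moment is reported with a warning. A singular Gram matrix (`p >= T - 1`)
#' falls back to the Moore-Penrose pseudoinverse with `rank_deficient =
#' TRUE` and a warning.
#'
#' @param x_sel An `expr_mat` of the selected genes (standardized scale).
#' @return An object of class `var1_fit`: `gene_ids`, `A`, `B`,
#'   `residual_cov`, `rank_deficient`, `n_obs`.
#' @export
fit_var1 <- function(x_sel) {
  x_sel <- as_expression_matrix(x_sel)
  vals <- em_values(x_sel)
  p <- nrow(vals)
  tt <- ncol(vals)
  if (tt < 3L) abort("VAR(1) needs at least 3 time points")
  const <- apply(vals, 1L, function(r) all(r == r[1L]))
  if (any(const)) {
    abort(paste0("constant gene row(s): ",
                 paste(rownames(vals)[const], collapse = ", ")))
  }
  past <- t(vals[, -tt, drop = FALSE])    # (T-1) x p
  fut <- t(vals[, -1L, drop = FALSE])     # (T-1) x p
  n <- nrow(past)
  pc <- scale(past, scale = FALSE)
  fc <- scale(fut, scale = FALSE)
  gram <- crossprod(pc)
  qr_g <- qr(gram)
  rank_deficient <- qr_g$rank < p
  coefs <- if (!rank_deficient) {
    solve(gram, crossprod(pc, fc))
  } else {
    warn(sprintf("Gram matrix rank %d < p = %d; using pseudoinverse estimates",
                 qr_g$rank, p))
    pinv(gram) %*% crossprod(pc, fc)
  }
  A <- t(coefs)                            # A[i, j]: j at t -> i at t+1
  B <- as.vector(colMeans(fut) - A %*% colMeans(past))
  resid <- fc - pc %*% coefs
  dof <- n - (p + 1L)
  Sigma <- if (dof > 0L) {
    crossprod(resid) / dof
  } else {
    warn("non-positive residual degrees of freedom; reporting uncorrected second moments")
    crossprod(resid) / n
  }
  Sigma <- (Sigma + t(Sigma)) / 2
  dimnames(A) <- list(rownames(vals), rownames(vals))
  dimnames(Sigma) <- dimnames(A)
  structure(
    list(gene_ids = rownames(vals), A = A, B = setNames(B, rownames(vals)),
         residual_cov = Sigma, rank_deficient = rank_deficient, n_obs = n),
    class = "var1_fit"
  )
}

pinv <- function(m, tol = 1e-10) {
  s <- svd(m)
  keep <- s$d > tol * s$d[1L]
  s$v[, keep, drop = FALSE] %*% (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

#' @export
print.var1_fit <- function(x, ...) {
  cat(sprintf("VAR(1) over %d genes, %d lagged observations%s\n",
              length(x$gene_ids), x$n_obs,
              if (x$rank_deficient) " (rank deficient)" else ""))
  invisible(x)
}

#' @describeIn fit_var1 `tidy()` returns one row per ordered gene pair with
#'   the VAR coefficient.
#' @param x,object A `var1_fit`.
#' @param ... Unused.
#' @export
tidy.var1_fit <- function(x, ...) {
  p <- length(x$gene_ids)
  tibble::tibble(
    target = rep(x$gene_ids, times = p),
    source = rep(x$gene_ids, each = p),
    coefficient = as.vector(x$A)
  )
}

#' @describeIn fit_var1 `glance()` returns a one-row summary.
#' @export
glance.var1_fit <- function(x, ...) {
  tibble::tibble(p = length(x$gene_ids), n_obs = x$n_obs,
                 rank_deficient = x$rank_deficient,
                 mean_resid_var = mean(diag(x$residual_cov)))
}

#' Lagged partial correlation between a past gene and a future gene
#'
#' The strength of the direct lagged association source -> target, given
#' all other genes' past values. Two companion regressions are fitted:
#' the forward one of \eqn{y_i(t+1)} on all \eqn{y(t)} (coefficient
#' \eqn{a_{1k}} of the source) and the reverse one of \eqn{y_k(t)} on
#' \eqn{y_i(t+1)} and the remaining \eqn{y_j(t)} (coefficient
#' \eqn{a^*_{1k}}); the partial correlation is
#' \eqn{\sqrt{a_{1k} a^*_{1k}}\,\mathrm{sgn}(a^*_{1k})}. The product of
#' the two coefficients is algebraically non-negative (each equals the
#' partial correlation times a ratio of partial standard deviations), and
#' this is asserted at run time.
#'
#' `lagged_pcor_matrix()` computes all \eqn{p^2} values at once from the
#' precision matrix of the joint (past, single future) covariance, one
#' matrix inversion per target gene; the two formulations agree to
#' numerical precision.
#'
#' @param x_sel An `expr_mat` of the selected genes.
#' @param target_index,source_index Row indices (or gene ids) of the
#'   regulated and regulating gene.
#' @return A partial correlation in `[-1, 1]`; the matrix version returns
#'   a `p x p` matrix `P` with `P[i, k]` the partial correlation of the
#'   edge `k -> i` (diagonal included).
#' @export
lagged_partial_correlation <- function(x_sel, target_index, source_index) {
  x_sel <- as_expression_matrix(x_sel)
  vals <- em_values(x_sel)
  if (is.character(target_index)) target_index <- match(target_index, rownames(vals))
  if (is.character(source_index)) source_index <- match(source_index, rownames(vals))
  tt <- ncol(vals)
  past <- t(vals[, -tt, drop = FALSE])
  fut_i <- vals[target_index, -1L]
  k <- source_index
  forward <- stats::lm.fit(cbind(1, past), fut_i)
  a <- forward$coefficients[k + 1L]
  reverse_design <- cbind(1, fut_i, past[, -k, drop = FALSE])
  reverse <- stats::lm.fit(reverse_design, past[, k])
  a_star <- reverse$coefficients[2L]
  prod <- a * a_star
  stopifnot(prod >= -1e-10)
  unname(sqrt(max(prod, 0)) * sign(a_star))
}

#' @rdname lagged_partial_correlation
#' @export
lagged_pcor_matrix <- function(x_sel) {
  x_sel <- as_expression_matrix(x_sel)
  vals <- em_values(x_sel)
  p <- nrow(vals)
  tt <- ncol(vals)
  if (tt < 3L) abort("need at least 3 time points")
  past <- t(vals[, -tt, drop = FALSE])
  fut <- t(vals[, -1L, drop = FALSE])
  S_pp <- cov(past)
  out <- matrix(NA_real_, p, p, dimnames = list(rownames(vals), rownames(vals)))
  for (i in seq_len(p)) {
    s_pf <- cov(past, fut[, i])
    S <- rbind(cbind(S_pp, s_pf), c(s_pf, stats::var(fut[, i])))
    omega <- solve(S)
    pc <- -omega[seq_len(p), p + 1L] /
      sqrt(diag(omega)[seq_len(p)] * omega[p + 1L, p + 1L])
    out[i, ] <- pc
  }
  out
}

#' Functional inner product of two sampled curves
#'
#' Trapezoid-style weighted inner product
#' \eqn{\langle g, h\rangle = \sum_j g(t_j) h(t_j) (t_{j+1} - t_{j-1}) /
#' (2T)}, with the boundary convention \eqn{t_0 := t_1},
#' \eqn{t_{T+1} := t_T} (one-sided differences at the ends). Bilinear and
#' symmetric; on a uniform unit-spaced grid the interior weights are
#' `1/T` and the end weights `1/(2T)`.
#'
#' @param g,h Numeric sequences of equal length (>= 2).
#' @param times Strictly increasing observation times.
#' @return A single numeric value.
#' @export
dynamic_inner_product <- function(g, h, times = seq_along(g)) {
  if (length(g) != length(h) || length(g) != length(times)) {
    abort("g, h and times must have equal length")
  }
  n <- length(g)
  if (n < 2L) abort("need at least 2 observations")
  tpad <- c(times[1L], times, times[n])
  w <- (tpad[3:(n + 2L)] - tpad[1:n]) / (2 * n)
  sum(g * h * w)
}

dynamic_weights <- function(times) {
  n <- length(times)
  tpad <- c(times[1L], times, times[n])
  (tpad[3:(n + 2L)] - tpad[1:n]) / (2 * n)
}

#' Dynamic (functional) correlation matrix
#'
#' Each gene's trajectory is treated as a sampled function, standardized
#' functionally — centered by \eqn{\langle f, 1\rangle} and scaled by
#' \eqn{\sqrt{\langle f - \langle f,1\rangle,\, f - \langle
#' f,1\rangle\rangle}} under [dynamic_inner_product()] — and the dynamic
#' correlation is \eqn{\hat\varrho_{kl} = \langle f_k^S, f_l^S\rangle}.
#' Unlike the ordinary Pearson correlation this respects unequal time
#' spacing; on a uniform grid the two converge as `T` grows. The diagonal
#' is exactly 1 and the matrix symmetric.
#'
#' @param x_sel An `expr_mat` with no constant gene.
#' @return A symmetric `p x p` matrix with unit diagonal.
#' @export
dynamic_correlation_matrix <- function(x_sel) {
  x_sel <- as_expression_matrix(x_sel)
  vals <- em_values(x_sel)
  w <- dynamic_weights(em_times(x_sel))
  centered <- vals - as.vector(vals %*% w) / sum(w)
  norms <- sqrt(rowSums(sweep(centered^2, 2L, w, "*")))
  if (any(norms == 0)) {
    abort(paste0("constant series: ",
                 paste(rownames(vals)[norms == 0], collapse = ", ")))
  }
  fs <- centered / norms
  rho <- fs %*% (t(fs) * w)
  rho <- (rho + t(rho)) / 2
  diag(rho) <- 1
  dimnames(rho) <- list(rownames(vals), rownames(vals))
  rho
}

#' Partial correlations from a correlation matrix
#'
#' Inverts the correlation matrix and rescales:
#' \eqn{\mathrm{pcor}_{kl} = -\omega_{kl} / \sqrt{\omega_{kk}
#' \omega_{ll}}} with \eqn{\omega = \mathrm{corr}^{-1}}; the diagonal is
#' restored to 1. For two variables the partial correlation equals the
#' marginal one. A singular input can be regularised by shrinking toward
#' the identity with intensity `shrinkage`.
#'
#' @param corr Symmetric correlation matrix with unit diagonal, positive
#'   definite (after shrinkage).
#' @param shrinkage Shrinkage intensity in `[0, 1)` toward the identity
#'   (default 0 = none).
#' @return Symmetric partial correlation matrix with unit diagonal.
#' @export
dynamic_partial_correlation <- function(corr, shrinkage = 0) {
  if (shrinkage > 0) {
    corr <- (1 - shrinkage) * corr + shrinkage * diag(nrow(corr))
  }
  omega <- tryCatch(solve(corr), error = function(e) {
    abort("correlation matrix is singular; retry with shrinkage > 0 toward the identity")
  })
  pc <- -omega / sqrt(outer(diag(omega), diag(omega)))
  pc <- (pc + t(pc)) / 2
  diag(pc) <- 1
  dimnames(pc) <- dimnames(corr)
  pc
}

#' Rank the strongest edges of a weight matrix
#'
#' Sorts edges by descending absolute weight and keeps the first `n_top`.
#' For a directed weight matrix `W[i, k]` (edge `k -> i`) every ordered
#' off-diagonal pair is a candidate; for an undirected (symmetric) matrix
#' only one of each pair is ranked. Self-loops are excluded by default
#' because autocorrelation trivially dominates lagged rankings. Exact
#' absolute-weight ties break lexicographically by (source, target).
#'
#' @param weights Square numeric matrix with gene ids as dimnames.
#' @param n_top Number of edges to keep (all edges if fewer exist).
#' @param directed Is the weight matrix directed?
#' @param include_self_loops Keep diagonal entries as edges?
#' @return A tibble of class `edge_list` with columns `rank`, `source`,
#'   `target`, `weight`, `sign` (`"+"` positive, `"-"` negative
#'   correlation).
#' @export
top_edges <- function(weights, n_top = 150L, directed = TRUE,
                      include_self_loops = FALSE) {
  if (n_top < 1L) abort("n_top must be at least 1")
  ids <- rownames(weights) %||% paste0("g", seq_len(nrow(weights)))
  p <- nrow(weights)
  idx <- expand.grid(i = seq_len(p), k = seq_len(p))
  if (!directed) idx <- idx[idx$k < idx$i, , drop = FALSE]
  if (!include_self_loops) idx <- idx[idx$i != idx$k, , drop = FALSE]
  df <- tibble::tibble(
    source = ids[idx$k],
    target = ids[idx$i],
    weight = weights[cbind(idx$i, idx$k)]
  )
  df <- df[order(-abs(df$weight), df$source, df$target), ]
  df <- head(df, n_top)
  df$rank <- seq_len(nrow(df))
  df$sign <- ifelse(df$weight >= 0, "+", "-")
  out <- df[c("rank", "source", "target", "weight", "sign")]
  attr(out, "directed") <- directed
  class(out) <- c("edge_list", class(out))
  out
}

#' @describeIn top_edges `autoplot()` shows the ranked absolute weights,
#'   coloured by sign.
#' @param object An `edge_list`.
#' @param ... Unused.
#' @export
autoplot.edge_list <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$rank, y = abs(.data$weight),
                                       colour = .data$sign)) +
    ggplot2::geom_point(size = 0.9) +
    ggplot2::scale_colour_manual(values = c("+" = "#2166ac", "-" = "#b2182b")) +
    ggplot2::labs(x = "edge rank", y = "|partial correlation|",
                  colour = "sign") +
    ggplot2::theme_minimal()
}
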