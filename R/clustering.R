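# Evaluate `code` under a fixed RNG state, restoring the caller's state.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1L)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  code
}

#' Estimate the fuzzy C-means fuzzifier from data dimensions
#'
#' Closed-form estimate of the fuzzifier `m` as a function of the number of
#' items `N` (genes) and the feature dimension `D` (time points), following
#' the empirical relation of Schwammle and Jensen (2010):
#' \deqn{m = 1 + (1418/N + 22.05)\,D^{-2} +
#'           (12.33/N + 0.243)\,D^{-0.0406\ln N - 0.1134}.}
#' For high-dimensional time courses this yields values barely above 1,
#' i.e. nearly hard clustering, which protects against the uniform
#' membership collapse that large `m` causes in many dimensions.
#'
#' @param n_genes Number of genes (N >= 2).
#' @param n_timepoints Number of time points (D >= 1).
#' @return A single numeric fuzzifier, strictly greater than 1.
#' @export
estimate_fuzzifier <- function(n_genes, n_timepoints) {
  if (n_genes < 2 || n_timepoints < 1) {
    abort("need n_genes >= 2 and n_timepoints >= 1")
  }
  N <- as.numeric(n_genes)
  D <- as.numeric(n_timepoints)
  1 + (1418 / N + 22.05) * D^(-2) +
    (12.33 / N + 0.243) * D^(-0.0406 * log(N) - 0.1134)
}

#' Fuzzy C-means clustering of gene trajectories
#'
#' Minimises the weighted within-cluster sum of squares
#' \deqn{L(K,m) = \sum_{k=1}^{K}\sum_{i=1}^{N} u_{ki}^m\, \|y_i - c_k\|^2,
#'       \qquad \sum_k u_{ki} = 1,}
#' by the classic alternating updates: centroids as \eqn{u^m}-weighted means
#' of the gene profiles, memberships from squared Euclidean centroid
#' distances with exponent \eqn{2/(m-1)}. Memberships are initialised from a
#' symmetric Dirichlet(1) draw per gene, so identical seeds give identical
#' fits. Iteration stops when the absolute change in the objective falls
#' below `tol` or after `max_iter` sweeps; the recorded objective trace is
#' non-increasing.
#'
#' @param x An `expr_mat`; rows are expected to be standardized
#'   (see [standardize_genes()]).
#' @param k Number of clusters, `1 <= k <=` number of genes.
#' @param m Fuzzifier, `> 1`; defaults to [estimate_fuzzifier()] on the
#'   data's dimensions.
#' @param max_iter,tol Convergence controls.
#' @param seed Integer seed for the membership initialisation.
#' @return An object of class `fcm_fit` with elements `k`, `m`,
#'   `memberships` (k x N, columns sum to 1), `centroids` (k x T),
#'   `objective_trace`, `gene_ids`, `times`, `seed`.
#' @seealso [tidy.fcm_fit()], [glance.fcm_fit()], [autoplot.fcm_fit()],
#'   [gap_statistic()]
#' @export
fuzzy_cmeans <- function(x, k, m = NULL, max_iter = 300L, tol = 1e-6, seed = 1L) {
  x <- as_expression_matrix(x)
  vals <- em_values(x)
  n <- nrow(vals)
  if (k < 1L || k > n) abort(sprintf("k must be in 1..%d (number of genes), got %s", n, k))
  if (tol <= 0) abort("tol must be positive")
  m <- m %||% estimate_fuzzifier(n, ncol(vals))
  if (m <= 1) abort("fuzzifier m must exceed 1")

  u <- with_seed(seed, {
    g <- matrix(stats::rexp(k * n), nrow = k)
    sweep(g, 2L, colSums(g), "/")
  })
  if (k == 1L) u <- matrix(1, 1L, n)

  sq_dist <- function(cent) {
    # k x n matrix of squared Euclidean distances gene i vs centroid k
    d2 <- outer(rowSums(cent^2), rep(1, n)) - 2 * cent %*% t(vals) +
      outer(rep(1, k), rowSums(vals^2))
    pmax(d2, 0)
  }
  objective <- function(u, d2) sum(u^m * d2)

  trace <- numeric(0)
  prev <- Inf
  for (iter in seq_len(max_iter)) {
    um <- u^m
    cent <- (um %*% vals) / rowSums(um)
    d2 <- sq_dist(cent)
    if (k == 1L) {
      u <- matrix(1, 1L, n)
    } else {
      zero <- d2 < .Machine$double.eps
      inv <- d2^(-1 / (m - 1))
      u <- sweep(inv, 2L, colSums(inv), "/")
      hit <- colSums(zero) > 0L
      if (any(hit)) {
        u[, hit] <- sweep(zero[, hit, drop = FALSE], 2L,
                          colSums(zero[, hit, drop = FALSE]), "/")
      }
    }
    obj <- objective(u, d2)
    trace <- c(trace, obj)
    if (is.finite(prev) && abs(prev - obj) < tol) break
    prev <- obj
  }

  structure(
    list(k = as.integer(k), m = m, memberships = u, centroids = cent,
         objective_trace = trace, gene_ids = x$gene_id, times = em_times(x),
         seed = as.integer(seed), n_iter = length(trace)),
    class = "fcm_fit"
  )
}

#' @export
print.fcm_fit <- function(x, ...) {
  cat(sprintf("Fuzzy C-means fit: %d clusters, %d genes, m = %.4f\n",
              x$k, length(x$gene_ids), x$m))
  cat(sprintf("  objective %.6g after %d iterations (seed %d)\n",
              tail(x$objective_trace, 1L), x$n_iter, x$seed))
  invisible(x)
}

#' Hard cluster labels from a fuzzy fit
#'
#' Argmax membership per gene; ties go to the smallest cluster index.
#'
#' @param fit An `fcm_fit`.
#' @return Integer vector of cluster labels named by gene id.
#' @export
hard_labels <- function(fit) {
  lab <- apply(fit$memberships, 2L, which.max)
  setNames(as.integer(lab), fit$gene_ids)
}

#' Cluster containing a target gene
#'
#' Returns the cluster with the largest membership for `gene_id` (smallest
#' index on ties): the cluster a soft assignment would harden to.
#'
#' @param fit An `fcm_fit`.
#' @param gene_id A gene identifier present in the fit.
#' @return Integer cluster index.
#' @export
select_cluster_of <- function(fit, gene_id) {
  i <- match(gene_id, fit$gene_ids)
  if (is.na(i)) abort(paste0("gene '", gene_id, "' not present in the clustered matrix"))
  which.max(fit$memberships[, i])
}

#' @describeIn fuzzy_cmeans `tidy()` returns one row per gene-cluster pair
#'   with the membership weight and the hardened label.
#' @param x,object An `fcm_fit`.
#' @param ... Unused.
#' @export
tidy.fcm_fit <- function(x, ...) {
  lab <- hard_labels(x)
  tibble::tibble(
    gene_id = rep(x$gene_ids, each = x$k),
    cluster = rep(seq_len(x$k), times = length(x$gene_ids)),
    membership = as.vector(x$memberships),
    hard = rep(unname(lab), each = x$k) == rep(seq_len(x$k), times = length(x$gene_ids))
  )
}

#' @describeIn fuzzy_cmeans `glance()` returns a one-row summary.
#' @export
glance.fcm_fit <- function(x, ...) {
  tibble::tibble(
    k = x$k, m = x$m, n_genes = length(x$gene_ids),
    n_iter = x$n_iter, objective = tail(x$objective_trace, 1L),
    converged = x$n_iter < 300L
  )
}

#' Gap statistic for choosing the number of clusters
#'
#' For each candidate `k` the data are clustered by [fuzzy_cmeans()], the
#' memberships hardened, and the total within-cluster dispersion
#' \eqn{W_k = \sum_k \sum_{i \in k} \|y_i - \bar y_k\|^2} compared against
#' the same quantity on `b` reference datasets drawn uniformly over each
#' feature's observed range (no cluster structure):
#' \eqn{\mathrm{gap}(k) = \mathrm{mean}_b \log W^*_{kb} - \log W_k}.
#' `k_hat` is the argmax of the gap curve; the full curve (with reference
#' standard errors) is returned so an elbow can be preferred when the
#' argmax over-segments, which is common on smooth expression profiles.
#'
#' @inheritParams fuzzy_cmeans
#' @param k_max Largest number of clusters to try.
#' @param b Number of uniform reference datasets (>= 1).
#' @return A `gap_curve` tibble with columns `k`, `log_w`, `gap`, `sd`, and
#'   attribute `k_hat`.
#' @export
gap_statistic <- function(x, k_max, b = 20L, m = NULL, seed = 1L) {
  x <- as_expression_matrix(x)
  if (b < 1L) abort("b (number of reference datasets) must be at least 1")
  if (k_max < 1L) abort("k_max must be at least 1")
  vals <- em_values(x)
  m <- m %||% estimate_fuzzifier(nrow(vals), ncol(vals))

  within_dispersion <- function(v, labels) {
    sum(vapply(split(seq_len(nrow(v)), labels), function(idx) {
      sub <- v[idx, , drop = FALSE]
      sum(sweep(sub, 2L, colMeans(sub))^2)
    }, numeric(1)))
  }
  cluster_w <- function(v, k, s) {
    em <- expression_matrix(v, paste0("r", seq_len(nrow(v))), seq_len(ncol(v)))
    fit <- fuzzy_cmeans(em, k, m = m, seed = s)
    within_dispersion(v, hard_labels(fit))
  }

  lo <- apply(vals, 2L, min)
  hi <- apply(vals, 2L, max)
  res <- with_seed(seed, {
    ref_seeds <- matrix(sample.int(.Machine$integer.max, k_max * (b + 1L)),
                        nrow = k_max)
    purrr::map(seq_len(k_max), function(k) {
      log_w <- log(cluster_w(vals, k, ref_seeds[k, 1L]))
      log_wstar <- vapply(seq_len(b), function(j) {
        ref <- matrix(runif(length(vals), min = rep(lo, each = nrow(vals)),
                            max = rep(hi, each = nrow(vals))),
                      nrow = nrow(vals))
        log(cluster_w(ref, k, ref_seeds[k, j + 1L]))
      }, numeric(1))
      tibble::tibble(
        k = k, log_w = log_w,
        gap = mean(log_wstar) - log_w,
        sd = sd(log_wstar) * sqrt(1 + 1 / b)
      )
    })
  })
  out <- dplyr::bind_rows(res)
  if (b == 1L) out$sd <- 0
  attr(out, "k_hat") <- out$k[which.max(out$gap)]
  class(out) <- c("gap_curve", class(out))
  out
}

#' @export
print.gap_curve <- function(x, ...) {
  cat(sprintf("Gap curve over k = 1..%d (k_hat = %d)\n", max(x$k), attr(x, "k_hat")))
  NextMethod()
}

#' @describeIn gap_statistic `autoplot()` draws the gap curve with
#'   reference-dispersion error bars and marks the argmax.
#' @param object A `gap_curve`.
#' @param ... Unused.
#' @export
autoplot.gap_curve <- function(object, ...) {
  k_hat <- attr(object, "k_hat")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$k, y = .data$gap)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$gap - .data$sd,
                                          ymax = .data$gap + .data$sd)) +
    ggplot2::geom_vline(xintercept = k_hat, linetype = "dashed") +
    ggplot2::labs(x = "number of clusters k", y = "Gap(k)",
                  title = sprintf("Gap statistic (k_hat = %d)", k_hat)) +
    ggplot2::theme_minimal()
}

#' @describeIn fuzzy_cmeans `autoplot()` shows the cluster centroid
#'   trajectories over time.
#' @export
autoplot.fcm_fit <- function(object, ...) {
  df <- tibble::tibble(
    cluster = factor(rep(seq_len(object$k), times = length(object$times))),
    time = rep(object$times, each = object$k),
    value = as.vector(object$centroids)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value,
                                   colour = .data$cluster)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time", y = "centroid expression (standardized)",
                  colour = "cluster") +
    ggplot2::theme_minimal()
}
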