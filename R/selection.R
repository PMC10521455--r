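#' Global distance-based ranks
#'
#' Rank 1 is the smallest distance over *all* genes, ties broken by input
#' order, so the result is a permutation of `1..N`. Cluster genes keep
#' their global ranks: a cluster gene can rank far beyond the cluster size
#' when genes from other clusters lie closer to the target curve, which is
#' exactly what the incremental Wilcoxon comparison probes.
#'
#' @param table A `distance_table` (or any data frame with a `distance`
#'   column).
#' @return Integer vector of ranks aligned with the rows.
#' @export
global_ranks <- function(table) {
  d <- table$distance
  if (any(!is.finite(d))) abort("distances must be finite")
  as.integer(rank(d, ties.method = "first"))
}

#' Two-sided Wilcoxon signed-rank test
#'
#' Paired signed-rank test on the differences `a - b`. Zero differences
#' are discarded before ranking (the classic reduced-sample treatment);
#' absolute differences are midranked. For effective sample size
#' `n <= 25` the p-value comes from the exact null distribution of the
#' positive-rank sum, computed by convolution over the (tie-aware)
#' midranks; above that, from the normal approximation with the usual tie
#' correction of the variance. If every difference is zero the p-value
#' is 1.
#'
#' @param a,b Paired numeric samples of equal length.
#' @return Two-sided p-value in `(0, 1]`.
#' @export
wilcoxon_signed_rank <- function(a, b) {
  if (length(a) != length(b)) {
    abort(sprintf("paired samples must have equal length, got %d and %d",
                  length(a), length(b)))
  }
  d <- as.numeric(a) - as.numeric(b)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) return(1)
  r <- rank(abs(d))
  w_pos <- sum(r[d > 0])
  if (n <= 25L) {
    # exact distribution of 2*W+ (doubled midranks are integers)
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    counts <- numeric(total + 1L)
    counts[1L] <- 1
    for (ri in r2) {
      counts <- counts + c(rep(0, ri), counts[seq_len(total + 1L - ri)])
    }
    probs <- counts / 2^n
    w2 <- as.integer(round(2 * w_pos))
    p_le <- sum(probs[seq_len(w2 + 1L)])
    p_ge <- sum(probs[(w2 + 1L):(total + 1L)])
    min(1, 2 * min(p_le, p_ge))
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w_pos - mu) / sqrt(sigma2)
    min(1, 2 * pnorm(-abs(z)))
  }
}

#' Number of significant cluster genes by incremental rank agreement
#'
#' The genes of the target's cluster, sorted by ascending distance to the
#' smoothed target, would have global ranks `1, 2, ..., n` if the cluster
#' held the n closest genes overall. Starting from `start` genes and
#' growing by `step`, the first `n` global ranks are tested against the
#' ordinal ranks `1..n` with [wilcoxon_signed_rank()]; while the two
#' rankings are statistically the same the window grows, and the first
#' significant `n` stops the scan. `n_sig` is the last non-significant
#' window (`n - step`); if no window is ever significant, the whole
#' cluster counts (`n_sig` = cluster size).
#'
#' @param cluster_global_ranks Integer global ranks of the cluster's genes,
#'   sorted by ascending distance.
#' @param start First window size (default 10).
#' @param step Window increment (default 1).
#' @param threshold Significance level (default 0.05).
#' @return List with `n_sig` and `p_trace`, a tibble of every tested
#'   `(n, p)`.
#' @export
significant_count <- function(cluster_global_ranks, start = 10L, step = 1L,
                              threshold = 0.05) {
  if (start < 2L) abort("start must be at least 2")
  if (threshold <= 0 || threshold >= 1) abort("threshold must be in (0, 1)")
  size <- length(cluster_global_ranks)
  if (size < start) {
    warn(sprintf("cluster has %d genes, fewer than start = %d; keeping all",
                 size, start))
    return(list(n_sig = size,
                p_trace = tibble::tibble(n = integer(), p = numeric())))
  }
  ns <- seq.int(start, size, by = step)
  if (tail(ns, 1L) < size) ns <- c(ns, size)
  ps <- numeric(0)
  n_sig <- size
  for (n in ns) {
    p <- wilcoxon_signed_rank(cluster_global_ranks[seq_len(n)], seq_len(n))
    ps <- c(ps, p)
    if (p < threshold) {
      n_sig <- n - step
      break
    }
  }
  list(n_sig = as.integer(n_sig),
       p_trace = tibble::tibble(n = ns[seq_along(ps)], p = ps))
}

#' Rescue near-target genes from other clusters
#'
#' Genes assigned to other clusters whose distance to the smoothed target
#' is within the range of the significant genes (at most the largest
#' significant distance, boundary inclusive) are kept, so relevant genes
#' are not lost to a soft cluster boundary.
#'
#' @param table A `distance_table` covering all genes.
#' @param labels Named integer hard cluster labels (see [hard_labels()]).
#' @param cluster_index The target's cluster.
#' @param significant_ids Non-empty character vector of significant gene
#'   ids.
#' @return Character vector of rescued gene ids, ordered by ascending
#'   distance.
#' @export
rescue_genes <- function(table, labels, cluster_index, significant_ids) {
  if (length(significant_ids) == 0L) {
    abort("no significant genes: nothing to define the rescue distance range")
  }
  cutoff <- max(table$distance[table$gene_id %in% significant_ids])
  outside <- table$gene_id[labels[table$gene_id] != cluster_index]
  cand <- table[table$gene_id %in% outside & table$distance <= cutoff, ]
  cand$gene_id[order(cand$distance)]
}

#' Select the target-relevant gene set
#'
#' Runs the full selection step: global ranks, the incremental Wilcoxon
#' scan over the target's cluster, and cross-cluster rescue.
#'
#' @inheritParams rescue_genes
#' @inheritParams significant_count
#' @return An object of class `selection_result`: `cluster_index`,
#'   `significant_ids` (ascending distance), `n_sig`, `p_trace`,
#'   `rescued_ids`, `threshold_distance`, plus the annotated `table`.
#' @export
select_significant_genes <- function(table, labels, cluster_index,
                                     start = 10L, step = 1L,
                                     threshold = 0.05) {
  table$rank <- global_ranks(table)
  in_cluster <- labels[table$gene_id] == cluster_index
  cl <- table[in_cluster, ]
  cl <- cl[order(cl$distance), ]
  sc <- significant_count(cl$rank, start = start, step = step,
                          threshold = threshold)
  significant_ids <- head(cl$gene_id, sc$n_sig)
  threshold_distance <- if (sc$n_sig > 0L) max(cl$distance[seq_len(sc$n_sig)]) else NA_real_
  rescued_ids <- if (sc$n_sig > 0L) {
    rescue_genes(table, labels, cluster_index, significant_ids)
  } else {
    character()
  }
  structure(
    list(cluster_index = as.integer(cluster_index),
         significant_ids = significant_ids,
         n_sig = sc$n_sig,
         p_trace = sc$p_trace,
         rescued_ids = rescued_ids,
         threshold_distance = threshold_distance,
         table = table),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("Selection from cluster %d: %d significant, %d rescued (cutoff %.4g)\n",
              x$cluster_index, x$n_sig, length(x$rescued_ids),
              x$threshold_distance))
  invisible(x)
}

#' @describeIn select_significant_genes `tidy()` returns one row per
#'   selected gene: `gene_id`, `distance`, `global_rank`, `status`
#'   (`"significant"` or `"rescued"`).
#' @param x,object A `selection_result`.
#' @param ... Unused.
#' @export
tidy.selection_result <- function(x, ...) {
  tbl <- x$table
  sel <- tibble::tibble(
    gene_id = c(x$significant_ids, x$rescued_ids),
    status = rep(c("significant", "rescued"),
                 c(length(x$significant_ids), length(x$rescued_ids)))
  )
  out <- dplyr::inner_join(sel,
                           tbl[c("gene_id", "distance", "rank")],
                           by = "gene_id")
  out <- dplyr::rename(out, global_rank = "rank")
  dplyr::arrange(out[c("gene_id", "distance", "global_rank", "status")],
                 .data$distance)
}

#' @describeIn select_significant_genes `glance()` returns a one-row
#'   summary.
#' @export
glance.selection_result <- function(x, ...) {
  tibble::tibble(cluster_index = x$cluster_index, n_sig = x$n_sig,
                 n_rescued = length(x$rescued_ids),
                 threshold_distance = x$threshold_distance,
                 n_tested = nrow(x$p_trace))
}

#' @describeIn select_significant_genes `autoplot()` shows the p-value
#'   trace of the incremental Wilcoxon scan.
#' @export
autoplot.selection_result <- function(object, ...) {
  ggplot2::ggplot(object$p_trace, ggplot2::aes(x = .data$n, y = .data$p)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::geom_hline(yintercept = 0.05, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = object$n_sig, colour = "#b2182b") +
    ggplot2::labs(x = "window size n", y = "Wilcoxon p-value",
                  title = sprintf("n_sig = %d", object$n_sig)) +
    ggplot2::theme_minimal()
}
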