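#' Lock-step Minkowski distance between two equal-length series
#'
#' \eqn{d_{L_n}(Y, Z) = (\sum_j |Y_j - Z_j|^n)^{1/n}}: values are compared
#' at identical time indices. `n = 1` is the Manhattan distance, `n = 2`
#' Euclidean, general `n` Minkowski.
#'
#' @param y,z Numeric sequences of equal length.
#' @param n Positive integer order.
#' @return A single non-negative distance.
#' @export
lockstep <- function(y, z, n = 2L) {
  if (length(y) != length(z)) {
    abort(sprintf("lock-step distance needs equal lengths, got %d and %d",
                  length(y), length(z)))
  }
  if (n < 1) abort("Minkowski order n must be a positive integer")
  sum(abs(y - z)^n)^(1 / n)
}

#' Dynamic time warping distance
#'
#' Minimum over all monotone, continuous warping paths
#' \eqn{p_1, \ldots, p_h} from \eqn{(1,1)} to \eqn{(t_Y, t_Z)} of the
#' normalized weighted path cost
#' \eqn{\sum_s d(p_s) w_s / \sum_s w_s}, with pointwise cost
#' \eqn{d(p_s) = |Y_{u_s} - Z_{v_s}|}. Step weights use the index-step
#' convention: `"symmetric"` weights diagonal moves 2 and axis moves 1
#' (normalizer \eqn{t_Y + t_Z}, symmetric in its arguments);
#' `"asymmetric"` weights each step by the advance of the `y` index
#' (normalizer \eqn{t_Y}). Unlike lock-step distances, the two series may
#' have different lengths.
#'
#' @param y,z Non-empty numeric sequences.
#' @param weighting `"symmetric"` (default) or `"asymmetric"`.
#' @return A single non-negative normalized distance; 0 iff a warping path
#'   of zero total cost exists.
#' @export
dtw_distance <- function(y, z, weighting = c("symmetric", "asymmetric")) {
  if (length(y) == 0L || length(z) == 0L) abort("dtw needs non-empty series")
  weighting <- match.arg(weighting)
  dtw_cost_cpp(as.numeric(y), as.numeric(z), weighting == "symmetric")
}

supported_metrics <- c("manhattan", "euclidean", "minkowski", "dtw")

#' Distance of every gene to the smoothed target curve
#'
#' Computes one distance per gene between its (standardized) trajectory and
#' the fitted target curve. Similarity to the *smoothed* target, rather
#' than to the noisy target itself, is what ranks candidate co-regulated
#' genes; the target gene itself is kept in the table (its distance to its
#' own smooth is typically positive).
#'
#' @param x An `expr_mat` (standardized scale recommended).
#' @param curve A `cgrf_smooth` fitted on the same time grid, or a numeric
#'   vector of length `T`.
#' @param metric One of `"manhattan"`, `"euclidean"`, `"minkowski"`,
#'   `"dtw"`.
#' @param minkowski_n Order for `metric = "minkowski"`.
#' @param dtw_weighting Weighting for `metric = "dtw"`.
#' @return A tibble of class `distance_table` with columns `gene_id`,
#'   `distance`, `rank` (global rank, 1 = closest, ties by row order), and
#'   attributes `metric` / `params`.
#' @export
compute_target_distances <- function(x, curve,
                                     metric = c("dtw", "manhattan",
                                                "euclidean", "minkowski"),
                                     minkowski_n = 3L,
                                     dtw_weighting = "symmetric") {
  x <- as_expression_matrix(x)
  if (length(metric) == 1L && !metric %in% supported_metrics) {
    abort(paste0("unsupported metric '", metric, "'; supported: ",
                 paste(supported_metrics, collapse = ", ")))
  }
  metric <- match.arg(metric)
  z <- if (inherits(curve, "cgrf_smooth")) curve$fitted else as.numeric(curve)
  vals <- em_values(x)
  if (length(z) != ncol(vals)) {
    abort(sprintf("curve length %d does not match the %d time points",
                  length(z), ncol(vals)))
  }
  f <- switch(metric,
    manhattan = function(y) lockstep(y, z, 1L),
    euclidean = function(y) lockstep(y, z, 2L),
    minkowski = function(y) lockstep(y, z, minkowski_n),
    dtw       = function(y) dtw_distance(y, z, dtw_weighting)
  )
  d <- apply(vals, 1L, f)
  params <- switch(metric,
    minkowski = list(n = minkowski_n),
    dtw = list(weighting = dtw_weighting),
    list()
  )
  out <- tibble::tibble(gene_id = x$gene_id, distance = unname(d))
  out$rank <- global_ranks(out)
  attr(out, "metric") <- metric
  attr(out, "params") <- params
  class(out) <- c("distance_table", class(out))
  out
}

#' @describeIn compute_target_distances `autoplot()` shows the distance
#'   distribution with the closest genes labelled by rank.
#' @param object A `distance_table`.
#' @param ... Unused.
#' @export
autoplot.distance_table <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$distance)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey30") +
    ggplot2::labs(x = paste0(attr(object, "metric"), " distance to smoothed target"),
                  y = "genes") +
    ggplot2::theme_minimal()
}
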