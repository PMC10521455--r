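#' Default planted regulatory core
#'
#' A 6-gene stable VAR(1) adjacency used by [simulate_dataset()]: every
#' gene is mildly autocorrelated (diagonal 0.3) and the target (first
#' core gene) is driven by two regulators with coefficients +0.5 and
#' -0.5; two further edges connect the remaining core genes. The matrix
#' is triangular, so its spectral radius is 0.3 and the process is
#' stable.
#'
#' @return A named 6 x 6 coefficient matrix, `A[i, j]` the effect of gene
#'   `j` at `t` on gene `i` at `t + 1`.
#' @export
default_core_adjacency <- function() {
  ids <- c("target", paste0("core", 2:6))
  A <- diag(0.3, 6L)
  A[1L, 2L] <- 0.5
  A[1L, 3L] <- -0.5
  A[4L, 5L] <- 0.5
  A[5L, 6L] <- -0.5
  dimnames(A) <- list(ids, ids)
  A
}

#' Simulate a time-course expression matrix with known structure
#'
#' Generates the study conditions every stage of the workflow is tested
#' against: a dense circadian-style time course (default 480 observations
#' over 24 h, mirroring a 3-minute sampling grid) in which
#' * background genes follow one of `n_clusters` archetype profiles —
#'   unit-variance sinusoids phased `2*pi*k/n_clusters` apart plus one
#'   monotone trend archetype — with i.i.d. Gaussian observation noise;
#' * a small regulatory core follows a stable VAR(1) process
#'   \eqn{x(t+1) = A x(t) + \epsilon}, superimposed on the first
#'   archetype so the core (including the target, core gene 1) clusters
#'   with the target-like background genes.
#'
#' @param n_genes Total genes (background + core).
#' @param n_times Number of time points.
#' @param n_clusters Number of background archetypes (>= 1).
#' @param core_adjacency Stable VAR(1) coefficient matrix for the core,
#'   or `NULL` for a background-only dataset.
#' @param noise_sd Standard deviation of both the observation noise on
#'   background genes and the VAR innovations.
#' @param seed Integer seed; identical seeds give identical matrices.
#' @return A list with `matrix` (an `expr_mat`) and `truth`, a list with
#'   `cluster_labels` (named integer vector), `target_id`, `core_ids`,
#'   `core_adjacency`, `noise_sd`, `seed`.
#' @export
simulate_dataset <- function(n_genes = 200L, n_times = 480L, n_clusters = 4L,
                             core_adjacency = default_core_adjacency(),
                             noise_sd = 0.5, seed = 1L) {
  if (n_clusters < 1L) abort("n_clusters must be at least 1")
  p_core <- if (is.null(core_adjacency)) 0L else nrow(core_adjacency)
  if (p_core > 0L) {
    radius <- max(Mod(eigen(core_adjacency, only.values = TRUE)$values))
    if (radius >= 1) {
      abort(sprintf("core adjacency is unstable (spectral radius %.3f >= 1)", radius))
    }
  }
  n_bg <- n_genes - p_core
  if (n_bg < n_clusters) {
    abort("n_genes must cover n_clusters background archetypes plus the core")
  }
  times <- seq_len(n_times) * 24 / n_times

  archetype <- function(k) {
    prof <- if (n_clusters >= 2L && k == n_clusters) {
      times                                   # monotone trend
    } else {
      sin(2 * pi * times / 24 + 2 * pi * (k - 1) / n_clusters)
    }
    (prof - mean(prof)) / sd(prof)
  }
  arch <- t(vapply(seq_len(n_clusters), archetype, numeric(n_times)))

  with_seed(seed, {
    labels_bg <- rep(seq_len(n_clusters), length.out = n_bg)
    bg <- arch[labels_bg, , drop = FALSE] +
      matrix(rnorm(n_bg * n_times, sd = noise_sd), n_bg, n_times)
    bg_ids <- sprintf("g%04d", seq_len(n_bg))

    if (p_core > 0L) {
      burn <- 100L
      xs <- matrix(0, p_core, n_times + burn)
      for (t in seq_len(n_times + burn - 1L)) {
        xs[, t + 1L] <- core_adjacency %*% xs[, t] +
          rnorm(p_core, sd = noise_sd)
      }
      core_vals <- matrix(arch[1L, ], p_core, n_times, byrow = TRUE) +
        xs[, burn + seq_len(n_times), drop = FALSE]
      core_ids <- rownames(core_adjacency) %||% paste0("core", seq_len(p_core))
      values <- rbind(bg, core_vals)
      ids <- c(bg_ids, core_ids)
      labels <- c(labels_bg, rep(1L, p_core))
    } else {
      values <- bg
      ids <- bg_ids
      labels <- labels_bg
      core_ids <- character()
    }

    list(
      matrix = expression_matrix(values, ids, times),
      truth = list(
        cluster_labels = setNames(as.integer(labels), ids),
        target_id = if (p_core > 0L) core_ids[1L] else NA_character_,
        core_ids = core_ids,
        core_adjacency = core_adjacency,
        noise_sd = noise_sd,
        seed = as.integer(seed)
      )
    )
  })
}

#' Planted regulators of the simulated target
#'
#' Reads the nonzero off-diagonal entries of the first row of the planted
#' core adjacency: the genes whose past values directly drive the target.
#'
#' @param truth The `truth` element returned by [simulate_dataset()].
#' @return Character vector of regulator gene ids.
#' @export
planted_regulators <- function(truth) {
  A <- truth$core_adjacency
  if (is.null(A)) return(character())
  src <- which(A[1L, ] != 0)
  truth$core_ids[setdiff(src, 1L)]
}
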