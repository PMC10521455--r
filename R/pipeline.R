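#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end workflow. `"auto"` fields are
#' resolved by their owning stage: `k` by the Gap-statistic argmax,
#' `fuzzifier` by [estimate_fuzzifier()], `alpha` by [select_alpha()] over
#' its default grid.
#'
#' @param input Path to a delimited expression matrix, or an `expr_mat`.
#' @param target Target gene identifier.
#' @param k Number of clusters, or `"auto"`.
#' @param fuzzifier Fuzzy C-means fuzzifier, or `"auto"`.
#' @param degree Smoothing polynomial degree (0, 1 or 2).
#' @param alpha Smoothing neighbourhood parameter, or `"auto"`.
#' @param metric Distance metric: `"dtw"`, `"manhattan"`, `"euclidean"`,
#'   `"minkowski"`.
#' @param minkowski_n Minkowski order (used when `metric = "minkowski"`).
#' @param dtw_weighting `"symmetric"` or `"asymmetric"`.
#' @param start,step,p_threshold Incremental Wilcoxon controls
#'   (see [significant_count()]).
#' @param network_mode `"var"`, `"dynamic"` or `"both"`.
#' @param top_edges Number of edges to keep per network mode.
#' @param shrinkage Shrinkage intensity for the dynamic partial
#'   correlation (0 = none).
#' @param k_max,gap_b Gap-statistic search range and reference count,
#'   used when `k = "auto"`.
#' @param seed Integer seed for all stochastic stages.
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(input, target, k = "auto", fuzzifier = "auto",
                            degree = 2L, alpha = "auto", metric = "dtw",
                            minkowski_n = 3L, dtw_weighting = "symmetric",
                            start = 10L, step = 1L, p_threshold = 0.05,
                            network_mode = "both", top_edges = 150L,
                            shrinkage = 0, k_max = 10L, gap_b = 10L,
                            seed = 1L, out_dir = NULL) {
  if (!identical(k, "auto")) k <- as.integer(k)
  structure(
    list(input = input, target = target, k = k, fuzzifier = fuzzifier,
         degree = as.integer(degree), alpha = alpha, metric = metric,
         minkowski_n = as.integer(minkowski_n),
         dtw_weighting = dtw_weighting, start = as.integer(start),
         step = as.integer(step), p_threshold = p_threshold,
         network_mode = network_mode, top_edges = as.integer(top_edges),
         shrinkage = shrinkage, k_max = as.integer(k_max),
         gap_b = as.integer(gap_b), seed = as.integer(seed),
         out_dir = out_dir),
    class = "pipeline_config"
  )
}

#' Read a flat key: value configuration file
#'
#' One `key: value` pair per line; blank lines and `#` comments are
#' ignored. Values parseable as numbers are coerced; everything else
#' (paths, `"auto"`, metric names) stays character. The same format is
#' written back as the run manifest, so a manifest re-reads as a config.
#'
#' @param path Configuration file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexec("^([^:]+):\\s*(.*)$", lines))
  bad <- vapply(kv, length, integer(1)) != 3L
  if (any(bad)) abort(paste0("malformed config line: ", lines[bad][1L]))
  keys <- vapply(kv, `[`, character(1), 2L)
  vals <- vapply(kv, `[`, character(1), 3L)
  parsed <- lapply(vals, function(v) {
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  names(parsed) <- trimws(keys)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(parsed), known)
  if (length(unknown) > 0L) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  do.call(pipeline_config, parsed)
}

#' Run the full target-gene workflow
#'
#' Executes the whole inference chain: zero-variance filtering, per-gene
#' standardization, fuzzy C-means clustering, selection of the target's
#' cluster, tricube local-polynomial smoothing of the target, distances
#' of every gene to the smoothed curve, the incremental Wilcoxon
#' selection with cross-cluster rescue, and VAR(1) / dynamic
#' partial-correlation network inference over the selected genes (the
#' target is force-included). With `out_dir` set, every stage's table is
#' written as TSV along with a `manifest.txt` of all resolved parameters;
#' the manifest re-read as a config reproduces the run exactly.
#'
#' @param config A `pipeline_config`.
#' @param quiet Suppress stage-by-stage progress messages?
#' @return An object of class `cgrf_run`: the resolved `config` and the
#'   stage results (`removed`, `clustering`, `gap` or NULL,
#'   `cluster_index`, `smooth`, `distances`, `selection`, `network_ids`,
#'   `var`, `lagged_pcor`, `edges`).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(sprintf(...))

  x <- if (inherits(config$input, "expr_mat")) {
    config$input
  } else {
    read_expression_matrix(config$input)
  }
  say("input: %d genes x %d time points", nrow(x), ncol(x) - 1L)

  filt <- filter_zero_variance(x)
  say("zero-variance filter: removed %d, kept %d genes",
      length(filt$removed), nrow(filt$matrix))
  if (!config$target %in% filt$matrix$gene_id) {
    abort(paste0("stage filter: target gene '", config$target,
                 "' absent after zero-variance filtering"))
  }
  std <- standardize_genes(filt$matrix)

  m <- if (identical(config$fuzzifier, "auto")) {
    estimate_fuzzifier(nrow(std), ncol(std) - 1L)
  } else as.numeric(config$fuzzifier)

  gap <- NULL
  k <- if (identical(config$k, "auto")) {
    gap <- gap_statistic(std, k_max = config$k_max, b = config$gap_b,
                         m = m, seed = config$seed)
    say("gap statistic: k_hat = %d", attr(gap, "k_hat"))
    attr(gap, "k_hat")
  } else as.integer(config$k)

  fit <- withCallingHandlers(
    fuzzy_cmeans(std, k = k, m = m, seed = config$seed),
    error = function(e) abort(paste0("stage cluster: ", conditionMessage(e)))
  )
  cluster_index <- select_cluster_of(fit, config$target)
  labels <- hard_labels(fit)
  say("clustering: k = %d, m = %.4f; target in cluster %d (%d genes)",
      k, m, cluster_index, sum(labels == cluster_index))

  y <- as.numeric(em_values(std)[config$target, ])
  tms <- em_times(std)
  smooth <- if (identical(config$alpha, "auto")) {
    search <- select_alpha(y, tms, degree = config$degree)
    say("smoothing: GCV selected alpha = %g", search$alpha_star)
    search$fit
  } else {
    loess_fit(y, tms, alpha = as.numeric(config$alpha),
              degree = config$degree)
  }

  distances <- tryCatch(
    compute_target_distances(std, smooth, metric = config$metric,
                             minkowski_n = config$minkowski_n,
                             dtw_weighting = config$dtw_weighting),
    error = function(e) abort(paste0("stage distance: ", conditionMessage(e)))
  )

  selection <- select_significant_genes(distances, labels, cluster_index,
                                        start = config$start,
                                        step = config$step,
                                        threshold = config$p_threshold)
  say("selection: %d significant, %d rescued",
      selection$n_sig, length(selection$rescued_ids))

  network_ids <- unique(c(config$target, selection$significant_ids,
                          selection$rescued_ids))
  x_sel <- as_expression_matrix(std[match(network_ids, std$gene_id), ])
  say("network: %d genes enter the VAR stage", length(network_ids))

  var_fit <- NULL
  lagged <- NULL
  edges <- NULL
  if (config$network_mode %in% c("var", "both")) {
    var_fit <- fit_var1(x_sel)
    lagged <- lagged_pcor_matrix(x_sel)
    e1 <- top_edges(lagged, n_top = config$top_edges, directed = TRUE)
    e1$type <- "lagged"
    edges <- e1
  }
  if (config$network_mode %in% c("dynamic", "both")) {
    rho <- dynamic_correlation_matrix(x_sel)
    pc <- dynamic_partial_correlation(rho, shrinkage = config$shrinkage)
    e2 <- top_edges(pc, n_top = config$top_edges, directed = FALSE)
    e2$type <- "dynamic"
    edges <- if (is.null(edges)) e2 else dplyr::bind_rows(edges, e2)
  }

  run <- structure(
    list(config = resolve_config(config, k = k, m = m,
                                 alpha = smooth$alpha),
         removed = filt$removed, clustering = fit, gap = gap,
         cluster_index = cluster_index, smooth = smooth,
         distances = distances, selection = selection,
         network_ids = network_ids, var = var_fit,
         lagged_pcor = lagged, edges = edges),
    class = "cgrf_run"
  )
  if (!is.null(config$out_dir)) write_run(run, config$out_dir)
  run
}

resolve_config <- function(config, k, m, alpha) {
  config$k <- as.integer(k)
  config$fuzzifier <- m
  config$alpha <- alpha
  config
}

#' @export
print.cgrf_run <- function(x, ...) {
  cat(sprintf(
    "cgrf run: target '%s', k = %d, %d significant + %d rescued genes, %d edges\n",
    x$config$target, x$config$k, x$selection$n_sig,
    length(x$selection$rescued_ids),
    if (is.null(x$edges)) 0L else nrow(x$edges)))
  invisible(x)
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- run$config
  num <- function(v) {
    if (is.numeric(v)) format(v, digits = 17L, trim = TRUE, scientific = FALSE) else as.character(v)
  }
  manifest_keys <- setdiff(names(cfg), c("input", "out_dir"))
  manifest <- c(
    paste0("input: ", if (inherits(cfg$input, "expr_mat")) "<in-memory matrix>" else cfg$input),
    vapply(manifest_keys, function(kk) paste0(kk, ": ", num(cfg[[kk]])), character(1))
  )
  writeLines(manifest, file.path(out_dir, "manifest.txt"))

  wt <- function(df, name) readr::write_tsv(df, file.path(out_dir, name), progress = FALSE)

  fit <- run$clustering
  memb <- tibble::as_tibble(t(fit$memberships), .name_repair = "minimal")
  names(memb) <- paste0("cluster", seq_len(fit$k))
  wt(dplyr::bind_cols(tibble::tibble(gene_id = fit$gene_ids), memb),
     "memberships.tsv")
  cent <- tibble::as_tibble(fit$centroids, .name_repair = "minimal")
  names(cent) <- format_times(fit$times)
  wt(dplyr::bind_cols(tibble::tibble(cluster = seq_len(fit$k)), cent),
     "centroids.tsv")
  if (!is.null(run$gap)) wt(tibble::as_tibble(run$gap), "gap.tsv")
  wt(tidy(run$smooth), "smooth.tsv")
  wt(tibble::as_tibble(run$distances), "distances.tsv")
  wt(tidy(run$selection), "selection.tsv")
  wt(run$selection$p_trace, "p_trace.tsv")
  if (!is.null(run$var)) {
    Atab <- tibble::as_tibble(run$var$A, .name_repair = "minimal")
    wt(dplyr::bind_cols(tibble::tibble(gene_id = run$var$gene_ids), Atab),
       "A-matrix.tsv")
  }
  if (!is.null(run$edges)) wt(tibble::as_tibble(run$edges), "edges.tsv")
  invisible(run)
}
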