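test_that("fuzzifier estimate exceeds 1, matches its closed form, and shrinks with dimension", {
  for (case in list(c(10, 5), c(1000, 100), c(2, 1))) {
    expect_gt(estimate_fuzzifier(case[1], case[2]), 1)
  }
  # frozen evaluation of the implemented closed form at the full-data scale
  expect_equal(estimate_fuzzifier(17879, 480), 1.010493098204, tolerance = 1e-10)
  expect_lte(estimate_fuzzifier(100, 1000), estimate_fuzzifier(100, 10))
  expect_error(estimate_fuzzifier(1, 10), "n_genes")
  expect_error(estimate_fuzzifier(10, 0), "n_timepoints")
})

test_that("k = 1 collapses to the column mean with unit memberships", {
  em <- expression_matrix(matrix(rnorm(30), 5L), letters[1:5], 1:6)
  fit <- fuzzy_cmeans(em, k = 1, m = 1.5, seed = 1)
  expect_equal(as.vector(fit$centroids), unname(colMeans(as.matrix(em[-1]))),
               tolerance = 1e-12)
  expect_equal(as.vector(fit$memberships), rep(1, 5))
})

test_that("a gene equidistant from two symmetric centroids gets membership 1/2", {
  # two tight mirrored groups and one gene exactly between them
  vals <- rbind(c(1, 1), c(1, 1), c(-1, -1), c(-1, -1), c(0, 0))
  em <- expression_matrix(vals, c("p1", "p2", "m1", "m2", "mid"), 1:2)
  fit <- fuzzy_cmeans(em, k = 2, m = 1.5, seed = 4, tol = 1e-13,
                      max_iter = 2000)
  expect_equal(sort(fit$memberships[, 5]), c(0.5, 0.5), tolerance = 1e-3)
})

test_that("planted archetypes are recovered and the objective never increases", {
  blobs <- two_blob_matrix(n_per = 50, noise_sd = 0.1, seed = 2)
  fit <- fuzzy_cmeans(blobs$em, k = 2, m = 1.5, seed = 3)
  side <- hard_labels(fit)
  expect_equal(permutation_accuracy(unname(side), blobs$labels), 1)
  expect_true(all(diff(fit$objective_trace) <= 1e-8))
  expect_lt(max(abs(colSums(fit$memberships) - 1)), 1e-9)
})

test_that("membership columns sum to 1 and traces are monotone across seeded runs", {
  blobs <- two_blob_matrix(n_per = 20, t_obs = 12, noise_sd = 0.4, seed = 5)
  for (s in 1:5) {
    fit <- fuzzy_cmeans(blobs$em, k = 3, m = 1.3, seed = s)
    expect_lt(max(abs(colSums(fit$memberships) - 1)), 1e-9)
    expect_true(all(diff(fit$objective_trace) <= 1e-8))
  }
})

test_that("identical seeds give identical fits; invalid arguments error", {
  blobs <- two_blob_matrix(n_per = 10, t_obs = 8, seed = 6)
  f1 <- fuzzy_cmeans(blobs$em, k = 2, m = 1.5, seed = 11)
  f2 <- fuzzy_cmeans(blobs$em, k = 2, m = 1.5, seed = 11)
  expect_identical(f1$memberships, f2$memberships)
  expect_identical(f1$centroids, f2$centroids)
  expect_error(fuzzy_cmeans(blobs$em, k = 100, m = 1.5), "k must be in")
  expect_error(fuzzy_cmeans(blobs$em, k = 2, m = 1.5, tol = 0), "tol")
  expect_error(fuzzy_cmeans(blobs$em, k = 2, m = 1), "fuzzifier")
})

test_that("noiseless duplicated archetypes are partitioned perfectly", {
  tt <- 1:16
  a1 <- scale(sin(2 * pi * tt / 16))[, 1]
  a2 <- scale(cos(2 * pi * tt / 16))[, 1]
  a3 <- scale(tt)[, 1]
  vals <- rbind(a1, a1, a1, a2, a2, a2, a3, a3, a3)
  em <- expression_matrix(vals, paste0("g", 1:9), tt)
  fit <- fuzzy_cmeans(em, k = 3, m = 2, seed = 8)
  lab <- unname(hard_labels(fit))
  expect_equal(permutation_accuracy(lab, rep(1:3, each = 3)), 1)
})

test_that("the target's cluster is the membership argmax with smallest-index ties", {
  blobs <- two_blob_matrix(n_per = 5, t_obs = 8, seed = 7)
  fit <- fuzzy_cmeans(blobs$em, k = 2, m = 1.5, seed = 2)
  i <- 3L
  expect_identical(select_cluster_of(fit, fit$gene_ids[i]),
                   which.max(fit$memberships[, i]))
  fit$memberships[, i] <- c(0.5, 0.5)
  expect_identical(select_cluster_of(fit, fit$gene_ids[i]), 1L)
  expect_error(select_cluster_of(fit, "nope"), "not present")
})

test_that("gap statistic prefers the planted number of clusters", {
  # single low-dimensional blob: argmax gap = 1 in >= 80% of seeds
  one <- vapply(1:20, function(s) {
    set.seed(s + 100)
    em <- expression_matrix(matrix(rnorm(100), 50, 2), paste0("g", 1:50), 1:2)
    g <- gap_statistic(em, k_max = 4, b = 20, m = 1.5, seed = s)
    attr(g, "k_hat") == 1L
  }, logical(1))
  expect_gte(mean(one), 0.8)

  three <- vapply(1:20, function(s) {
    set.seed(s + 200)
    centers <- matrix(rnorm(3 * 8, sd = 4), 3, 8)
    v <- centers[rep(1:3, each = 15), ] + matrix(rnorm(45 * 8, sd = 0.5), 45)
    em <- expression_matrix(v, paste0("g", 1:45), 1:8)
    g <- gap_statistic(em, k_max = 5, b = 10, m = 1.5, seed = s)
    attr(g, "k_hat") == 3L
  }, logical(1))
  expect_gte(mean(three), 0.8)
})

test_that("gap statistic is reproducible under a seed and validates b", {
  em <- expression_matrix(matrix(rnorm(60), 20, 3), paste0("g", 1:20), 1:3)
  g1 <- gap_statistic(em, k_max = 3, b = 5, m = 1.5, seed = 9)
  g2 <- gap_statistic(em, k_max = 3, b = 5, m = 1.5, seed = 9)
  expect_identical(g1$gap, g2$gap)
  expect_identical(attr(g1, "k_hat"), attr(g2, "k_hat"))
  expect_true(attr(g1, "k_hat") %in% g1$k)
  expect_error(gap_statistic(em, k_max = 3, b = 0), "b")
})
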