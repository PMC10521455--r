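test_that("global ranks order by distance with first-come tie-breaks", {
  tbl <- tibble::tibble(gene_id = c("a", "b", "c"), distance = c(0.3, 0.1, 0.2))
  expect_identical(global_ranks(tbl), c(3L, 1L, 2L))
  ties <- tibble::tibble(gene_id = letters[1:4], distance = rep(1, 4))
  expect_identical(global_ranks(ties), 1:4)
  expect_identical(global_ranks(tibble::tibble(gene_id = "x", distance = 5)), 1L)
})

test_that("signed-rank p-values match exact enumeration for small n", {
  expect_equal(wilcoxon_signed_rank(1:5, 1:5), 1)
  expect_equal(wilcoxon_signed_rank(1:6, 2:7), 2 / 2^6)
  set.seed(51)
  for (rep in 1:60) {
    n <- sample(2:12, 1)
    a <- sample(1:8, n, replace = TRUE)
    b <- sample(1:8, n, replace = TRUE)
    expect_equal(wilcoxon_signed_rank(a, b), wilcoxon_enum_oracle(a, b),
                 tolerance = 1e-12)
  }
  expect_error(wilcoxon_signed_rank(1:3, 1:4), "equal length")
})

test_that("signed-rank test agrees with the stats package on tie-free data", {
  set.seed(52)
  for (rep in 1:10) {
    a <- rnorm(15); b <- rnorm(15)
    expect_equal(wilcoxon_signed_rank(a, b),
                 stats::wilcox.test(a, b, paired = TRUE, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
  # large-sample branch stays close to the stats normal approximation
  set.seed(53)
  a <- rnorm(60); b <- rnorm(60, mean = 0.3)
  ours <- wilcoxon_signed_rank(a, b)
  ref <- stats::wilcox.test(a, b, paired = TRUE, exact = FALSE,
                            correct = FALSE)$p.value
  expect_equal(ours, ref, tolerance = 1e-10)
})

test_that("perfectly agreeing rankings keep the whole cluster", {
  sc <- significant_count(1:60)
  expect_identical(sc$n_sig, 60L)
  expect_true(all(sc$p_trace$p == 1))
})

test_that("a planted rank break is located near the true boundary", {
  set.seed(9)
  r <- 1:40
  for (i in seq(1, 39, by = 8)) r[c(i, i + 1)] <- r[c(i + 1, i)]
  ranks <- c(r, sample(1001:3000, 30))
  sc <- significant_count(ranks)
  expect_gte(sc$n_sig, 35)
  expect_lte(sc$n_sig, 45)
  expect_true(all(sc$p_trace$n >= 10))
})

test_that("clusters smaller than the start window are kept whole with a warning", {
  expect_warning(sc <- significant_count(c(1L, 2L, 3L)), "fewer than start")
  expect_identical(sc$n_sig, 3L)
})

test_that("appending far-ranked genes never increases the significant count", {
  set.seed(54)
  base <- sample(1:50)
  sc1 <- significant_count(base)
  for (extra in c(10, 30)) {
    sc2 <- significant_count(c(base, sample(5000:9000, extra)))
    expect_lte(sc2$n_sig, sc1$n_sig + 0L)
  }
})

test_that("rescue keeps outside genes within the significant distance range", {
  tbl <- tibble::tibble(
    gene_id = c("s1", "s2", "out_in", "out_eq", "out_far"),
    distance = c(0.1, 0.5, 0.3, 0.5, 0.9)
  )
  labels <- setNames(c(1L, 1L, 2L, 2L, 3L), tbl$gene_id)
  resc <- rescue_genes(tbl, labels, 1L, c("s1", "s2"))
  expect_identical(resc, c("out_in", "out_eq"))   # inclusive boundary
  none <- rescue_genes(tbl[tbl$gene_id != "out_in" & tbl$gene_id != "out_eq", ],
                       labels, 1L, c("s1", "s2"))
  expect_identical(none, character(0))
  expect_error(rescue_genes(tbl, labels, 1L, character(0)), "significant")
})

test_that("selection is a distance-threshold superset across clusters", {
  set.seed(55)
  n <- 120
  tbl <- tibble::tibble(gene_id = sprintf("g%03d", 1:n), distance = runif(n))
  labels <- setNames(sample(1:3, n, replace = TRUE), tbl$gene_id)
  sel <- select_significant_genes(tbl, labels, cluster_index = 1L)
  expect_identical(sel$n_sig, length(sel$significant_ids))
  expect_true(all(labels[sel$significant_ids] == 1L))
  expect_true(all(labels[sel$rescued_ids] != 1L))
  expect_true(all(tbl$distance[tbl$gene_id %in% sel$rescued_ids] <=
                    sel$threshold_distance))
  # every gene anywhere within the threshold is either significant or rescued
  within <- tbl$gene_id[tbl$distance <= sel$threshold_distance]
  expect_true(all(within %in% c(sel$significant_ids, sel$rescued_ids)))
  out <- tidy(sel)
  expect_identical(sort(unique(out$status)), c("rescued", "significant"))
  expect_true(!is.unsorted(out$distance))
})
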