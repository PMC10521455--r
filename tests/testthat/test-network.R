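test_that("VAR(1) solves a two-equation scalar system exactly", {
  fit <- fit_var1(expression_matrix(matrix(c(1, 2, 4), 1), "g", 1:3))
  expect_equal(unname(fit$A[1, 1]), 2, tolerance = 1e-12)
  expect_equal(unname(fit$B[1]), 0, tolerance = 1e-12)
})

test_that("a noiseless planted system is recovered to machine precision", {
  A <- matrix(c(0.5, 0, 0.3, 0.2), 2, 2, byrow = TRUE)
  x <- matrix(0, 2, 50); x[, 1] <- c(1, -0.7)
  for (t in 1:49) x[, t + 1] <- A %*% x[, t]
  fit <- fit_var1(expression_matrix(x, c("a", "b"), 1:50))
  expect_lt(max(abs(fit$A - A)), 1e-6)
  expect_lt(max(abs(fit$B)), 1e-6)
  expect_false(fit$rank_deficient)
  # residual covariance symmetric positive semidefinite
  expect_equal(fit$residual_cov, t(fit$residual_cov))
  expect_gte(min(eigen(fit$residual_cov, only.values = TRUE)$values), -1e-8)
})

test_that("a pure-intercept process fits near-zero dynamics", {
  set.seed(61)
  x <- matrix(3 + rnorm(2 * 200, sd = 0.1), 2, 200)
  fit <- fit_var1(expression_matrix(x, c("a", "b"), 1:200))
  # intercept SE ~ sd * sqrt(xbar^2 / sum((x - xbar)^2)) ~ 0.21 here
  expect_lt(max(abs(fit$A)), 0.25)           # coefficients near zero
  expect_lt(max(abs(fit$B - 3)), 3 * 0.25)   # intercept within ~3 SE
  expect_error(fit_var1(expression_matrix(matrix(1:2, 1), "g", 1:2)), "3 time points")
  expect_error(fit_var1(expression_matrix(rbind(c(1, 1, 1), c(1, 2, 1)),
                                          c("flat", "x"), 1:3)), "constant")
})

test_that("independent noise genes have small lagged partial correlations", {
  set.seed(62)
  x <- matrix(rnorm(5 * 400), 5, 400)
  em <- expression_matrix(x, paste0("g", 1:5), 1:400)
  P <- lagged_pcor_matrix(em)
  expect_lt(max(abs(P[row(P) != col(P)])), 0.15)
  expect_true(all(abs(P) <= 1 + 1e-12))
})

test_that("a planted lagged driver is detected with high partial correlation", {
  set.seed(63)
  n <- 300
  y2 <- rnorm(n + 1)
  y3 <- rnorm(n + 1)
  y1 <- c(0, y2[1:n]) + rnorm(n + 1, sd = 0.05)
  em <- expression_matrix(rbind(y1, y2, y3), c("y1", "y2", "y3"), 1:(n + 1))
  expect_gt(lagged_partial_correlation(em, "y1", "y2"), 0.9)
})

test_that("the vectorized lagged partial correlation matches the two regressions", {
  set.seed(64)
  for (rep in 1:5) {
    x <- matrix(rnorm(4 * 50), 4, 50)
    em <- expression_matrix(x, paste0("g", 1:4), 1:50)
    P <- lagged_pcor_matrix(em)
    for (i in 1:4) for (k in 1:4) {
      if (i == k) next
      expect_equal(P[i, k], lagged_partial_correlation(em, i, k),
                   tolerance = 1e-10)
    }
  }
})

test_that("top lagged edges recover a sparse planted network", {
  prec <- vapply(1:5, function(s) {
    g <- gen_sparse_var(s)
    lagged_edge_precision(g$A, g$x, n_top = 10)
  }, numeric(1))
  expect_gte(mean(prec), 0.8)
})

test_that("the functional inner product is symmetric, bilinear and well weighted", {
  set.seed(65)
  g <- rnorm(20); h <- rnorm(20)
  expect_equal(dynamic_inner_product(g, h), dynamic_inner_product(h, g),
               tolerance = 1e-12)
  expect_equal(dynamic_inner_product(g, rep(0, 20)), 0)
  a <- rnorm(20)
  expect_equal(dynamic_inner_product(g + h, a),
               dynamic_inner_product(g, a) + dynamic_inner_product(h, a),
               tolerance = 1e-12)
  # uniform unit spacing: interior weights 1/T, end weights 1/(2T)
  ones <- rep(1, 5)
  expect_equal(dynamic_inner_product(ones, ones, 1:5),
               (0.5 + 1 + 1 + 1 + 0.5) / 5)
  expect_error(dynamic_inner_product(1:3, 1:4), "equal length")
})

test_that("dynamic correlations have unit diagonal, antisymmetry and orthogonality", {
  tt <- seq(0, 2 * pi, length.out = 401)[-1]
  f <- sin(tt) + 0.3 * cos(3 * tt)
  em <- expression_matrix(rbind(f, -f, cos(tt)), c("f", "mf", "c"), tt)
  rho <- dynamic_correlation_matrix(em)
  expect_lt(max(abs(diag(rho) - 1)), 1e-10)
  expect_equal(rho[1, 2], -1, tolerance = 1e-10)
  em2 <- expression_matrix(rbind(sin(tt), cos(tt)), c("s", "c"), tt)
  expect_lt(abs(dynamic_correlation_matrix(em2)[1, 2]), 0.05)
  expect_error(dynamic_correlation_matrix(
    expression_matrix(rbind(rep(1, 10), rnorm(10)), c("k", "x"), 1:10)),
    "constant")
})

test_that("dynamic correlation approaches Pearson correlation on uniform grids", {
  set.seed(66)
  sm <- matrix(rnorm(4 * 2000), 4, 2000)
  for (i in 1:4) {
    f <- stats::filter(sm[i, ], rep(1 / 25, 25), sides = 2)
    f[is.na(f)] <- 0
    sm[i, ] <- f + rnorm(2000, sd = 0.05)
  }
  em <- expression_matrix(sm, paste0("g", 1:4), 1:2000)
  expect_lt(max(abs(dynamic_correlation_matrix(em) - cor(t(sm)))), 0.02)
})

test_that("partial correlations from a correlation matrix behave", {
  expect_equal(dynamic_partial_correlation(diag(3)), diag(3))
  r <- 0.6
  c2 <- matrix(c(1, r, r, 1), 2)
  expect_equal(dynamic_partial_correlation(c2)[1, 2], r, tolerance = 1e-12)
  # residual-correlation oracle on a 3-variable sample correlation
  set.seed(67)
  x <- matrix(rnorm(3 * 200), 200, 3)
  C <- cor(x)
  pc <- dynamic_partial_correlation(C)
  res1 <- residuals(lm(x[, 1] ~ x[, 3]))
  res2 <- residuals(lm(x[, 2] ~ x[, 3]))
  expect_equal(pc[1, 2], cor(res1, res2), tolerance = 1e-10)
  sing <- matrix(1, 3, 3)
  expect_error(dynamic_partial_correlation(sing), "shrinkage")
  expect_silent(dynamic_partial_correlation(sing, shrinkage = 0.5))
})

test_that("edges are ranked by absolute weight with documented tie-breaks", {
  w <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  w[2, 1] <- 0.9   # a -> b
  w[3, 2] <- -0.8  # b -> c
  e <- top_edges(w, n_top = 2, directed = TRUE)
  expect_identical(e$source, c("a", "b"))
  expect_identical(e$target, c("b", "c"))
  expect_identical(e$sign, c("+", "-"))
  expect_identical(e$rank, 1:2)
  all_e <- top_edges(w, n_top = 100, directed = TRUE)
  expect_identical(nrow(all_e), 6L)   # self-loops excluded
  wt <- matrix(0.5, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  et <- top_edges(wt, n_top = 2, directed = TRUE)
  expect_identical(et$source, c("a", "b"))  # lexicographic on ties
  und <- top_edges(wt, n_top = 10, directed = FALSE)
  expect_identical(nrow(und), 1L)
})
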