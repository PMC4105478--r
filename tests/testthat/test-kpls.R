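test_that("label encoding centers the one-hot indicator", {
  Y <- encode_labels(c("A", "A", "B", "B"))
  expect_equal(dim(Y), c(4L, 2L))
  expect_true(all(abs(colSums(Y)) < 1e-12))
  expect_true(all(abs(abs(unclass(Y)) - 0.5) < 1e-12))

  Y3 <- encode_labels(rep(c("A", "B", "C"), each = 2))
  expect_equal(dim(Y3), c(6L, 3L))
  expect_true(all(abs(colSums(Y3)) < 1e-12))

  # unbalanced classes: column 1 is the centered [1,1,1,0,0]
  Y4 <- encode_labels(c("A", "A", "A", "B", "B"))
  expect_equal(unname(unclass(Y4)[, 1]), c(0.4, 0.4, 0.4, -0.6, -0.6))

  expect_error(encode_labels(rep("A", 4)), "2 distinct classes")
  expect_error(encode_labels(c("A", "A", "B")), "at least 2 samples")
})

test_that("two-class extraction closes in one pass at the rank-one fixed point", {
  set.seed(21)
  X <- matrix(rnorm(8 * 6), 8, 6)
  labels <- rep(c("a", "b"), each = 4)
  K <- center_gram(compute_gram(X, "linear"))
  Y <- encode_labels(labels)
  comp <- extract_component(K, Y)
  expect_equal(sum(comp$t^2), 1, tolerance = 1e-10)
  expected <- drop(unclass(K) %*% unclass(Y)[, 1])
  expected <- expected / sqrt(sum(expected^2))
  expect_lt(max_abs_diff_up_to_sign(comp$t, expected), 1e-10)
  expect_lte(comp$iters, 3L)
})

test_that("extracted score is the dominant eigenvector of K Y Y'", {
  for (seed in 1:8) {
    inst <- rand_instance(n = 6, p = 4, n_classes = 3, seed = seed)
    K <- center_gram(compute_gram(inst$X, "rbf"))
    Y <- encode_labels(inst$labels)
    comp <- extract_component(K, Y, inner_tol = 1e-12,
                              inner_max_iter = 100000L)
    M <- unclass(K) %*% tcrossprod(unclass(Y))
    e <- eigen(M)
    v <- Re(e$vectors[, which.max(Re(e$values))])
    v <- v / sqrt(sum(v^2))
    expect_lt(max_abs_diff_up_to_sign(comp$t, v), 1e-6)
  }
})

test_that("sign convention makes the largest response projection positive", {
  for (seed in 1:5) {
    inst <- rand_instance(10, 5, 2, seed)
    K <- center_gram(compute_gram(inst$X, "linear"))
    Y <- encode_labels(inst$labels)
    comp <- extract_component(K, Y)
    cvec <- drop(crossprod(unclass(Y), comp$t))
    expect_gt(cvec[which.max(abs(cvec))], 0)
  }
})

test_that("deflation removes the component from both working matrices", {
  set.seed(31)
  K <- crossprod(matrix(rnorm(36), 6, 6))
  Y <- unclass(encode_labels(rep(c("x", "y", "z"), each = 2)))
  t_vec <- rnorm(6); t_vec <- t_vec / sqrt(sum(t_vec^2))
  d <- deflate_kpls(K, Y, t_vec)
  expect_lt(max(abs(crossprod(t_vec, d$Y))), 1e-10)
  expect_lt(sqrt(sum((d$K %*% t_vec)^2)), 1e-8)
  # projector idempotence: deflating again with the same t changes nothing
  d2 <- deflate_kpls(d$K, d$Y, t_vec)
  expect_equal(d2$K, d$K, tolerance = 1e-12)
  expect_equal(d2$Y, d$Y, tolerance = 1e-12)
  # hand example: identity kernel and a coordinate direction
  d3 <- deflate_kpls(diag(4), matrix(rnorm(8), 4, 2), c(1, 0, 0, 0))
  expect_equal(d3$K[1, ], rep(0, 4))
  expect_equal(d3$K[, 1], rep(0, 4))
  expect_equal(d3$K[2:4, 2:4], diag(3))
})

test_that("Rd is the mean squared correlation with the indicator columns", {
  # a score equal to the centered two-class indicator explains everything
  Y <- encode_labels(rep(c("a", "b"), each = 3))
  t_vec <- unclass(Y)[, 1] / sqrt(sum(unclass(Y)[, 1]^2))
  expect_equal(rd_contribution(t_vec, Y), 1, tolerance = 1e-12)
  # independent per-column correlation oracle on a 3-class toy
  Y3 <- encode_labels(rep(c("a", "b", "c"), each = 2))
  t3 <- c(0.1, -0.4, 2, 0.3, -1, 0.5)
  oracle <- mean(apply(unclass(Y3), 2, function(y) cor(y, t3)^2))
  expect_equal(rd_contribution(t3, Y3), oracle, tolerance = 1e-12)
  # orthogonal, uncorrelated score explains nothing
  Yb <- encode_labels(c("a", "a", "b", "b"))
  expect_equal(rd_contribution(c(-1, 1, -1, 1), Yb), 0, tolerance = 1e-12)
  # degenerate score
  expect_warning(out <- rd_contribution(rep(1, 4), Yb), "zero variance")
  expect_equal(out, 0)
})

test_that("Fisher ratio matches hand-computed scatter sums", {
  expect_equal(fisher_ratio(c(0, 1, 2, 3), c(0, 0, 1, 1)), 4)
  expect_identical(fisher_ratio(c(-1, -1, 1, 1), c(0, 0, 1, 1)), Inf)
  expect_equal(fisher_ratio(c(0, 1, 0, 1), c(0, 0, 1, 1)), 0)
})

test_that("fitted score vectors are orthonormal and deterministic", {
  inst <- rand_instance(20, 30, 3, seed = 42)
  fit <- kpls(inst$X, inst$labels, kernel = "rbf", n_components = 5)
  G <- crossprod(fit$scores)
  expect_lt(max(abs(G - diag(ncol(G)))), 1e-8)
  fit2 <- kpls(inst$X, inst$labels, kernel = "rbf", n_components = 5)
  expect_identical(fit$scores, fit2$scores)
  expect_identical(fit$rd, fit2$rd)
})

test_that("response residual norm is non-increasing across components", {
  inst <- rand_instance(16, 25, 2, seed = 7)
  fit <- kpls(inst$X, inst$labels, kernel = "polynomial", degree = 2,
              n_components = 6)
  Y <- unclass(fit$Y)
  norms <- numeric(fit$kappa + 1L)
  norms[1] <- sqrt(sum(Y^2))
  for (h in seq_len(fit$kappa)) {
    t_h <- fit$scores[, h]
    Y <- Y - t_h %*% crossprod(t_h, Y)
    norms[h + 1L] <- sqrt(sum(Y^2))
  }
  expect_true(all(diff(norms) <= 1e-10))
})

test_that("separable data always yields a discriminating first component", {
  sim <- simulate_microarray(n_samples = 30, n_genes = 80,
                             effect_size = 3, seed = 2)
  fit <- kpls(sim$expression, sim$labels, kernel = "linear")
  expect_gte(fit$kappa, 1L)
  expect_gt(fit$fisher_j[1], 0)
  expect_gt(fit$rd[1], 0.5)
})

test_that("kernel scores with a linear kernel match primal NIPALS PLS2", {
  for (seed in 1:4) {
    inst <- rand_instance(15, 25, if (seed %% 2) 2 else 3, seed = 100 + seed)
    fit <- kpls(inst$X, inst$labels, kernel = "linear", n_components = 3,
                inner_tol = 1e-13)
    oracle <- nipals_pls2_oracle(inst$X, inst$labels, 3, tol = 1e-13)
    for (h in 1:3)
      expect_lt(max_abs_diff_up_to_sign(fit$scores[, h],
                                        oracle$scores[, h]), 1e-8)
  }
})

test_that("fit trace records every extracted component for auditing", {
  inst <- rand_instance(20, 40, 2, seed = 5)
  fit <- kpls(inst$X, inst$labels, kernel = "rbf")
  expect_true(all(c("component", "rd", "fisher_j", "retained") %in%
                    names(fit$trace)))
  expect_equal(sum(fit$trace$retained), fit$kappa)
  if (fit$stopping_reason == "threshold")
    expect_false(fit$trace$retained[nrow(fit$trace)])
})
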