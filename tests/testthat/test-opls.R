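test_that("orthogonal scores are numerically orthogonal to the predictive score", {
  for (seed in c(1, 2, 3)) {
    tb <- total_sum_normalize(null_table(seed, n = 14, p = 25,
                                         groups = rep(c("t", "c"), 7)))
    fit <- opls_da(tb, tb$groups, n_orthogonal = 2, cv_folds = 0)
    for (j in seq_len(ncol(fit$ortho_scores))) {
      ip <- abs(sum(fit$scores * fit$ortho_scores[, j]))
      expect_lte(ip, 1e-8 * sqrt(sum(fit$scores^2) * sum(fit$ortho_scores[, j]^2)))
    }
    expect_gte(fit$r2x, 0)
    expect_lte(fit$r2x, 1)
    expect_lte(fit$r2y, 1)
  }
})

test_that("zero orthogonal components reduce to one-component PLS-DA", {
  tb <- total_sum_normalize(null_table(5, n = 12, p = 18))
  fit <- opls_da(tb, tb$groups, n_orthogonal = 0, cv_folds = 0)
  X <- tb$areas[, setdiff(colnames(tb$areas), "olomoucine"), drop = FALSE]
  y_num <- ifelse(tb$groups == "treated", 1, -1)
  oracle <- pls1_oracle(X, y_num)
  # sign convention: both code the second level positive
  expect_lt(max(abs(abs(fit$scores) - abs(oracle$scores))), 1e-8)
  expect_lt(max(abs((fit$fitted_y + mean(y_num)) - oracle$y_hat)), 1e-8)
  pred <- predict(fit)
  expect_equal(pred$class[tb$groups == "treated"][1], "treated")
})

test_that("a single discriminating variable concentrates the loading", {
  set.seed(8)
  X <- matrix(rnorm(12 * 2, 0, 0.2), 12, 2,
              dimnames = list(paste0("s", 1:12), c("hit", "noise")))
  y <- rep(c("treated", "control"), each = 6)
  X[y == "treated", "hit"] <- X[y == "treated", "hit"] + 3
  fit <- opls_da(X, y, n_orthogonal = 0, cv_folds = 0)
  w <- coef(fit, "weights")
  # brute-force weight on the 2-variable case: normalized X'y_c after scaling
  yc <- ifelse(y == "treated", 1, -1)
  w_oracle <- drop(crossprod(scale(X), yc - mean(yc)))
  w_oracle <- w_oracle / sqrt(sum(w_oracle^2))
  expect_equal(abs(unname(w)), abs(unname(w_oracle)), tolerance = 1e-10)
  expect_gt(abs(w["hit"]), 0.9)
  expect_gt(abs(w["hit"]), 3 * abs(w["noise"]))
})

test_that("fit preconditions are enforced", {
  tb <- total_sum_normalize(null_table(1))
  expect_error(opls_da(tb, rep("treated", 12)), "two classes")
  expect_error(opls_da(null_table(1), rep(c("t", "c"), each = 6)), "normalized")
  # rank exhausted: 12 samples cannot support many orthogonal components
  expect_error(opls_da(tb, tb$groups, n_orthogonal = 50, cv_folds = 0), "rank")
})

test_that("q2 on label-permuted null data is near or below zero", {
  q2s <- vapply(1:20, function(seed) {
    tb <- total_sum_normalize(null_table(100 + seed))
    opls_da(tb, tb$groups, n_orthogonal = 0)$q2
  }, numeric(1))
  expect_lt(median(q2s), 0.2)
})

test_that("q2 does not exceed r2y on informative fits", {
  for (seed in 1:5) {
    sim <- generate_peak_table(builtin_scenarios()$pgp_inhibitor, seed = seed)
    tb <- total_sum_normalize(sim$table)
    fit <- opls_da(tb, tb$groups, n_orthogonal = 0)
    expect_lte(fit$q2, fit$r2y + 1e-12)
    expect_gt(fit$q2, 0.5)  # strong planted effect is cross-validated
  }
})

test_that("select_n_orthogonal is parsimonious", {
  tb <- null_table(7)
  norm <- total_sum_normalize(tb)
  expect_identical(as.integer(select_n_orthogonal(norm, norm$groups, max_k = 2)), 0L)
  expect_identical(as.integer(select_n_orthogonal(norm, norm$groups, max_k = 0)), 0L)
  expect_error(select_n_orthogonal(norm, norm$groups, cv_folds = 1), "folds")
  expect_error(select_n_orthogonal(norm, norm$groups, cv_folds = 20), "fewer samples")
})

test_that("a strong y-orthogonal confounder direction selects one component", {
  set.seed(2)
  y <- rep(c("treated", "control"), each = 6)
  yv <- rep(c(1, -1), each = 6)
  conf <- scale(rnorm(12))[, 1]
  X <- matrix(rnorm(12 * 15, 0, 1), 12, 15)
  X[, 1:8] <- X[, 1:8] * 0.4 + outer(yv, runif(8, 0.8, 1.2))
  X[, 9:15] <- X[, 9:15] * 0.4 + outer(conf, runif(7, 1.5, 2.5))
  dimnames(X) <- list(paste0("s", 1:12), paste0("v", 1:15))
  k <- select_n_orthogonal(X, y, max_k = 3)
  expect_identical(as.integer(k), 1L)
  prof <- attr(k, "q2_profile")
  expect_gt(prof["k1"], prof["k0"])  # removing the confounder helps
})

test_that("permutation p-value follows the add-one formula and flags real effects", {
  sim <- generate_peak_table(builtin_scenarios()$pgp_inhibitor, seed = 3)
  tb <- total_sum_normalize(sim$table)
  pt <- permutation_test(tb, tb$groups, n_permutations = 99, seed = 5,
                         n_orthogonal = 0)
  expect_equal(pt$p_value_q2, 1 / 100)  # observed q2 beats every permutation
  expect_equal(pt$p_value_q2,
               (1 + sum(pt$permuted_q2 >= pt$observed_q2)) / (pt$n_permutations + 1))
  expect_length(pt$permuted_q2, 99)
  expect_gt(pt$p_value_q2, 0)
  expect_lte(pt$p_value_q2, 1)

  # determinism in the seed
  pt2 <- permutation_test(tb, tb$groups, n_permutations = 19, seed = 9,
                          n_orthogonal = 0)
  pt3 <- permutation_test(tb, tb$groups, n_permutations = 19, seed = 9,
                          n_orthogonal = 0)
  expect_identical(pt2$permuted_q2, pt3$permuted_q2)
  expect_equal(pt2$p_value_q2, 0.05)  # 19 permutations all below observed
  expect_error(permutation_test(tb, tb$groups, n_permutations = 5), "19")
})
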