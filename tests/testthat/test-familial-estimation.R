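test_that("pair extraction counts spouse, parent-offspring and sibling pairs", {
  fam <- simulate_families(hp(n_families = 1, seed = 1))
  pc <- pair_concordance(fam)
  expect_setequal(pc$relation, c("spouse", "parent_offspring", "sibling"))
  expect_equal(pc$n_pairs[pc$relation == "spouse"], 1L)
  expect_equal(pc$n_pairs[pc$relation == "parent_offspring"], 4L)
  expect_equal(pc$n_pairs[pc$relation == "sibling"], 1L)

  fam3 <- simulate_families(hp(n_families = 50, n_offspring = 3, seed = 2))
  pc3 <- pair_concordance(fam3)
  expect_equal(pc3$n_pairs[pc3$relation == "spouse"], 50L)
  expect_equal(pc3$n_pairs[pc3$relation == "parent_offspring"], 2L * 50L * 3L)
  expect_equal(pc3$n_pairs[pc3$relation == "sibling"], 50L * choose(3, 2))
})

test_that("single-offspring families omit the sibling relation with a warning", {
  fam <- simulate_families(hp(n_families = 100, n_offspring = 1, seed = 3))
  expect_warning(pc <- pair_concordance(fam), "sibling")
  expect_false("sibling" %in% pc$relation)
  expect_setequal(pc$relation, c("spouse", "parent_offspring"))
})

test_that("bivariate normal CDF matches independent quadrature and mvtnorm", {
  cases <- expand.grid(h = c(-2, -0.5, 0, 1.2816, 2.5),
                       k = c(-1.5, 0, 1.2816),
                       rho = c(-0.99, -0.7, -0.2, 0, 0.35, 0.8, 0.99))
  got <- pbvnorm(cases$h, cases$k, cases$rho)
  oracle <- mapply(pbvnorm_integrate, cases$h, cases$k, cases$rho)
  expect_true(all(abs(got - oracle) < 1e-8))
  if (requireNamespace("mvtnorm", quietly = TRUE)) {
    mv <- mapply(function(h, k, rho) {
      mvtnorm::pmvnorm(upper = c(h, k),
                       corr = matrix(c(1, rho, rho, 1), 2))[1]
    }, cases$h, cases$k, cases$rho)
    expect_true(all(abs(got - mv) < 1e-9))
  }
  # exact limits
  expect_equal(pbvnorm(0.5, 1.5, 1), pnorm(0.5))
  expect_equal(pbvnorm(0.5, 1.5, -1), pnorm(0.5) + pnorm(1.5) - 1)
  expect_equal(pbvnorm(0.7, -0.3, 0), pnorm(0.7) * pnorm(-0.3))
  expect_equal(pbvnorm(0, 0, 0.5), 0.25 + asin(0.5) / (2 * pi))
})

test_that("tetrachoric is near zero for independent margins", {
  fit <- tetrachoric(100 * c(9, 81, 1, 9))
  expect_lt(abs(fit$rho), 0.01)
})

test_that("tetrachoric recovers a generating latent correlation", {
  counts <- simulate_binary_pairs(2e5, rho = 0.35, K1 = 0.1, seed = 314)
  fit <- tetrachoric(counts)
  expect_lt(abs(fit$rho - 0.35), 0.02)
  expect_true(is.finite(fit$se))
  expect_lt(fit$se, 0.02)
})

test_that("tetrachoric converges to the truth across prevalences", {
  for (K in c(0.01, 0.1, 0.3)) {
    counts <- simulate_binary_pairs(1e6, rho = 0.4, K1 = K, seed = 1000 + K * 100)
    fit <- tetrachoric(counts)
    expect_lt(abs(fit$rho - 0.4), 3 * fit$se)
  }
})

test_that("zero cells are continuity-corrected and flagged, not fatal", {
  fit <- tetrachoric(c(0, 20, 30, 950))
  expect_true(fit$continuity_corrected)
  expect_true(is.finite(fit$rho))
  expect_error(tetrachoric(c(0, 0, 30, 970)), "degenerate margin")
  expect_error(tetrachoric(c(0, 30, 0, 970)), "degenerate margin")
})

test_that("a strongly diagonal table stays finite near the search boundary", {
  fit <- tetrachoric(c(50, 1, 1, 50))
  expect_true(is.finite(fit$rho))
  expect_gt(fit$rho, 0.9)
  expect_lt(fit$rho, 1)
})

test_that("the 1-D optimiser agrees with a likelihood grid search", {
  tables <- random_tables(5, seed = 2024)
  for (counts in tables) {
    fit <- tetrachoric(counts)
    grid_rho <- tetra_grid_search(counts, step = 1e-3)
    expect_lt(abs(fit$rho - grid_rho), 1.5e-3)
  }
})

test_that("tidy and glance methods expose the fit as tibbles", {
  fit <- tetrachoric(c(50, 150, 140, 1660))
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("estimate", "std.error", "threshold_row",
                     "threshold_col", "continuity_corrected"))
  gl <- glance(fit)
  expect_equal(gl$nobs, 2000)
  expect_true(is.finite(gl$logLik))
})

test_that("component recovery exactly inverts the closed-form correlations", {
  corrs <- tibble::tibble(
    relation = c("spouse", "parent_offspring", "sibling"),
    r = c(0.30, 0.35, 0.375)
  )
  est <- recover_components(corrs, x_assumed = 0.5)
  expect_equal(est$G_A_hat, 0.4, tolerance = 1e-15)
  expect_equal(est$E_P_hat, 0.3, tolerance = 1e-15)
  expect_equal(est$E_S_hat, 0.1, tolerance = 1e-15)
  expect_equal(est$H2_naive, 0.7, tolerance = 1e-15)
  expect_equal(est$H2_hybrid_numerator, 0.55, tolerance = 1e-15)
  expect_false(est$flag_out_of_range)

  null <- recover_components(
    tibble::tibble(relation = corrs$relation, r = c(0, 0, 0)), 0.5
  )
  expect_equal(unlist(null[, c("G_A_hat", "E_P_hat", "E_S_hat", "H2_naive")]),
               c(G_A_hat = 0, E_P_hat = 0, E_S_hat = 0, H2_naive = 0))
})

test_that("recovery is the exact inverse of the forward map on a grid", {
  grid <- expand.grid(G_A = c(0.1, 0.4, 0.6), E_P = c(0, 0.2, 0.3),
                      E_S = c(0, 0.1), x = c(0.1, 0.5, 0.8))
  grid <- grid[grid$G_A + grid$E_P <= 1 &
                 grid$G_A + grid$x * grid$E_P + grid$E_S <= 1, ]
  for (i in seq_len(nrow(grid))) {
    p <- hp(G_A = grid$G_A[i], E_P = grid$E_P[i], E_S = grid$E_S[i],
            x = min(grid$x[i], 1 - 1e-9))
    est <- recover_components(expected_latent_correlations(p),
                              x_assumed = p$x)
    expect_equal(est$G_A_hat, p$G_A, tolerance = 1e-12)
    expect_equal(est$E_P_hat, p$E_P, tolerance = 1e-12)
    expect_equal(est$E_S_hat, p$E_S, tolerance = 1e-12)
  }
})

test_that("assuming no transmission inflates G_A by exactly 2 x E_P", {
  p <- hp(G_A = 0.4, E_P = 0.3, x = 0.5)
  est <- recover_components(expected_latent_correlations(p), x_assumed = 0)
  expect_equal(est$G_A_hat, 0.4 + 2 * 0.5 * 0.3, tolerance = 1e-12)
  # the direction holds across the feasible grid whenever x * E_P > 0
  grid <- expand.grid(G_A = c(0.2, 0.5), E_P = c(0.1, 0.3), x = c(0.25, 0.6))
  for (i in seq_len(nrow(grid))) {
    p_i <- hp(G_A = grid$G_A[i], E_P = grid$E_P[i], E_S = 0, x = grid$x[i])
    est_i <- recover_components(expected_latent_correlations(p_i),
                                x_assumed = 0)
    expect_gt(est_i$G_A_hat, grid$G_A[i])
  }
})

test_that("the recovery experiment summarises bias and is reproducible", {
  p <- hp(n_families = 3000, seed = 77)
  ex <- recovery_experiment(p, x_assumed = 0.5, n_reps = 3)
  expect_s3_class(ex, "recovery_experiment")
  expect_equal(nrow(ex$estimates), 3)
  expect_setequal(ex$summary$component, c("G_A", "E_P", "E_S"))
  expect_equal(ex$summary$truth, c(0.4, 0.3, 0.1))
  # loose sanity bound at this size; tight bias bounds live in the
  # full-scale acceptance experiment
  expect_true(all(abs(ex$summary$bias) < 0.1))
  ex2 <- recovery_experiment(p, x_assumed = 0.5, n_reps = 3)
  expect_identical(ex$estimates, ex2$estimates)
  expect_equal(nrow(tidy(ex)), 3)
  gl <- glance(ex)
  expect_equal(gl$n_reps, 3)
  expect_true(all(c("bias_G_A", "rmse_E_P", "mean_H2_naive") %in% names(gl)))
  expect_error(recovery_experiment(p, n_reps = 1), "n_reps")
})
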