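test_that("closed-form G_A back-substitutes into the heritability identity", {
  d <- solve_hybrid(H2 = 0.6, E = 0.4, E_P = 0.3, x = 0.5)
  expect_equal(d$G_A, 0.225, tolerance = 1e-12)
  expect_equal(d$G, 0.375, tolerance = 1e-12)
  expect_identical(d$mode, "solved")

  inputs <- random_feasible_inputs(200, seed = 101)
  res <- solve_hybrid(inputs$H2, inputs$E, inputs$E_P, inputs$x)
  h2_back <- (res$G_A + inputs$x * inputs$E_P) / (res$G_A + inputs$E)
  expect_true(all(abs(h2_back - inputs$H2) < 1e-10))
  # internal consistency of the decomposition
  expect_true(all(abs(res$G - (res$G_A + res$xEP)) < 1e-12))
  expect_true(all(abs(res$residual - (inputs$H2 - res$G)) < 1e-12))
})

test_that("closed form agrees with brute-force bisection", {
  inputs <- random_feasible_inputs(50, seed = 202)
  res <- solve_hybrid(inputs$H2, inputs$E, inputs$E_P, inputs$x)
  g_bis <- mapply(bisect_G_A, inputs$H2, inputs$E, inputs$E_P, inputs$x)
  expect_true(all(abs(res$G_A - g_bis) < 1e-8))
})

test_that("no shared parental environment collapses the hybrid to pure genetics", {
  # when E_P = 0 and the components fill 1 - H2, G = G_A = H2
  d <- solve_hybrid(H2 = 0.924, E = 1 - 0.924, E_P = 0, x = 0.5)
  expect_equal(d$G_A, 0.924, tolerance = 1e-12)
  expect_equal(d$G, 0.924, tolerance = 1e-12)
  expect_equal(d$residual, 0, tolerance = 1e-12)
})

test_that("feasibility boundary gives G_A = 0 and beyond it raises", {
  d <- solve_hybrid(H2 = 0.5, E = 0.4, E_P = 0.4, x = 0.5)
  expect_equal(d$G_A, 0, tolerance = 1e-12)
  expect_equal(d$G, 0.2, tolerance = 1e-12)
  expect_error(solve_hybrid(H2 = 0.3, E = 0.4, E_P = 0.4, x = 0.5),
               "infeasible")
  expect_error(solve_hybrid(H2 = 1, E = 0.4, E_P = 0.1, x = 0.5), "H2")
  expect_error(solve_hybrid(H2 = 0.5, E = 0.2, E_P = 0.3, x = 0.5), "E_P")
  expect_error(solve_hybrid(H2 = 0.5, E = 0.4, E_P = 0.1, x = 1.5), "x")
})

test_that("G_A decreases in x at the exact rate -E_P / (1 - H2)", {
  grid <- expand.grid(H2 = c(0.3, 0.6, 0.9), E_P = c(0.1, 0.3),
                      x = c(0.25, 0.5, 0.6))
  for (i in seq_len(nrow(grid))) {
    H2 <- grid$H2[i]; E_P <- grid$E_P[i]; x <- grid$x[i]
    E <- max(1 - H2 + 0.1, E_P + 0.2) # comfortably feasible
    dx <- 0.05
    g1 <- solve_hybrid(H2, E, E_P, x)$G_A
    g2 <- solve_hybrid(H2, E, E_P, x + dx)$G_A
    expect_equal((g2 - g1) / dx, -E_P / (1 - H2), tolerance = 1e-9)
  }
})

test_that("the x -> 0 limit is the pure-genetic solution H2 E / (1 - H2)", {
  d <- solve_hybrid(H2 = 0.6, E = 0.4, E_P = 0.3, x = 1e-9)
  expect_equal(d$G_A, 0.6 * 0.4 / 0.4, tolerance = 1e-6)
  expect_equal(d$G, d$G_A, tolerance = 1e-6)
})

test_that("percent shares of H2 always sum to 100 unrounded", {
  inputs <- random_feasible_inputs(100, seed = 303)
  res <- solve_hybrid(inputs$H2, inputs$E, inputs$E_P, inputs$x)
  expect_true(all(abs(res$pct_G_of_H2 + res$pct_residual_of_H2 - 100) < 1e-9))
  rep <- reproduce_hybrid(c(0.763, 0.676), c(0.468, 0.333), c(0.2, 0.27))
  expect_true(all(abs(rep$pct_G_of_H2 + rep$pct_residual_of_H2 - 100) < 1e-9))
})

test_that("reproduce mode assembles published decompositions", {
  d <- reproduce_hybrid(H2 = 0.763, G_A_reported = 0.468, E_P = 0.2, x = 0.5)
  expect_equal(d$G, 0.568, tolerance = 1e-12)
  expect_equal(d$residual, 0.195, tolerance = 1e-12)
  expect_equal(d$pct_G_of_H2, 74.4, tolerance = 0.05)
  expect_identical(d$mode, "reproduced")

  d2 <- reproduce_hybrid(H2 = 0.676, G_A_reported = 0.333, E_P = 0.27, x = 0.5)
  expect_equal(d2$G, 0.468, tolerance = 1e-12)
  expect_equal(d2$residual, 0.208, tolerance = 1e-12)

  d3 <- reproduce_hybrid(H2 = 0.924, G_A_reported = 0.924, E_P = 0, x = 0.5)
  expect_equal(d3$G, 0.924, tolerance = 1e-12)
  expect_equal(d3$residual, 0, tolerance = 1e-12)

  # printed rounding can push G past H2: flagged, not raised
  d4 <- reproduce_hybrid(H2 = 0.5, G_A_reported = 0.45, E_P = 0.15, x = 0.5)
  expect_true(d4$flag_negative_residual)
  expect_lt(d4$residual, 0)
})

test_that("measured genetics sums SNP and CNV contributions", {
  expect_equal(measured_genetics(0.28, 0.02), 0.30)
  expect_equal(measured_genetics(0.17, 0.2), 0.37)
  expect_equal(measured_genetics(0.21), 0.21)
  expect_equal(measured_genetics(0.21, NA), 0.21)
  expect_error(measured_genetics(-0.1), "G_SNP")
})

test_that("residual share matches published cells and rejects H2 = 0", {
  rs <- residual_share(c(0.763, 0.924, 0.562), c(0.30, 0.924, 0.435))
  expect_equal(rs$residual, c(0.463, 0, 0.127), tolerance = 1e-12)
  expect_equal(round(rs$pct_of_H2, 1), c(60.7, 0, 22.6))
  expect_error(residual_share(0, 0.1), "undefined share")
})

test_that("explained range handles exclusions and degenerate lists", {
  d <- tibble::tibble(
    name = c("a", "b", "c"), H2 = c(0.8, 0.6, 0.5), G = c(0.4, 0.3, 0.2)
  )
  r <- explained_range(d)
  expect_equal(r$pct_min, 40)
  expect_equal(r$pct_max, 50)
  single <- explained_range(d[1, ])
  expect_equal(single$pct_min, single$pct_max)
  r2 <- explained_range(d, exclude = "c")
  expect_equal(r2$n_disorders, 2)
  expect_error(explained_range(d, exclude = c("a", "b", "c")), "no disorders")
})

test_that("total environment sums components or passes the total through", {
  expect_equal(
    total_environment(tibble::tibble(E_P = 0.2, E_F = 0, E_S = 0.05, E_U = 0.1)),
    0.35
  )
  expect_equal(total_environment(tibble::tibble(E_total = 0.4)), 0.4)
  # couple-shared share of 63% of total environmental variance
  E <- 0.27 / 0.63
  d <- tibble::tibble(E_P = 0.27, E_S = 0.05, E_U = E - 0.27 - 0.05)
  got <- total_environment(d)
  expect_equal(got, E, tolerance = 1e-12)
  expect_equal(0.27 / got, 0.63, tolerance = 1e-12)
  expect_gte(got, d$E_P)
  expect_error(total_environment(tibble::tibble(H2 = 0.5)),
               "insufficient environmental data")
  expect_error(
    total_environment(tibble::tibble(E_P = 0.2, E_F = 0, E_S = 0.1,
                                     E_U = 0.1, E_total = 0.5)),
    "disagrees"
  )
})
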