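# Shared fixtures and independent oracles used across the suite.

# Quick sim_params constructor with the study's headline defaults.
hp <- function(G_A = 0.4, E_P = 0.3, E_S = 0.1, x = 0.5, K = 0.1,
               n_families = 1000, n_offspring = 2, seed = 1) {
  sim_params(G_A = G_A, E_P = E_P, E_S = E_S, x = x, K = K,
             n_families = n_families, n_offspring = n_offspring, seed = seed)
}

# Brute-force bisection solve of H2 = (G_A + x E_P) / (G_A + E) for G_A on
# [0, 10]; independent of the closed form. The map G_A -> H2 is monotone
# decreasing in H2... (increasing in G_A since E > x E_P), so bisection on
# the sign of the residual converges.
bisect_G_A <- function(H2, E, E_P, x, iters = 100) {
  f <- function(g) (g + x * E_P) / (g + E) - H2
  lo <- 0; hi <- 10
  if (f(lo) > 0) return(NA_real_) # infeasible: G_A would be negative
  while (f(hi) < 0) hi <- hi * 2  # extend the bracket for extreme H2
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (f(mid) <= 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Draw random feasible solver inputs under a local seed.
random_feasible_inputs <- function(n, seed) {
  withr::with_seed(seed, {
    out <- NULL
    while (is.null(out) || nrow(out) < n) {
      H2 <- runif(2 * n, 0.05, 0.95)
      E <- runif(2 * n, 0.05, 1)
      E_P <- runif(2 * n, 0, 1) * E
      x <- runif(2 * n, 0.01, 0.99)
      keep <- H2 * E >= x * E_P
      out <- rbind(out, data.frame(H2, E, E_P, x)[keep, ])
    }
    out[seq_len(n), ]
  })
}

# Simulate n binary pairs whose latent scale is bivariate normal with
# correlation rho and per-margin prevalences K1, K2; returns counts
# c(n11, n10, n01, n00). Oracle for tetrachoric recovery: the generating rho.
simulate_binary_pairs <- function(n, rho, K1 = 0.1, K2 = K1, seed = 1) {
  withr::with_seed(seed, {
    z1 <- rnorm(n)
    z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
    a <- z1 > qnorm(1 - K1)
    b <- z2 > qnorm(1 - K2)
    c(n11 = sum(a & b), n10 = sum(a & !b), n01 = sum(!a & b), n00 = sum(!a & !b))
  })
}

# Brute-force likelihood grid search sharing the model likelihood with the
# ML path; validates the one-dimensional optimiser.
tetra_grid_search <- function(counts, step = 1e-4) {
  counts <- as.numeric(counts)
  if (any(counts == 0)) counts <- counts + 0.5
  n <- sum(counts)
  t1 <- qnorm(1 - (counts[1] + counts[2]) / n)
  t2 <- qnorm(1 - (counts[1] + counts[3]) / n)
  grid <- seq(-1 + 1e-6, 1 - 1e-6, by = step)
  ll <- transherit:::tetrachoric_loglik(grid, counts, t1, t2)
  grid[which.max(ll)]
}

# Slow but independent bivariate-normal CDF: one-dimensional adaptive
# quadrature of the conditional-probability integrand.
pbvnorm_integrate <- function(h, k, rho) {
  f <- function(z) dnorm(z) * pnorm((k - rho * z) / sqrt(1 - rho^2))
  stats::integrate(f, -Inf, h, rel.tol = 1e-12, abs.tol = 1e-14)$value
}

# Random non-degenerate 2x2 tables for oracle-equivalence checks.
random_tables <- function(n_tables, seed) {
  withr::with_seed(seed, {
    lapply(seq_len(n_tables), function(i) {
      repeat {
        rho <- runif(1, -0.9, 0.9)
        K1 <- runif(1, 0.05, 0.5)
        K2 <- runif(1, 0.05, 0.5)
        n <- sample(500:5000, 1)
        counts <- simulate_binary_pairs(n, rho, K1, K2,
                                        seed = sample.int(1e6, 1))
        if (all(counts > 0)) return(counts)
      }
    })
  })
}

# Printed five-disorder reference cells, transcribed once for report tests.
printed_reference <- function() {
  tibble::tibble(
    name = c("ASD", "ADHD", "bipolar disorder", "depression", "schizophrenia"),
    H2 = c(0.924, 0.763, 0.676, 0.579, 0.562),
    G_measured = c(0.37, 0.30, 0.25, 0.21, 0.27),
    pct_measured = c(40, 39.3, 37, 36, 48),
    pct_measured_digits = c(0, 1, 0, 0, 0),
    residual_measured = c(0.554, 0.463, 0.426, 0.369, 0.292),
    pct_residual_measured = c(60, 60.7, 63, 63.7, 52),
    pct_residual_digits = c(0, 1, 0, 1, 0),
    G_hybrid = c(0.924, 0.568, 0.468, 0.373, 0.435),
    pct_hybrid = c(NA, 74.4, 69.2, 64.2, 77.4),
    residual_hybrid = c(0, 0.195, 0.208, 0.207, 0.127),
    pct_residual_hybrid = c(0, 25.6, 30.8, 35.8, 22.6)
  )
}
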