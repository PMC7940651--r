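#' Simulation parameters for the family liability model
#'
#' Validates the generative settings for [simulate_families()]: variance
#' fractions for additive genetics (`G_A`), couple-shared parental
#' environment (`E_P`), sibling-shared environment (`E_S`), the transmitted
#' fraction `x` of `E_P`, disorder prevalence `K`, and the design sizes.
#' Unique environment is not a parameter: it fills each generation's
#' liability variance to 1, so both budgets must leave room:
#' parental `G_A + E_P <= 1` and offspring `G_A + x * E_P + E_S <= 1`.
#'
#' @param G_A Additive genetic variance fraction.
#' @param E_P Couple-shared parental environmental variance fraction.
#' @param E_S Sibling-shared environmental variance fraction.
#' @param x Transmitted fraction of `E_P`, in `[0, 1)` (0 models no
#'   transmission).
#' @param K Disorder prevalence in `(0, 1)`.
#' @param n_families Number of nuclear families.
#' @param n_offspring Offspring per family (default 2).
#' @param seed Integer seed; mandatory for reproducibility.
#' @return A validated list of class `"sim_params"`.
#' @examples
#' sim_params(G_A = 0.4, E_P = 0.3, E_S = 0.1, x = 0.5,
#'            K = 0.1, n_families = 1000, seed = 1)
#' @export
sim_params <- function(G_A, E_P, E_S = 0, x = 0.5, K = 0.1,
                       n_families, n_offspring = 2, seed) {
  assert_scalar_number(G_A, "G_A"); assert_in_range(G_A, "G_A", 0, 1)
  assert_scalar_number(E_P, "E_P"); assert_in_range(E_P, "E_P", 0, 1)
  assert_scalar_number(E_S, "E_S"); assert_in_range(E_S, "E_S", 0, 1)
  assert_scalar_number(x, "x")
  assert_in_range(x, "x", 0, 1, upper_open = TRUE)
  assert_scalar_number(K, "K")
  assert_in_range(K, "K", 0, 1, lower_open = TRUE, upper_open = TRUE)
  assert_scalar_number(n_families, "n_families")
  assert_scalar_number(n_offspring, "n_offspring")
  assert_scalar_number(seed, "seed")
  if (n_families < 1 || n_families != round(n_families)) {
    abort("`n_families` must be a positive integer.")
  }
  if (n_offspring < 1 || n_offspring != round(n_offspring)) {
    abort("`n_offspring` must be a positive integer.")
  }
  if (G_A + E_P > 1 + 1e-12) {
    abort("parental variance budget violated: G_A + E_P must be <= 1.")
  }
  if (G_A + x * E_P + E_S > 1 + 1e-12) {
    abort("offspring variance budget violated: G_A + x*E_P + E_S must be <= 1.")
  }
  structure(
    list(G_A = G_A, E_P = E_P, E_S = E_S, x = x, K = K,
         n_families = as.integer(n_families),
         n_offspring = as.integer(n_offspring), seed = as.integer(seed)),
    class = "sim_params"
  )
}

#' Simulate nuclear families under the liability-threshold transmission model
#'
#' Each family's binary disease statuses arise from standardized Gaussian
#' liabilities. A couple-shared environmental deviate
#' \eqn{C \sim N(0, E_P)} enters both parents' liabilities with loading 1;
#' offspring receive the transmitted component \eqn{x C} plus an independent
#' top-up of variance \eqn{x(1-x) E_P}, so the transmitted environment has
#' variance \eqn{x E_P} and parent-offspring covariance \eqn{x E_P}.
#' Genetics follow the infinitesimal additive model: parental genetic values
#' \eqn{N(0, G_A)}, offspring mid-parent average plus a Mendelian
#' segregation deviate \eqn{N(0, G_A/2)}. One sibling-shared deviate
#' \eqn{N(0, E_S)} is drawn per family, and unique environment fills each
#' liability's variance to 1. An individual is affected when its liability
#' exceeds \eqn{\tau = \Phi^{-1}(1 - K)}.
#'
#' Identical parameters (including the seed) give bit-identical tables; the
#' seed is applied locally and does not disturb the caller's RNG state.
#'
#' @param params A [sim_params()] object.
#' @return A tibble with one row per individual and columns `family_id`,
#'   `role` (`"father"`, `"mother"`, `"offspring"`), `offspring_index` (`NA`
#'   for parents), `genetic`, `shared_env` (couple deviate for parents,
#'   transmitted component for offspring), `sibling_env`, `unique_env`,
#'   `liability` (the sum of the four components), and `affected`. The
#'   threshold and parameters are attached as attributes `"threshold"` and
#'   `"params"`.
#' @examples
#' fam <- simulate_families(sim_params(
#'   G_A = 0.4, E_P = 0.3, E_S = 0.1, x = 0.5,
#'   K = 0.1, n_families = 500, seed = 42
#' ))
#' mean(fam$affected)
#' @export
simulate_families <- function(params) {
  if (!inherits(params, "sim_params")) {
    abort("`params` must be created with sim_params().")
  }
  p <- params
  n <- p$n_families
  m <- p$n_offspring
  u_par <- 1 - p$G_A - p$E_P            # parental unique environment
  u_off <- 1 - p$G_A - p$x * p$E_P - p$E_S # offspring unique environment
  tau <- qnorm(1 - p$K)

  fam <- withr::with_seed(p$seed, {
    C <- rnorm(n, 0, sqrt(p$E_P))       # couple-shared deviate
    G_f <- rnorm(n, 0, sqrt(p$G_A))
    G_m <- rnorm(n, 0, sqrt(p$G_A))
    U_f <- rnorm(n, 0, sqrt(u_par))
    U_m <- rnorm(n, 0, sqrt(u_par))
    S <- rnorm(n, 0, sqrt(p$E_S))       # sibling-shared, one per family

    # offspring deviates drawn column-wise so adding offspring extends, not
    # reshuffles, the parental draws
    mid <- (G_f + G_m) / 2
    M <- matrix(rnorm(n * m, 0, sqrt(p$G_A / 2)), n, m)
    D <- matrix(rnorm(n * m, 0, sqrt(p$x * (1 - p$x) * p$E_P)), n, m)
    U_o <- matrix(rnorm(n * m, 0, sqrt(u_off)), n, m)

    parents <- tibble::tibble(
      family_id = rep(seq_len(n), 2L),
      role = rep(c("father", "mother"), each = n),
      offspring_index = NA_integer_,
      genetic = c(G_f, G_m),
      shared_env = c(C, C),
      sibling_env = 0,
      unique_env = c(U_f, U_m)
    )
    offspring <- tibble::tibble(
      family_id = rep(seq_len(n), m),
      role = "offspring",
      offspring_index = rep(seq_len(m), each = n),
      genetic = as.vector(mid + M),
      shared_env = as.vector(p$x * C + D),
      sibling_env = rep(S, m),
      unique_env = as.vector(U_o)
    )
    dplyr::bind_rows(parents, offspring)
  })

  fam <- fam |>
    dplyr::mutate(
      liability = .data$genetic + .data$shared_env + .data$sibling_env +
        .data$unique_env,
      affected = .data$liability > tau
    ) |>
    dplyr::arrange(.data$family_id, .data$role, .data$offspring_index)
  attr(fam, "threshold") <- tau
  attr(fam, "params") <- p
  fam
}

#' Closed-form latent correlations implied by the transmission model
#'
#' Covariance algebra of the generative recipe in [simulate_families()]
#' gives the latent (liability-scale) correlations
#' \deqn{r_{spouse} = E_P,}
#' \deqn{r_{parent-offspring} = G_A/2 + x E_P,}
#' \deqn{r_{sibling} = G_A/2 + x^2 E_P + E_S.}
#' Since `2 * r_parent_offspring = G_A + 2 x E_P`, a naive parent-offspring
#' heritability estimator exceeds the true `G_A` whenever `x * E_P > 0` —
#' the shared-environment confounding of heritability this package
#' quantifies.
#'
#' @param params A [sim_params()] object (design sizes and seed are ignored).
#' @return A tibble with columns `relation`
#'   (`spouse`, `parent_offspring`, `sibling`) and `r`.
#' @examples
#' expected_latent_correlations(sim_params(
#'   G_A = 0.4, E_P = 0.3, E_S = 0.1, x = 0.5,
#'   K = 0.1, n_families = 1, seed = 1
#' )) # 0.30, 0.35, 0.375
#' @export
expected_latent_correlations <- function(params) {
  if (!inherits(params, "sim_params")) {
    abort("`params` must be created with sim_params().")
  }
  p <- params
  tibble::tibble(
    relation = c("spouse", "parent_offspring", "sibling"),
    r = c(p$E_P,
          p$G_A / 2 + p$x * p$E_P,
          p$G_A / 2 + p$x^2 * p$E_P + p$E_S)
  )
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Family simulation parameters\n")
  cat(sprintf("  G_A = %g, E_P = %g, E_S = %g, x = %g, K = %g\n",
              x$G_A, x$E_P, x$E_S, x$x, x$K))
  cat(sprintf("  %d families x %d offspring, seed %d\n",
              x$n_families, x$n_offspring, x$seed))
  invisible(x)
}
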