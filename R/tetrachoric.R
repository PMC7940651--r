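# Gauss-Legendre nodes/weights on [0, 1] via the Golub-Welsch eigenvalue
# method on the Jacobi matrix; cached after first use.
gauss_legendre_01 <- function(n = 64L) {
  key <- paste0("gl", n)
  cached <- .transherit_env[[key]]
  if (!is.null(cached)) return(cached)
  i <- seq_len(n - 1L)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1L)] <- b
  J[cbind(i + 1L, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  # nodes on [-1, 1]; map to [0, 1]
  ord <- order(e$values)
  res <- list(nodes = (e$values[ord] + 1) / 2,
              weights = (2 * e$vectors[1, ord]^2) / 2)
  .transherit_env[[key]] <- res
  res
}

#' Standard bivariate normal distribution function
#'
#' \eqn{\Phi_2(h, k, \rho) = P(Z_1 \le h, Z_2 \le k)} for standard normal
#' margins with correlation \eqn{\rho}, evaluated by 64-point Gauss-Legendre
#' quadrature of the single-integral form
#' \deqn{\Phi_2(h,k,\rho) = \Phi(h)\Phi(k) + \frac{1}{2\pi}
#'   \int_0^{\arcsin\rho} \exp\!\Big(\frac{2hk\sin\theta - h^2 - k^2}
#'   {2\cos^2\theta}\Big)\, d\theta.}
#' Vectorised over all three arguments (recycled), which makes dense
#' likelihood grids over \eqn{\rho} cheap. \eqn{\rho = \pm 1} is handled by
#' the exact comonotone/antimonotone limits.
#'
#' @param h,k Upper integration limits (standard-normal scale).
#' @param rho Correlations in `[-1, 1]`.
#' @return A numeric vector of probabilities.
#' @examples
#' pbvnorm(0, 0, 0.5) # 1/4 + asin(0.5) / (2 * pi) = 1/3
#' @export
pbvnorm <- function(h, k, rho) {
  n <- max(length(h), length(k), length(rho))
  h <- rep_len(h, n); k <- rep_len(k, n); rho <- rep_len(rho, n)
  if (any(is.na(rho)) || any(abs(rho) > 1)) {
    abort("`rho` must lie in [-1, 1].")
  }
  out <- numeric(n)
  hi <- rho >= 1
  lo <- rho <= -1
  out[hi] <- pnorm(pmin(h[hi], k[hi]))
  out[lo] <- pmax(0, pnorm(h[lo]) + pnorm(k[lo]) - 1)
  mid <- !hi & !lo
  if (any(mid)) {
    gl <- gauss_legendre_01()
    hm <- h[mid]; km <- k[mid]
    asr <- asin(rho[mid])
    # theta matrix: each row scales the nodes onto [0, asin(rho)]
    theta <- outer(asr, gl$nodes)
    sn <- sin(theta)
    cs2 <- cos(theta)^2
    f <- exp((2 * hm * km * sn - hm^2 - km^2) / (2 * cs2))
    out[mid] <- pnorm(hm) * pnorm(km) +
      asr * as.vector(f %*% gl$weights) / (2 * pi)
  }
  pmin(pmax(out, 0), 1)
}

# Multinomial log-likelihood of a 2x2 concordance table under the
# liability-threshold model, vectorised over rho. Thresholds are fixed from
# the margins (two-step practice); counts ordered n11, n10, n01, n00 with
# "1" = affected.
tetrachoric_loglik <- function(rho, counts, t1, t2) {
  p00 <- pbvnorm(t1, t2, rho)
  p11 <- 1 - pnorm(t1) - pnorm(t2) + p00
  p10 <- (1 - pnorm(t1)) - p11
  p01 <- (1 - pnorm(t2)) - p11
  P <- cbind(p11, p10, p01, p00)
  P <- pmax(P, 1e-300)
  as.vector(log(P) %*% counts)
}

#' Maximum-likelihood tetrachoric correlation of a 2x2 table
#'
#' Estimates the latent bivariate-normal correlation underlying a 2x2 table
#' of binary (affected / unaffected) outcomes. Thresholds are fixed at the
#' inverse-normal of each margin's affected proportion; the correlation then
#' maximises the multinomial cell-probability likelihood by a
#' one-dimensional search on `(-1 + 1e-6, 1 - 1e-6)` to tolerance `1e-6`.
#' The standard error comes from the observed information (numerical second
#' derivative of the log-likelihood at the maximum).
#'
#' If any cell is zero (but both margins are interior), a continuity
#' correction of +0.5 is added to every cell and flagged in the result. A
#' margin with no affected or no unaffected observations is degenerate and
#' raises an error.
#'
#' @param tab A 2x2 matrix of counts with affected status first in both
#'   dimensions (`tab[1,1]` = both affected), or a length-4 count vector
#'   ordered `n11, n10, n01, n00`.
#' @return An object of class `"tetrachoric"` with elements `rho`, `se`,
#'   `thresholds`, `loglik`, `n`, `counts`, `continuity_corrected`. Use
#'   [tidy()] / [glance()] for tibble output.
#' @examples
#' tetrachoric(matrix(c(500, 500, 500, 8500), 2, byrow = TRUE))
#' @export
tetrachoric <- function(tab) {
  if (is.matrix(tab)) {
    stopifnot(all(dim(tab) == c(2L, 2L)))
    counts <- c(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
  } else {
    stopifnot(is.numeric(tab), length(tab) == 4L)
    counts <- as.numeric(tab)
  }
  if (any(counts < 0) || sum(counts) <= 0) {
    abort("counts must be non-negative with a positive total.")
  }
  corrected <- FALSE
  if (any(counts == 0)) {
    row_aff <- counts[1] + counts[2]
    col_aff <- counts[1] + counts[3]
    n0 <- sum(counts)
    if (row_aff %in% c(0, n0) || col_aff %in% c(0, n0)) {
      abort("degenerate margin: a margin has no affected or no unaffected observations.")
    }
    counts <- counts + 0.5
    corrected <- TRUE
  }
  n <- sum(counts)
  p_row <- (counts[1] + counts[2]) / n
  p_col <- (counts[1] + counts[3]) / n
  t1 <- qnorm(1 - p_row)
  t2 <- qnorm(1 - p_col)
  eps <- 1e-6
  opt <- optimize(tetrachoric_loglik, c(-1 + eps, 1 - eps),
                  counts = counts, t1 = t1, t2 = t2,
                  maximum = TRUE, tol = 1e-6)
  rho <- opt$maximum
  # observed information by central second difference
  hstep <- 1e-4
  r_lo <- max(rho - hstep, -1 + eps)
  r_hi <- min(rho + hstep, 1 - eps)
  ll <- tetrachoric_loglik(c(r_lo, rho, r_hi), counts, t1, t2)
  d2 <- (ll[1] - 2 * ll[2] + ll[3]) / ((r_hi - rho) * (rho - r_lo))
  se <- if (is.finite(d2) && d2 < 0) sqrt(-1 / d2) else NA_real_
  structure(
    list(rho = rho, se = se, thresholds = c(row = t1, col = t2),
         loglik = opt$objective, n = n, counts = counts,
         continuity_corrected = corrected),
    class = "tetrachoric"
  )
}

#' @export
print.tetrachoric <- function(x, ...) {
  cat(sprintf("Tetrachoric correlation: %.4f (SE %s), n = %g%s\n",
              x$rho,
              if (is.na(x$se)) "NA" else sprintf("%.4f", x$se),
              x$n,
              if (x$continuity_corrected) ", continuity-corrected" else ""))
  invisible(x)
}

#' @rdname tetrachoric
#' @param x A `"tetrachoric"` object.
#' @param ... Unused.
#' @method tidy tetrachoric
#' @export
tidy.tetrachoric <- function(x, ...) {
  tibble::tibble(estimate = x$rho, std.error = x$se,
                 threshold_row = unname(x$thresholds["row"]),
                 threshold_col = unname(x$thresholds["col"]),
                 continuity_corrected = x$continuity_corrected)
}

#' @rdname tetrachoric
#' @method glance tetrachoric
#' @export
glance.tetrachoric <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, nobs = x$n)
}

#' Pairwise concordance tables from a family table
#'
#' Extracts the three familial pair relations from a per-individual family
#' table and cross-tabulates affected status: one spouse pair per family
#' (father x mother), every parent x offspring pair, and every unordered
#' offspring pair (ordered by offspring index, so both margins are
#' offspring). A relation with no eligible pairs (e.g. siblings with
#' single-offspring families) is omitted with a warning.
#'
#' @param fam A family table from [simulate_families()] or
#'   [read_family_table()]; needs `family_id`, `role`, `affected`, and
#'   `offspring_index` for offspring.
#' @return A tibble with one row per available relation: `relation`, counts
#'   `n11`, `n10`, `n01`, `n00` (first index father / parent / lower-index
#'   sibling), and `n_pairs`.
#' @examples
#' fam <- simulate_families(sim_params(
#'   G_A = 0.4, E_P = 0.3, E_S = 0.1, x = 0.5,
#'   K = 0.1, n_families = 200, seed = 7
#' ))
#' pair_concordance(fam)
#' @export
pair_concordance <- function(fam) {
  pairs <- extract_pairs(fam, value = "affected", warn_empty = TRUE)
  if (length(pairs) == 0L) abort("no eligible pairs for any relation.")
  rows <- purrr::map(pairs, function(p) {
    c(n11 = sum(p$a & p$b), n10 = sum(p$a & !p$b),
      n01 = sum(!p$a & p$b), n00 = sum(!p$a & !p$b))
  })
  out <- tibble::as_tibble(do.call(rbind, rows))
  out <- dplyr::mutate(out, relation = names(rows), .before = 1)
  dplyr::mutate(out, n_pairs = .data$n11 + .data$n10 + .data$n01 + .data$n00)
}

# Pair extraction shared by the concordance and latent-correlation paths.
# Returns a named list of tibbles (family_id, a, b) per relation; the pair
# orientation is (father, mother), (parent, offspring), (lower, higher
# offspring index). Empty relations are dropped.
extract_pairs <- function(fam, value = "affected", warn_empty = FALSE) {
  stopifnot(is.data.frame(fam))
  needed <- c("family_id", "role", value)
  if (!all(needed %in% names(fam))) {
    abort(sprintf("family table needs columns %s.",
                  paste(needed, collapse = ", ")))
  }
  out <- list()
  note_empty <- function(rel) {
    if (warn_empty) warn(sprintf("no eligible %s pairs; relation omitted.", rel))
  }

  spouses <- fam |>
    dplyr::filter(.data$role %in% c("father", "mother")) |>
    dplyr::select("family_id", "role", value = dplyr::all_of(value)) |>
    tidyr::pivot_wider(names_from = "role", values_from = "value") |>
    tidyr::drop_na()
  if (nrow(spouses) > 0 && all(c("father", "mother") %in% names(spouses))) {
    out$spouse <- tibble::tibble(family_id = spouses$family_id,
                                 a = spouses$father, b = spouses$mother)
  } else {
    note_empty("spouse")
  }

  parents <- fam |>
    dplyr::filter(.data$role %in% c("father", "mother")) |>
    dplyr::select("family_id", a = dplyr::all_of(value))
  offspring <- fam |>
    dplyr::filter(.data$role == "offspring") |>
    dplyr::select("family_id", "offspring_index", b = dplyr::all_of(value))
  po <- dplyr::inner_join(parents, offspring, by = "family_id",
                          relationship = "many-to-many")
  if (nrow(po) > 0) {
    out$parent_offspring <- dplyr::select(po, "family_id", "a", "b")
  } else {
    note_empty("parent-offspring")
  }

  sib <- dplyr::inner_join(
    dplyr::rename(offspring, a = "b"), offspring,
    by = "family_id", suffix = c("_a", "_b"),
    relationship = "many-to-many"
  ) |>
    dplyr::filter(.data$offspring_index_a < .data$offspring_index_b)
  if (nrow(sib) > 0) {
    out$sibling <- dplyr::select(sib, "family_id", "a", "b")
  } else {
    note_empty("sibling")
  }
  out
}

#' Empirical latent (liability-scale) familial correlations
#'
#' Pearson correlations of the simulated latent liabilities for the three
#' familial relations, with Monte-Carlo standard errors that are robust to
#' family clustering (parent-offspring pairs share parents and a couple
#' deviate, so treating the pairs as independent would understate the
#' uncertainty). The SE comes from the cluster-aggregated variance of the
#' standardized cross-products whose mean is the correlation estimate.
#'
#' @param fam A family table from [simulate_families()] with a `liability`
#'   column.
#' @return A tibble with one row per relation: `relation`, `r`, `se`,
#'   `n_pairs`.
#' @examples
#' fam <- simulate_families(sim_params(
#'   G_A = 0.4, E_P = 0.3, E_S = 0.1, x = 0.5,
#'   K = 0.1, n_families = 2000, seed = 7
#' ))
#' latent_correlations(fam)
#' @export
latent_correlations <- function(fam) {
  pairs <- extract_pairs(fam, value = "liability", warn_empty = TRUE)
  if (length(pairs) == 0L) abort("no eligible pairs for any relation.")
  purrr::map_dfr(names(pairs), function(rel) {
    p <- pairs[[rel]]
    za <- (p$a - mean(p$a)) / stats::sd(p$a)
    zb <- (p$b - mean(p$b)) / stats::sd(p$b)
    z <- za * zb
    n <- length(z)
    # cluster-robust variance of mean(z) by family
    cl <- rowsum(z - mean(z), p$family_id)
    se <- sqrt(sum(cl^2)) / n
    tibble::tibble(relation = rel, r = mean(z) * n / (n - 1),
                   se = se, n_pairs = n)
  })
}

#' Latent familial correlations from binary family data
#'
#' Convenience pipeline: build the three pairwise concordance tables
#' (unless already supplied) and estimate each relation's tetrachoric
#' correlation with [tetrachoric()].
#'
#' @param x A family table (with a `role` column) or a concordance tibble
#'   from [pair_concordance()].
#' @return A tibble with one row per relation: `relation`, `r`, `se`,
#'   `n_pairs`, `continuity_corrected`.
#' @examples
#' fam <- simulate_families(sim_params(
#'   G_A = 0.4, E_P = 0.3, E_S = 0.1, x = 0.5,
#'   K = 0.1, n_families = 2000, seed = 7
#' ))
#' familial_correlations(fam)
#' @export
familial_correlations <- function(x) {
  pairs <- if ("role" %in% names(x)) pair_concordance(x) else tibble::as_tibble(x)
  needed <- c("relation", "n11", "n10", "n01", "n00")
  if (!all(needed %in% names(pairs))) {
    abort(sprintf("concordance input needs columns %s.",
                  paste(needed, collapse = ", ")))
  }
  fits <- purrr::pmap(
    pairs[, c("n11", "n10", "n01", "n00")],
    function(n11, n10, n01, n00) tetrachoric(c(n11, n10, n01, n00))
  )
  tibble::tibble(
    relation = pairs$relation,
    r = purrr::map_dbl(fits, "rho"),
    se = purrr::map_dbl(fits, "se"),
    n_pairs = pairs$n11 + pairs$n10 + pairs$n01 + pairs$n00,
    continuity_corrected = purrr::map_lgl(fits, "continuity_corrected")
  )
}
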