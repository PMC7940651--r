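#' Solve the hybrid heritability model for additive genetic variance
#'
#' Under the hybrid transmission model, liability-scale broad-sense
#' heritability satisfies
#' \deqn{H^2 = \frac{G_A + x E_P}{G_A + E},}
#' where \eqn{G_A} is additive genetic variance, \eqn{E_P} the couple-shared
#' parental environmental variance, \eqn{E} the total environmental variance,
#' and \eqn{x \in (0,1)} the fraction of \eqn{E_P} transmitted to offspring.
#' `solve_hybrid()` inverts this for \eqn{G_A}:
#' \deqn{G_A = \frac{H^2 E - x E_P}{1 - H^2},}
#' the unique algebraic solution, and returns the full decomposition: the
#' transmitted component \eqn{x E_P}, total genetic variance
#' \eqn{G = G_A + x E_P}, the residual heritability \eqn{H^2 - G}, and the
#' percent shares of \eqn{H^2}.
#'
#' Inputs where the transmitted environment exceeds the heritability budget
#' (\eqn{H^2 E < x E_P}, which would force \eqn{G_A < 0}) are rejected with an
#' error rather than clamped: a negative variance signals inconsistent inputs.
#' The boundary case \eqn{x E_P = H^2 E} (exactly \eqn{G_A = 0}) is allowed.
#'
#' @param H2 Numeric vector of liability-scale heritabilities in `[0, 1)`.
#' @param E Numeric vector of total environmental variance fractions,
#'   `E >= E_P`.
#' @param E_P Numeric vector of couple-shared parental environmental variance
#'   fractions.
#' @param x Transmitted fraction of `E_P`, in `(0, 1)`. Scalar or vector.
#'
#' @return A tibble with one row per input: `G_A`, `xEP`, `G`, `residual`,
#'   `pct_G_of_H2`, `pct_residual_of_H2`, `mode` (`"solved"`), and
#'   `flag_negative_residual` (`TRUE` when `G > H2`, which can occur when the
#'   supplied components do not sum to `1 - H2`).
#'
#' @examples
#' solve_hybrid(H2 = 0.6, E = 0.4, E_P = 0.3, x = 0.5) # G_A = 0.225
#' @seealso [reproduce_hybrid()] for assembling the decomposition from a
#'   published `G_A` when `E` is unknown.
#' @export
solve_hybrid <- function(H2, E, E_P, x = 0.5) {
  assert_in_range(H2, "H2", 0, 1, upper_open = TRUE)
  assert_in_range(x, "x", 0, 1, lower_open = TRUE, upper_open = TRUE)
  assert_in_range(E_P, "E_P", 0, Inf)
  if (!is.numeric(E)) abort("`E` must be numeric.")
  n <- max(length(H2), length(E), length(E_P), length(x))
  H2 <- rep_len(H2, n); E <- rep_len(E, n)
  E_P <- rep_len(E_P, n); x <- rep_len(x, n)
  if (any(E < E_P)) {
    abort("`E` must be at least `E_P` (E_P is one of E's components).")
  }
  G_A <- (H2 * E - x * E_P) / (1 - H2)
  infeasible <- G_A < -1e-12
  if (any(infeasible)) {
    abort(paste0(
      "infeasible: transmitted environment exceeds heritability budget ",
      "(H2 * E < x * E_P) for input", if (sum(infeasible) > 1) "s" else "",
      " ", paste(which(infeasible), collapse = ", "),
      "; G_A would be negative."
    ))
  }
  G_A <- pmax(G_A, 0)
  hybrid_tbl(G_A = G_A, xEP = x * E_P, H2 = H2, mode = "solved")
}

#' Assemble the hybrid decomposition from a published additive variance
#'
#' When the total environmental variance \eqn{E} is not available but an
#' additive genetic variance \eqn{G_A} is printed in a source table,
#' the hybrid decomposition can still be assembled directly:
#' \eqn{G = G_A + x E_P}, residual \eqn{= H^2 - G}. This "reproduce" mode is
#' how published per-disorder decompositions are regenerated without the
#' unprinted environmental totals.
#'
#' A negative residual (published rounding can make \eqn{G} exceed \eqn{H^2}
#' by a whisker) is reported and flagged, not raised.
#'
#' @param H2 Heritabilities in `[0, 1)`.
#' @param G_A_reported Published additive genetic variance fractions in
#'   `[0, 1]`.
#' @param E_P Couple-shared parental environmental variance fractions.
#' @param x Transmitted fraction of `E_P`, in `(0, 1)`.
#'
#' @return A tibble as in [solve_hybrid()], with `mode = "reproduced"`.
#' @examples
#' reproduce_hybrid(H2 = 0.763, G_A_reported = 0.468, E_P = 0.2, x = 0.5)
#' @export
reproduce_hybrid <- function(H2, G_A_reported, E_P, x = 0.5) {
  assert_in_range(H2, "H2", 0, 1, upper_open = TRUE)
  assert_in_range(G_A_reported, "G_A_reported", 0, 1)
  assert_in_range(E_P, "E_P", 0, 1)
  assert_in_range(x, "x", 0, 1, lower_open = TRUE, upper_open = TRUE)
  n <- max(length(H2), length(G_A_reported), length(E_P), length(x))
  H2 <- rep_len(H2, n); G_A <- rep_len(G_A_reported, n)
  E_P <- rep_len(E_P, n); x <- rep_len(x, n)
  hybrid_tbl(G_A = G_A, xEP = x * E_P, H2 = H2, mode = "reproduced")
}

# Shared constructor: completes (G, residual, percent shares) from G_A + xEP.
hybrid_tbl <- function(G_A, xEP, H2, mode) {
  G <- G_A + xEP
  residual <- H2 - G
  pct_G <- ifelse(H2 > 0, 100 * G / H2, NA_real_)
  tibble::tibble(
    G_A = G_A,
    xEP = xEP,
    G = G,
    residual = residual,
    pct_G_of_H2 = pct_G,
    pct_residual_of_H2 = ifelse(H2 > 0, 100 - pct_G, NA_real_),
    mode = mode,
    flag_negative_residual = residual < 0
  )
}

#' Total measured additive genetic variance
#'
#' Sums the SNP-based additive genetic variance with the copy-number-variant
#' contribution, `G_A = G_SNP + G_CNV`. Missing CNV values count as zero.
#'
#' @param G_SNP SNP-based additive genetic variance fractions (required,
#'   non-negative).
#' @param G_CNV CNV contributions; `NA` or absent treated as 0.
#' @return Numeric vector `G_SNP + G_CNV`.
#' @examples
#' measured_genetics(0.28, 0.02) # 0.30
#' measured_genetics(0.21)       # 0.21
#' @export
measured_genetics <- function(G_SNP, G_CNV = 0) {
  assert_in_range(G_SNP, "G_SNP", 0, 1)
  if (is.logical(G_CNV) && all(is.na(G_CNV))) G_CNV <- as.numeric(G_CNV)
  assert_in_range(G_CNV, "G_CNV", 0, 1, allow_na = TRUE)
  G_CNV <- ifelse(is.na(G_CNV), 0, G_CNV)
  G_SNP + rep_len(G_CNV, length(G_SNP))
}

#' Residual heritability and its share of total heritability
#'
#' @param H2 Heritabilities, strictly positive.
#' @param G Modelled genetic (or hybrid genetic plus transmitted
#'   environmental) variance.
#' @return A tibble with columns `residual` (`H2 - G`) and `pct_of_H2`
#'   (`100 * residual / H2`), unrounded. Report formatting applies the
#'   package rounding convention separately.
#' @examples
#' residual_share(0.763, 0.30) # residual 0.463, 60.7% of H2
#' @export
residual_share <- function(H2, G) {
  if (!is.numeric(H2) || any(is.na(H2)) || any(H2 <= 0)) {
    abort("undefined share: `H2` must be strictly positive.")
  }
  n <- max(length(H2), length(G))
  H2 <- rep_len(H2, n); G <- rep_len(G, n)
  residual <- H2 - G
  tibble::tibble(residual = residual, pct_of_H2 = 100 * residual / H2)
}

#' Range of heritability explained across disorders
#'
#' Given per-disorder heritability `H2` and modelled genetic variance `G`,
#' computes the extremes of the explained share `100 * G / H2` and of the
#' residual `H2 - G` across disorders, optionally after excluding named
#' outliers (e.g. a disorder with no shared parental environmental
#' component). Integer-rounded percent endpoints and 3-decimal residual
#' endpoints are included for comparison against printed summary ranges.
#'
#' @param data A data frame with columns `H2`, `G` and (if `exclude` is used)
#'   `name`.
#' @param exclude Character vector of disorder names to drop before taking
#'   ranges.
#' @return A one-row tibble: `n_disorders`, `pct_min`, `pct_max`,
#'   `pct_min_int`, `pct_max_int`, `residual_min`, `residual_max`,
#'   `residual_min_3dp`, `residual_max_3dp`.
#' @examples
#' d <- tibble::tibble(
#'   name = c("a", "b"), H2 = c(0.763, 0.562), G = c(0.30, 0.27)
#' )
#' explained_range(d)
#' @export
explained_range <- function(data, exclude = NULL) {
  stopifnot(is.data.frame(data))
  if (!all(c("H2", "G") %in% names(data))) {
    abort("`data` must have columns `H2` and `G`.")
  }
  if (!is.null(exclude)) {
    if (!"name" %in% names(data)) {
      abort("excluding disorders requires a `name` column.")
    }
    data <- dplyr::filter(data, !.data$name %in% exclude)
  }
  if (nrow(data) == 0L) {
    abort("no disorders left after exclusions.")
  }
  pct <- 100 * data$G / data$H2
  res <- data$H2 - data$G
  tibble::tibble(
    n_disorders = nrow(data),
    pct_min = min(pct),
    pct_max = max(pct),
    pct_min_int = round_half_away(min(pct), 0),
    pct_max_int = round_half_away(max(pct), 0),
    residual_min = min(res),
    residual_max = max(res),
    residual_min_3dp = round_half_away(min(res), 3),
    residual_max_3dp = round_half_away(max(res), 3)
  )
}

#' The transmission-fraction grid evaluated by the hybrid model
#'
#' The four transmitted fractions of the couple-shared environmental variance
#' under which the hybrid model is evaluated, with 0.5 as the headline model.
#'
#' @return A numeric vector `c(0.25, 0.5, 0.6, 0.667)`.
#' @export
transmission_grid <- function() c(0.25, 0.5, 0.6, 0.667)
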