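#' Total environmental variance of a disorder summary
#'
#' The liability-scale environmental variance decomposes as
#' \eqn{E = E_P + E_F + E_S + E_U}: couple-shared parental, shared familial,
#' sibling-shared, and unique components. `total_environment()` returns the
#' supplied total `E_total` when present, otherwise the sum of the available
#' components. The component path needs at least `E_P` and `E_U` — a sum
#' without the unique-environment term is not a total — while absent `E_F` /
#' `E_S` count as zero. When both `E_total` and the full component set are
#' supplied they must agree to `1e-9`.
#'
#' @param data A data frame of disorder summaries with any of the columns
#'   `E_total`, `E_P`, `E_F`, `E_S`, `E_U` (per-row `NA` means absent).
#' @return A numeric vector of total environmental variances, one per row.
#' @examples
#' total_environment(tibble::tibble(E_P = 0.2, E_S = 0.05, E_U = 0.1)) # 0.35
#' total_environment(tibble::tibble(E_total = 0.4))                    # 0.4
#' @export
total_environment <- function(data) {
  stopifnot(is.data.frame(data))
  n <- nrow(data)
  comp_cols <- c("E_P", "E_F", "E_S", "E_U")
  get_col <- function(nm) {
    if (nm %in% names(data)) as.numeric(data[[nm]]) else rep(NA_real_, n)
  }
  comps <- vapply(comp_cols, get_col, numeric(n))
  comps <- matrix(comps, nrow = n, dimnames = list(NULL, comp_cols))
  e_total <- get_col("E_total")
  # the component-sum path needs the couple-shared and unique terms at least
  has_comp_set <- !is.na(comps[, "E_P"]) & !is.na(comps[, "E_U"])
  neg <- comps < 0
  if (any(neg, na.rm = TRUE) || any(e_total < 0, na.rm = TRUE)) {
    abort("environmental variance components must be non-negative.")
  }
  comp_sum <- rowSums(comps, na.rm = TRUE)
  out <- ifelse(!is.na(e_total), e_total, ifelse(has_comp_set, comp_sum, NA))
  bad <- is.na(out)
  if (any(bad)) {
    abort(sprintf(
      "insufficient environmental data for row%s %s: need `E_total` or the components (at least E_P and E_U).",
      if (sum(bad) > 1) "s" else "", paste(which(bad), collapse = ", ")
    ))
  }
  both <- !is.na(e_total) & rowSums(is.na(comps)) == 0
  if (any(both) && any(abs(e_total[both] - comp_sum[both]) > 1e-9)) {
    abort("`E_total` disagrees with the sum of the environmental components.")
  }
  out
}

# Columns the tabular disorder-summary format may carry; only `name` and `H2`
# are mandatory, everything else is NA-tolerant.
disorder_summary_cols <- function() {
  c("name", "H2", "E_P", "E_F", "E_S", "E_U", "E_total",
    "G_SNP", "G_CNV", "G_A_reported", "residual_hybrid_printed")
}

#' Validate a disorder summary table
#'
#' Checks the invariants of a per-disorder summary-statistics table:
#' mandatory `name` and `H2` columns, `H2` in `[0, 1)`, non-negative
#' environmental components, genetic fractions in `[0, 1]`, and agreement of
#' `E_total` with the component sum when both are fully specified.
#'
#' @param data A data frame; extra columns are permitted and preserved.
#' @return The input as a tibble, invisibly validated.
#' @export
validate_disorder_summary <- function(data) {
  stopifnot(is.data.frame(data))
  if (!all(c("name", "H2") %in% names(data))) {
    abort("a disorder summary needs `name` and `H2` columns.")
  }
  data <- tibble::as_tibble(data)
  assert_in_range(data$H2, "H2", 0, 1, upper_open = TRUE)
  for (col in c("E_P", "E_F", "E_S", "E_U", "E_total")) {
    if (col %in% names(data)) {
      assert_in_range(data[[col]], col, 0, 1, allow_na = TRUE)
    }
  }
  for (col in c("G_SNP", "G_CNV", "G_A_reported")) {
    if (col %in% names(data)) {
      assert_in_range(data[[col]], col, 0, 1, allow_na = TRUE)
    }
  }
  env_cols <- c("E_P", "E_F", "E_S", "E_U")
  if (all(c(env_cols, "E_total") %in% names(data))) {
    full <- stats::complete.cases(data[, env_cols]) & !is.na(data$E_total)
    if (any(full)) {
      s <- rowSums(data[full, env_cols])
      if (any(abs(s - data$E_total[full]) > 1e-9)) {
        abort("`E_total` disagrees with the sum of the environmental components.")
      }
    }
  }
  data
}

#' Bundled five-disorder summary table
#'
#' The five high-heritability neuropsychiatric disorders (autism spectrum
#' disorder, ADHD, bipolar disorder, major depression, schizophrenia) with
#' their liability-scale heritability `H2`, SNP-based and CNV genetic
#' variance (`G_SNP`, `G_CNV`), the additive genetic variance published for
#' the hybrid model at transmitted fraction 0.5 (`G_A_reported`), the
#' couple-shared parental environmental variance `E_P`, and the published
#' hybrid residual (`residual_hybrid_printed`, carried so reports can flag
#' source-rounding discrepancies).
#'
#' @return A five-row tibble in disorder-summary format.
#' @examples
#' example_disorders()
#' @export
example_disorders <- function() {
  path <- system.file("extdata", "disorder_summaries.tsv",
                      package = "transherit", mustWork = TRUE)
  read_disorder_summary(path)
}
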