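#' Per-disorder residual-heritability table under both models
#'
#' For each disorder in a summary table, computes the decomposition of
#' liability-scale heritability under (a) the measured-genetics model
#' (`G = G_SNP + G_CNV`) and (b) the hybrid transmission model
#' (`G = G_A + x * E_P`), with residuals and percent shares of `H2`.
#' In `"reproduced"` mode the hybrid additive variance comes from the
#' `G_A_reported` column (no environmental totals needed); in `"solved"`
#' mode it is solved from `H2`, the total environmental variance (from
#' `E_total` or the component columns) and `E_P` via [solve_hybrid()].
#'
#' If the input carries a `residual_hybrid_printed` column (a residual as
#' printed in the source the summary was transcribed from), rows whose
#' computed residual disagrees with the printed one at 3 decimals get a
#' provenance note — the package reports its own arithmetic and flags the
#' source's rounding, rather than forcing the printed value.
#'
#' @param disorders A disorder summary data frame (see
#'   [read_disorder_summary()] for the column contract).
#' @param x Transmitted fraction of `E_P`, in `(0, 1)`.
#' @param mode `"reproduced"` (default) or `"solved"`.
#' @return A tibble with one row per disorder: `name`, `H2`,
#'   `G_measured`, `pct_measured`, `residual_measured`,
#'   `pct_residual_measured`, `G_A_hybrid`, `xEP`, `G_hybrid`,
#'   `pct_hybrid`, `residual_hybrid`, `pct_residual_hybrid`, `note`.
#'   Values are unrounded; see [format_residual_table()] for the report rounding
#'   convention.
#' @examples
#' build_residual_table(example_disorders(), x = 0.5)
#' @export
build_residual_table <- function(disorders, x = 0.5, mode = c("reproduced", "solved")) {
  mode <- match.arg(mode)
  assert_scalar_number(x, "x")
  assert_in_range(x, "x", 0, 1, lower_open = TRUE, upper_open = TRUE)
  disorders <- validate_disorder_summary(disorders)
  if (nrow(disorders) == 0L) {
    return(tibble::tibble(
      name = character(), H2 = numeric(),
      G_measured = numeric(), pct_measured = numeric(),
      residual_measured = numeric(), pct_residual_measured = numeric(),
      G_A_hybrid = numeric(), xEP = numeric(), G_hybrid = numeric(),
      pct_hybrid = numeric(), residual_hybrid = numeric(),
      pct_residual_hybrid = numeric(), note = character()
    ))
  }

  # field requirements, reported per disorder
  missing_fields <- purrr::map_chr(seq_len(nrow(disorders)), function(i) {
    want <- c("G_SNP",
              if (mode == "reproduced") c("G_A_reported", "E_P") else "E_P")
    absent <- want[vapply(want, function(col) {
      !col %in% names(disorders) || is.na(disorders[[col]][i])
    }, logical(1))]
    paste(absent, collapse = ", ")
  })
  if (any(missing_fields != "")) {
    bad <- which(missing_fields != "")
    abort(paste0(
      "missing required fields:\n",
      paste(sprintf("  %s: %s", disorders$name[bad], missing_fields[bad]),
            collapse = "\n")
    ))
  }

  G_CNV <- if ("G_CNV" %in% names(disorders)) disorders$G_CNV else 0
  G_meas <- measured_genetics(disorders$G_SNP, G_CNV)
  meas <- residual_share(disorders$H2, G_meas)

  note <- rep(NA_character_, nrow(disorders))
  if (mode == "reproduced") {
    hyb <- reproduce_hybrid(disorders$H2, disorders$G_A_reported,
                            disorders$E_P, x = x)
  } else {
    hyb <- purrr::map_dfr(seq_len(nrow(disorders)), function(i) {
      tryCatch(
        solve_hybrid(disorders$H2[i],
                     total_environment(disorders[i, ]),
                     disorders$E_P[i], x = x),
        error = function(e) {
          note[i] <<- conditionMessage(e)
          tibble::tibble(
            G_A = NA_real_, xEP = NA_real_, G = NA_real_,
            residual = NA_real_, pct_G_of_H2 = NA_real_,
            pct_residual_of_H2 = NA_real_, mode = "solved",
            flag_negative_residual = NA
          )
        }
      )
    })
  }

  out <- tibble::tibble(
    name = disorders$name,
    H2 = disorders$H2,
    G_measured = G_meas,
    pct_measured = 100 * G_meas / disorders$H2,
    residual_measured = meas$residual,
    pct_residual_measured = meas$pct_of_H2,
    G_A_hybrid = hyb$G_A,
    xEP = hyb$xEP,
    G_hybrid = hyb$G,
    pct_hybrid = hyb$pct_G_of_H2,
    residual_hybrid = hyb$residual,
    pct_residual_hybrid = hyb$pct_residual_of_H2,
    note = note
  )

  if ("residual_hybrid_printed" %in% names(disorders)) {
    printed <- disorders$residual_hybrid_printed
    mismatch <- !is.na(printed) & !is.na(out$residual_hybrid) &
      round_half_away(out$residual_hybrid, 3) != printed
    out$note[mismatch] <- paste0(
      ifelse(is.na(out$note[mismatch]), "", paste0(out$note[mismatch], "; ")),
      sprintf(
        "computed hybrid residual %.3f differs from source-printed %.3f (source rounding)",
        round_half_away(out$residual_hybrid[mismatch], 3), printed[mismatch]
      )
    )
  }
  out
}

#' Format a residual-heritability table with the report rounding convention
#'
#' Variances are rounded to 3 decimals, percentages to 1 decimal (ties half
#' away from zero), mirroring how such summary tables are printed.
#'
#' @param tbl Output of [build_residual_table()].
#' @return A tibble of character cells `"<variance> (<pct>%)"` per model
#'   plus `name`, `H2` and `note`.
#' @export
format_residual_table <- function(tbl) {
  cell <- function(v, p) {
    ifelse(is.na(v), NA_character_,
           sprintf("%.3f (%.1f%%)", round_half_away(v, 3),
                   round_half_away(p, 1)))
  }
  tibble::tibble(
    name = tbl$name,
    H2 = sprintf("%.3f", round_half_away(tbl$H2, 3)),
    measured_G = cell(tbl$G_measured, tbl$pct_measured),
    measured_residual = cell(tbl$residual_measured, tbl$pct_residual_measured),
    hybrid_G = cell(tbl$G_hybrid, tbl$pct_hybrid),
    hybrid_residual = cell(tbl$residual_hybrid, tbl$pct_residual_hybrid),
    note = tbl$note
  )
}

#' Stacked genetic-variance series ordered by heritability
#'
#' Builds the data series behind the stacked-bar view of the hybrid model:
#' disorders sorted by decreasing `H2` (ties broken by name for
#' determinism), each with its additive genetic variance `G_A`, transmitted
#' environmental component `x * E_P`, their sum `G`, and `H2`. Render with
#' [autoplot()].
#'
#' @inheritParams build_residual_table
#' @return A tibble of class `"variance_series"` with columns `name`, `H2`,
#'   `G_A`, `xEP`, `G`, carrying `x` as an attribute.
#' @examples
#' series <- build_variance_series(example_disorders(), x = 0.5)
#' autoplot(series)
#' @export
build_variance_series <- function(disorders, x = 0.5,
                              mode = c("reproduced", "solved")) {
  tbl <- build_residual_table(disorders, x = x, mode = mode)
  series <- tbl |>
    dplyr::arrange(dplyr::desc(.data$H2), .data$name) |>
    dplyr::select("name", "H2", G_A = "G_A_hybrid", "xEP", G = "G_hybrid")
  attr(series, "x") <- x
  class(series) <- c("variance_series", class(series))
  series
}

#' @rdname build_variance_series
#' @param object A `"variance_series"` tibble.
#' @param ... Unused.
#' @method autoplot variance_series
#' @export
autoplot.variance_series <- function(object, ...) {
  long <- object |>
    dplyr::mutate(name = factor(.data$name, levels = .data$name)) |>
    tidyr::pivot_longer(c("G_A", "xEP"), names_to = "component",
                        values_to = "variance") |>
    dplyr::mutate(component = factor(
      .data$component, levels = c("xEP", "G_A"),
      labels = c("transmitted environment (x E_P)",
                 "additive genetic (G_A)")
    ))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$name)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$variance,
                                   fill = .data$component)) +
    ggplot2::geom_point(
      data = dplyr::distinct(long, .data$name, .data$H2),
      ggplot2::aes(y = .data$H2, shape = "H2"), size = 2
    ) +
    ggplot2::scale_shape_manual(NULL, values = c(H2 = 18)) +
    ggplot2::labs(
      x = NULL, y = "liability variance fraction", fill = NULL,
      title = sprintf("Hybrid genetic variance G = G_A + %g E_P, by decreasing H2",
                      attr(object, "x") %||% NA)
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Aggregate explained and residual ranges across disorders
#'
#' Recomputes the headline cross-disorder summaries from a
#' [build_residual_table()] result: the range of heritability explained by measured
#' genetics, and — after excluding named outliers (typically a disorder
#' whose environment has no couple-shared component, for which the hybrid
#' model is degenerate) — the ranges of heritability explained and left
#' residual under the hybrid model.
#'
#' @param tbl Output of [build_residual_table()].
#' @param exclude_hybrid Disorder names excluded from the hybrid-model
#'   ranges.
#' @return A tibble with columns `model`, `quantity`, `min`, `max`,
#'   `min_rounded`, `max_rounded` (percent ranges rounded to integer,
#'   residual variances to 3 decimals).
#' @examples
#' aggregate_claims(build_residual_table(example_disorders()), exclude_hybrid = "ASD")
#' @export
aggregate_claims <- function(tbl, exclude_hybrid = NULL) {
  stopifnot(is.data.frame(tbl))
  meas <- explained_range(
    dplyr::transmute(tbl, name = .data$name, H2 = .data$H2,
                     G = .data$G_measured)
  )
  hyb <- explained_range(
    dplyr::transmute(tbl, name = .data$name, H2 = .data$H2,
                     G = .data$G_hybrid),
    exclude = exclude_hybrid
  )
  res_pct <- 100 * c(
    min = 1 - hyb$pct_max / 100,
    max = 1 - hyb$pct_min / 100
  )
  tibble::tibble(
    model = c("measured", "hybrid", "hybrid", "hybrid"),
    quantity = c("explained_pct", "explained_pct", "residual_variance",
                 "residual_pct"),
    min = c(meas$pct_min, hyb$pct_min, hyb$residual_min, res_pct[["min"]]),
    max = c(meas$pct_max, hyb$pct_max, hyb$residual_max, res_pct[["max"]]),
    min_rounded = c(meas$pct_min_int, hyb$pct_min_int, hyb$residual_min_3dp,
                    round_half_away(res_pct[["min"]], 0)),
    max_rounded = c(meas$pct_max_int, hyb$pct_max_int, hyb$residual_max_3dp,
                    round_half_away(res_pct[["max"]], 0))
  )
}
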