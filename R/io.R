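# Tabular input/output. TSV (tab-separated, header row, '.' decimals) is the
# canonical format; CSV is accepted on read by sniffing the header line.
# readr handles .gz paths transparently in both directions.

sniff_delim <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

#' Read a disorder summary table
#'
#' Reads a per-disorder summary-statistics table (TSV canonical; CSV detected
#' automatically) and validates it with [validate_disorder_summary()].
#' Expected columns: `name`, `H2`, and optionally `E_P`, `E_F`, `E_S`, `E_U`,
#' `E_total`, `G_SNP`, `G_CNV`, `G_A_reported`, `residual_hybrid_printed`.
#'
#' @param path Path to a TSV/CSV file (optionally gzip-compressed).
#' @return A validated tibble.
#' @export
read_disorder_summary <- function(path) {
  delim <- sniff_delim(path)
  spec <- readr::cols(name = readr::col_character(),
                      .default = readr::col_double())
  data <- readr::read_delim(path, delim = delim, col_types = spec,
                            na = c("", "NA"), progress = FALSE)
  validate_disorder_summary(data)
}

#' Write a disorder summary table
#'
#' @param data A disorder summary data frame.
#' @param path Output path; written as TSV.
#' @return `path`, invisibly.
#' @export
write_disorder_summary <- function(data, path) {
  validate_disorder_summary(data)
  readr::write_tsv(data, path, progress = FALSE)
  invisible(path)
}

#' Write a simulated family table
#'
#' Writes the per-individual family table as TSV (gzip-transparent: use a
#' `.gz` path to compress). When `metadata = TRUE` a sidecar JSON
#' (`<path>.meta.json`) records the generating parameters, seed, threshold
#' and package version, making runs reproducible from the file pair alone.
#'
#' @param fam A family table from [simulate_families()].
#' @param path Output TSV path.
#' @param metadata Write the sidecar JSON? Default `TRUE` when the table
#'   carries simulation parameters.
#' @return `path`, invisibly.
#' @export
write_family_table <- function(fam, path,
                               metadata = !is.null(attr(fam, "params"))) {
  stopifnot(is.data.frame(fam))
  readr::write_tsv(tibble::as_tibble(fam), path, progress = FALSE)
  if (isTRUE(metadata)) {
    params <- attr(fam, "params")
    meta <- list(
      params = unclass(params),
      threshold = attr(fam, "threshold"),
      package = "transherit",
      version = as.character(utils::packageVersion("transherit"))
    )
    jsonlite::write_json(meta, paste0(path, ".meta.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Read a simulated family table
#'
#' Restores a family table written by [write_family_table()]. If the sidecar
#' metadata JSON is present, the simulation parameters and threshold are
#' re-attached as attributes.
#'
#' @param path Path to the family TSV.
#' @return A tibble with the documented family-table columns.
#' @export
read_family_table <- function(path) {
  spec <- readr::cols(
    family_id = readr::col_integer(),
    role = readr::col_character(),
    offspring_index = readr::col_integer(),
    genetic = readr::col_double(),
    shared_env = readr::col_double(),
    sibling_env = readr::col_double(),
    unique_env = readr::col_double(),
    liability = readr::col_double(),
    affected = readr::col_logical()
  )
  fam <- readr::read_tsv(path, col_types = spec, progress = FALSE)
  missing_cols <- setdiff(c("family_id", "role", "affected"), names(fam))
  if (length(missing_cols)) {
    abort(sprintf("family table is missing column(s): %s.",
                  paste(missing_cols, collapse = ", ")))
  }
  meta_path <- paste0(path, ".meta.json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    attr(fam, "params") <- meta$params
    attr(fam, "threshold") <- meta$threshold
  }
  fam
}
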