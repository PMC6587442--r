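#' ABB confidence level of a score
#'
#' Bins an ABB score into the four genotype callability levels:
#' high (abb <= 0.15), medium (0.15 < abb <= 0.75), low (0.75 < abb <= 0.9)
#' and very_low (abb > 0.9). Boundaries belong to the lower bin, so 0.9 is
#' still `low` and anything strictly above it `very_low`.
#'
#' @param abb Numeric vector of ABB scores in \[0, 1\].
#' @return Factor with levels `high`, `medium`, `low`, `very_low`.
#' @export
abb_confidence <- function(abb) {
  cut(abb,
      breaks = c(-Inf, 0.15, 0.75, 0.9, Inf),
      labels = c("high", "medium", "low", "very_low"),
      right = TRUE)
}

score_table_float_cols <- c("rdab1", "rdab2", "rdab3", "lr_response", "abb")

#' Write an ABB score table
#'
#' Writes per-position score rows as a tab-separated file with a header and
#' floats at 6 decimals. Rows must already be sorted by (chrom, pos) —
#' chromosomes in contiguous blocks, positions non-decreasing within each —
#' so the table can be streamed against a sorted VCF.
#'
#' @param rows Tibble with columns `chrom`, `pos`, `n_informative`, `rdab1`,
#'   `rdab2`, `rdab3`, `lr_response`, `abb`, `confidence`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_score_table <- function(rows, path) {
  needed <- c("chrom", "pos", "n_informative", score_table_float_cols,
              "confidence")
  missing_cols <- setdiff(needed, names(rows))
  if (length(missing_cols) > 0L) {
    abort(paste0("score table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(rows) > 0L) {
    blocks <- rle(as.character(rows$chrom))$values
    if (anyDuplicated(blocks)) {
      abort("score table rows must be sorted by (chrom, pos): chromosome blocks interleaved")
    }
    ok <- rows |>
      group_by(.data$chrom) |>
      summarise(sorted = !is.unsorted(.data$pos), .groups = "drop")
    if (!all(ok$sorted)) {
      abort("score table rows must be sorted by (chrom, pos)")
    }
  }
  out <- rows |>
    select(all_of(needed)) |>
    mutate(across(all_of(score_table_float_cols), ~ sprintf("%.6f", .x)),
           confidence = as.character(.data$confidence))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read an ABB score table
#'
#' Inverse of [write_score_table()]; round-trips losslessly at the written
#' 6-decimal precision.
#'
#' @param path Path to a score table TSV.
#' @return Tibble with typed columns and `confidence` as a factor.
#' @export
read_score_table <- function(path) {
  readr::read_tsv(
    path,
    col_types = readr::cols(
      chrom = readr::col_character(),
      pos = readr::col_integer(),
      n_informative = readr::col_integer(),
      rdab1 = readr::col_double(),
      rdab2 = readr::col_double(),
      rdab3 = readr::col_double(),
      lr_response = readr::col_double(),
      abb = readr::col_double(),
      confidence = readr::col_character()
    ),
    progress = FALSE
  ) |>
    mutate(confidence = factor(.data$confidence,
                               levels = c("high", "medium", "low", "very_low")))
}
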