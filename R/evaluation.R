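#' Round half-up
#'
#' Rounds to `digits` decimals with halves going up, matching how the
#' summary tables print rates and ratios (base `round()` rounds half to
#' even).
#'
#' @param x Non-negative numeric vector.
#' @param digits Number of decimals, default 2.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' True/false positive and failure rates of validation bins
#'
#' Computes, per bin of Sanger-validated SNVs, the TP and FP rates among
#' conclusive experiments (failed experiments excluded from the
#' denominator) and the failure rate over all attempted SNVs. Rates are
#' percentages rounded half-up to two decimals.
#'
#' @param data Tibble with columns `n_snvs`, `tp`, `fp`, `failed`
#'   (`tp + fp + failed` must equal `n_snvs` row-wise); other columns
#'   (e.g. a bin label) are carried through.
#' @return `data` with `tp_rate`, `fp_rate`, `fail_rate` columns added
#'   (percent, 2 decimals; `NA` when no conclusive experiment exists).
#' @export
sanger_rates <- function(data) {
  stopifnot(all(c("n_snvs", "tp", "fp", "failed") %in% names(data)))
  if (any(data$tp + data$fp + data$failed != data$n_snvs)) {
    abort("sanger_rates: tp + fp + failed must equal n_snvs")
  }
  data |>
    mutate(
      tp_rate = ifelse(.data$tp + .data$fp > 0,
                       round_half_up(100 * .data$tp / (.data$tp + .data$fp)),
                       NA_real_),
      fp_rate = ifelse(.data$tp + .data$fp > 0,
                       round_half_up(100 * .data$fp / (.data$tp + .data$fp)),
                       NA_real_),
      fail_rate = ifelse(.data$n_snvs > 0,
                         round_half_up(100 * .data$failed / .data$n_snvs),
                         NA_real_)
    )
}

#' Enrichment of flagged positions in a database versus background
#'
#' Observed frequency of flagged (very low confidence) positions in a
#' database, the ratio of that frequency to the background (exome-wide)
#' frequency, and a Pearson chi-square p-value (no continuity correction)
#' on the 2x2 flagged/unflagged table.
#'
#' @param data Tibble with columns `db_total`, `db_flagged`, `bg_total`,
#'   `bg_flagged`; other columns are carried through.
#' @return `data` with `observed_freq`, `expected_freq`, `ratio`,
#'   `chi_square_p` columns added (`ratio` is `NA` when nothing is flagged
#'   in the background).
#' @export
enrichment_ratio <- function(data) {
  stopifnot(all(c("db_total", "db_flagged", "bg_total", "bg_flagged")
                %in% names(data)))
  if (any(data$db_flagged > data$db_total | data$bg_flagged > data$bg_total)) {
    abort("enrichment_ratio: flagged counts exceed totals")
  }
  data |>
    mutate(
      observed_freq = .data$db_flagged / .data$db_total,
      expected_freq = .data$bg_flagged / .data$bg_total,
      ratio = ifelse(.data$bg_flagged > 0,
                     .data$observed_freq / .data$expected_freq, NA_real_),
      chi_square_p = purrr::pmap_dbl(
        list(.data$db_flagged, .data$db_total, .data$bg_flagged,
             .data$bg_total),
        function(df, dt, bf, bt) {
          chisq_p_2x2(matrix(c(df, dt - df, bf, bt - bf),
                             nrow = 2, byrow = TRUE))
        }
      )
    )
}

#' Transition-transversion ratio
#'
#' Transitions are A<->G and C<->T; everything else among SNVs is a
#' transversion. Around 3 is expected for exome callsets; systematic-error
#' sites drag the ratio down.
#'
#' @param ref,alt Character vectors of reference and alternative bases.
#' @return `count(transitions) / count(transversions)`, `NA` with a
#'   warning when there are no transversions.
#' @export
titv_ratio <- function(ref, alt) {
  ref <- toupper(ref)
  alt <- toupper(alt)
  ok <- ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T") &
    ref != alt
  if (!all(ok)) {
    abort("titv_ratio: inputs must be SNVs over A/C/G/T")
  }
  ti <- (ref == "A" & alt == "G") | (ref == "G" & alt == "A") |
    (ref == "C" & alt == "T") | (ref == "T" & alt == "C")
  n_tv <- sum(!ti)
  if (n_tv == 0L) {
    warn("titv_ratio: no transversions; ratio undefined")
    return(NA_real_)
  }
  sum(ti) / n_tv
}

#' Sanger validation counts per callability bin
#'
#' The published validation experiment: 209 suspicious heterozygous SNP
#' calls (allele balance 0.2-0.35) sampled across the four ABB confidence
#' bins and re-sequenced by Sanger. Input constants for the worked
#' examples in [sanger_rates()].
#'
#' @return Tibble with `bin`, `n_snvs`, `tp`, `fp`, `failed`.
#' @export
sanger_validation_counts <- function() {
  tibble(
    bin = factor(c("high", "medium", "low", "very_low"),
                 levels = c("high", "medium", "low", "very_low")),
    n_snvs = c(42L, 73L, 46L, 48L),
    tp = c(38L, 55L, 20L, 21L),
    fp = c(0L, 10L, 9L, 21L),
    failed = c(4L, 8L, 17L, 6L)
  )
}

#' Very-low-confidence position counts per variant database
#'
#' Counts of very-low-confidence (ABB > 0.9) positions in public variant
#' databases against the exome-wide background (81,609,944 informative
#' positions, 20,725 flagged). Input constants for the worked examples in
#' [enrichment_ratio()].
#'
#' @return Tibble with `database`, `db_total`, `db_flagged`, `bg_total`,
#'   `bg_flagged`.
#' @export
database_enrichment_counts <- function() {
  tibble(
    database = c("dbSNP", "EVS", "1000GP", "ExAC"),
    db_total = c(3172724L, 1840709L, 2653982L, 2662396L),
    db_flagged = c(12787L, 1114L, 4690L, 3510L),
    bg_total = 81609944L,
    bg_flagged = 20725L
  )
}
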