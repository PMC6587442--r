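#' Is a site observation informative?
#'
#' A sample is informative at a position when it covers it with at least
#' `min_depth` reads passing the base-quality filter (the quality filter
#' itself is applied at parse time, see [parse_pileup_line()]).
#'
#' @param depth_informative Integer vector of quality-passing depths.
#' @param min_depth Minimum informative depth, default 20.
#' @return Logical vector; `NA` depths are not informative.
#' @export
informative_filter <- function(depth_informative, min_depth = 20) {
  !is.na(depth_informative) & depth_informative >= min_depth
}

#' Per-position allele-balance bias summaries
#'
#' Aggregates per-sample genotype calls into the three per-position bias
#' strength measures:
#' * `rdab1` — mean devAB across informative samples,
#' * `rdab2` — fraction of samples whose best-genotype p-value falls below
#'   `sig_threshold` (significant deviation from the expected distribution),
#' * `rdab3` — mean of -log10(p) across samples, with p floored at
#'   `p_floor` to stay finite at extreme counts.
#'
#' Positions seen in fewer than `min_samples` informative samples are
#' excluded (dropped from the result, count reported via a message). Two
#' helper columns used for classifier training are carried along: `n_het`
#' (number of heterozygous-called samples) and `mean_dev_het` (mean devAB
#' among those).
#'
#' @param calls Tibble of per-sample calls as produced by
#'   [call_genotypes()]; must contain `chrom`, `pos`, `dev_ab`, `p_best`,
#'   `genotype`, already restricted to informative observations.
#' @param min_samples Minimum number of informative samples per position,
#'   default 80.
#' @param sig_threshold Per-sample significance level for `rdab2`, default
#'   0.05.
#' @param p_floor Floor applied to p-values before -log10, default 1e-12.
#' @return Tibble with one row per retained position: `chrom`, `pos`,
#'   `n_informative`, `rdab1`, `rdab2`, `rdab3`, `n_het`, `mean_dev_het`.
#' @export
summarize_sites <- function(calls, min_samples = 80, sig_threshold = 0.05,
                            p_floor = 1e-12) {
  stopifnot(all(c("chrom", "pos", "dev_ab", "p_best", "genotype")
                %in% names(calls)))
  out <- calls |>
    group_by(.data$chrom, .data$pos) |>
    summarise(
      n_informative = dplyr::n(),
      rdab1 = mean(.data$dev_ab),
      rdab2 = mean(.data$p_best < sig_threshold),
      rdab3 = mean(-log10(pmax(.data$p_best, p_floor))),
      n_het = sum(.data$genotype == "het"),
      mean_dev_het = if (any(.data$genotype == "het")) {
        mean(.data$dev_ab[.data$genotype == "het"])
      } else NA_real_,
      .groups = "drop"
    )
  n_excluded <- sum(out$n_informative < min_samples)
  if (n_excluded > 0L) {
    inform(paste0("excluded ", n_excluded, " position(s) with fewer than ",
                  min_samples, " informative samples"))
  }
  dplyr::filter(out, .data$n_informative >= min_samples)
}
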