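#' Detect potentially missed alternative alleles
#'
#' A homozygous-reference call is a potentially "missed" alternative
#' genotype when its observed allele balance is improbably high under the
#' fitted zero-inflated beta: upper-tail p-value below `alpha`.
#'
#' @param ab Numeric vector of allele balances for homozygous-reference
#'   calls.
#' @param hom_ref_model Zero-inflated [beinf_model()].
#' @param alpha Tail significance level, default 0.05.
#' @param genotype Optional character vector of genotype calls; if given,
#'   any non-`hom_ref` entry is an error (the definition only applies to
#'   homozygous-reference calls).
#' @return Logical vector.
#' @export
detect_missed <- function(ab, hom_ref_model, alpha = 0.05, genotype = NULL) {
  stopifnot(inherits(hom_ref_model, "beinf_model"))
  if (!is.null(genotype) && any(genotype != "hom_ref")) {
    abort("detect_missed: all calls must be hom_ref")
  }
  beinf_upper_tail(ab, hom_ref_model) < alpha
}

#' Variant-level called-missed ratio test
#'
#' Two-sided Fisher exact test of whether the ratio of called to missed
#' alternative genotypes differs between cases and controls, on the 2x2
#' table \[cases_called, cases_missed; controls_called, controls_missed\].
#'
#' @param cases_called,cases_missed,controls_called,controls_missed
#'   Non-negative integer counts.
#' @return Two-sided p-value. An all-zero table returns 1 with a warning.
#' @export
variant_called_missed_test <- function(cases_called, cases_missed,
                                       controls_called, controls_missed) {
  tab <- matrix(c(cases_called, cases_missed,
                  controls_called, controls_missed),
                nrow = 2, byrow = TRUE)
  if (any(tab < 0)) {
    abort("variant_called_missed_test: negative counts")
  }
  if (sum(tab) == 0) {
    warn("variant_called_missed_test: all-zero table, p = 1")
    return(1)
  }
  fisher.test(tab)$p.value
}

chisq_p_2x2 <- function(tab) {
  if (sum(tab) == 0 || any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(1)
  }
  p <- suppressWarnings(chisq.test(tab, correct = FALSE)$p.value)
  if (!is.finite(p)) 1 else p
}

# carriers-vs-noncarriers 2x2 from aggregated counts, capped at arm size
carrier_test <- function(case_carriers, control_carriers, case_n, control_n) {
  a <- min(case_carriers, case_n)
  c_ <- min(control_carriers, control_n)
  chisq_p_2x2(matrix(c(a, case_n - a, c_, control_n - c_),
                     nrow = 2, byrow = TRUE))
}

gene_tests_one <- function(v, case_n, control_n) {
  cc <- sum(v$cases_called)
  cm <- sum(v$cases_missed)
  kc <- sum(v$controls_called)
  km <- sum(v$controls_missed)

  # test 1: gene-aggregated called-missed ratio; Fisher when expected
  # cells are small, Pearson chi-square otherwise
  tab1 <- matrix(c(cc, cm, kc, km), nrow = 2, byrow = TRUE)
  p1 <- if (sum(tab1) == 0) {
    1
  } else {
    expected <- outer(rowSums(tab1), colSums(tab1)) / sum(tab1)
    if (min(expected) < 5) fisher.test(tab1)$p.value else chisq_p_2x2(tab1)
  }

  # test 2: association re-run with missed calls added as carriers
  p2 <- carrier_test(cc + cm, kc + km, case_n, control_n)

  # test 3: association re-run on called genotypes at non-biased sites
  clean <- dplyr::filter(v, !.data$bias)
  p3 <- if (nrow(clean) == 0L) {
    1
  } else {
    carrier_test(sum(clean$cases_called), sum(clean$controls_called),
                 case_n, control_n)
  }
  tibble(p_called_missed = p1, p_regenotyped = p2, p_cleaned = p3)
}

#' Association-ABB: re-evaluate candidate genes for bias-driven burden
#'
#' Given per-variant called/missed counts in cases and controls for a set
#' of candidate genes (typically the output of a rare-variant association
#' scan), performs the full re-evaluation:
#'
#' 1. a variant-wise Fisher exact test of the called-missed ratio between
#'    arms, with Benjamini-Hochberg FDR across variants; variants below
#'    `fdr_level` are flagged as AB-biased;
#' 2. three gene-level tests — the aggregated called-missed ratio test,
#'    a Pearson chi-square association re-run with missed calls included
#'    as carriers, and a chi-square re-run on called genotypes at
#'    non-biased variants only — each followed by BH FDR across genes.
#'
#' A gene is verdicted `likely_false` when its called-missed FDR is below
#' `fdr_level`, or when it is no longer significantly associated
#' (FDR above `fdr_level`) after adding missed calls or after removing
#' biased sites; otherwise `keep`.
#'
#' @param variants Tibble with columns `gene`, `cases_called`,
#'   `cases_missed`, `controls_called`, `controls_missed` and optionally
#'   identifying columns (`chrom`, `pos`, ...).
#' @param case_n,control_n Cohort sizes per arm.
#' @param fdr_level FDR level for all decisions, default 0.1.
#' @return List with two tibbles: `variants` (input plus
#'   `p_called_missed`, `fdr_called_missed`, `bias`) and `genes` (per-gene
#'   p-values, FDRs and `verdict`).
#' @export
associate_abb <- function(variants, case_n, control_n, fdr_level = 0.1) {
  needed <- c("gene", "cases_called", "cases_missed", "controls_called",
              "controls_missed")
  missing_cols <- setdiff(needed, names(variants))
  if (length(missing_cols) > 0L) {
    abort(paste0("associate_abb: missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(variants) == 0L) {
    abort("associate_abb: no variants")
  }

  variants <- variants |>
    mutate(
      p_called_missed = purrr::pmap_dbl(
        list(.data$cases_called, .data$cases_missed,
             .data$controls_called, .data$controls_missed),
        function(a, b, c, d) {
          if (a + b + c + d == 0) 1 else variant_called_missed_test(a, b, c, d)
        }
      )
    ) |>
    mutate(
      fdr_called_missed = p.adjust(.data$p_called_missed, method = "BH"),
      bias = .data$fdr_called_missed < fdr_level
    )

  genes <- variants |>
    group_by(.data$gene) |>
    group_modify(~ gene_tests_one(.x, case_n, control_n)) |>
    ungroup() |>
    mutate(
      fdr_called_missed = p.adjust(.data$p_called_missed, method = "BH"),
      fdr_regenotyped = p.adjust(.data$p_regenotyped, method = "BH"),
      fdr_cleaned = p.adjust(.data$p_cleaned, method = "BH"),
      verdict = ifelse(
        .data$fdr_called_missed < fdr_level |
          .data$fdr_regenotyped > fdr_level |
          .data$fdr_cleaned > fdr_level,
        "likely_false", "keep"
      )
    )

  list(variants = variants, genes = genes)
}
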