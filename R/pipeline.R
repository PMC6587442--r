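#' Build an ABB score table from cohort observations
#'
#' End-to-end driver for the callability workflow:
#' 1. fit the expected allele-balance model per genotype from labeled
#'    training pairs ([fit_ab_model()]);
#' 2. restrict to informative observations and call genotypes, p-values
#'    and devAB ([call_genotypes()]);
#' 3. aggregate per-position bias measures ([summarize_sites()]);
#' 4. label positions with at least `min_het` heterozygous-called samples
#'    by a two-component Gaussian mixture on their mean heterozygous
#'    devAB ([gmm_label()]);
#' 5. train the logistic callability model on those labels
#'    ([train_lr()]);
#' 6. score every summarized position ([score_positions()]).
#'
#' @param observations Tibble with `sample`, `chrom`, `pos`,
#'   `depth_informative`, `alt_count`, `ab`.
#' @param genotypes Tibble with `sample`, `chrom`, `pos`, `genotype`
#'   supplying training labels for the allele-balance model (from a
#'   variant callset or simulation truth).
#' @param min_depth,min_samples,sig_threshold Aggregation thresholds; see
#'   [informative_filter()] and [summarize_sites()].
#' @param min_het Minimum heterozygous-called samples for a position to
#'   enter classifier training; default 60 (scale it down for small
#'   cohorts).
#' @param n_bins Precision-map bins; see [train_lr()].
#' @param seed Integer seed for the mixture initialization and splits.
#' @return An `abb_fit` list with elements `ab_model`, `lr`, `summaries`
#'   and `scores` (the score table).
#' @export
build_abb_table <- function(observations, genotypes,
                            min_depth = 20, min_samples = 80,
                            sig_threshold = 0.05, min_het = 60,
                            n_bins = 20, seed = 1L) {
  training <- observations |>
    inner_join(genotypes, by = c("sample", "chrom", "pos"))
  ab_model <- fit_ab_model(training)

  calls <- observations |>
    dplyr::filter(informative_filter(.data$depth_informative, min_depth)) |>
    call_genotypes(ab_model)
  summaries <- summarize_sites(calls, min_samples = min_samples,
                               sig_threshold = sig_threshold)

  labeled <- summaries |>
    dplyr::filter(.data$n_het >= min_het, !is.na(.data$mean_dev_het))
  if (nrow(labeled) < 2L) {
    abort("build_abb_table: too few positions qualify for labeling")
  }
  labeled$label <- gmm_label(labeled$mean_dev_het, seed = seed)
  lr <- train_lr(labeled, n_bins = n_bins, seed = seed)

  structure(
    list(
      ab_model = ab_model,
      lr = lr,
      summaries = summaries,
      scores = score_positions(summaries, lr)
    ),
    class = "abb_fit"
  )
}

#' @export
print.abb_fit <- function(x, ...) {
  cat("<abb_fit>\n")
  print(x$ab_model)
  print(x$lr)
  cat(sprintf("  %d scored positions (%d very low confidence)\n",
              nrow(x$scores), sum(x$scores$confidence == "very_low")))
  invisible(x)
}

#' @describeIn build_abb_table One-row summary of the fitted pipeline.
#' @param x An `abb_fit`.
#' @param ... Unused.
#' @export
glance.abb_fit <- function(x, ...) {
  dplyr::bind_cols(
    glance(x$lr),
    tibble(n_positions = nrow(x$scores),
           n_very_low = sum(x$scores$confidence == "very_low"))
  )
}
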