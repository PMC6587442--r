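#' Fit the heterozygous allele-balance binomial
#'
#' Heterozygous read evidence is modeled as Binomial(depth, p_het) with
#' p_het close to 0.5; the pooled maximum likelihood estimate is
#' sum(alt_count) / sum(depth_informative).
#'
#' @param data Tibble with columns `alt_count` and `depth_informative`
#'   for heterozygous-called observations.
#' @return An object of class `het_model` with elements `p_het` and `n`.
#' @export
fit_het_binomial <- function(data) {
  stopifnot(all(c("alt_count", "depth_informative") %in% names(data)))
  if (nrow(data) == 0L) {
    abort("fit_het_binomial: empty input")
  }
  if (any(data$depth_informative < 1)) {
    abort("fit_het_binomial: depths must be >= 1")
  }
  if (nrow(data) < 50L) {
    warn(paste0("fit_het_binomial: only ", nrow(data), " observations"))
  }
  p <- sum(data$alt_count) / sum(data$depth_informative)
  structure(list(p_het = p, n = nrow(data)), class = "het_model")
}

#' @export
print.het_model <- function(x, ...) {
  cat(sprintf("<het_model> p_het=%.4f (n=%d)\n", x$p_het, x$n))
  invisible(x)
}

#' Default genotype allele-balance model
#'
#' Builds a `genotype_ab_model` from explicit components, defaulting to
#' p_het = 0.5 and small-contamination homozygous models. Used when no
#' training genotype pairs are available.
#'
#' @param het A `het_model` or a numeric p_het.
#' @param hom_ref,hom_alt [beinf_model()] objects for the homozygous
#'   reference (zero-inflated) and alternative (one-inflated) classes.
#' @return An object of class `genotype_ab_model`.
#' @export
genotype_ab_model <- function(het = 0.5,
                              hom_ref = beinf_model(0.9, 0, 0.01, 100),
                              hom_alt = beinf_model(0.9, 1, 0.99, 100)) {
  if (is.numeric(het)) het <- structure(list(p_het = het, n = NA_integer_),
                                        class = "het_model")
  stopifnot(inherits(het, "het_model"),
            inherits(hom_ref, "beinf_model"),
            inherits(hom_alt, "beinf_model"))
  structure(list(het = het, hom_ref = hom_ref, hom_alt = hom_alt),
            class = "genotype_ab_model")
}

#' Fit expected allele-balance distributions for all three genotypes
#'
#' Fits the heterozygous binomial and the two inflated-beta homozygous
#' models from labeled training observations. Labels come from the caller
#' (a variant callset or simulation truth); the fit is cohort-global, one
#' model per genotype class.
#'
#' @param data Tibble with columns `alt_count`, `depth_informative`, `ab`
#'   and `genotype` (values `hom_ref`, `het`, `hom_alt`).
#' @return An object of class `genotype_ab_model` with elements `het`,
#'   `hom_ref`, `hom_alt`.
#' @export
fit_ab_model <- function(data) {
  stopifnot(all(c("alt_count", "depth_informative", "ab", "genotype")
                %in% names(data)))
  het_obs <- dplyr::filter(data, .data$genotype == "het")
  hr_obs <- dplyr::filter(data, .data$genotype == "hom_ref")
  ha_obs <- dplyr::filter(data, .data$genotype == "hom_alt")
  genotype_ab_model(
    het = fit_het_binomial(het_obs),
    hom_ref = fit_beinf(hr_obs$ab, "zero_inflated"),
    hom_alt = fit_beinf(ha_obs$ab, "one_inflated")
  )
}

#' @export
print.genotype_ab_model <- function(x, ...) {
  cat("<genotype_ab_model>\n  het: ")
  print(x$het)
  cat("  hom_ref: ")
  print(x$hom_ref)
  cat("  hom_alt: ")
  print(x$hom_alt)
  invisible(x)
}

#' @describeIn fit_ab_model Tidy all model parameters into one tibble.
#' @param x A `genotype_ab_model`.
#' @param ... Unused.
#' @export
tidy.genotype_ab_model <- function(x, ...) {
  dplyr::bind_rows(
    tibble(component = "het", term = "p_het", estimate = x$het$p_het),
    tidy(x$hom_ref) |> mutate(component = "hom_ref", .before = 1L),
    tidy(x$hom_alt) |> mutate(component = "hom_alt", .before = 1L)
  )
}

#' @describeIn fit_ab_model One-row model summary.
#' @export
glance.genotype_ab_model <- function(x, ...) {
  tibble(
    p_het = x$het$p_het,
    n_het = x$het$n,
    hom_ref_alpha = x$hom_ref$alpha,
    hom_alt_alpha = x$hom_alt$alpha,
    hom_ref_degenerate = x$hom_ref$degenerate,
    hom_alt_degenerate = x$hom_alt$degenerate
  )
}

#' Serialize / restore a genotype allele-balance model
#'
#' The model is written as a small JSON text file (p_het plus
#' alpha/gamma/mu/phi per homozygous class) so scoring runs are
#' reproducible.
#'
#' @param model A `genotype_ab_model`.
#' @param path File path.
#' @return `write_ab_model()` returns `path` invisibly; `read_ab_model()`
#'   the restored model.
#' @export
write_ab_model <- function(model, path) {
  stopifnot(inherits(model, "genotype_ab_model"))
  payload <- list(
    het = list(p_het = model$het$p_het, n = model$het$n),
    hom_ref = model$hom_ref[c("alpha", "gamma", "mu", "phi", "degenerate")],
    hom_alt = model$hom_alt[c("alpha", "gamma", "mu", "phi", "degenerate")]
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ab_model
#' @export
read_ab_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  genotype_ab_model(
    het = structure(list(p_het = p$het$p_het,
                         n = p$het$n %||% NA_integer_),
                    class = "het_model"),
    hom_ref = beinf_model(p$hom_ref$alpha, p$hom_ref$gamma, p$hom_ref$mu,
                          p$hom_ref$phi, p$hom_ref$degenerate %||% FALSE),
    hom_alt = beinf_model(p$hom_alt$alpha, p$hom_alt$gamma, p$hom_alt$mu,
                          p$hom_alt$phi, p$hom_alt$degenerate %||% FALSE)
  )
}

#' Exact two-sided binomial p-value (minimum-likelihood ordering)
#'
#' P-value of observing `alt` successes in `depth` trials under success
#' probability `p`: the sum of the probabilities of all outcomes no more
#' likely than the observed one. Deviations in either direction count as
#' evidence against the heterozygous expectation. A relative tolerance of
#' 1e-7 absorbs floating-point ties between mathematically equal outcome
#' probabilities (the convention `stats::binom.test()` also uses).
#'
#' @param alt Integer vector of alternative read counts.
#' @param depth Integer vector of informative depths (recycled against
#'   `alt`).
#' @param p Success probability (scalar).
#' @return Numeric vector of p-values in \[0, 1\].
#' @export
binom_pvalue_two_sided <- function(alt, depth, p = 0.5) {
  stopifnot(length(p) == 1L, p > 0, p < 1)
  n_obs <- max(length(alt), length(depth))
  alt <- rep_len(alt, n_obs)
  depth <- rep_len(depth, n_obs)
  if (any(alt < 0 | alt > depth)) {
    abort("binom_pvalue_two_sided: alt outside [0, depth]")
  }
  out <- numeric(n_obs)
  for (n in unique(depth)) {
    idx <- which(depth == n)
    d <- dbinom(0:n, n, p)
    o <- order(d)
    ds <- d[o]
    cs <- cumsum(ds)
    pos <- findInterval(d[alt[idx] + 1L] * (1 + 1e-7), ds)
    out[idx] <- pmin(1, cs[pos])
  }
  out
}

#' Genotype p-values for observed allele balance
#'
#' For every observation, computes one p-value per diploid genotype:
#' `p_het` is the exact two-sided binomial p of the alt count given depth
#' ([binom_pvalue_two_sided()]); `p_hom_ref` the upper-tail probability of
#' the observed allele balance under the zero-inflated beta (point mass at
#' 0 included); `p_hom_alt` the symmetric lower tail under the
#' one-inflated beta.
#'
#' @param data Tibble with columns `alt_count`, `depth_informative`, `ab`.
#' @param model A `genotype_ab_model`.
#' @return `data` with `p_hom_ref`, `p_het`, `p_hom_alt` columns added.
#' @export
genotype_pvalues <- function(data, model) {
  stopifnot(inherits(model, "genotype_ab_model"))
  if (any(data$depth_informative < 1)) {
    abort("genotype_pvalues: depth_informative must be >= 1")
  }
  data |>
    mutate(
      p_hom_ref = beinf_upper_tail(.data$ab, model$hom_ref),
      p_het = binom_pvalue_two_sided(.data$alt_count,
                                     .data$depth_informative,
                                     model$het$p_het),
      p_hom_alt = beinf_lower_tail(.data$ab, model$hom_alt)
    )
}

#' Most likely genotype from three p-values
#'
#' The genotype with the greatest p-value is taken as the most likely one.
#' Ties break deterministically in the order hom_ref > het > hom_alt.
#'
#' @param p_hom_ref,p_het,p_hom_alt Numeric vectors of p-values.
#' @return Character vector with values `hom_ref`, `het`, `hom_alt`.
#' @export
assign_genotype <- function(p_hom_ref, p_het, p_hom_alt) {
  ifelse(p_hom_ref >= p_het & p_hom_ref >= p_hom_alt, "hom_ref",
         ifelse(p_het >= p_hom_alt, "het", "hom_alt"))
}

#' Deviation of observed from expected allele balance
#'
#' devAB measures how far the observed allele balance sits from the
#' expectation of the assigned genotype: `ab - 0` for homozygous
#' reference, `|ab - 0.5|` for heterozygous, `|ab - 1|` for homozygous
#' alternative.
#'
#' @param ab Numeric vector of allele balances in \[0, 1\].
#' @param genotype Character vector (`hom_ref`, `het`, `hom_alt`).
#' @return Numeric vector of deviations in \[0, 1\].
#' @export
dev_ab <- function(ab, genotype) {
  n <- max(length(ab), length(genotype))
  ab <- rep_len(ab, n)
  genotype <- rep_len(genotype, n)
  bad <- !genotype %in% c("hom_ref", "het", "hom_alt")
  if (any(bad)) {
    abort(paste0("dev_ab: unknown genotype '", genotype[bad][1], "'"))
  }
  ifelse(genotype == "hom_ref", ab,
         ifelse(genotype == "het", abs(ab - 0.5), 1 - ab))
}

#' Call genotypes and deviations for a cohort of observations
#'
#' Convenience wrapper: computes the three genotype p-values, assigns the
#' most likely genotype, and attaches the best-genotype p-value (`p_best`)
#' and `dev_ab`.
#'
#' @inheritParams genotype_pvalues
#' @return `data` with `p_hom_ref`, `p_het`, `p_hom_alt`, `genotype`,
#'   `p_best` and `dev_ab` columns added.
#' @export
call_genotypes <- function(data, model) {
  genotype_pvalues(data, model) |>
    mutate(
      genotype = assign_genotype(.data$p_hom_ref, .data$p_het,
                                 .data$p_hom_alt),
      p_best = pmax(.data$p_hom_ref, .data$p_het, .data$p_hom_alt),
      dev_ab = dev_ab(.data$ab, .data$genotype)
    )
}
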