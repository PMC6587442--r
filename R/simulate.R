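#' Configuration for a synthetic sequencing cohort
#'
#' Describes a diploid WES-like cohort with known ground truth: genotypes
#' drawn per site from Hardy-Weinberg proportions at a uniformly drawn
#' allele frequency, read depths from a negative binomial (mean 60,
#' dispersion 5 by default, approximating exome coverage heterogeneity),
#' heterozygous alt counts binomial around 0.5, homozygous allele balance
#' from inflated-beta error models, and a configurable fraction of sites
#' turned into systematic-error sites: at those, a `bias_penetrance`
#' fraction of samples (optionally restricted to a batch subset, mimicking
#' a capture-kit effect) has its read evidence replaced by
#' binomial(depth, `bias_ab`) draws — heterozygous-looking evidence in the
#' suspicious 0.2-0.35 allele-balance band.
#'
#' @param n_samples,n_sites Cohort dimensions.
#' @param depth_mean,depth_dispersion Negative-binomial depth parameters
#'   (mean / size).
#' @param maf_range Range of the per-site alternative allele frequency.
#' @param bias_fraction Fraction of sites made systematic-error sites.
#' @param bias_ab Target allele balance of biased evidence, default 0.25.
#' @param bias_penetrance Fraction of samples affected per biased site.
#' @param batch_fraction Optional fraction of samples forming the batch to
#'   which bias is restricted (`NULL` = all samples eligible).
#' @param het_p Heterozygous binomial success probability, default 0.5.
#' @param hom_ref,hom_alt Homozygous allele-balance error models
#'   ([beinf_model()]); defaults encode small alternative-read
#'   contamination from sequencing error.
#' @param seed Integer seed; everything downstream is deterministic in it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_samples = 100, n_sites = 2000,
                       depth_mean = 60, depth_dispersion = 5,
                       maf_range = c(0.05, 0.5),
                       bias_fraction = 0.05, bias_ab = 0.25,
                       bias_penetrance = 0.3, batch_fraction = NULL,
                       het_p = 0.5,
                       hom_ref = beinf_model(0.9, 0, 0.01, 100),
                       hom_alt = beinf_model(0.9, 1, 0.99, 100),
                       seed = 1L) {
  stopifnot(
    n_samples >= 1, n_sites >= 1, depth_mean >= 1, depth_dispersion > 0,
    length(maf_range) == 2, all(maf_range >= 0), all(maf_range <= 1),
    bias_ab >= 0, bias_ab <= 1,
    bias_penetrance >= 0, bias_penetrance <= 1,
    het_p > 0, het_p < 1,
    inherits(hom_ref, "beinf_model"), inherits(hom_alt, "beinf_model")
  )
  if (bias_fraction < 0 || bias_fraction > 1) {
    abort("sim_config: bias_fraction must be in [0, 1]")
  }
  if (!is.null(batch_fraction) &&
      (batch_fraction <= 0 || batch_fraction > 1)) {
    abort("sim_config: batch_fraction must be in (0, 1]")
  }
  structure(
    list(n_samples = n_samples, n_sites = n_sites, depth_mean = depth_mean,
         depth_dispersion = depth_dispersion, maf_range = maf_range,
         bias_fraction = bias_fraction, bias_ab = bias_ab,
         bias_penetrance = bias_penetrance, batch_fraction = batch_fraction,
         het_p = het_p, hom_ref = hom_ref, hom_alt = hom_alt,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

other_bases <- function(ref) {
  vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1L),
         character(1))
}

#' Simulate a sequencing cohort with known bias truth
#'
#' Draws the cohort described by a [sim_config()]: per-site allele
#' frequency and bias status, per-sample genotypes, depths and alt read
#' counts. Observations with zero depth are dropped (the position is
#' simply uncovered in that sample). Deterministic given `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return An `abb_cohort` list with elements `observations` (tibble:
#'   `sample`, `chrom`, `pos`, `ref_base`, `alt_base`,
#'   `depth_informative`, `alt_count`, `ab`, `true_genotype`,
#'   `called_genotype` — a naive threshold call standing in for the
#'   upstream variant caller's training labels — and `affected`),
#'   `truth` (tibble: `chrom`, `pos`, `maf`, `bias`), and `config`.
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed, {
    sites <- tibble(
      chrom = "chr1",
      pos = seq_len(cfg$n_sites) * 100L,
      ref_base = sample(c("A", "C", "G", "T"), cfg$n_sites, replace = TRUE),
      maf = runif(cfg$n_sites, cfg$maf_range[1], cfg$maf_range[2]),
      bias = seq_len(cfg$n_sites) %in%
        sample(cfg$n_sites, round(cfg$bias_fraction * cfg$n_sites))
    )
    sites$alt_base <- other_bases(sites$ref_base)

    samples <- sprintf("S%03d", seq_len(cfg$n_samples))
    in_batch <- if (is.null(cfg$batch_fraction)) {
      rep(TRUE, cfg$n_samples)
    } else {
      seq_len(cfg$n_samples) %in%
        sample(cfg$n_samples,
               max(1L, round(cfg$batch_fraction * cfg$n_samples)))
    }

    obs <- tidyr::expand_grid(
      sample = samples,
      site = seq_len(cfg$n_sites)
    ) |>
      mutate(
        chrom = sites$chrom[.data$site],
        pos = sites$pos[.data$site],
        ref_base = sites$ref_base[.data$site],
        alt_base = sites$alt_base[.data$site],
        maf = sites$maf[.data$site],
        bias = sites$bias[.data$site],
        in_batch = rep(in_batch, each = cfg$n_sites)
      )

    n <- nrow(obs)
    g_draw <- runif(n)
    p <- obs$maf
    hom_ref_cut <- (1 - p)^2
    het_cut <- hom_ref_cut + 2 * p * (1 - p)
    obs$true_genotype <- ifelse(g_draw < hom_ref_cut, "hom_ref",
                                ifelse(g_draw < het_cut, "het", "hom_alt"))
    obs$depth_informative <- rnbinom(n, size = cfg$depth_dispersion,
                                     mu = cfg$depth_mean)

    ab_true <- numeric(n)
    is_het <- obs$true_genotype == "het"
    is_hr <- obs$true_genotype == "hom_ref"
    is_ha <- obs$true_genotype == "hom_alt"
    ab_true[is_het] <- cfg$het_p
    ab_true[is_hr] <- rbeinf(sum(is_hr), cfg$hom_ref)
    ab_true[is_ha] <- rbeinf(sum(is_ha), cfg$hom_alt)

    obs$affected <- obs$bias & obs$in_batch &
      runif(n) < cfg$bias_penetrance &
      obs$true_genotype != "hom_alt"
    ab_true[obs$affected] <- cfg$bias_ab

    obs$alt_count <- rbinom(n, obs$depth_informative, ab_true)
    obs <- obs |>
      dplyr::filter(.data$depth_informative > 0) |>
      mutate(
        ab = .data$alt_count / .data$depth_informative,
        # a naive hard-threshold genotyper standing in for the upstream
        # variant caller whose calls supply model-training labels; biased
        # evidence (AB ~ 0.25) is called heterozygous, as a read-backed
        # caller would, so it contaminates the het class, not the clean
        # homozygous fits
        called_genotype = ifelse(.data$ab <= 0.15, "hom_ref",
                                 ifelse(.data$ab >= 0.85, "hom_alt", "het"))
      ) |>
      select("sample", "chrom", "pos", "ref_base", "alt_base",
             "depth_informative", "alt_count", "ab", "true_genotype",
             "called_genotype", "affected")

    structure(
      list(
        observations = obs,
        truth = sites |> select("chrom", "pos", "maf", "bias"),
        config = cfg
      ),
      class = "abb_cohort"
    )
  })
}

#' @export
print.abb_cohort <- function(x, ...) {
  cat(sprintf(
    "<abb_cohort> %d samples x %d sites (%d bias sites), %d observations\n",
    x$config$n_samples, x$config$n_sites, sum(x$truth$bias),
    nrow(x$observations)
  ))
  invisible(x)
}

#' Write a simulated cohort as mpileup text plus truth tables
#'
#' Emits one samtools-style 6-column mpileup text file per sample
#' (`<sample>.pileup`: reference reads as `.`, alternative reads as the
#' site's alt base, all base qualities `I` = Q40), a `truth.tsv` with the
#' per-site bias label, and a `genotypes.tsv` with each sample's called
#' genotype — the training-label input for [fit_ab_model()]. Output is
#' byte-identical for identical cohorts.
#'
#' @param cohort An `abb_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the written file paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "abb_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  obs <- cohort$observations
  pileups <- character(0)
  for (s in unique(obs$sample)) {
    rows <- obs |> dplyr::filter(.data$sample == s) |> arrange(.data$pos)
    bases <- mapply(function(d, a, alt) {
      paste0(strrep(".", d - a), strrep(alt, a))
    }, rows$depth_informative, rows$alt_count, rows$alt_base)
    lines <- sprintf("%s\t%d\t%s\t%d\t%s\t%s",
                     rows$chrom, rows$pos, rows$ref_base,
                     rows$depth_informative, bases,
                     strrep("I", rows$depth_informative))
    path <- file.path(dir, paste0(s, ".pileup"))
    writeLines(lines, path)
    pileups <- c(pileups, path)
  }
  truth_path <- file.path(dir, "truth.tsv")
  readr::write_tsv(cohort$truth, truth_path, progress = FALSE)
  genotypes_path <- file.path(dir, "genotypes.tsv")
  readr::write_tsv(
    obs |> select("sample", "chrom", "pos", genotype = "called_genotype"),
    genotypes_path, progress = FALSE
  )
  invisible(list(pileups = pileups, truth = truth_path,
                 genotypes = genotypes_path))
}

#' Simulate a case/control candidate-gene scenario
#'
#' Generates per-variant, per-arm read evidence and genotype calls for
#' candidate genes of three kinds:
#' * `null` — equal clean carrier rates in both arms;
#' * `associated` — excess clean carriers in cases (a true association);
#' * `confounded` — equal rates of samples with systematic het-like
#'   evidence at `bias_ab`; in cases that evidence is called
#'   heterozygous, in controls the caller reports homozygous reference,
#'   leaving the alternative reads as "missed" evidence. The apparent
#'   case burden is entirely an artifact of differential missed-call
#'   rates (the capture-kit scenario).
#'
#' Missed calls are not assigned by construction: homozygous-reference
#' calls are screened with [detect_missed()] under `hom_ref_model`, so the
#' counts reflect what the detection machinery actually finds.
#'
#' @param genes Tibble with columns `gene`, `n_variants`, `type`
#'   (`null`, `associated`, `confounded`).
#' @param case_n,control_n Arm sizes.
#' @param carrier_rate Per-variant carrier (or error-carrier) probability
#'   per sample, default 0.04.
#' @param assoc_rate_cases Carrier probability in cases for `associated`
#'   genes, default 0.12.
#' @param depth_mean,depth_dispersion Negative-binomial depth parameters.
#' @param bias_ab Allele balance of systematic-error evidence, default
#'   0.25.
#' @param hom_ref_model Zero-inflated beta used both to draw clean
#'   homozygous-reference evidence and to detect missed calls. The default
#'   point-mass weight (0.999) reflects the post-QC candidate-variant
#'   regime, where a homozygous-reference sample almost never shows
#'   alternative reads; the false missed-call rate per sample is then
#'   about 1 - alpha.
#' @param missed_alpha Tail level for [detect_missed()], default 0.05.
#' @param seed Integer seed.
#' @return List with `variants` (per-variant counts tibble suitable for
#'   [associate_abb()]), `truth` (the `genes` table) and the arm sizes.
#' @export
simulate_case_control <- function(genes, case_n = 200, control_n = 200,
                                  carrier_rate = 0.04,
                                  assoc_rate_cases = 0.12,
                                  depth_mean = 60, depth_dispersion = 5,
                                  bias_ab = 0.25,
                                  hom_ref_model = beinf_model(0.999, 0, 0.01, 100),
                                  missed_alpha = 0.05,
                                  seed = 1L) {
  stopifnot(all(c("gene", "n_variants", "type") %in% names(genes)),
            all(genes$type %in% c("null", "associated", "confounded")))
  if (anyDuplicated(genes$gene)) {
    abort("simulate_case_control: gene ids must be unique")
  }
  withr::with_seed(as.integer(seed), {
    variant_rows <- list()
    vid <- 0L
    for (g in seq_len(nrow(genes))) {
      type <- genes$type[g]
      for (v in seq_len(genes$n_variants[g])) {
        vid <- vid + 1L
        arm_counts <- function(n_arm, rate, carriers_called) {
          carrier <- runif(n_arm) < rate
          depth <- pmax(rnbinom(n_arm, size = depth_dispersion,
                                mu = depth_mean), 1L)
          # clean hom-ref allele balance straight from the model (the
          # BEINF describes the observed AB), discretized to read counts
          obs_ab <- round(rbeinf(n_arm, hom_ref_model) * depth) / depth
          called <- logical(n_arm)
          if (carriers_called) {
            # carriers are genotyped het with balanced read evidence
            obs_ab[carrier] <- rbinom(sum(carrier), depth[carrier], 0.5) /
              depth[carrier]
            called <- carrier
          } else {
            # carriers look het at the bias AB but are called hom_ref
            obs_ab[carrier] <- rbinom(sum(carrier), depth[carrier],
                                      bias_ab) / depth[carrier]
          }
          missed <- !called &
            detect_missed(obs_ab, hom_ref_model, alpha = missed_alpha)
          c(called = sum(called), missed = sum(missed))
        }
        case_rate <- switch(type,
                            null = carrier_rate,
                            associated = assoc_rate_cases,
                            confounded = carrier_rate)
        cs <- arm_counts(case_n, case_rate, carriers_called = TRUE)
        ct <- arm_counts(control_n, carrier_rate,
                         carriers_called = (type != "confounded"))
        variant_rows[[vid]] <- tibble(
          gene = genes$gene[g],
          chrom = "chr1",
          pos = vid * 1000L,
          cases_called = cs[["called"]],
          cases_missed = cs[["missed"]],
          controls_called = ct[["called"]],
          controls_missed = ct[["missed"]]
        )
      }
    }
    list(
      variants = dplyr::bind_rows(variant_rows),
      truth = genes,
      case_n = case_n,
      control_n = control_n
    )
  })
}
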