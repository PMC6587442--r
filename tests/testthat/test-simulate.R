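test_that("simulation is deterministic in the seed and honours bias_fraction", {
  cfg <- sim_config(n_samples = 8, n_sites = 40, seed = 7)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$observations, b$observations)
  expect_identical(a$truth, b$truth)

  clean <- simulate_cohort(sim_config(n_samples = 5, n_sites = 30,
                                      bias_fraction = 0, seed = 7))
  expect_false(any(clean$truth$bias))
  expect_false(any(clean$observations$affected))

  expect_error(sim_config(bias_fraction = 1.5), "bias_fraction")
})

test_that("affected samples at biased sites sit at the target allele balance", {
  sim <- simulate_cohort(sim_config(n_samples = 100, n_sites = 2000,
                                    bias_fraction = 0.05, bias_ab = 0.25,
                                    bias_penetrance = 0.3, seed = 901))
  affected <- sim$observations |>
    dplyr::filter(affected, depth_informative >= 20)
  expect_gt(nrow(affected), 1000)
  expect_lt(abs(mean(affected$ab) - 0.25), 0.02)
  # penetrance: fraction of samples affected at biased sites
  per_site <- sim$observations |>
    dplyr::semi_join(dplyr::filter(sim$truth, bias), by = c("chrom", "pos")) |>
    dplyr::group_by(pos) |>
    dplyr::summarise(frac = mean(affected))
  expect_lt(abs(mean(per_site$frac) -
                  0.3 * mean(sim$observations$true_genotype != "hom_alt")),
            0.05)
})

test_that("written pileups parse back to the simulated evidence", {
  sim <- simulate_cohort(sim_config(n_samples = 4, n_sites = 25, seed = 902))
  dir <- withr::local_tempdir()
  paths <- write_cohort(sim, dir)
  expect_length(paths$pileups, 4L)

  parsed <- dplyr::bind_rows(lapply(paths$pileups, function(p) {
    read_pileup(p, sample = sub("\\.pileup$", "", basename(p)))
  }))
  merged <- sim$observations |>
    dplyr::inner_join(parsed, by = c("sample", "chrom", "pos"),
                      suffix = c("", ".parsed"))
  expect_equal(nrow(merged), nrow(sim$observations))
  expect_equal(merged$depth_informative.parsed, merged$depth_informative)
  expect_equal(merged$alt_count.parsed, merged$alt_count)
  expect_equal(merged$ab.parsed, merged$ab)

  # byte-identical re-write
  dir2 <- withr::local_tempdir()
  write_cohort(sim, dir2)
  f1 <- file.path(dir, basename(paths$pileups[1]))
  f2 <- file.path(dir2, basename(paths$pileups[1]))
  expect_identical(readLines(f1), readLines(f2))
})

test_that("batch restriction confines bias to the batch subset", {
  sim <- simulate_cohort(sim_config(n_samples = 40, n_sites = 200,
                                    bias_fraction = 0.2, bias_penetrance = 0.8,
                                    batch_fraction = 0.5, seed = 903))
  affected_samples <- unique(sim$observations$sample[sim$observations$affected])
  expect_lte(length(affected_samples), 20L)
})

test_that("case/control scenarios generate the intended count asymmetries", {
  genes <- tibble::tibble(
    gene = c("NULL1", "ASSOC", "CONF"),
    n_variants = 3L,
    type = c("null", "associated", "confounded")
  )
  cc <- simulate_case_control(genes, case_n = 200, control_n = 200, seed = 904)
  v <- cc$variants
  agg <- v |>
    dplyr::group_by(gene) |>
    dplyr::summarise(dplyr::across(dplyr::where(is.numeric), sum))

  with(agg[agg$gene == "NULL1", ], {
    expect_lt(abs(cases_called - controls_called), 20)
  })
  expect_gt(agg$cases_called[agg$gene == "ASSOC"],
            2 * agg$controls_called[agg$gene == "ASSOC"])
  conf <- agg[agg$gene == "CONF", ]
  expect_equal(conf$controls_called, 0)
  expect_gt(conf$controls_missed, conf$cases_missed)
  expect_gt(conf$cases_called, 10)

  expect_error(
    simulate_case_control(dplyr::bind_rows(genes, genes[1, ]), 10, 10),
    "unique")
})
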