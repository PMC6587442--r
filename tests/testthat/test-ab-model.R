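test_that("pooled binomial MLE for the heterozygous class", {
  d <- tibble::tibble(alt_count = rep(5L, 60), depth_informative = rep(10L, 60))
  expect_equal(fit_het_binomial(d)$p_het, 0.5)

  d2 <- tibble::tibble(alt_count = rep(c(3L, 7L), 30),
                       depth_informative = 10L)
  expect_equal(fit_het_binomial(d2)$p_het, 0.5)

  set.seed(101)
  d3 <- tibble::tibble(depth_informative = 30L,
                       alt_count = rbinom(10000, 30, 0.48))
  expect_lt(abs(fit_het_binomial(d3)$p_het - 0.48), 0.005)

  expect_error(fit_het_binomial(d3[0, ]), "empty")
})

test_that("exact two-sided binomial p-values follow minimum-likelihood ordering", {
  # the mode of a symmetric binomial is never exceeded: p = 1
  expect_equal(binom_pvalue_two_sided(15, 30, 0.5), 1)
  # spot-check against the independent enumeration oracle
  expect_equal(binom_pvalue_two_sided(7, 30, 0.5),
               binom_two_sided_oracle(7, 30, 0.5), tolerance = 1e-14)
  # and against base binom.test, which uses the same ordering
  for (alt in c(0, 3, 11, 22)) {
    expect_equal(binom_pvalue_two_sided(alt, 40, 0.5),
                 binom.test(alt, 40, 0.5)$p.value, tolerance = 1e-12)
    expect_equal(binom_pvalue_two_sided(alt, 40, 0.48),
                 binom.test(alt, 40, 0.48)$p.value, tolerance = 1e-12)
  }
  expect_error(binom_pvalue_two_sided(5, 4), "outside")
})

test_that("genotype p-values honour the point masses and tails", {
  model <- genotype_ab_model()
  obs <- tibble::tibble(
    alt_count = c(0L, 15L, 30L),
    depth_informative = 30L,
    ab = c(0, 0.5, 1)
  )
  p <- genotype_pvalues(obs, model)
  expect_equal(p$p_hom_ref[1], 1)   # observed at the zero point mass
  expect_equal(p$p_het[2], 1)       # observed at the binomial mode
  expect_equal(p$p_hom_alt[3], 1)   # observed at the one point mass
  expect_true(all(p$p_hom_ref >= 0 & p$p_hom_ref <= 1))
  expect_true(all(p$p_hom_alt >= 0 & p$p_hom_alt <= 1))
  expect_error(genotype_pvalues(dplyr::mutate(obs, depth_informative = 0L),
                                model), "depth")
})

test_that("genotype assignment is the argmax with the documented tie-break", {
  expect_equal(assign_genotype(1.0, 0.001, 1e-9), "hom_ref")
  expect_equal(assign_genotype(1e-6, 0.9, 1e-6), "het")
  expect_equal(assign_genotype(0.5, 0.5, 0.1), "hom_ref")
  expect_equal(assign_genotype(0.1, 0.5, 0.5), "het")
  # vectorized
  expect_equal(assign_genotype(c(1, 0), c(0, 1), c(0, 0)),
               c("hom_ref", "het"))
})

test_that("devAB matches its genotype-specific definition and is 1-Lipschitz", {
  expect_equal(dev_ab(0.5, "het"), 0)
  expect_equal(dev_ab(0.0, "hom_ref"), 0)
  expect_equal(dev_ab(0.25, "het"), 0.25)
  expect_equal(dev_ab(0.25, "hom_ref"), 0.25)
  expect_equal(dev_ab(0.25, "hom_alt"), 0.75)

  set.seed(102)
  for (g in c("hom_ref", "het", "hom_alt")) {
    a <- runif(200)
    b <- runif(200)
    expect_true(all(abs(dev_ab(a, g) - dev_ab(b, g)) <= abs(a - b) + 1e-12))
  }
})

test_that("clean simulated data recover the generating genotype almost surely", {
  set.seed(103)
  model <- genotype_ab_model(
    het = 0.5,
    hom_ref = beinf_model(0.9, 0, 0.01, 100),
    hom_alt = beinf_model(0.9, 1, 0.99, 100)
  )
  n <- 2000
  depth <- 30L
  sim_class <- function(gen) {
    ab_true <- switch(gen,
                      het = rep(0.5, n),
                      hom_ref = rbeinf(n, model$hom_ref),
                      hom_alt = rbeinf(n, model$hom_alt))
    alt <- rbinom(n, depth, ab_true)
    tibble::tibble(alt_count = alt, depth_informative = depth,
                   ab = alt / depth, truth = gen)
  }
  calls <- dplyr::bind_rows(lapply(c("hom_ref", "het", "hom_alt"),
                                   sim_class)) |>
    call_genotypes(model)
  expect_gte(mean(calls$genotype == calls$truth), 0.99)
})

test_that("p-values are super-uniform under their own genotype's distribution", {
  # exact/discrete tests are conservative, so the empirical CDF of the
  # p-value must sit at or below the diagonal (small slack for sampling
  # noise at n = 5000)
  set.seed(104)
  n <- 5000
  model <- genotype_ab_model()
  grid <- c(0.01, 0.05, 0.1, 0.25, 0.5, 0.75, 0.9)

  depth <- pmax(rnbinom(n, size = 5, mu = 60), 1)
  p_het <- binom_pvalue_two_sided(rbinom(n, depth, 0.5), depth, 0.5)
  expect_true(all(vapply(grid, function(t) mean(p_het <= t), 0) <=
                    grid + 0.015))

  ab_hr <- rbeinf(n, model$hom_ref)
  p_hr <- beinf_upper_tail(ab_hr, model$hom_ref)
  expect_true(all(vapply(grid, function(t) mean(p_hr <= t), 0) <=
                    grid + 0.015))

  ab_ha <- rbeinf(n, model$hom_alt)
  p_ha <- beinf_lower_tail(ab_ha, model$hom_alt)
  expect_true(all(vapply(grid, function(t) mean(p_ha <= t), 0) <=
                    grid + 0.015))
})

test_that("genotype AB models serialize and restore exactly", {
  set.seed(105)
  model <- genotype_ab_model(
    het = fit_het_binomial(tibble::tibble(
      alt_count = rbinom(100, 30, 0.5), depth_informative = 30L)),
    hom_ref = beinf_model(0.91, 0.001, 0.013, 87.5),
    hom_alt = beinf_model(0.88, 0.999, 0.985, 92.1)
  )
  path <- withr::local_tempfile(fileext = ".json")
  write_ab_model(model, path)
  back <- read_ab_model(path)
  expect_equal(back$het$p_het, model$het$p_het)
  expect_equal(back$hom_ref[c("alpha", "gamma", "mu", "phi")],
               model$hom_ref[c("alpha", "gamma", "mu", "phi")])
  expect_equal(back$hom_alt$mu, model$hom_alt$mu)
  # tidy() exposes all ten parameters
  expect_equal(nrow(tidy(model)), 9L)
})
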