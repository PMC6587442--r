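test_that("missed-call detection matches a quadrature oracle", {
  m <- beinf_model(0.8, 0, 0.05, 20)
  # upper-tail p at the zero point mass is 1: never missed
  expect_false(detect_missed(0, m))
  # alpha = 0 can never flag anything
  expect_false(any(detect_missed(c(0, 0.1, 0.5, 0.9), m, alpha = 0)))
  expect_error(detect_missed(0.2, m, genotype = "het"), "hom_ref")

  oracle_p <- function(y) {
    integrate(function(t) (1 - m$alpha) *
                dbeta(t, m$mu * m$phi, (1 - m$mu) * m$phi),
              y, 1, rel.tol = 1e-10)$value + m$alpha * m$gamma
  }
  for (y in c(0.05, 0.12, 0.3)) {
    p <- oracle_p(y)
    expect_equal(detect_missed(y, m, alpha = 0.05), p < 0.05)
    expect_equal(detect_missed(y, m, alpha = p * 1.01), TRUE)
    expect_equal(detect_missed(y, m, alpha = p * 0.99), FALSE)
  }
})

test_that("the variant-level Fisher test matches hypergeometric enumeration", {
  expect_equal(variant_called_missed_test(10, 0, 10, 0), 1)
  expect_equal(variant_called_missed_test(8, 2, 1, 9),
               fisher_oracle(8, 2, 1, 9), tolerance = 1e-10)
  expect_warning(p <- variant_called_missed_test(0, 0, 0, 0), "all-zero")
  expect_equal(p, 1)

  # exhaustive over all tables with small margins
  for (a in 0:5) for (b in 0:5) for (c_ in 0:5) for (d in 0:5) {
    if (a + b + c_ + d == 0) next
    expect_equal(variant_called_missed_test(a, b, c_, d),
                 fisher_oracle(a, b, c_, d), tolerance = 1e-10)
  }
})

test_that("variant-level type-I error is controlled under equal missed rates", {
  set.seed(701)
  reps <- 10000
  called_case <- rbinom(reps, 50, 0.3)
  missed_case <- rbinom(reps, 50, 0.1)
  called_ctrl <- rbinom(reps, 50, 0.3)
  missed_ctrl <- rbinom(reps, 50, 0.1)
  p <- vapply(seq_len(reps), function(i) {
    variant_called_missed_test(called_case[i], missed_case[i],
                               called_ctrl[i], missed_ctrl[i])
  }, numeric(1))
  expect_lte(mean(p < 0.05), 0.06)
})

test_that("a balanced gene exercises the never-significant rejection path", {
  v <- tibble::tibble(
    gene = "G1",
    cases_called = c(5L, 3L), cases_missed = c(1L, 1L),
    controls_called = c(5L, 3L), controls_missed = c(1L, 1L)
  )
  res <- associate_abb(v, case_n = 100, control_n = 100)
  g <- res$genes
  expect_equal(g$p_called_missed, 1)
  expect_equal(g$p_regenotyped, 1)
  expect_equal(g$p_cleaned, 1)
  # a candidate that is never significant cannot stand: flagged
  expect_equal(g$verdict, "likely_false")
})

test_that("burden driven by differential missed calls is flagged, true burden kept", {
  # confounded gene: controls carry the variant evidence but are called
  # hom_ref (missed); cases are called
  confounded <- tibble::tibble(
    gene = "CONF",
    cases_called = c(6L, 5L, 5L), cases_missed = c(0L, 1L, 0L),
    controls_called = c(0L, 1L, 0L), controls_missed = c(6L, 5L, 5L)
  )
  # truly associated gene: clean carrier excess in cases, no missed calls
  assoc <- tibble::tibble(
    gene = "TRUE_HIT",
    cases_called = c(14L, 12L, 13L), cases_missed = 0L,
    controls_called = c(2L, 1L, 2L), controls_missed = 0L
  )
  res <- associate_abb(dplyr::bind_rows(confounded, assoc),
                       case_n = 200, control_n = 200)
  g <- res$genes
  expect_equal(g$verdict[g$gene == "CONF"], "likely_false")
  expect_lt(g$fdr_called_missed[g$gene == "CONF"], 0.1)
  expect_equal(g$verdict[g$gene == "TRUE_HIT"], "keep")
  # the biased variants were flagged at the variant level too
  expect_gte(sum(res$variants$bias[res$variants$gene == "CONF"]), 2)
  expect_equal(sum(res$variants$bias[res$variants$gene == "TRUE_HIT"]), 0L)
})

test_that("cleaning away every variant leaves no evidence of association", {
  v <- tibble::tibble(
    gene = "ALLBIAS",
    cases_called = c(10L, 9L), cases_missed = c(0L, 0L),
    controls_called = c(0L, 0L), controls_missed = c(10L, 9L)
  )
  res <- associate_abb(v, case_n = 100, control_n = 100)
  expect_equal(res$genes$p_cleaned, 1)
  expect_equal(res$genes$verdict, "likely_false")
})

test_that("input validation catches missing columns and empty input", {
  expect_error(associate_abb(tibble::tibble(gene = "G"), 10, 10), "missing")
  v <- tibble::tibble(gene = character(), cases_called = integer(),
                      cases_missed = integer(), controls_called = integer(),
                      controls_missed = integer())
  expect_error(associate_abb(v, 10, 10), "no variants")
})
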