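make_features <- function(n, frac1 = 0.2, noisy = FALSE) {
  label <- as.integer(seq_len(n) <= round(frac1 * n))
  up <- label == 1L
  tibble::tibble(
    rdab1 = ifelse(up, runif(n, 0.15, 0.30), runif(n, 0, 0.06)),
    rdab2 = ifelse(up, runif(n, 0.25, 0.60), runif(n, 0, 0.08)),
    rdab3 = ifelse(up, runif(n, 1.0, 3.0), runif(n, 0, 0.4)),
    label = label
  )
}

test_that("perfectly separable features yield validation F1 of 1", {
  set.seed(601)
  model <- train_lr(make_features(600), seed = 601)
  expect_equal(model$metrics$f1_val, 1)
  expect_equal(model$metrics$f1, 1)
  expect_true(all(is.finite(model$coefficients)))
})

test_that("labels independent of features give chance-level AUC", {
  set.seed(602)
  d <- make_features(10000)
  d$label <- sample(d$label)  # break the association
  model <- train_lr(d, seed = 602)
  expect_lt(abs(model$metrics$roc_auc - 0.5), 0.03)
})

test_that("the chosen cutoff matches a brute-force F1 scan", {
  set.seed(603)
  d <- make_features(900)
  # blur the boundary so the optimum is non-trivial
  d$rdab1 <- d$rdab1 + rnorm(900, 0, 0.06)
  d$rdab2 <- pmin(pmax(d$rdab2 + rnorm(900, 0, 0.12), 0), 1)
  model <- train_lr(d, seed = 603)

  # reconstruct the validation responses independently
  split <- withr::with_seed(603, {
    grp <- character(900)
    for (cl in unique(d$label)) {
      idx <- sample(which(d$label == cl))
      m <- length(idx)
      n_train <- min(max(1L, round(2 / 3 * m)), m - 2L)
      n_val <- max(1L, round(1 / 6 * m))
      grp[idx[seq_len(n_train)]] <- "train"
      grp[idx[n_train + seq_len(n_val)]] <- "val"
      grp[idx[(n_train + n_val + 1L):m]] <- "test"
    }
    grp
  })
  val <- d[split == "val", ]
  resp <- predict(model, val)
  f1_at <- function(t) {
    tp <- sum(resp >= t & val$label == 1L)
    fp <- sum(resp >= t & val$label == 0L)
    fn <- sum(resp < t & val$label == 1L)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }
  brute <- vapply(sort(unique(resp)), f1_at, numeric(1))
  expect_equal(f1_at(model$cutoff), max(brute), tolerance = 1e-12)
})

test_that("single-class labels are rejected", {
  d <- make_features(100)
  d$label <- 1L
  expect_error(train_lr(d), "both classes")
})

test_that("the precision map is non-decreasing and bounded", {
  set.seed(604)
  for (i in 1:5) {
    d <- make_features(800)
    d$rdab1 <- d$rdab1 + rnorm(800, 0, 0.1)  # make labels noisy
    model <- train_lr(d, seed = i)
    expect_true(all(diff(model$precision_y) >= -1e-12))
    expect_true(all(model$precision_y >= 0 & model$precision_y <= 1))
    # interpolation inherits monotonicity
    resp <- seq(0, 1, by = 0.01)
    expect_true(all(diff(map_precision(model, resp)) >= -1e-12))
  }
})

test_that("scored positions land in the right confidence bins", {
  set.seed(605)
  model <- train_lr(make_features(600), seed = 605)
  clean <- tibble::tibble(chrom = "chr1", pos = 1L, n_informative = 100L,
                          rdab1 = 0, rdab2 = 0, rdab3 = 0)
  biased <- tibble::tibble(chrom = "chr1", pos = 2L, n_informative = 100L,
                           rdab1 = 0.25, rdab2 = 0.5, rdab3 = 2.5)
  scores <- score_positions(dplyr::bind_rows(clean, biased), model)
  expect_equal(as.character(scores$confidence), c("high", "very_low"))
  expect_true(all(scores$abb >= 0 & scores$abb <= 1))

  # with an identity precision map the score equals the response
  ident <- model
  ident$precision_x <- c(0, 1)
  ident$precision_y <- c(0, 1)
  s2 <- score_positions(biased, ident)
  expect_equal(s2$abb, s2$lr_response)
})

test_that("response moves in the direction of each coefficient's sign", {
  set.seed(606)
  model <- train_lr(make_features(800), seed = 606)
  beta <- model$coefficients
  base <- tibble::tibble(rdab1 = 0.05, rdab2 = 0.1, rdab3 = 0.5)
  r0 <- predict(model, base)
  for (f in c("rdab1", "rdab2", "rdab3")) {
    up <- base
    up[[f]] <- up[[f]] + 0.05
    delta <- predict(model, up) - r0
    # on this synthetic cohort bias raises every feature, so slopes
    # (including the interaction contribution) point upward
    expect_gt(delta, 0)
  }
})

test_that("rank-based AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(607)
  score <- runif(500)
  label <- as.integer(runif(500) < plogis(4 * score - 2))
  mine <- rank_auc_ref(score, label)
  ref <- suppressMessages(as.numeric(pROC::auc(label, score,
                                               direction = "<")))
  expect_equal(mine, ref, tolerance = 1e-12)
})

test_that("fitted callability models serialize and restore predictions", {
  set.seed(608)
  model <- train_lr(make_features(600), seed = 608)
  path <- withr::local_tempfile(fileext = ".json")
  write_lr_model(model, path)
  back <- read_lr_model(path)
  newdata <- make_features(50)
  expect_equal(predict(back, newdata), predict(model, newdata),
               tolerance = 1e-12)
  expect_equal(predict(back, newdata, type = "abb"),
               predict(model, newdata, type = "abb"), tolerance = 1e-12)
  expect_equal(back$cutoff, model$cutoff)
  # broom-style accessors
  expect_true(all(c("term", "estimate", "p.value") %in% names(tidy(model))))
  expect_equal(nrow(glance(model)), 1L)
})

test_that("the very-low-confidence filter removes strictly above the threshold", {
  variants <- tibble::tibble(chrom = "chr1", pos = c(10L, 20L, 30L),
                             ref = "A", alt = "G")
  scores <- tibble::tibble(chrom = "chr1", pos = c(10L, 20L),
                           abb = c(0.95, 0.90))
  parts <- filter_variants(variants, scores, max_abb = 0.9)
  expect_equal(parts$removed$pos, 10L)
  expect_setequal(parts$kept$pos, c(20L, 30L))  # 0.90 kept: strict inequality
  expect_equal(parts$n_unscored, 1L)            # pos 30 has no score
})
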