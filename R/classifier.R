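#' Train the ABB callability logistic regression (LR1)
#'
#' Fits a logistic regression of recurrent-deviation labels on the three
#' per-position bias measures plus their rdab2:rdab3 interaction,
#'
#' \deqn{logit(y) = \beta_0 + \beta_1 rdab1 + \beta_2 rdab2 +
#'   \beta_3 rdab3 + \beta_4 rdab2 \cdot rdab3}
#'
#' on a stratified training split, picks the response cutoff maximizing F1
#' on the validation split, and builds the monotone response-to-precision
#' map from the pooled validation + test responses: sorted responses are
#' cut into `n_bins` equal-count bins, empirical precision (fraction of
#' label-1 positions) is computed per bin, and monotonicity is enforced by
#' isotonic pooling. Scores of new positions are obtained by interpolating
#' this map; the resulting precision-scaled score is the ABB genotype
#' callability score.
#'
#' @param data Tibble with columns `rdab1`, `rdab2`, `rdab3` and a binary
#'   `label` column (1 = recurrently deviated).
#' @param train_frac,val_frac Fractions of positions for training and
#'   validation (test takes the remainder). Defaults 2/3 and 1/6.
#' @param n_bins Number of equal-count bins for the precision map,
#'   default 20.
#' @param seed Integer seed for the stratified splits.
#' @return An object of class `abb_lr` holding the coefficients, the
#'   F1-optimal `cutoff`, the precision map knots and held-out metrics.
#' @export
train_lr <- function(data, train_frac = 2 / 3, val_frac = 1 / 6,
                     n_bins = 20, seed = 1L) {
  stopifnot(all(c("rdab1", "rdab2", "rdab3", "label") %in% names(data)))
  label <- as.integer(data$label)
  if (length(unique(label)) < 2L) {
    abort("train_lr: both classes must be present")
  }
  if (train_frac <= 0 || val_frac <= 0 || train_frac + val_frac >= 1) {
    abort("train_lr: split fractions must be positive and sum below 1")
  }

  n <- nrow(data)
  split <- withr::with_seed(seed, {
    grp <- character(n)
    for (cl in unique(label)) {
      idx <- sample(which(label == cl))
      m <- length(idx)
      n_train <- max(1L, round(train_frac * m))
      n_val <- max(1L, round(val_frac * m))
      n_train <- min(n_train, m - 2L)
      grp[idx[seq_len(n_train)]] <- "train"
      grp[idx[n_train + seq_len(n_val)]] <- "val"
      grp[idx[(n_train + n_val + 1L):m]] <- "test"
    }
    grp
  })

  df <- data |>
    mutate(label = label, .split = split)
  train <- dplyr::filter(df, .data$.split == "train")
  val <- dplyr::filter(df, .data$.split == "val")
  test <- dplyr::filter(df, .data$.split == "test")

  fit <- suppressWarnings(
    glm(label ~ rdab1 + rdab2 + rdab3 + rdab2:rdab3,
        family = binomial(), data = train)
  )
  beta <- coef(fit)
  beta[!is.finite(beta)] <- 0
  coef_table <- as_tibble(summary(fit)$coefficients, rownames = "term")
  names(coef_table) <- c("term", "estimate", "std.error", "statistic",
                         "p.value")

  resp_val <- lr_response_raw(beta, val)
  resp_test <- lr_response_raw(beta, test)
  scan <- f1_scan(resp_val, val$label)
  cutoff <- scan$cutoff

  pooled_resp <- c(resp_val, resp_test)
  pooled_label <- c(val$label, test$label)
  pm <- precision_map_knots(pooled_resp, pooled_label, n_bins = n_bins)

  metrics <- c(
    classification_metrics(resp_test, test$label, cutoff),
    list(roc_auc = rank_auc(resp_test, test$label), f1_val = scan$f1)
  )

  structure(
    list(
      coefficients = beta,
      coef_table = coef_table,
      cutoff = cutoff,
      precision_x = pm$x,
      precision_y = pm$y,
      metrics = metrics,
      n = c(train = nrow(train), val = nrow(val), test = nrow(test)),
      seed = seed
    ),
    class = "abb_lr"
  )
}

# linear predictor -> response for a named coefficient vector
lr_response_raw <- function(beta, data) {
  plogis(beta[["(Intercept)"]] +
           beta[["rdab1"]] * data$rdab1 +
           beta[["rdab2"]] * data$rdab2 +
           beta[["rdab3"]] * data$rdab3 +
           beta[["rdab2:rdab3"]] * data$rdab2 * data$rdab3)
}

# F1-maximizing threshold over every distinct response value
f1_scan <- function(resp, label) {
  ts <- sort(unique(resp))
  pos_total <- sum(label == 1L)
  f1 <- vapply(ts, function(t) {
    pred <- resp >= t
    tp <- sum(pred & label == 1L)
    fp <- sum(pred & label == 0L)
    fn <- pos_total - tp
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  best <- which.max(f1)
  list(cutoff = ts[best], f1 = f1[best])
}

classification_metrics <- function(resp, label, cutoff) {
  pred <- resp >= cutoff
  tp <- sum(pred & label == 1L)
  fp <- sum(pred & label == 0L)
  fn <- sum(!pred & label == 1L)
  precision <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
  recall <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) {
    NA_real_
  } else 2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, f1 = f1)
}

# Wilcoxon / rank formulation of the ROC AUC
rank_auc <- function(resp, label) {
  n1 <- sum(label == 1L)
  n0 <- sum(label == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(resp)
  (sum(r[label == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# equal-count binning + isotonic pooling of empirical precision
precision_map_knots <- function(resp, label, n_bins = 20) {
  n <- length(resp)
  stopifnot(n > 0L)
  nb <- max(1L, min(n_bins, n))
  o <- order(resp)
  bin <- ceiling(seq_len(n) * nb / n)
  bx <- tapply(resp[o], bin, mean)
  by <- tapply(label[o], bin, mean)
  iso <- isoreg(seq_along(by), as.numeric(by))
  list(x = as.numeric(bx), y = pmin(pmax(iso$yf, 0), 1))
}

#' Map logistic responses to precision-scaled ABB scores
#'
#' Interpolates the fitted monotone precision map at the given responses;
#' responses outside the knot range take the boundary precision.
#'
#' @param model An `abb_lr` model.
#' @param response Numeric vector of logistic responses in (0, 1).
#' @return Numeric vector of ABB scores in \[0, 1\].
#' @export
map_precision <- function(model, response) {
  stopifnot(inherits(model, "abb_lr"))
  if (length(model$precision_x) < 2L) {
    return(rep(model$precision_y[1], length(response)))
  }
  approx(model$precision_x, model$precision_y, xout = response,
         rule = 2, ties = "ordered")$y
}

#' @export
print.abb_lr <- function(x, ...) {
  cat("<abb_lr> logistic callability model\n")
  cat(sprintf("  cutoff (F1-optimal): %.4f\n", x$cutoff))
  cat(sprintf("  held-out: precision %.3f recall %.3f F1 %.3f AUC %.3f\n",
              x$metrics$precision, x$metrics$recall, x$metrics$f1,
              x$metrics$roc_auc))
  invisible(x)
}

#' @describeIn train_lr Coefficient table (term, estimate, std.error,
#'   statistic, p.value).
#' @param x An `abb_lr` model.
#' @param ... Unused.
#' @export
tidy.abb_lr <- function(x, ...) {
  x$coef_table
}

#' @describeIn train_lr One-row fit summary with cutoff and held-out
#'   metrics.
#' @export
glance.abb_lr <- function(x, ...) {
  tibble(
    cutoff = x$cutoff,
    f1_val = x$metrics$f1_val,
    precision_test = x$metrics$precision,
    recall_test = x$metrics$recall,
    f1_test = x$metrics$f1,
    roc_auc_test = x$metrics$roc_auc,
    n_train = x$n[["train"]],
    n_val = x$n[["val"]],
    n_test = x$n[["test"]]
  )
}

#' @export
predict.abb_lr <- function(object, newdata, type = c("response", "abb"), ...) {
  type <- match.arg(type)
  resp <- lr_response_raw(object$coefficients, newdata)
  if (type == "response") resp else map_precision(object, resp)
}

#' Score positions with a fitted callability model
#'
#' Computes the logistic response for each per-position summary, maps it
#' to the precision-scaled ABB score and bins the score into the four
#' confidence levels.
#'
#' @param summaries Per-position summaries from [summarize_sites()].
#' @param model A fitted `abb_lr`.
#' @return Tibble with `chrom`, `pos`, `n_informative`, `rdab1`, `rdab2`,
#'   `rdab3`, `lr_response`, `abb` and `confidence` columns — the score
#'   table layout of [write_score_table()].
#' @export
score_positions <- function(summaries, model) {
  stopifnot(inherits(model, "abb_lr"))
  summaries |>
    mutate(
      lr_response = lr_response_raw(model$coefficients, summaries),
      abb = map_precision(model, .data$lr_response),
      confidence = abb_confidence(.data$abb)
    ) |>
    select(dplyr::any_of(c("chrom", "pos", "n_informative")),
           "rdab1", "rdab2", "rdab3", "lr_response", "abb", "confidence")
}

#' Partition variants by the very-low-confidence ABB filter
#'
#' Joins variant rows to the score table by (chrom, pos) and removes rows
#' whose ABB score strictly exceeds `max_abb` (default 0.9, the very low
#' confidence filter). Unscored positions are kept and counted.
#'
#' @param variants Tibble with `chrom` and `pos` columns (e.g. from
#'   [read_vcf_sites()]).
#' @param score_table Tibble with `chrom`, `pos`, `abb`.
#' @param max_abb Removal threshold, strict inequality. Default 0.9.
#' @return List with elements `kept`, `removed` (both tibbles carrying an
#'   `abb` column) and `n_unscored`.
#' @export
filter_variants <- function(variants, score_table, max_abb = 0.9) {
  scored <- variants |>
    left_join(score_table |> select("chrom", "pos", "abb"),
              by = c("chrom", "pos"))
  removed <- dplyr::filter(scored, !is.na(.data$abb) & .data$abb > max_abb)
  kept <- dplyr::filter(scored, is.na(.data$abb) | .data$abb <= max_abb)
  list(
    kept = kept,
    removed = removed,
    n_unscored = sum(is.na(scored$abb))
  )
}

#' Serialize / restore a fitted callability model
#'
#' Coefficients, the F1-optimal cutoff and the precision map knots are
#' written as JSON text so scoring runs are reproducible without refitting.
#'
#' @param model An `abb_lr`.
#' @param path File path.
#' @return `write_lr_model()` returns `path` invisibly; `read_lr_model()`
#'   the restored model.
#' @export
write_lr_model <- function(model, path) {
  stopifnot(inherits(model, "abb_lr"))
  payload <- list(
    coefficients = as.list(model$coefficients),
    cutoff = model$cutoff,
    precision_x = model$precision_x,
    precision_y = model$precision_y,
    metrics = model$metrics,
    n = as.list(model$n),
    seed = model$seed
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_lr_model
#' @export
read_lr_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(
      coefficients = unlist(p$coefficients),
      coef_table = NULL,
      cutoff = p$cutoff,
      precision_x = as.numeric(p$precision_x),
      precision_y = as.numeric(p$precision_y),
      metrics = p$metrics,
      n = unlist(p$n),
      seed = p$seed
    ),
    class = "abb_lr"
  )
}
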