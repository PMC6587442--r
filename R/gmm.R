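#' Two-component Gaussian mixture labeling of mean deviations
#'
#' Splits per-position mean devAB values into non-deviated (0) and
#' recurrently deviated (1) positions with a univariate two-component
#' Gaussian mixture fitted by EM: k-means initialization under a fixed
#' seed, unequal variances with a small floor, convergence when the
#' log-likelihood improves by less than `tol`. The component with the
#' larger mean is the deviated class; each point receives its
#' maximum-posterior label.
#'
#' @param x Numeric vector of per-position mean devAB values (heterozygous
#'   positions, range \[0, 0.5\]).
#' @param seed Integer seed for the k-means initialization.
#' @param tol Absolute log-likelihood convergence tolerance, default 1e-8.
#' @param max_iter Iteration cap, default 1000.
#' @return Integer vector of 0/1 labels. Degenerate input (fewer than two
#'   points or zero spread) yields all-zero labels with a warning.
#' @export
gmm_label <- function(x, seed = 1L, tol = 1e-8, max_iter = 1000L) {
  n <- length(x)
  if (n < 2L || !is.finite(sd(x)) || sd(x) < 1e-10) {
    warn("gmm_label: degenerate input; all positions labeled 0")
    return(rep(0L, n))
  }
  cluster <- if (length(unique(x)) > 2L) {
    withr::with_seed(seed, kmeans(x, centers = 2L, nstart = 5L))$cluster
  } else {
    # too few distinct values for k-means: split at the range midpoint
    1L + as.integer(x > (min(x) + max(x)) / 2)
  }
  w <- tabulate(cluster, 2L) / n
  mu <- vapply(1:2, function(k) mean(x[cluster == k]), numeric(1))
  s2 <- vapply(1:2, function(k) {
    v <- var(x[cluster == k])
    if (!is.finite(v) || v < 1e-10) 1e-10 else v
  }, numeric(1))

  ll_old <- -Inf
  r <- NULL
  for (it in seq_len(max_iter)) {
    dens <- cbind(w[1] * dnorm(x, mu[1], sqrt(s2[1])),
                  w[2] * dnorm(x, mu[2], sqrt(s2[2])))
    tot <- rowSums(dens)
    tot[tot < 1e-300] <- 1e-300
    r <- dens / tot
    ll <- sum(log(tot))
    if (is.finite(ll) && abs(ll - ll_old) < tol) break
    ll_old <- ll
    nk <- colSums(r)
    nk[nk < 1e-10] <- 1e-10
    w <- nk / n
    mu <- colSums(r * x) / nk
    s2 <- pmax(c(sum(r[, 1] * (x - mu[1])^2),
                 sum(r[, 2] * (x - mu[2])^2)) / nk, 1e-10)
  }
  deviated <- which.max(mu)
  as.integer(max.col(r, ties.method = "first") == deviated)
}
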