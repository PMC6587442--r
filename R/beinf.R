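#' Zero/one-inflated beta (BEINF) model
#'
#' Container for the expected allele-balance distribution of a homozygous
#' genotype: a continuous beta component on (0, 1) mixed with point masses
#' at the boundaries. Parameterized by the mixture weight `alpha` of the
#' point masses, the Bernoulli split `gamma` of boundary mass between 0 and
#' 1 (so P(y = 0) = alpha * (1 - gamma) and P(y = 1) = alpha * gamma), and
#' the beta mean `mu` and precision `phi` (shape1 = mu * phi,
#' shape2 = (1 - mu) * phi).
#'
#' @param alpha Mixture weight of the point masses, in \[0, 1\].
#' @param gamma Share of boundary mass at 1, in \[0, 1\].
#' @param mu Beta mean, in (0, 1).
#' @param phi Beta precision, > 0.
#' @param degenerate Flag set by [fit_beinf()] when no interior data were
#'   available and (`mu`, `phi`) are placeholder defaults.
#' @return An object of class `beinf_model`.
#' @export
beinf_model <- function(alpha, gamma, mu, phi, degenerate = FALSE) {
  stopifnot(
    is.numeric(alpha), length(alpha) == 1, alpha >= 0, alpha <= 1,
    is.numeric(gamma), length(gamma) == 1, gamma >= 0, gamma <= 1,
    is.numeric(mu), length(mu) == 1, mu > 0, mu < 1,
    is.numeric(phi), length(phi) == 1, phi > 0
  )
  structure(
    list(alpha = alpha, gamma = gamma, mu = mu, phi = phi,
         degenerate = isTRUE(degenerate)),
    class = "beinf_model"
  )
}

#' @export
print.beinf_model <- function(x, ...) {
  cat(sprintf(
    "<beinf_model> alpha=%.4f gamma=%.4f mu=%.4f phi=%.2f%s\n",
    x$alpha, x$gamma, x$mu, x$phi,
    if (x$degenerate) " (degenerate fit)" else ""
  ))
  invisible(x)
}

#' @describeIn beinf_model Tidy the parameters into a tibble.
#' @param x A `beinf_model`.
#' @param ... Unused.
#' @export
tidy.beinf_model <- function(x, ...) {
  tibble(term = c("alpha", "gamma", "mu", "phi"),
         estimate = c(x$alpha, x$gamma, x$mu, x$phi))
}

#' BEINF density / mass
#'
#' Density of the inflated beta: mass `alpha * (1 - gamma)` at 0,
#' `alpha * gamma` at 1, and `(1 - alpha)` times the beta density with mean
#' `mu` and precision `phi` on the open interval.
#'
#' @param y Numeric vector of allele balance values in \[0, 1\].
#' @param model A [beinf_model()].
#' @return Numeric vector of densities (masses at the boundaries).
#' @export
beinf_density <- function(y, model) {
  stopifnot(inherits(model, "beinf_model"))
  if (any(y < 0 | y > 1, na.rm = TRUE)) {
    abort("beinf_density: y outside [0, 1]")
  }
  sh1 <- model$mu * model$phi
  sh2 <- (1 - model$mu) * model$phi
  out <- (1 - model$alpha) * dbeta(y, sh1, sh2)
  out[y == 0] <- model$alpha * (1 - model$gamma)
  out[y == 1] <- model$alpha * model$gamma
  out
}

#' BEINF tail probabilities
#'
#' `beinf_upper_tail()` returns P(Y >= y) and `beinf_lower_tail()` P(Y <= y)
#' under an inflated beta, with the boundary point masses included whenever
#' they lie in the tail. These are the one-sided p-values used to score
#' evidence against a homozygous genotype: for homozygous reference the
#' upper tail (alternative reads pile up above expectation), for homozygous
#' alternative the lower tail.
#'
#' @param y Numeric vector in \[0, 1\].
#' @param model A [beinf_model()].
#' @return Numeric vector of tail probabilities in \[0, 1\].
#' @export
beinf_upper_tail <- function(y, model) {
  stopifnot(inherits(model, "beinf_model"))
  sh1 <- model$mu * model$phi
  sh2 <- (1 - model$mu) * model$phi
  out <- (1 - model$alpha) * pbeta(y, sh1, sh2, lower.tail = FALSE) +
    model$alpha * model$gamma
  out[y <= 0] <- 1
  out[y >= 1] <- model$alpha * model$gamma
  pmin(pmax(out, 0), 1)
}

#' @rdname beinf_upper_tail
#' @export
beinf_lower_tail <- function(y, model) {
  stopifnot(inherits(model, "beinf_model"))
  sh1 <- model$mu * model$phi
  sh2 <- (1 - model$mu) * model$phi
  out <- (1 - model$alpha) * pbeta(y, sh1, sh2) +
    model$alpha * (1 - model$gamma)
  out[y >= 1] <- 1
  out[y <= 0] <- model$alpha * (1 - model$gamma)
  pmin(pmax(out, 0), 1)
}

#' Draw from a BEINF distribution
#'
#' @param n Number of draws.
#' @param model A [beinf_model()].
#' @return Numeric vector in \[0, 1\].
#' @export
rbeinf <- function(n, model) {
  stopifnot(inherits(model, "beinf_model"))
  u <- runif(n)
  out <- numeric(n)
  at_boundary <- u < model$alpha
  out[at_boundary] <- as.numeric(runif(sum(at_boundary)) < model$gamma)
  k <- sum(!at_boundary)
  if (k > 0) {
    out[!at_boundary] <- rbeta(k, model$mu * model$phi,
                               (1 - model$mu) * model$phi)
  }
  out
}

#' Fit a BEINF model by maximum penalized likelihood
#'
#' The boundary parameters have closed-form maximum likelihood estimates:
#' `alpha` is the fraction of observations exactly at 0 or 1 and `gamma`
#' the fraction of those at 1. The beta parameters (`mu`, `phi`) maximize
#' the beta log-likelihood of the interior points numerically
#' (Nelder-Mead on the (logit mu, log phi) scale) with a small ridge
#' penalty on log phi (weight 1e-3) that keeps the precision finite when
#' interior data are nearly degenerate while leaving healthy fits
#' untouched.
#'
#' @param ab Numeric vector of allele balance observations in \[0, 1\].
#' @param orientation `"zero_inflated"` (homozygous reference) or
#'   `"one_inflated"` (homozygous alternative); decides the default `gamma`
#'   and placeholder `mu` when the sample has no boundary / interior points.
#' @param penalty Ridge weight on `log(phi)^2`. Default 1e-3.
#' @return A [beinf_model()].
#' @export
fit_beinf <- function(ab, orientation = c("zero_inflated", "one_inflated"),
                      penalty = 1e-3) {
  orientation <- match.arg(orientation)
  ab <- ab[!is.na(ab)]
  if (length(ab) == 0L) {
    abort("fit_beinf: empty input")
  }
  if (any(ab < 0 | ab > 1)) {
    abort("fit_beinf: observations outside [0, 1]")
  }
  if (length(ab) < 50L) {
    warn(paste0("fit_beinf: only ", length(ab),
                " observations; estimates may be unstable"))
  }
  boundary <- ab == 0 | ab == 1
  alpha <- mean(boundary)
  gamma <- if (any(boundary)) {
    mean(ab[boundary] == 1)
  } else if (orientation == "zero_inflated") 0 else 1
  interior <- ab[!boundary]

  if (length(interior) == 0L) {
    warn("fit_beinf: no interior observations; (mu, phi) set to defaults")
    mu0 <- if (orientation == "zero_inflated") 0.01 else 0.99
    return(beinf_model(alpha, gamma, mu0, 50, degenerate = TRUE))
  }

  m <- mean(interior)
  v <- var(interior)
  if (!is.finite(v) || v < 1e-12) v <- 1e-6
  m <- min(max(m, 1e-4), 1 - 1e-4)
  phi0 <- max(m * (1 - m) / v - 1, 0.5)
  nll <- function(p) {
    mu <- plogis(p[1])
    phi <- exp(p[2])
    -(sum(dbeta(interior, mu * phi, (1 - mu) * phi, log = TRUE)) -
        penalty * p[2]^2)
  }
  fit <- optim(c(qlogis(m), log(phi0)), nll, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-12))
  beinf_model(alpha, gamma, plogis(fit$par[1]), exp(fit$par[2]))
}
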