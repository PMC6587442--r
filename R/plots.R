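#' Plot the expected allele-balance distributions of a genotype model
#'
#' Shows the fitted continuous components of the two homozygous
#' inflated-beta models, their boundary point masses as vertical
#' segments, and the heterozygous binomial pmf at a representative depth.
#'
#' @param model A `genotype_ab_model`.
#' @param depth Depth at which the heterozygous binomial pmf is drawn,
#'   default 30.
#' @return A ggplot object.
#' @export
plot_ab_expectations <- function(model, depth = 30) {
  stopifnot(inherits(model, "genotype_ab_model"))
  grid <- seq(0.001, 0.999, length.out = 400)
  cont <- dplyr::bind_rows(
    tibble(ab = grid, density = beinf_density(grid, model$hom_ref),
           genotype = "hom_ref"),
    tibble(ab = grid, density = beinf_density(grid, model$hom_alt),
           genotype = "hom_alt")
  )
  masses <- tibble(
    ab = c(0, 1, 0, 1),
    mass = c(model$hom_ref$alpha * (1 - model$hom_ref$gamma),
             model$hom_ref$alpha * model$hom_ref$gamma,
             model$hom_alt$alpha * (1 - model$hom_alt$gamma),
             model$hom_alt$alpha * model$hom_alt$gamma),
    genotype = c("hom_ref", "hom_ref", "hom_alt", "hom_alt")
  )
  k <- 0:depth
  het <- tibble(ab = k / depth,
                density = dbinom(k, depth, model$het$p_het) * depth,
                genotype = "het")
  ggplot() +
    geom_line(data = cont, aes(x = .data$ab, y = .data$density,
                               colour = .data$genotype)) +
    geom_col(data = het, aes(x = .data$ab, y = .data$density,
                             fill = .data$genotype),
             alpha = 0.4, width = 1 / (depth + 1)) +
    geom_segment(data = masses,
                 aes(x = .data$ab, xend = .data$ab, y = 0,
                     yend = .data$mass * 10, colour = .data$genotype),
                 linewidth = 1.2) +
    labs(x = "allele balance", y = "density (point masses x10)",
         title = "Expected allele balance per genotype") +
    theme_minimal()
}

#' @describeIn train_lr Plot the response-to-precision map with the
#'   F1-optimal cutoff.
#' @param object An `abb_lr` model.
#' @export
autoplot.abb_lr <- function(object, ...) {
  knots <- tibble(response = object$precision_x,
                  precision = object$precision_y)
  ggplot(knots, aes(x = .data$response, y = .data$precision)) +
    geom_step(direction = "mid") +
    geom_point(size = 1) +
    geom_vline(xintercept = object$cutoff, linetype = "dashed") +
    geom_hline(yintercept = c(0.15, 0.75, 0.9), colour = "grey60",
               linetype = "dotted") +
    coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    labs(x = "logistic response", y = "precision (ABB score)",
         title = "Response-to-precision map",
         subtitle = "dashed: F1-optimal cutoff; dotted: confidence bin edges") +
    theme_minimal()
}

#' @describeIn build_abb_table Histogram of ABB scores coloured by
#'   confidence level.
#' @param object An `abb_fit`.
#' @export
autoplot.abb_fit <- function(object, ...) {
  ggplot(object$scores, aes(x = .data$abb, fill = .data$confidence)) +
    geom_histogram(bins = 50, boundary = 0) +
    scale_y_sqrt() +
    labs(x = "ABB genotype callability score", y = "positions (sqrt scale)",
         title = "Distribution of ABB scores") +
    theme_minimal()
}
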