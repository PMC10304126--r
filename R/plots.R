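#' WAASB-by-yield quadrant plot
#'
#' Mean yield on the x axis, WAASB on the y axis, cut-off lines at the
#' respective means; genotypes and environments are drawn together (the
#' quadrant labels stored in the fit were computed per entity type).
#'
#' @param x A `waasb_fit` from [waasb()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
plot.waasb_fit <- function(x, ...) {
  d <- x$scores
  ggplot2::ggplot(d, ggplot2::aes(x = .data$yield, y = .data$waasb,
                                  colour = .data$type)) +
    ggplot2::geom_vline(data = stats::aggregate(yield ~ type, d, mean),
                        ggplot2::aes(xintercept = .data$yield,
                                     colour = .data$type),
                        linetype = 2, show.legend = FALSE) +
    ggplot2::geom_hline(data = stats::aggregate(waasb ~ type, d, mean),
                        ggplot2::aes(yintercept = .data$waasb,
                                     colour = .data$type),
                        linetype = 2, show.legend = FALSE) +
    ggplot2::geom_text(ggplot2::aes(label = .data$id), size = 3) +
    ggplot2::labs(x = "Mean yield (t/ha)", y = "WAASB",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Yield by environment-IPCA1 reaction-norm plot
#'
#' The crossover display of the AMMI1 model: for each genotype the nominal
#' yield `mu + alpha_g + lambda_1 gamma_g1 * s` is drawn as a line over the
#' environment IPCA1 score `s`, with the environments marked at their own
#' scores.  Crossing lines are crossover interactions.
#'
#' @param fit An `ammi_fit`.
#' @return A ggplot object.
#' @export
plot_yield_ipca1 <- function(fit) {
  stopifnot(inherits(fit, "ammi_fit"))
  s_env <- fit$delta[, 1L]
  grid <- range(s_env)
  gens <- rownames(fit$means)
  d <- do.call(rbind, lapply(seq_along(gens), function(i) {
    data.frame(GEN = gens[i], s = grid,
               yield = fit$mu + fit$alpha[i] +
                 fit$lambda[1L] * fit$gamma[i, 1L] * grid)
  }))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$s, y = .data$yield,
                                  colour = .data$GEN)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = s_env, linetype = 3,
                        colour = "grey60") +
    ggplot2::labs(x = "Environment IPCA1 score",
                  y = "Nominal yield (t/ha)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Genotype-ranking GGE biplot
#'
#' Axis-1/axis-2 genotype coordinates with concentric circles centred on
#' the ideal genotype and the average-environment axis drawn through it.
#'
#' @param x A `gge_fit`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
plot.gge_fit <- function(x, ...) {
  rk <- ideal_genotype_ranking(x)
  ideal <- attr(rk, "ideal")
  if (length(ideal) < 2L) ideal <- c(ideal, 0)
  gc <- x$gen_coord[, 1:2, drop = FALSE]
  d <- data.frame(GEN = rownames(gc), a1 = gc[, 1L], a2 = gc[, 2L])
  radii <- seq(0.25, 1, by = 0.25) * max(sqrt((d$a1 - ideal[1L])^2 +
                                                (d$a2 - ideal[2L])^2))
  circ <- do.call(rbind, lapply(radii, function(r) {
    th <- seq(0, 2 * pi, length.out = 120)
    data.frame(r = r, xx = ideal[1L] + r * cos(th),
               yy = ideal[2L] + r * sin(th))
  }))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$a1, y = .data$a2)) +
    ggplot2::geom_path(data = circ,
                       ggplot2::aes(x = .data$xx, y = .data$yy,
                                    group = .data$r),
                       colour = "grey70") +
    ggplot2::geom_abline(slope = ideal[2L] / max(ideal[1L], 1e-12),
                         intercept = 0, colour = "grey50") +
    ggplot2::annotate("point", x = ideal[1L], y = ideal[2L], shape = 3,
                      size = 3) +
    ggplot2::geom_text(ggplot2::aes(label = .data$GEN), size = 3) +
    ggplot2::labs(x = sprintf("Axis 1 (%.1f%%)", 100 * x$var_explained[1L]),
                  y = sprintf("Axis 2 (%.1f%%)",
                              100 * x$var_explained[min(2L, length(x$var_explained))])) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' Boxplot of cross-validated RMSPD per model
#'
#' @param x A `cv_result` from [cv_compare()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
plot.cv_result <- function(x, ...) {
  d <- x$rmspd
  d$model <- factor(d$model, levels = x$summary$model)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$model, y = .data$rmspd)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::labs(x = NULL, y = "RMSPD (t/ha)") +
    ggplot2::theme_minimal()
}
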