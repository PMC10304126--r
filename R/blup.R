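#' ANOVA variance components for a balanced two-way MET
#'
#' Moment (expected-mean-square) estimators from the joint ANOVA of a
#' balanced RCBD MET, with genotype and genotype-by-environment random:
#' `s2_res = MS_res`, `s2_ge = (MS_GE - MS_res) / r`,
#' `s2_g = (MS_G - MS_GE) / (e * r)`, each truncated at zero.  For balanced
#' data these coincide with REML except at the truncation boundary, and are
#' exactly testable in closed form.
#'
#' @param x A balanced [met_data] object.
#' @return List of class `met_vc`: `sigma2_g`, `sigma2_ge`, `sigma2_res`,
#'   `method = "anova"`, and the underlying `anova` table.
#' @export
variance_components <- function(x) {
  an <- joint_anova(x)
  ms <- function(src) an$ms[an$source == src]
  s2_res <- ms("Residual")
  s2_ge <- (ms("GEN:ENV") - s2_res) / x$r
  s2_g <- (ms("GEN") - ms("GEN:ENV")) / (x$e * x$r)
  if (s2_ge < 0 || s2_g < 0) {
    s2_ge <- max(0, s2_ge); s2_g <- max(0, s2_g)
  }
  structure(list(sigma2_g = s2_g, sigma2_ge = s2_ge, sigma2_res = s2_res,
                 method = "anova", anova = an),
            class = "met_vc")
}

#' @export
print.met_vc <- function(x, ...) {
  cat(sprintf(
    "Variance components (%s): sigma2_g = %.4g, sigma2_ge = %.4g, sigma2_res = %.4g\n",
    x$method, x$sigma2_g, x$sigma2_ge, x$sigma2_res))
  invisible(x)
}

#' BLUP of genotype means
#'
#' Shrinks each raw genotype mean toward the grand mean by the reliability
#' weight `w = s2_g / (s2_g + s2_ge/e + s2_res/(e*r))` — the best linear
#' unbiased prediction of the genotype mean under the balanced two-way
#' random model (genotype and GxE random, environments and blocks absorbed
#' as fixed centering).  On balanced data the weight is common to all
#' genotypes, so BLUP preserves the raw-mean ranking; its value-add is the
#' shrinkage magnitude.
#'
#' @param x A balanced [met_data] object.
#' @param vc Variance components from [variance_components()] (computed if
#'   omitted).
#' @return Tibble sorted by predicted mean (descending): `GEN`,
#'   `raw_mean`, `blup` (predicted genotype mean `mu + w*(raw - mu)`),
#'   `effect` (shrunken deviation), `rank`; attribute `w` (weight) and
#'   `mu` (grand mean).
#' @export
genotype_blups <- function(x, vc = variance_components(x)) {
  stopifnot(inherits(x, "met_data"), inherits(vc, "met_vc"))
  mu <- mean(x$data$YIELD)
  gm <- tapply(x$data$YIELD, x$data$GEN, mean)[x$genotypes]
  denom <- vc$sigma2_g + vc$sigma2_ge / x$e + vc$sigma2_res / (x$e * x$r)
  w <- if (denom > 0) vc$sigma2_g / denom else 0
  blup <- mu + w * (gm - mu)
  out <- tibble::tibble(GEN = names(gm), raw_mean = as.numeric(gm),
                        blup = as.numeric(blup),
                        effect = as.numeric(blup - mu))
  out <- out[order(-out$blup), ]
  out$rank <- seq_len(nrow(out))
  attr(out, "w") <- w
  attr(out, "mu") <- mu
  out
}

#' BLUP-shrunken genotype-by-environment interaction matrix
#'
#' The doubly-centered interaction residual of the cell-mean table,
#' shrunken toward zero by `s = s2_ge / (s2_ge + s2_res/r)` — the BLUP of
#' the random GxE effects given the cell means.  Its singular value
#' decomposition underlies the WAASB stability index: shrinkage discounts
#' the part of the observed interaction that is plot noise.
#'
#' @inheritParams genotype_blups
#' @return g x e matrix (doubly centered; zero when `s2_ge = 0`), with the
#'   shrinkage factor as attribute `s`.
#' @export
blup_ge_matrix <- function(x, vc = variance_components(x)) {
  stopifnot(inherits(x, "met_data"), inherits(vc, "met_vc"))
  m <- cell_means(x)
  z <- sweep(sweep(m, 1L, rowMeans(m)), 2L, colMeans(m)) + mean(m)
  denom <- vc$sigma2_ge + vc$sigma2_res / x$r
  s <- if (denom > 0) vc$sigma2_ge / denom else 0
  out <- s * z
  attr(out, "s") <- s
  out
}
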