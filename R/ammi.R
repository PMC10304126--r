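#' Joint fixed-effects ANOVA for a balanced MET
#'
#' Partitions the total plot-level sum of squares of a balanced RCBD MET
#' into environment, replicate-within-environment, genotype,
#' genotype-by-environment and residual sources — the ANOVA frame of the
#' AMMI analysis.  Genotype and GxE are tested against the residual;
#' environment is tested against replicate-within-environment, as is
#' conventional when blocks are nested in trials.
#'
#' @param x A balanced [met_data] object.
#' @return A tibble of class `met_anova` with columns `source`, `df`, `ss`,
#'   `ms`, `f`, `p` (rows `ENV`, `REP(ENV)`, `GEN`, `GEN:ENV`, `Residual`,
#'   `Total`) and attribute `shares`: the fractions of `SS_G + SS_E + SS_GE`
#'   attributable to genotype, environment and interaction.
#' @examples
#' met <- generate_met(g = 5, e = 4, r = 3, seed = 2)$data
#' joint_anova(met)
#' @export
joint_anova <- function(x) {
  stopifnot(inherits(x, "met_data"))
  if (!x$balanced) stop("joint_anova requires a balanced dataset",
                        call. = FALSE)
  if (x$g < 2L || x$e < 2L || x$r < 2L) {
    stop("need at least 2 genotypes, 2 environments and 2 replicates",
         call. = FALSE)
  }
  d <- x$data
  d$GEN <- factor(d$GEN); d$ENV <- factor(d$ENV); d$REP <- factor(d$REP)
  fit <- stats::aov(YIELD ~ ENV + ENV:REP + GEN + GEN:ENV, data = d)
  s <- summary(fit)[[1L]]
  rn <- trimws(rownames(s))
  get <- function(nm) {
    i <- match(nm, rn)
    c(df = s[["Df"]][i], ss = s[["Sum Sq"]][i])
  }
  env <- get("ENV"); rep_env <- get("ENV:REP")
  gen <- get("GEN"); ge <- get("ENV:GEN")
  if (is.na(ge["df"])) ge <- get("GEN:ENV")
  res <- get("Residuals")

  src <- c("ENV", "REP(ENV)", "GEN", "GEN:ENV", "Residual")
  df <- unname(c(env["df"], rep_env["df"], gen["df"], ge["df"], res["df"]))
  ss <- unname(c(env["ss"], rep_env["ss"], gen["ss"], ge["ss"], res["ss"]))
  ms <- ss / df
  # F: ENV against REP(ENV); GEN and GEN:ENV against Residual
  f <- c(ms[1L] / ms[2L], NA, ms[3L] / ms[5L], ms[4L] / ms[5L], NA)
  fdf2 <- c(df[2L], NA, df[5L], df[5L], NA)
  p <- ifelse(is.na(f), NA,
              stats::pf(f, df, fdf2, lower.tail = FALSE))
  out <- tibble::tibble(
    source = c(src, "Total"),
    df = c(df, sum(df)),
    ss = c(ss, sum(ss)),
    ms = c(ms, NA),
    f = c(f, NA),
    p = c(p, NA)
  )
  trio <- ss[c(3L, 1L, 4L)]
  attr(out, "shares") <- stats::setNames(trio / sum(trio),
                                         c("G", "E", "GE"))
  class(out) <- c("met_anova", class(out))
  out
}

#' Fit the AMMI decomposition to a table of cell means
#'
#' Additive main effects by row/column means, multiplicative interaction by
#' singular value decomposition of the doubly-centered residual table
#' `Z[g,e] = y[g,e] - y[g,.] - y[.,e] + y[..]`.  Singular values are
#' returned in nonincreasing order; the sign of each axis is fixed so that
#' the largest-magnitude genotype loading is positive, making axes
#' reproducible across platforms.
#'
#' @param means g x e matrix of cell means (rows genotypes, columns
#'   environments), e.g. from [cell_means()].
#' @param r Number of replicates behind each cell mean (used to convert
#'   axis sums of squares to the plot basis in [ipca_tests()]).
#' @param residual_ms Plot-level residual mean square from [joint_anova()]
#'   (optional; needed for axis F-tests).
#' @param residual_df Residual degrees of freedom (optional, as above).
#' @return An object of class `ammi_fit`: list with `mu`, `alpha` (genotype
#'   effects, sum 0), `beta` (environment effects, sum 0), `lambda`
#'   (singular values), `gamma` (g x p genotype axis matrix, orthonormal
#'   columns), `delta` (e x p environment axis matrix), `ep` (variance
#'   explained per axis), `means`, `r`, `residual_ms`, `residual_df`.
#' @seealso [ammi()] for the one-call wrapper from plot data.
#' @export
fit_ammi <- function(means, r = 1L, residual_ms = NA_real_,
                     residual_df = NA_integer_) {
  m <- as.matrix(means)
  g <- nrow(m); e <- ncol(m)
  if (g < 2L || e < 2L) stop("need >= 2 genotypes and environments",
                             call. = FALSE)
  mu <- mean(m)
  alpha <- rowMeans(m) - mu
  beta <- colMeans(m) - mu
  z <- sweep(sweep(m, 1L, rowMeans(m)), 2L, colMeans(m)) + mu
  p <- min(g - 1L, e - 1L)
  sv <- svd(z, nu = p, nv = p)
  lambda <- sv$d[seq_len(p)]
  gamma <- sv$u; delta <- sv$v
  # deterministic sign: largest |gamma| entry of each axis positive
  for (k in seq_len(p)) {
    i <- which.max(abs(gamma[, k]))
    if (gamma[i, k] < 0) {
      gamma[, k] <- -gamma[, k]
      delta[, k] <- -delta[, k]
    }
  }
  rownames(gamma) <- rownames(m); rownames(delta) <- colnames(m)
  ss <- lambda^2
  ep <- if (sum(ss) > 0) ss / sum(ss) else rep(0, p)
  structure(
    list(mu = mu, alpha = alpha, beta = beta, lambda = lambda,
         gamma = gamma, delta = delta, ep = ep, means = m, r = r,
         residual_ms = residual_ms, residual_df = residual_df),
    class = "ammi_fit"
  )
}

#' @export
print.ammi_fit <- function(x, ...) {
  cat(sprintf("AMMI fit: %d genotypes x %d environments, %d axes\n",
              nrow(x$means), ncol(x$means), length(x$lambda)))
  cat("Variance explained (%):",
      paste(sprintf("%.1f", 100 * x$ep), collapse = " "), "\n")
  invisible(x)
}

#' Fit AMMI from plot-level data
#'
#' Convenience wrapper: runs [joint_anova()], forms [cell_means()] and calls
#' [fit_ammi()] with the residual mean square attached, so [ipca_tests()]
#' can be applied directly.
#'
#' @param x A balanced [met_data] object.
#' @return An `ammi_fit` with the `met_anova` table attached as `$anova`.
#' @export
ammi <- function(x) {
  an <- joint_anova(x)
  res <- an[an$source == "Residual", ]
  fit <- fit_ammi(cell_means(x), r = x$r, residual_ms = res$ms,
                  residual_df = res$df)
  fit$anova <- an
  fit
}

#' F-tests and variance explained for the interaction axes
#'
#' Tests each interaction principal component axis (IPCA) with Gollob's
#' approximate F-test: on the plot basis the axis sum of squares is
#' `r * lambda_k^2` with `g + e - 1 - 2k` degrees of freedom, tested against
#' the plot-level residual mean square.  Axes whose Gollob df are
#' non-positive are reported untestable (`NA`).
#'
#' @param fit An `ammi_fit` carrying `r`, `residual_ms` and `residual_df`.
#' @return Tibble with one row per axis: `axis`, `ss` (plot basis), `df`,
#'   `ms`, `f`, `p`, `prop` (share of the interaction SS) and `cum_prop`
#'   (cumulative share, in percent: `prop` and `cum_prop` are 0-100).
#' @export
ipca_tests <- function(fit) {
  stopifnot(inherits(fit, "ammi_fit"))
  if (is.na(fit$residual_ms) || is.na(fit$residual_df)) {
    stop("fit carries no residual mean square; fit via ammi() or pass ",
         "residual_ms/residual_df to fit_ammi()", call. = FALSE)
  }
  g <- nrow(fit$means); e <- ncol(fit$means)
  k <- seq_along(fit$lambda)
  ss <- fit$r * fit$lambda^2
  df <- gollob_df(g, e, k)
  ms <- ifelse(df > 0, ss / df, NA)
  f <- ifelse(df > 0,
              ifelse(ss == 0, 0, ms / fit$residual_ms), NA)
  p <- ifelse(is.na(f), NA,
              ifelse(f == 0, 1,
                     stats::pf(f, df, fit$residual_df, lower.tail = FALSE)))
  tibble::tibble(axis = k, ss = ss, df = df, ms = ms, f = f, p = p,
                 prop = 100 * fit$ep, cum_prop = 100 * cumsum(fit$ep))
}

#' Gollob degrees of freedom for the k-th interaction axis
#'
#' @param g,e Genotype and environment counts.
#' @param k Axis index (vectorised).
#' @return `g + e - 1 - 2k`.
#' @export
gollob_df <- function(g, e, k) g + e - 1 - 2 * k

#' Signal/noise partition of the interaction sum of squares
#'
#' The pure-noise expectation of the GxE sum of squares is its degrees of
#' freedom times the residual mean square; whatever exceeds that is treated
#' as real (signal) interaction.  A large signal fraction argues for
#' retaining multiplicative axes; a fraction near zero argues for the
#' additive model.
#'
#' @param anova A `met_anova` table from [joint_anova()].
#' @return List with `ss_ge`, `noise`, `signal` (clamped at 0) and
#'   `signal_fraction` in [0, 1].
#' @export
ge_signal_noise <- function(anova) {
  ge <- anova[anova$source == "GEN:ENV", ]
  res <- anova[anova$source == "Residual", ]
  if (nrow(ge) != 1L || nrow(res) != 1L) {
    stop("anova table lacks GEN:ENV or Residual rows", call. = FALSE)
  }
  ss_ge <- unname(ge$ss)
  noise <- unname(ge$df * res$ms)
  signal <- max(0, ss_ge - noise)
  list(ss_ge = ss_ge, noise = min(noise, ss_ge), signal = signal,
       signal_fraction = if (ss_ge > 0) signal / ss_ge else 0)
}

#' Predict cell means from a truncated AMMI model
#'
#' `AMMIk` prediction: grand mean + genotype effect + environment effect +
#' the first `k` multiplicative terms.  `k = 0` is the purely additive
#' model; `k = p` (all axes) reproduces the observed cell means exactly.
#'
#' @param fit An `ammi_fit`.
#' @param k Number of interaction axes retained, `0 <= k <= p`.
#' @return g x e matrix of predicted cell means.
#' @export
predict_ammi <- function(fit, k) {
  stopifnot(inherits(fit, "ammi_fit"))
  p <- length(fit$lambda)
  if (length(k) != 1L || k < 0 || k > p || k != round(k)) {
    stop("k must be an integer in [0, ", p, "]", call. = FALSE)
  }
  pred <- fit$mu + outer(fit$alpha, fit$beta, `+`)
  if (k > 0) {
    idx <- seq_len(k)
    pred <- pred + fit$gamma[, idx, drop = FALSE] %*%
      diag(fit$lambda[idx], nrow = k) %*% t(fit$delta[, idx, drop = FALSE])
  }
  dimnames(pred) <- dimnames(fit$means)
  pred
}
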