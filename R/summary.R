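#' Per-environment descriptive summary
#'
#' For each environment (trial) computes the mean plot yield, the trial
#' coefficient of variation, and broad-sense heritability.  The CV is the
#' residual-based trial-quality CV used in breeding reports,
#' `100 * sqrt(MS_res) / mean`, where `MS_res` is the residual mean square of
#' the within-environment RCBD ANOVA (genotype and block effects removed) —
#' not the raw standard deviation of the plots.
#'
#' @param x A [met_data] object (need not be balanced across environments,
#'   but each summarised environment needs >= 2 genotypes; CV and H2 need
#'   >= 2 replicates and are `NA` otherwise).
#' @param environments Environments to summarise (default all).
#' @return A tibble with columns `ENV`, `MEAN`, `CV`, `H2`.
#' @seealso [heritability()]
#' @export
env_summary <- function(x, environments = x$environments) {
  stopifnot(inherits(x, "met_data"))
  rows <- lapply(environments, function(ev) {
    d <- x$data[x$data$ENV == ev, , drop = FALSE]
    if (nrow(d) == 0L) stop("environment not present: ", ev, call. = FALSE)
    mu <- mean(d$YIELD)
    n_rep <- length(unique(d$REP))
    n_gen <- length(unique(d$GEN))
    if (n_rep < 2L || n_gen < 2L) {
      return(tibble::tibble(ENV = ev, MEAN = mu, CV = NA_real_,
                            H2 = NA_real_))
    }
    aov_tab <- rcbd_anova(d)
    cv <- 100 * sqrt(aov_tab["Residual", "ms"]) / mu
    h2 <- tryCatch(heritability(x, ev), error = function(e) NA_real_)
    tibble::tibble(ENV = ev, MEAN = mu, CV = cv, H2 = h2)
  })
  do.call(rbind, rows)
}

# Within-environment RCBD ANOVA (genotype + block), via aov().
# Returns a matrix with rows Genotype/Block/Residual and columns df/ss/ms.
rcbd_anova <- function(d) {
  d$GEN <- factor(d$GEN)
  d$REP <- factor(d$REP)
  fit <- stats::aov(YIELD ~ GEN + REP, data = d)
  s <- summary(fit)[[1L]]
  rn <- trimws(rownames(s))
  out <- cbind(df = s[["Df"]], ss = s[["Sum Sq"]], ms = s[["Mean Sq"]])
  rownames(out) <- c("Genotype", "Block", "Residual")[match(
    rn, c("GEN", "REP", "Residuals"))]
  out
}

#' Broad-sense heritability within one environment
#'
#' Plot-basis broad-sense heritability of a single RCBD trial:
#' `H2 = s2_g / (s2_g + s2_res)` with `s2_res = MS_res` and
#' `s2_g = max(0, (MS_G - MS_res) / r)` from the within-environment ANOVA
#' expected mean squares.  Negative variance-component estimates are
#' truncated at zero before the ratio is formed, so the result lies in
#' [0, 1].
#'
#' @param x A [met_data] object.
#' @param environment Environment identifier.
#' @param entry_mean If `TRUE`, compute heritability on an entry-mean basis,
#'   `s2_g / (s2_g + s2_res / r)`, instead of the plot basis (the default).
#' @return Heritability in [0, 1].
#' @export
heritability <- function(x, environment, entry_mean = FALSE) {
  stopifnot(inherits(x, "met_data"))
  d <- x$data[x$data$ENV == environment, , drop = FALSE]
  if (nrow(d) == 0L) stop("environment not present: ", environment,
                          call. = FALSE)
  if (length(unique(d$GEN)) < 2L || length(unique(d$REP)) < 2L) {
    stop("heritability needs >= 2 genotypes and >= 2 replicates",
         call. = FALSE)
  }
  if (stats::var(d$YIELD) == 0) stop("no variation in environment ",
                                     environment, call. = FALSE)
  tab <- rcbd_anova(d)
  r <- length(unique(d$REP))
  s2_res <- tab["Residual", "ms"]
  s2_g <- max(0, (tab["Genotype", "ms"] - s2_res) / r)
  denom <- if (entry_mean) s2_g + s2_res / r else s2_g + s2_res
  if (denom == 0) return(0)  # only block variation: no genotypic signal
  min(1, max(0, s2_g / denom))
}

#' Bin heritability estimates
#'
#' Classifies heritability values into the three bands used for trial
#' portfolio summaries: high (>= 0.5), intermediate ([0.2, 0.5)) and low
#' (< 0.2).  Boundaries are inclusive at the lower edge of each band.
#'
#' @param values Numeric vector of heritabilities in [0, 1].
#' @return Named numeric vector of three proportions (summing to one):
#'   `high`, `mid`, `low`.
#' @export
heritability_bins <- function(values) {
  stopifnot(length(values) > 0L, all(is.finite(values)))
  c(high = mean(values >= 0.5),
    mid  = mean(values >= 0.2 & values < 0.5),
    low  = mean(values < 0.2))
}

#' Yield reduction from the most to the least favourable environment
#'
#' `100 * (max - min) / max` over a vector of environment mean yields:
#' the percent loss in the worst environment relative to the best.
#'
#' @param env_means Numeric vector (possibly named) of per-environment mean
#'   yields; `NA`s are dropped.
#' @return Percent reduction in [0, 100).
#' @export
yield_reduction <- function(env_means) {
  v <- env_means[!is.na(env_means)]
  if (length(v) < 2L) stop("need >= 2 environment means", call. = FALSE)
  if (max(v) <= 0) stop("maximum environment mean must be positive",
                        call. = FALSE)
  100 * (max(v) - min(v)) / max(v)
}

#' Class means over common testing environments
#'
#' Restricts an environment-by-class table of mean yields to the
#' environments in which *every* class was tested, then averages each class
#' column — the fair comparison of market classes grown side by side.
#'
#' @param table A data frame or matrix: rows = environments, columns =
#'   classes, entries = mean yields, `NA` where a class was not tested.
#' @return Named numeric vector of per-class means over the shared
#'   environments, with attribute `n_env` (number of shared environments).
#' @export
common_env_class_means <- function(table) {
  m <- as.matrix(table)
  storage.mode(m) <- "double"
  complete <- stats::complete.cases(m)
  if (!any(complete)) stop("no environment common to all classes",
                           call. = FALSE)
  out <- colMeans(m[complete, , drop = FALSE])
  attr(out, "n_env") <- sum(complete)
  out
}
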