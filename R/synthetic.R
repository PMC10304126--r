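#' Generate a balanced synthetic MET with known structure
#'
#' Simulates plot yields from the model the MET analyses assume:
#' `y[g,e,r] = mu + alpha_g + beta_e + sum_k lambda_k gamma[g,k] delta[e,k]
#' + b[e,r] + eps`, with genotype effects (variance `sigma2_g`),
#' environment effects (`sigma2_e`) and block-within-environment effects
#' (`sigma2_b`) Gaussian and centered, a low-rank multiplicative
#' interaction with prescribed singular values `lambda` on orthonormal axis
#' vectors (drawn by QR of seeded Gaussian matrices), an optional
#' unstructured Gaussian interaction (`sigma2_ge`, i.e. full-rank GxE as in
#' the classical random model), and Gaussian plot error (`sigma2_res`).
#' Yields are shifted up if necessary so all plots are nonnegative.
#'
#' @param g,e,r Genotype, environment, replicate counts (each >= 2).
#' @param mu Grand mean (t/ha).
#' @param sigma2_g,sigma2_e,sigma2_b,sigma2_res Variances of the Gaussian
#'   effect draws, (t/ha)^2.
#' @param sigma2_ge Variance of an unstructured iid Gaussian GxE effect
#'   (default 0: interaction comes only from `lambda`).
#' @param lambda Singular values of the planted multiplicative interaction,
#'   on the cell-mean basis (length t <= min(g-1, e-1); default none).
#' @param alpha Optional fixed genotype effects (length g) overriding the
#'   Gaussian draw.
#' @param stable_genotype Optional index of a genotype given a zero row in
#'   every interaction axis (and no unstructured GxE): a planted perfectly
#'   stable genotype.
#' @param seed Integer seed; the dataset is a deterministic function of the
#'   arguments and the seed.
#' @return List: `data` (a balanced [met_data]), `truth` (list with all
#'   drawn effects: `mu`, `alpha`, `beta`, `lambda`, `gamma`, `delta`,
#'   `ge`, `blocks`, the variance arguments and `seed`).
#' @examples
#' sim <- generate_met(g = 6, e = 5, r = 3, lambda = c(4, 2), seed = 7)
#' ammi(sim$data)
#' @export
generate_met <- function(g, e, r, mu = 2.7,
                         sigma2_g = 0.03, sigma2_e = 0.9,
                         sigma2_b = 0.01, sigma2_res = 0.09,
                         sigma2_ge = 0, lambda = numeric(0),
                         alpha = NULL, stable_genotype = NULL,
                         seed = 1L) {
  if (g < 2L || e < 2L || r < 2L) {
    stop("need g, e, r >= 2", call. = FALSE)
  }
  t_ax <- length(lambda)
  if (t_ax > min(g - 1L, e - 1L)) {
    stop("too many interaction axes for the table size", call. = FALSE)
  }
  set.seed(seed)
  gens <- sprintf("G%02d", seq_len(g))
  loc <- paste0(LETTERS[(seq_len(e) - 1L) %/% 26L + 1L],
                LETTERS[(seq_len(e) - 1L) %% 26L + 1L])
  envs <- paste0(loc, 2000 + seq_len(e))  # location code + 4-digit year
  if (is.null(alpha)) {
    alpha <- stats::rnorm(g, 0, sqrt(sigma2_g))
  } else {
    stopifnot(length(alpha) == g)
  }
  alpha <- alpha - mean(alpha)
  beta <- stats::rnorm(e, 0, sqrt(sigma2_e)); beta <- beta - mean(beta)

  gamma <- delta <- NULL
  ge_mat <- matrix(0, g, e)
  if (t_ax > 0L) {
    gm <- matrix(stats::rnorm(g * t_ax), g, t_ax)
    dm <- matrix(stats::rnorm(e * t_ax), e, t_ax)
    if (!is.null(stable_genotype)) gm[stable_genotype, ] <- 0
    gamma <- qr.Q(qr(cbind(1, gm)))[, -1L, drop = FALSE]  # centered axes
    delta <- qr.Q(qr(cbind(1, dm)))[, -1L, drop = FALSE]
    if (!is.null(stable_genotype)) {
      # re-zero: orthogonalisation against the constant keeps a zero row
      # only if we orthogonalise within the non-stable genotypes
      gm2 <- gm[-stable_genotype, , drop = FALSE]
      q2 <- qr.Q(qr(cbind(1, gm2)))[, -1L, drop = FALSE]
      gamma <- matrix(0, g, t_ax)
      gamma[-stable_genotype, ] <- q2
    }
    ge_mat <- gamma %*% diag(lambda, nrow = t_ax) %*% t(delta)
  }
  if (sigma2_ge > 0) {
    extra <- matrix(stats::rnorm(g * e, 0, sqrt(sigma2_ge)), g, e)
    if (!is.null(stable_genotype)) extra[stable_genotype, ] <- 0
    ge_mat <- ge_mat + extra
  }

  blocks <- matrix(stats::rnorm(e * r, 0, sqrt(sigma2_b)), e, r)
  idx <- expand.grid(GEN = seq_len(g), ENV = seq_len(e), REP = seq_len(r),
                     KEEP.OUT.ATTRS = FALSE)
  yy <- mu + alpha[idx$GEN] + beta[idx$ENV] +
    ge_mat[cbind(idx$GEN, idx$ENV)] + blocks[cbind(idx$ENV, idx$REP)] +
    stats::rnorm(nrow(idx), 0, sqrt(sigma2_res))
  if (min(yy) < 0) yy <- yy - min(yy)  # yields are nonnegative

  df <- data.frame(GEN = gens[idx$GEN], ENV = envs[idx$ENV],
                   REP = as.character(idx$REP), YIELD = yy,
                   stringsAsFactors = FALSE)
  truth <- list(mu = mu, alpha = stats::setNames(alpha, gens),
                beta = stats::setNames(beta, envs), lambda = lambda,
                gamma = gamma, delta = delta, ge = ge_mat, blocks = blocks,
                sigma2_g = sigma2_g, sigma2_e = sigma2_e,
                sigma2_b = sigma2_b, sigma2_res = sigma2_res,
                sigma2_ge = sigma2_ge, seed = seed)
  list(data = met_data(df), truth = truth)
}

#' Preset parameterisations for the synthetic generator
#'
#' Named argument lists for [generate_met()]:
#' \describe{
#'   \item{`pea_like`}{12 genotypes x 28 environments x 3 replicates with an
#'     environment-dominated sum-of-squares budget (expected G/E/GE shares
#'     of G+E+GE about 0.03/0.90/0.07).  The interaction mixes two strong
#'     planted axes with a diffuse full-rank Gaussian tail — the pattern
#'     seen in real pea trial archives, where several axes test significant
#'     but one to three carry most of the signal — sized so the expected
#'     signal fraction of the interaction is about 0.6.}
#'   \item{`noise_dominated`}{Interaction entirely plot noise: the additive
#'     model is the right choice and the GE signal fraction is near 0.}
#'   \item{`rank1_crossover`}{One strong interaction axis on a small table,
#'     producing crossover reaction norms.}
#' }
#'
#' @param name Preset name.
#' @return Named list of [generate_met()] arguments (without `seed`).
#' @export
met_preset <- function(name = c("pea_like", "noise_dominated",
                                "rank1_crossover")) {
  name <- match.arg(name)
  switch(name,
    pea_like = list(g = 12L, e = 28L, r = 3L, mu = 2.7,
                    sigma2_g = 0.031, sigma2_e = 0.884, sigma2_b = 0.01,
                    sigma2_res = 0.09, lambda = c(2.005, 1.418),
                    sigma2_ge = 0.0248),
    noise_dominated = list(g = 10L, e = 12L, r = 3L, mu = 2.7,
                           sigma2_g = 0.05, sigma2_e = 0.5, sigma2_b = 0.01,
                           sigma2_res = 0.2, lambda = numeric(0)),
    rank1_crossover = list(g = 6L, e = 8L, r = 3L, mu = 2.7,
                           sigma2_g = 0.02, sigma2_e = 0.4, sigma2_b = 0.01,
                           sigma2_res = 0.04, lambda = 3)
  )
}

#' Generate daily weather linked to environment mean yields
#'
#' Simulates a daily May-August weather series (maximum temperature and
#' rainfall) for `e` synthetic environments, with environment-level
#' temperature and rain-frequency offsets so the period covariates of
#' [aggregate_weather()] vary across environments, and then builds
#' environment mean yields as a linear function of chosen *standardized*
#' covariates plus Gaussian noise.
#'
#' @param e Number of environments.
#' @param effects Named numeric vector mapping covariate names (as produced
#'   by [aggregate_weather()], e.g. `"MaxTJune2"`) to linear effects (t/ha
#'   per standard deviation of the covariate).  Empty means yield is
#'   independent of weather.
#' @param base Mean yield level (t/ha).
#' @param noise_sd Residual standard deviation of the environment means.
#' @param hot_threshold Hot-day threshold handed to [aggregate_weather()].
#' @param seed Integer seed.
#' @return List: `daily` (data frame ENV/DATE/TMAX/RAIN), `covariates`
#'   (from [aggregate_weather()]), `yields` (named vector of environment
#'   mean yields), `effects`, `seed`.
#' @export
generate_weather_yield <- function(e, effects = numeric(0), base = 2.7,
                                   noise_sd = 0.1, hot_threshold = 90,
                                   seed = 1L) {
  stopifnot(e >= 3L)
  set.seed(seed)
  envs <- paste0("W", LETTERS[(seq_len(e) - 1L) %% 26L + 1L],
                 2000 + seq_len(e))
  daily <- do.call(rbind, lapply(seq_len(e), function(i) {
    year <- 2000 + i
    dates <- seq(as.Date(sprintf("%d-05-01", year)),
                 as.Date(sprintf("%d-08-31", year)), by = "day")
    doy <- as.integer(format(dates, "%j"))
    # seasonal arc peaking late July, env-specific warmth and dryness
    warm <- stats::rnorm(1L, 0, 6)
    t_mean <- 68 + 22 * sin(pi * (doy - 110) / 150) + warm
    tmax <- t_mean + stats::rnorm(length(dates), 0, 6)
    p_rain <- stats::plogis(stats::qlogis(0.25) + stats::rnorm(1L, 0, 0.8) -
                              0.01 * (doy - 150))
    wet <- stats::runif(length(dates)) < p_rain
    rain <- ifelse(wet, round(stats::rgamma(length(dates), 1.2, 4), 2), 0)
    data.frame(ENV = envs[i], DATE = dates, TMAX = round(tmax, 1),
               RAIN = rain, stringsAsFactors = FALSE)
  }))
  covs <- aggregate_weather(daily, hot_threshold = hot_threshold)
  xm <- as.matrix(covs[setdiff(names(covs), "ENV")])
  y <- rep(base, e)
  if (length(effects) > 0L) {
    if (!all(names(effects) %in% colnames(xm))) {
      stop("effects name covariates that are not generated: ",
           paste(setdiff(names(effects), colnames(xm)), collapse = ", "),
           call. = FALSE)
    }
    xs <- scale(xm[, names(effects), drop = FALSE])
    if (anyNA(xs)) stop("degenerate covariate in effects", call. = FALSE)
    y <- y + drop(xs %*% effects)
  }
  y <- y + stats::rnorm(e, 0, noise_sd)
  list(daily = daily, covariates = covs,
       yields = stats::setNames(y, covs$ENV), effects = effects,
       seed = seed)
}
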