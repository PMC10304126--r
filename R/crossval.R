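#' Split a MET into training and validation replicates
#'
#' Within every environment one replicate label is drawn uniformly at
#' random and its plots become the validation set; the remaining r-1
#' replicates per environment form the training set.  Replicate labels are
#' local to an environment, so the held-out block differs across
#' environments.  Deterministic under a fixed seed.
#'
#' @param x A balanced [met_data] object with r >= 2.
#' @param seed Integer seed (optional; the caller's RNG stream is used when
#'   omitted).
#' @return List with `train` and `validate`, both [met_data] objects, plus
#'   `held_out` (named character: validation replicate per environment).
#' @export
split_train_validate <- function(x, seed = NULL) {
  stopifnot(inherits(x, "met_data"))
  if (!x$balanced) stop("requires a balanced dataset", call. = FALSE)
  if (x$r < 2L) stop("need >= 2 replicates to hold one out", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  held <- vapply(x$environments,
                 function(ev) sample(x$replicates[[ev]], 1L), character(1L))
  d <- x$data
  is_val <- d$REP == held[d$ENV]
  list(train = met_data(d[!is_val, , drop = FALSE]),
       validate = met_data(d[is_val, , drop = FALSE]),
       held_out = held)
}

#' Root-mean-square prediction difference
#'
#' `sqrt(mean((predicted - observed)^2))` over validation plots: the loss
#' used to compare MET prediction models, smaller meaning more accurate.
#'
#' @param predicted g x e matrix of predicted cell values (dimnames =
#'   genotype/environment labels) or a numeric vector aligned with
#'   `observed`.
#' @param observed A [met_data] object of validation plots, or a numeric
#'   vector.
#' @return Nonnegative scalar.
#' @export
rmspd <- function(predicted, observed) {
  if (inherits(observed, "met_data")) {
    d <- observed$data
    if (is.null(dimnames(predicted))) {
      stop("predicted matrix needs genotype/environment dimnames",
           call. = FALSE)
    }
    pred <- predicted[cbind(match(d$GEN, rownames(predicted)),
                            match(d$ENV, colnames(predicted)))]
    if (anyNA(pred)) stop("validation records without predictions",
                          call. = FALSE)
    obs <- d$YIELD
  } else {
    pred <- predicted; obs <- observed
    if (length(pred) != length(obs)) stop("length mismatch", call. = FALSE)
  }
  if (length(obs) == 0L) stop("empty validation set", call. = FALSE)
  sqrt(mean((pred - obs)^2))
}

# BLUP cell predictions from a training dataset: grand mean + shrunken
# genotype effect + environment mean deviation + BLUP GxE entry.
blup_cell_predictions <- function(train) {
  vc <- variance_components(train)
  gb <- genotype_blups(train, vc)
  ge <- blup_ge_matrix(train, vc)
  m <- cell_means(train)
  mu <- mean(m)
  eff <- stats::setNames(gb$effect, gb$GEN)[rownames(m)]
  beta <- colMeans(m) - mu
  pred <- mu + outer(eff, beta, `+`) + ge
  dimnames(pred) <- dimnames(m)
  pred
}

#' Cross-validated comparison of BLUP and the AMMI model family
#'
#' Replicate-holdout cross-validation: for each resample the data are split
#' with [split_train_validate()], every AMMI family member (AMMI0, the
#' purely additive model, through AMMIF, all axes) and the BLUP model are
#' fitted to the training data, variance components re-estimated within the
#' resample, and each model's cell predictions are scored against the
#' held-out plots by [rmspd()].
#'
#' @param x A balanced [met_data] object (r >= 2; the classical design uses
#'   r = 3, two replicates training and one validation).
#' @param n_resamples Number of resamples (study designs typically use
#'   1000; a few hundred suffice for stable means).
#' @param seed Integer root seed; the whole RMSPD table is reproducible
#'   from it.
#' @param comparable_frac Two models are "comparable" when their mean
#'   RMSPDs differ by less than this fraction of the best model's RMSPD
#'   (used for the simplicity rule, default 0.01).
#' @return Object of class `cv_result`: `rmspd` (tibble: `model`,
#'   `resample`, `rmspd`), `summary` (tibble: `model`, `mean_rmspd`,
#'   `sd_rmspd`), `best` (model with smallest mean RMSPD), `chosen`
#'   (simplest AMMI member comparable to the best AMMI member, or the best
#'   model overall if that is BLUP/AMMI0), `n_resamples`, `seed`.
#' @export
cv_compare <- function(x, n_resamples = 1000L, seed = 1L,
                       comparable_frac = 0.01) {
  stopifnot(inherits(x, "met_data"))
  if (n_resamples < 1L) stop("n_resamples must be >= 1", call. = FALSE)
  if (!x$balanced) stop("requires a balanced dataset", call. = FALSE)
  p <- min(x$g - 1L, x$e - 1L)
  models <- c(paste0("AMMI", 0:p), "BLUP")
  models[p + 1L] <- "AMMIF"
  set.seed(seed)
  res <- matrix(NA_real_, nrow = n_resamples, ncol = length(models),
                dimnames = list(NULL, models))
  for (b in seq_len(n_resamples)) {
    sp <- split_train_validate(x)
    an <- joint_anova(sp$train)
    resid <- an[an$source == "Residual", ]
    fit <- fit_ammi(cell_means(sp$train), r = sp$train$r,
                    residual_ms = resid$ms, residual_df = resid$df)
    for (k in 0:p) {
      res[b, k + 1L] <- rmspd(predict_ammi(fit, k), sp$validate)
    }
    res[b, "BLUP"] <- rmspd(blup_cell_predictions(sp$train), sp$validate)
  }
  long <- tibble::tibble(
    model = rep(models, each = n_resamples),
    resample = rep(seq_len(n_resamples), times = length(models)),
    rmspd = as.vector(res)
  )
  summ <- tibble::tibble(
    model = models,
    mean_rmspd = unname(colMeans(res)),
    sd_rmspd = unname(apply(res, 2L, stats::sd))
  )
  best <- summ$model[which.min(summ$mean_rmspd)]
  # simplicity rule among AMMI members: smallest k comparable to best AMMI
  am <- summ[summ$model != "BLUP", ]
  best_am <- min(am$mean_rmspd)
  comparable <- am$model[am$mean_rmspd <= best_am * (1 + comparable_frac)]
  chosen <- comparable[1L]  # models ordered AMMI0..AMMIF
  structure(list(rmspd = long, summary = summ, best = best,
                 chosen_ammi = chosen, n_resamples = n_resamples,
                 seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("Cross-validation over %d resamples (seed %d)\n",
              x$n_resamples, x$seed))
  s <- x$summary[order(x$summary$mean_rmspd), ]
  print(s, n = nrow(s))
  cat("Best model:", x$best,
      "| simplest comparable AMMI member:", x$chosen_ammi, "\n")
  invisible(x)
}
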