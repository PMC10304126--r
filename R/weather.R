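#' Aggregate daily weather into period covariates
#'
#' Builds the environment-by-covariate matrix used to relate trial mean
#' yields to growing-season weather.  Each month is cut into three periods
#' — days 1-10, 11-20, and 21 to month end — and per period the maximum
#' temperature is averaged (`MaxT<Month><1|2|3>`) and rainfall totalled
#' (`RF<Month><1|2|3>`).  For June and July two count variables are added:
#' `RF0<Month>`, the number of rainless days in the month, and
#' `MaxT>90<Month>`, the number of days with maximum temperature at or
#' above the hot-day threshold (default 90, on the Fahrenheit scale; pass
#' 32.2 for Celsius data).
#'
#' @param daily Data frame with columns `ENV`, `DATE` (Date or
#'   "YYYY-MM-DD"), `TMAX`, `RAIN`.  Each environment's records must cover
#'   the requested months of its year; a period with missing days yields
#'   `NA` for its covariates.
#' @param months Integer months for the period variables (default May-July,
#'   `5:7`; August can be added with `5:8`).
#' @param count_months Months receiving the rainless-day and hot-day
#'   counts (default June and July).
#' @param hot_threshold Hot-day threshold on the `TMAX` scale (inclusive).
#' @return Data frame (one row per environment, `ENV` column first) whose
#'   remaining columns are the named covariates.
#' @export
aggregate_weather <- function(daily, months = 5:7, count_months = 6:7,
                              hot_threshold = 90) {
  stopifnot(all(c("ENV", "DATE", "TMAX", "RAIN") %in% names(daily)))
  daily$DATE <- as.Date(daily$DATE)
  month_names <- month.name
  envs <- unique(daily$ENV)
  rows <- lapply(envs, function(ev) {
    d <- daily[daily$ENV == ev, , drop = FALSE]
    mo <- as.integer(format(d$DATE, "%m"))
    dy <- as.integer(format(d$DATE, "%d"))
    out <- list(ENV = ev)
    for (m in months) {
      in_m <- mo == m
      n_days <- days_in_month(m, as.integer(format(d$DATE[1L], "%Y")))
      bounds <- list(c(1L, 10L), c(11L, 20L), c(21L, n_days))
      for (p in 1:3) {
        sel <- in_m & dy >= bounds[[p]][1L] & dy <= bounds[[p]][2L]
        expected <- bounds[[p]][2L] - bounds[[p]][1L] + 1L
        complete <- sum(sel) == expected && !anyNA(d$TMAX[sel]) &&
          !anyNA(d$RAIN[sel])
        out[[paste0("MaxT", month_names[m], p)]] <-
          if (complete) mean(d$TMAX[sel]) else NA_real_
        out[[paste0("RF", month_names[m], p)]] <-
          if (complete) sum(d$RAIN[sel]) else NA_real_
      }
      if (m %in% count_months) {
        sel <- in_m
        complete <- sum(sel) == n_days && !anyNA(d$RAIN[sel]) &&
          !anyNA(d$TMAX[sel])
        out[[paste0("RF0", month_names[m])]] <-
          if (complete) sum(d$RAIN[sel] == 0) else NA_real_
        out[[paste0("MaxT>90", month_names[m])]] <-
          if (complete) sum(d$TMAX[sel] >= hot_threshold) else NA_real_
      }
    }
    as.data.frame(out, check.names = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

days_in_month <- function(m, year) {
  # year matters only for February, outside the growing-season months used
  # here, but handle it anyway
  d <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)[m]
  if (m == 2L && (year %% 4 == 0 & (year %% 100 != 0 | year %% 400 == 0))) {
    d <- 29L
  }
  d
}

#' Pearson screening of weather covariates against yield
#'
#' Plain Pearson correlation of each covariate column with the
#' environment mean yields, pairwise-complete.  Zero-variance columns are
#' reported as `NA`.
#'
#' @param x Covariate data frame from [aggregate_weather()] (with `ENV`
#'   column) or a plain numeric matrix.
#' @param y Named numeric vector of environment mean yields; when `x` has
#'   an `ENV` column, `y` is aligned by name.
#' @return Named numeric vector of correlations.
#' @export
pearson_screen <- function(x, y) {
  xm <- covariate_matrix(x, y)
  y <- attr(xm, "y")
  if (length(y) < 3L) stop("need >= 3 environments", call. = FALSE)
  apply(xm, 2L, function(col) {
    ok <- !is.na(col) & !is.na(y)
    if (sum(ok) < 3L || stats::sd(col[ok]) == 0) return(NA_real_)
    stats::cor(col[ok], y[ok])
  })
}

covariate_matrix <- function(x, y) {
  if (is.data.frame(x) && "ENV" %in% names(x)) {
    envs <- x$ENV
    xm <- as.matrix(x[setdiff(names(x), "ENV")])
    rownames(xm) <- envs
    if (!is.null(names(y))) {
      if (!all(envs %in% names(y))) stop("yields missing for some ",
                                         "environments", call. = FALSE)
      y <- y[envs]
    }
  } else {
    xm <- as.matrix(x)
  }
  if (length(y) != nrow(xm)) stop("yield vector does not match covariate ",
                                  "rows", call. = FALSE)
  storage.mode(xm) <- "double"
  attr(xm, "y") <- as.numeric(y)
  xm
}

#' Partial least squares regression of yield on weather covariates
#'
#' Univariate-response PLSR by the NIPALS sequence: covariates are
#' autoscaled (zero mean, unit variance), yield is centered, and latent
#' components are extracted successively (weight vector proportional to
#' `X'y`, scores, loadings, deflation).  The returned coefficients are on
#' the standardized-predictor scale, so their signs and relative sizes read
#' directly as directions and strengths of the weather effects.  With as
#' many components as the rank of `X` the coefficients equal the ordinary
#' least squares solution on the standardized data.
#'
#' @inheritParams pearson_screen
#' @param n_components Number of latent components (default 2, the usual
#'   choice for a coefficient screen; must be < number of environments).
#' @return List of class `plsr_fit`: `coefficients` (named, standardized
#'   scale), `correlations` (Pearson screen of the same variables),
#'   `n_components`, `dropped` (constant columns removed).
#' @export
plsr_fit <- function(x, y, n_components = 2L) {
  xm <- covariate_matrix(x, y)
  y0 <- attr(xm, "y")
  if (anyNA(xm) || anyNA(y0)) stop("PLSR requires complete covariates",
                                   call. = FALSE)
  if (nrow(xm) < n_components + 1L) {
    stop("need more environments than components", call. = FALSE)
  }
  sds <- apply(xm, 2L, stats::sd)
  dropped <- colnames(xm)[sds == 0]
  if (length(dropped) > 0L) {
    warning("dropping constant column(s): ", paste(dropped, collapse = ", "))
    xm <- xm[, sds > 0, drop = FALSE]
  }
  xs <- scale(xm)
  ys <- y0 - mean(y0)
  nvar <- ncol(xs)
  a <- min(n_components, nvar, nrow(xs) - 1L)
  W <- P <- matrix(0, nvar, a)
  qv <- numeric(a)
  Xd <- xs; yd <- ys
  for (h in seq_len(a)) {
    w <- drop(crossprod(Xd, yd))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { a <- h - 1L; break }
    w <- w / nw
    t_h <- drop(Xd %*% w)
    tt <- sum(t_h^2)
    p_h <- drop(crossprod(Xd, t_h)) / tt
    q_h <- sum(yd * t_h) / tt
    Xd <- Xd - tcrossprod(t_h, p_h)
    yd <- yd - q_h * t_h
    W[, h] <- w; P[, h] <- p_h; qv[h] <- q_h
  }
  if (a == 0L) {
    coefs <- stats::setNames(rep(0, nvar), colnames(xs))
  } else {
    Wa <- W[, seq_len(a), drop = FALSE]
    Pa <- P[, seq_len(a), drop = FALSE]
    B <- Wa %*% solve(crossprod(Pa, Wa), qv[seq_len(a)])
    coefs <- stats::setNames(drop(B), colnames(xs))
  }
  structure(list(coefficients = coefs,
                 correlations = pearson_screen(xm, y0),
                 n_components = a, dropped = dropped),
            class = "plsr_fit")
}

#' @export
print.plsr_fit <- function(x, ...) {
  cat(sprintf("PLSR with %d latent component(s)\n", x$n_components))
  ord <- order(-abs(x$coefficients))
  print(round(x$coefficients[ord], 4))
  invisible(x)
}
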