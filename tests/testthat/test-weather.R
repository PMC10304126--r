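make_daily <- function(env = "PU2001", year = 2001, tmax = 70, rain = 0.1) {
  dates <- seq(as.Date(sprintf("%d-05-01", year)),
               as.Date(sprintf("%d-08-31", year)), by = "day")
  data.frame(ENV = env, DATE = dates,
             TMAX = rep_len(tmax, length(dates)),
             RAIN = rep_len(rain, length(dates)),
             stringsAsFactors = FALSE)
}

test_that("period covariates follow the 10/10/remainder calendar cut", {
  d <- make_daily()
  # plant a recognizable May profile: 60 deg first 10 days, 70 next 10,
  # 80 for the remaining 11
  may <- as.integer(format(d$DATE, "%m")) == 5
  dy <- as.integer(format(d$DATE, "%d"))
  d$TMAX[may & dy <= 10] <- 60
  d$TMAX[may & dy > 10 & dy <= 20] <- 70
  d$TMAX[may & dy > 20] <- 80
  d$RAIN[may] <- 0.2
  cov <- aggregate_weather(d)
  expect_equal(cov$MaxTMay1, 60)
  expect_equal(cov$MaxTMay2, 70)
  expect_equal(cov$MaxTMay3, 80)
  expect_equal(cov$RFMay1, 2)
  expect_equal(cov$RFMay3, 0.2 * 11)   # 11 remaining days in May
  # June/July only get the count variables
  expect_true(all(c("RF0June", "RF0July", "MaxT>90June",
                    "MaxT>90July") %in% names(cov)))
  expect_false("RF0May" %in% names(cov))
})

test_that("rainless and hot-day counters count inclusively", {
  d <- make_daily(rain = 0)
  june <- as.integer(format(d$DATE, "%m")) == 6
  dy <- as.integer(format(d$DATE, "%d"))
  d$TMAX[june] <- 85
  d$TMAX[june & dy %in% c(3, 9, 20, 30)] <- c(90, 95, 102, 90)
  cov <- aggregate_weather(d)
  expect_equal(cov$RF0June, 30)
  expect_equal(cov[["MaxT>90June"]], 4)  # the threshold itself counts
  expect_true(all(cov[grepl("^RFJune", names(cov))] == 0))
  # a missing day in a period flags its covariates as missing
  d2 <- make_daily()
  d2 <- d2[d2$DATE != as.Date("2001-06-05"), ]
  cov2 <- aggregate_weather(d2)
  expect_true(is.na(cov2$MaxTJune1))
  expect_true(is.na(cov2$RF0June))
  expect_false(is.na(cov2$MaxTJune2))
})

test_that("Pearson screening finds exact and null relations", {
  set.seed(2)
  x <- data.frame(ENV = paste0("E", 1:6), a = 1:6, b = rnorm(6),
                  const = 1, check.names = FALSE)
  y <- setNames(2 * (1:6) + 3, x$ENV)
  r <- pearson_screen(x, y)
  expect_equal(unname(r["a"]), 1)
  expect_true(is.na(r["const"]))
  # affine invariance (positive scale)
  r2 <- pearson_screen(x, 10 * y + 4)
  expect_equal(r2[c("a", "b")], r[c("a", "b")])
  # orthogonal column has r near 0 by construction
  x$orth <- resid(lm(rnorm(6) ~ y))
  expect_equal(unname(pearson_screen(x, y)["orth"]), 0,
               tolerance = 1e-10)
})

test_that("single-predictor PLSR equals the standardized LS slope", {
  set.seed(5)
  x <- matrix(rnorm(12), 12, 1, dimnames = list(NULL, "v"))
  y <- 2 + 0.8 * x[, 1] + rnorm(12, 0, 0.3)
  fit <- plsr_fit(x, y, n_components = 1)
  ref <- unname(coef(lm(y ~ scale(x)))[2])
  expect_equal(unname(fit$coefficients), ref)
})

test_that("full-rank PLSR reproduces OLS on standardized data", {
  set.seed(6)
  x <- matrix(rnorm(60), 12, 5, dimnames = list(NULL, paste0("v", 1:5)))
  y <- drop(x %*% c(1, -0.5, 0, 0.2, 0.1)) + rnorm(12, 0, 0.2)
  fit <- plsr_fit(x, y, n_components = 5)
  ref <- coef(lm(y ~ scale(x)))[-1]
  expect_equal(unname(fit$coefficients), unname(ref), tolerance = 1e-8)
})

test_that("PLSR predictions agree with an independent implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(7)
  x <- matrix(rnorm(80), 16, 5, dimnames = list(NULL, paste0("v", 1:5)))
  y <- drop(x %*% c(0.8, -0.6, 0.3, 0, 0)) + rnorm(16, 0, 0.3)
  for (nc in 1:2) {
    fit <- plsr_fit(x, y, n_components = nc)
    mine <- drop(scale(x) %*% fit$coefficients) + mean(y)
    ref <- mixOmics::pls(x, y, ncomp = nc, mode = "regression",
                         scale = TRUE)
    theirs <- predict(ref, x)$predict[, 1, nc]
    expect_equal(mine, unname(theirs), tolerance = 1e-6)
  }
})

test_that("null covariates give near-zero coefficients", {
  set.seed(8)
  coefs <- replicate(30, {
    x <- matrix(rnorm(45), 15, 3)
    colnames(x) <- paste0("v", 1:3)
    y <- rnorm(15)
    max(abs(plsr_fit(x, y, 2)$coefficients))
  })
  expect_lt(median(coefs), 0.5)
})

test_that("a planted June-heat penalty is recovered with negative signs", {
  hits <- vapply(1:12, function(s) {
    sim <- generate_weather_yield(
      e = 14, effects = c(MaxTJune2 = -0.5, MaxTJune3 = -0.4),
      noise_sd = 0.1, seed = 300 + s)
    r <- pearson_screen(sim$covariates, sim$yields)
    fit <- plsr_fit(sim$covariates, sim$yields, n_components = 2)
    r["MaxTJune2"] < 0 && fit$coefficients["MaxTJune2"] < 0
  }, logical(1))
  expect_gte(mean(hits), 0.95)
  # zero effects: correlations hover near zero
  null <- generate_weather_yield(e = 20, seed = 9)
  r0 <- pearson_screen(null$covariates, null$yields)
  expect_lt(median(abs(r0), na.rm = TRUE), 0.5)
})
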