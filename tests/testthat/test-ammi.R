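test_that("joint ANOVA matches brute-force SS enumeration", {
  for (dims in list(c(2, 2, 2), c(5, 4, 3))) {
    x <- toy_met(dims[1], dims[2], dims[3], seed = sum(dims))
    an <- joint_anova(x)
    bf <- brute_force_ss(x$data)
    get_ss <- function(src) an$ss[an$source == src]
    expect_equal(get_ss("ENV"), bf$env, tolerance = 1e-8)
    expect_equal(get_ss("REP(ENV)"), bf$rep_env, tolerance = 1e-8)
    expect_equal(get_ss("GEN"), bf$gen, tolerance = 1e-8)
    expect_equal(get_ss("GEN:ENV"), bf$ge, tolerance = 1e-8)
    expect_equal(get_ss("Residual"), bf$res, tolerance = 1e-8)
    expect_equal(get_ss("Total"), bf$total, tolerance = 1e-8)
    # df bookkeeping
    g <- dims[1]; e <- dims[2]; r <- dims[3]
    expect_equal(an$df[an$source == "Total"], g * e * r - 1)
    expect_equal(an$df[an$source == "Residual"], e * (g - 1) * (r - 1))
  }
})

test_that("no genotype differences means zero genotype SS", {
  df <- expand.grid(GEN = c("A", "B"), ENV = c("X", "Y"),
                    REP = c("1", "2"), stringsAsFactors = FALSE)
  df$YIELD <- ifelse(df$ENV == "X", 2, 5)  # environments differ only
  an <- joint_anova(met_data(df))
  expect_equal(an$ss[an$source == "GEN"], 0, tolerance = 1e-12)
  expect_error(joint_anova(met_data(df[-1, ])), "balanced")
})

test_that("environment-dominant simulation returns its SS share", {
  sim <- do.call(generate_met, c(met_preset("pea_like"), list(seed = 1)))
  shares <- attr(joint_anova(sim$data), "shares")
  expect_equal(unname(shares["E"]), 0.90, tolerance = 0.06)
  expect_equal(sum(shares), 1)
})

test_that("AMMI decomposition recovers structure and conserves SS", {
  # purely additive table -> all singular values zero
  mu <- 3; a <- c(-1, 0, 1); b <- c(-0.5, 0.5, 0, 0)
  add <- mu + outer(a, b, `+`)
  dimnames(add) <- list(paste0("G", 1:3), paste0("E", 1:4))
  f_add <- fit_ammi(add)
  expect_equal(f_add$lambda, rep(0, length(f_add$lambda)),
               tolerance = 1e-12)
  expect_equal(predict_ammi(f_add, 0), add)

  # planted rank-1 interaction: one positive singular value, exact EP
  u <- c(2, -1, -1) / sqrt(6); v <- c(1, -1, 0, 0) / sqrt(2)
  rank1 <- add + 2.5 * outer(u, v)
  f1 <- fit_ammi(rank1)
  expect_equal(f1$lambda[1], 2.5)
  expect_equal(f1$lambda[-1], rep(0, length(f1$lambda) - 1),
               tolerance = 1e-12)
  expect_equal(f1$ep[1], 1)
  expect_equal(predict_ammi(f1, 1), rank1)  # k=1 recovers the table

  # random table: sum lambda^2 equals the brute-force SS of Z
  set.seed(8)
  m <- matrix(rnorm(20, 5), 5, 4,
              dimnames = list(paste0("G", 1:5), paste0("E", 1:4)))
  f <- fit_ammi(m)
  z <- sweep(sweep(m, 1, rowMeans(m)), 2, colMeans(m)) + mean(m)
  expect_equal(sum(f$lambda^2), sum(z^2))
  # Frobenius reconstruction of Z from the axes
  expect_equal(f$gamma %*% diag(f$lambda) %*% t(f$delta), z,
               ignore_attr = TRUE)
  # orthonormal axes, nonincreasing EP
  expect_equal(crossprod(f$gamma), diag(ncol(f$gamma)),
               ignore_attr = TRUE)
  expect_equal(crossprod(f$delta), diag(ncol(f$delta)),
               ignore_attr = TRUE)
  expect_true(all(diff(f$ep) <= 1e-12))
})

test_that("AMMIF reproduces cell means and fit is permutation-equivariant", {
  x <- toy_met(5, 4, 3, seed = 21)
  m <- cell_means(x)
  fit <- fit_ammi(m)
  p <- length(fit$lambda)
  expect_equal(predict_ammi(fit, p), m, tolerance = 1e-12)
  # RSS nonincreasing in k
  rss <- vapply(0:p, function(k) sum((predict_ammi(fit, k) - m)^2),
                numeric(1))
  expect_true(all(diff(rss) <= 1e-10))
  # permuting rows/columns permutes the fit, lambda unchanged
  pr <- sample(nrow(m)); pc <- sample(ncol(m))
  fit_p <- fit_ammi(m[pr, pc])
  expect_equal(fit_p$lambda, fit$lambda)
  expect_equal(abs(fit_p$gamma), abs(fit$gamma[pr, , drop = FALSE]),
               ignore_attr = TRUE)
  expect_error(predict_ammi(fit, p + 1), "integer in")
})

test_that("Gollob axis tests follow the published df and F layout", {
  expect_equal(gollob_df(12, 28, 1), 37)
  expect_equal(gollob_df(12, 28, 1:3), c(37, 35, 33))
  # zero singular value -> F 0, p 1
  mu_tab <- matrix(2, 4, 4, dimnames = list(paste0("G", 1:4),
                                            paste0("E", 1:4)))
  fit <- fit_ammi(mu_tab, r = 3, residual_ms = 0.5, residual_df = 24)
  it <- ipca_tests(fit)
  expect_equal(it$f, rep(0, 3))
  expect_equal(it$p, rep(1, 3))
  # plot-basis SS: r * lambda^2; untestable axes flagged NA
  x <- toy_met(3, 8, 3, seed = 3)
  a <- ammi(x)
  it2 <- ipca_tests(a)
  expect_equal(it2$ss, x$r * a$lambda^2)
  expect_equal(it2$df, 3 + 8 - 1 - 2 * it2$axis)
  expect_equal(it2$cum_prop[length(it2$cum_prop)], 100)
})

test_that("planted strong axes are declared significant", {
  hits <- vapply(1:20, function(s) {
    sim <- do.call(generate_met, c(met_preset("pea_like"), list(seed = s)))
    it <- ipca_tests(ammi(sim$data))
    all(it$p[1:2] < 0.05)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("signal/noise partition follows the df times MS rule", {
  x <- toy_met(4, 5, 3, seed = 6)
  an <- joint_anova(x)
  part <- ge_signal_noise(an)
  ge_row <- an[an$source == "GEN:ENV", ]
  res_row <- an[an$source == "Residual", ]
  expect_equal(part$noise, min(ge_row$df * res_row$ms, part$ss_ge))
  expect_equal(part$signal + part$noise, part$ss_ge)
  expect_true(part$signal_fraction >= 0 && part$signal_fraction <= 1)

  # pure-noise interaction: fraction near zero on average
  set.seed(10)
  fr <- replicate(30, {
    sim <- generate_met(g = 8, e = 8, r = 3, sigma2_res = 0.2,
                        sigma2_b = 0, lambda = numeric(0),
                        seed = sample.int(1e6, 1))
    ge_signal_noise(joint_anova(sim$data))$signal_fraction
  })
  expect_lt(mean(fr), 0.15)
})
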