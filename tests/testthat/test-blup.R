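test_that("variance components match hand ANOVA arithmetic on a 2x2x2", {
  x <- toy_met(2, 2, 2, seed = 19)
  bf <- brute_force_ss(x$data)
  ms_res <- bf$res / (2 * 1 * 1)
  ms_ge <- bf$ge / 1
  ms_g <- bf$gen / 1
  vc <- variance_components(x)
  expect_equal(vc$sigma2_res, ms_res)
  expect_equal(vc$sigma2_ge, max(0, (ms_ge - ms_res) / 2))
  expect_equal(vc$sigma2_g, max(0, (ms_g - ms_ge) / 4))
})

test_that("moment estimators agree with REML on balanced interior data", {
  skip_if_not_installed("lme4")
  sim <- generate_met(g = 8, e = 6, r = 3, sigma2_g = 0.25,
                      sigma2_ge = 0.1, sigma2_res = 0.3, sigma2_b = 0,
                      seed = 5)
  vc <- variance_components(sim$data)
  # oracle precondition: estimates away from the truncation boundary
  expect_true(vc$sigma2_g > 0 && vc$sigma2_ge > 0)
  d <- sim$data$data
  # blocks enter as fixed nuisance terms, matching the ANOVA layout
  fit <- lme4::lmer(YIELD ~ ENV + ENV:REP + (1 | GEN) + (1 | GEN:ENV),
                    data = d, REML = TRUE)
  vv <- as.data.frame(lme4::VarCorr(fit))
  reml <- setNames(vv$vcov, vv$grp)
  expect_equal(vc$sigma2_g, unname(reml["GEN"]), tolerance = 1e-4)
  expect_equal(vc$sigma2_ge, unname(reml["GEN:ENV"]), tolerance = 1e-4)
  expect_equal(vc$sigma2_res, unname(reml["Residual"]), tolerance = 1e-4)
})

test_that("genotype BLUPs equal the mixed-model-equations solution", {
  sim <- generate_met(g = 6, e = 5, r = 3, sigma2_g = 0.25,
                      sigma2_ge = 0.1, sigma2_res = 0.3, sigma2_b = 0,
                      seed = 23)
  x <- sim$data
  vc <- variance_components(x)
  expect_true(vc$sigma2_g > 0 && vc$sigma2_ge > 0)
  gb <- genotype_blups(x, vc)
  u <- mme_genotype_effects(x$data, vc$sigma2_g, vc$sigma2_ge,
                            vc$sigma2_res)
  expect_equal(setNames(gb$effect, gb$GEN)[names(u)], u,
               tolerance = 1e-8)
})

test_that("BLUP shrinks toward the grand mean, never past the raw mean", {
  x <- generate_met(g = 6, e = 4, r = 3, sigma2_g = 0.3, sigma2_ge = 0.05,
                    sigma2_res = 0.2, seed = 3)$data
  vc <- variance_components(x)
  gb <- genotype_blups(x, vc)
  mu <- attr(gb, "mu")
  expect_true(all(abs(gb$blup - mu) <= abs(gb$raw_mean - mu) + 1e-12))
  expect_equal(sum(gb$effect), 0, tolerance = 1e-10)
  # balanced data: BLUP ranking equals raw-mean ranking
  expect_equal(order(-gb$raw_mean), order(-gb$blup))
  # degenerate weights
  w <- attr(gb, "w")
  expect_true(w >= 0 && w <= 1)
})

test_that("shrinkage limits behave as the variance components dictate", {
  x <- toy_met(4, 3, 2, seed = 8)
  vc0 <- structure(list(sigma2_g = 0.5, sigma2_ge = 0.2, sigma2_res = 0,
                        method = "manual"), class = "met_vc")
  # no noise, no interaction shrinkage of means: w = 1 needs sigma2_ge = 0
  vc1 <- structure(list(sigma2_g = 0.5, sigma2_ge = 0, sigma2_res = 0,
                        method = "manual"), class = "met_vc")
  gb1 <- genotype_blups(x, vc1)
  expect_equal(gb1$blup, gb1$raw_mean)
  vcg0 <- structure(list(sigma2_g = 0, sigma2_ge = 0.2, sigma2_res = 0.3,
                         method = "manual"), class = "met_vc")
  gb0 <- genotype_blups(x, vcg0)
  expect_equal(gb0$blup, rep(mean(x$data$YIELD), x$g))

  # GE matrix: s = 1 at zero residual; zero matrix at sigma2_ge = 0
  bm1 <- blup_ge_matrix(x, vc0)
  m <- cell_means(x)
  z <- sweep(sweep(m, 1, rowMeans(m)), 2, colMeans(m)) + mean(m)
  expect_equal(unclass(bm1), z, ignore_attr = TRUE)
  bm0 <- blup_ge_matrix(x, vc1)
  expect_true(all(bm0 == 0))
})

test_that("the BLUP GE matrix is centered and never larger than raw", {
  for (s in 1:5) {
    x <- toy_met(5, 4, 3, seed = s)
    vc <- variance_components(x)
    bm <- blup_ge_matrix(x, vc)
    expect_equal(rowSums(bm), rep(0, x$g), tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_equal(colSums(bm), rep(0, x$e), tolerance = 1e-10,
                 ignore_attr = TRUE)
    m <- cell_means(x)
    z <- sweep(sweep(m, 1, rowMeans(m)), 2, colMeans(m)) + mean(m)
    expect_lte(sqrt(sum(bm^2)), sqrt(sum(z^2)) + 1e-12)
  }
})

test_that("variance recovery improves with trial size", {
  # correlation of predicted vs true genotype effects grows with g*e*r
  cors <- vapply(c(4, 12), function(e) {
    set.seed(100 + e)
    mean(replicate(15, {
      sim <- generate_met(g = 8, e = e, r = 3, sigma2_g = 0.2,
                          sigma2_ge = 0.1, sigma2_res = 0.3,
                          seed = sample.int(1e6, 1))
      gb <- genotype_blups(sim$data)
      cor(setNames(gb$blup, gb$GEN)[names(sim$truth$alpha)],
          sim$truth$alpha)
    }))
  }, numeric(1))
  expect_gt(cors[2], cors[1])
})
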