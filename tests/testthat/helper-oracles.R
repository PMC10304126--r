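# Independent oracles used across the suite: everything here is computed
# from definitions (sums over records, direct linear algebra), never by
# calling the code path under test.

# Brute-force sum-of-squares partition of a balanced RCBD MET, straight
# from the definition of each source as a sum of squared deviations.
brute_force_ss <- function(df) {
  y <- df$YIELD
  gm <- mean(y)
  mean_by <- function(...) tapply(y, list(...), mean)
  g <- length(unique(df$GEN))
  e <- length(unique(df$ENV))
  r <- nrow(df) / (g * e)
  m_g <- mean_by(df$GEN)
  m_e <- mean_by(df$ENV)
  m_ge <- mean_by(df$GEN, df$ENV)
  m_er <- mean_by(df$ENV, df$REP)
  ss_env <- g * r * sum((m_e - gm)^2)
  ss_gen <- e * r * sum((m_g - gm)^2)
  ss_rep <- g * sum((sweep(m_er, 1L, rowMeans(m_er)))^2)
  z <- sweep(sweep(m_ge, 1L, m_g), 2L, m_e) + gm
  ss_ge <- r * sum(z^2)
  ss_tot <- sum((y - gm)^2)
  list(env = ss_env, rep_env = ss_rep, gen = ss_gen, ge = ss_ge,
       res = ss_tot - ss_env - ss_rep - ss_gen - ss_ge, total = ss_tot)
}

# Henderson mixed-model-equations solution for the balanced two-way model
# with environments fixed and genotype / genotype-by-environment random.
# Returns the BLUP genotype effects by direct matrix inversion.
mme_genotype_effects <- function(df, sigma2_g, sigma2_ge, sigma2_res) {
  df$GEN <- factor(df$GEN); df$ENV <- factor(df$ENV)
  X <- stats::model.matrix(~ENV, df)
  Zg <- stats::model.matrix(~GEN - 1, df)
  Zge <- stats::model.matrix(~GEN:ENV - 1, df)
  Z <- cbind(Zg, Zge)
  D <- diag(c(rep(sigma2_res / sigma2_g, ncol(Zg)),
              rep(sigma2_res / sigma2_ge, ncol(Zge))))
  C <- rbind(cbind(crossprod(X), crossprod(X, Z)),
             cbind(crossprod(Z, X), crossprod(Z) + D))
  rhs <- c(crossprod(X, df$YIELD), crossprod(Z, df$YIELD))
  sol <- solve(C, rhs)
  u <- sol[(ncol(X) + 1):(ncol(X) + ncol(Zg))]
  names(u) <- levels(df$GEN)
  u
}

# Tiny deterministic balanced fixture with arbitrary (non-round) yields.
toy_met <- function(g = 2, e = 2, r = 2, seed = 42) {
  set.seed(seed)
  grid <- expand.grid(GEN = paste0("G", seq_len(g)),
                      ENV = paste0("E", seq_len(e)),
                      REP = as.character(seq_len(r)),
                      stringsAsFactors = FALSE)
  grid$YIELD <- round(stats::runif(nrow(grid), 1, 5), 3)
  met_data(grid)
}

table1_path <- function() {
  system.file("extdata", "pea_class_env_means.csv", package = "metstab")
}

read_table1 <- function() {
  utils::read.csv(table1_path(), check.names = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
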