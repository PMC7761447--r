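make_Z <- function(n, k, seed = 1) {
  set.seed(seed)
  scale(matrix(sample(c(-10, 0, 10), n * k, replace = TRUE), n, k,
               dimnames = list(seq_len(n), paste0("S", seq_len(k)))),
        center = TRUE, scale = FALSE)[, , drop = FALSE]
}

test_that("BayesC with pi = 0 reproduces the weighted ridge solution", {
  n <- 120; k <- 60
  Z <- make_Z(n, k, seed = 31)
  set.seed(32)
  u <- rnorm(k, 0, 0.03)
  w <- runif(n, 0.5, 3)
  y <- drop(Z %*% u) + rnorm(n, 0, 1 / sqrt(w))
  fit <- bayes_fit(Z, y, w, method = "BayesC",
                   config = mcmc_config(n_iter = 6000, burnin = 1000,
                                        thin = 2, pi = 0, seed = 4))
  lam <- mean(fit$sigma2e_samples) / mean(fit$sigma2u_samples)
  Zc <- cbind(1, Z)
  CC <- t(Zc) %*% (w * Zc) + diag(c(0, rep(lam, k)))
  ridge <- solve(CC, t(Zc) %*% (w * y))[-1]
  expect_gt(stats::cor(ridge, fit$post_mean_effect), 0.999)
  ## 2 MC SE scale: posterior sd of an effect / sqrt(ESS) is ~1e-3 here
  expect_lt(max(abs(ridge - fit$post_mean_effect)), 2e-3)
})

test_that("a single locus matches the conjugate closed-form mean", {
  n <- 60
  Z <- make_Z(n, 1, seed = 33)
  set.seed(34)
  y <- drop(Z * 0.05) + rnorm(n, 0, 0.4)
  fit <- bayes_fit(Z, y, method = "BayesC",
                   config = mcmc_config(n_iter = 30000, burnin = 3000,
                                        thin = 1, pi = 0, seed = 5))
  lam <- mean(fit$sigma2e_samples) / mean(fit$sigma2u_samples)
  closed <- sum(Z * (y - mean(y))) / (sum(Z^2) + lam)
  expect_equal(unname(fit$post_mean_effect), closed, tolerance = 0.02)
})

test_that("the prior-dominated null keeps the inclusion rate at 1 - pi", {
  k <- 800; n <- 250
  Z <- make_Z(n, k, seed = 35)
  set.seed(36)
  y <- rnorm(n)
  for (m in c("BayesB", "BayesC")) {
    fit <- bayes_fit(Z, y, method = m,
                     config = mcmc_config(n_iter = 2500, burnin = 500,
                                          thin = 2, pi = 0.99, seed = 6,
                                          target_genvar = 1e-6))
    inc <- fit$n_included_samples
    mcse <- stats::sd(inc) / sqrt(length(inc) / 10)   # ~lag-adjusted
    expect_lt(abs(mean(inc) - k * 0.01), 3 * max(mcse, 0.2))
    expect_equal(mean(fit$model_freq), mean(inc) / k, tolerance = 1e-10)
  }
})

test_that("chains are deterministic given the seed and pass a stationarity screen", {
  Z <- make_Z(100, 50, seed = 37)
  set.seed(38)
  y <- drop(Z %*% rnorm(50, 0, 0.02)) + rnorm(100, 0, 0.5)
  cfg <- mcmc_config(n_iter = 1500, burnin = 300, thin = 2, pi = 0.9, seed = 7)
  f1 <- bayes_fit(Z, y, method = "BayesB", config = cfg, store_samples = TRUE)
  f2 <- bayes_fit(Z, y, method = "BayesB", config = cfg, store_samples = TRUE)
  expect_identical(f1$effect_samples, f2$effect_samples)
  expect_identical(f1$sigma2e_samples, f2$sigma2e_samples)
  expect_equal(f1$n_saved, (1500 - 300) %/% 2)
  expect_lt(abs(geweke_z(f1$sigma2e_samples)), 3)
})

test_that("duplicating a record is posterior-equivalent to doubling its weight", {
  n <- 80; k <- 40
  Z <- make_Z(n, k, seed = 39)
  set.seed(40)
  y <- drop(Z %*% rnorm(k, 0, 0.03)) + rnorm(n, 0, 0.5)
  w <- rep(1, n)
  cfg <- mcmc_config(n_iter = 12000, burnin = 2000, thin = 2, pi = 0, seed = 8)
  dup <- bayes_fit(rbind(Z, Z[1:10, ]), c(y, y[1:10]), c(w, w[1:10]),
                   method = "BayesC", config = cfg)
  dbl <- bayes_fit(Z, y, replace(w, 1:10, 2), method = "BayesC", config = cfg)
  expect_gt(stats::cor(dup$post_mean_effect, dbl$post_mean_effect), 0.995)
  expect_lt(mean(abs(dup$post_mean_effect - dbl$post_mean_effect)), 2e-3)
})

test_that("QTL markers acquire far higher model frequency than null markers", {
  set.seed(41)
  n <- 400; k <- 400; nq <- 10
  Z <- make_Z(n, k, seed = 41)
  qtl <- sample(k, nq)
  u <- numeric(k); u[qtl] <- rnorm(nq, 0, 1)
  g <- drop(Z %*% u); g <- g / stats::sd(g) * sqrt(0.3)
  y <- g + rnorm(n, 0, sqrt(0.7))
  fit <- bayes_fit(Z, y, method = "BayesB",
                   config = mcmc_config(n_iter = 3000, burnin = 500, thin = 2,
                                        pi = 0.99, seed = 9))
  expect_gt(mean(fit$model_freq[qtl]) / mean(fit$model_freq[-qtl]), 10)
})

test_that("DGVs sum coded genotypes times posterior-mean effects", {
  fit <- structure(list(k = 2L, snp = c("a", "b"),
                        post_mean_effect = c(a = 0.01, b = -0.02)),
                   class = "bayes_fit")
  Z <- matrix(c(-10, 10, 0, 10), 2, 2, dimnames = list(1:2, c("a", "b")))
  expect_equal(dgv(fit, Z), c(`1` = -0.1, `2` = -0.1))
  ## uncentred heterozygote code 0 contributes nothing
  expect_equal(unname(dgv(fit, matrix(c(0, 0), 1, 2,
                                      dimnames = list(1, c("a", "b"))))), 0)
  expect_error(dgv(fit, Z[, 1, drop = FALSE]), "match")
})

test_that("responses and inputs are validated", {
  Z <- make_Z(10, 5)
  expect_error(bayes_fit(Z, rep(NA_real_, 10)), "non-finite")
  expect_error(bayes_fit(Z, 1:9), "nrow")
  expect_error(mcmc_config(n_iter = 100, burnin = 200), "burnin")
})
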