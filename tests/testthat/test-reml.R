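test_that("design construction books fixed effects and random maps correctly", {
  d <- fix_simdata(n_founders = 10, gens = 2, litter = 3, seed = 1)
  des1 <- build_design(ibw_kg ~ factor(sex) + litter_size, d$phen, d$ped,
                       eq_model(1))
  expect_equal(des1$p, 3L)                      # intercept + sex contrast + covariate
  expect_null(des1$litter)

  des4 <- build_design(ibw_kg ~ factor(sex) + litter_size, d$phen, d$ped,
                       eq_model(4))
  expect_false(is.null(des4$litter))

  ## two litters of sizes 3 and 2: litter incidence sums to the sizes
  ped <- as_pedigree(data.frame(id = 1:9, sire = c(0, 0, 0, rep(1, 6)),
                                dam = c(0, 0, 0, rep(2, 3), rep(3, 3))))
  phen <- data.frame(id = 4:8, ibw_kg = rnorm(5), x = 1,
                     litter = c("L1", "L1", "L1", "L2", "L2"))
  des <- build_design(ibw_kg ~ x, phen, ped, eq_model(3))
  expect_equal(sort(as.integer(table(des$litter)), decreasing = TRUE), c(3L, 2L))
})

test_that("REML log-likelihood matches the dense matrix formula on a small fixture", {
  d <- fix_simdata(n_founders = 8, gens = 2, litter = 3, seed = 3,
                   var_direct = 0.3, var_maternal = 0.2, var_litter = 0.25,
                   var_residual = 0.4)
  phen <- d$phen[seq_len(min(50, nrow(d$phen))), ]
  A <- build_A(d$ped)
  form <- ibw_kg ~ litter_size
  for (m in c(1L, 4L)) {
    fit <- reml_animal(form, phen, d$ped, spec = eq_model(m), se = FALSE,
                       blup = FALSE)
    des <- build_design(form, phen, d$ped, eq_model(m))
    expect_equal(dense_neg2_reml(fit$varcomp, des, A), -2 * fit$logLik,
                 tolerance = 1e-4 / abs(2 * fit$logLik))
    ## the dense likelihood cannot be improved from the converged point
    opt <- stats::optim(unname(fit$varcomp),
                        function(th) dense_neg2_reml(
                          stats::setNames(th, names(fit$varcomp)), des, A),
                        method = "L-BFGS-B", lower = 1e-6)
    ## small slack: both optimizers stop on relative-change criteria
    expect_lt((-2 * fit$logLik) - opt$value, 5e-3)
  }
})

test_that("pure-noise data yield near-zero heritability", {
  hits <- 0L
  for (s in 1:20) {
    cfg <- sim_config(n_founders = 150, n_generations = 3,
                      litter_size_mean = 8, n_dams_per_gen = c(50, 75),
                      seed = 200 + s, panel = NULL, var_direct = 0,
                      var_maternal = 0, var_litter = 0, var_residual = 0.05)
    ped <- simulate_pedigree(cfg)
    ph <- simulate_phenotypes(ped, NULL, cfg)
    ## the full fixed model: parity and contemporary group are litter-level
    ## factors, and leaving them out would masquerade as heritability
    fit <- reml_animal(ibw_kg ~ factor(sex) + factor(parity) + factor(cg) +
                         litter_size, ph, ped,
                       spec = eq_model(1), se = FALSE, blup = FALSE)
    if (fit$h2 < 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 18L)
})

test_that("the model ladder has non-decreasing log-likelihood and a clean MME", {
  d <- fix_simdata(n_founders = 40, gens = 3, litter = 5, seed = 5,
                   var_direct = 0.3, var_maternal = 0.2, var_litter = 0.25,
                   var_residual = 0.4)
  form <- ibw_kg ~ factor(sex) + litter_size
  fits <- lapply(1:4, function(m)
    reml_animal(form, d$phen, d$ped, spec = eq_model(m), se = FALSE,
                blup = (m == 4)))
  ll <- vapply(fits, function(f) f$logLik, numeric(1))
  expect_true(all(diff(c(ll[1], ll[4])) >= -1e-4))
  expect_true(all(ll[2:3] >= ll[1] - 1e-4))
  expect_true(all(ll[4] >= ll[2:3] - 1e-4))

  mme <- fits[[4]]$mme
  expect_lt(max(abs(mme$C %*% mme$sol - mme$rhs)), 1e-8)

  tab <- varcomp_table(fits)
  expect_equal(nrow(tab), 4L)
  expect_true(all(tab$delta_logl[1:3] >= -1e-6))
})

test_that("reliabilities match the dense MME-inverse oracle and are clipped", {
  d <- fix_simdata(n_founders = 10, gens = 2, litter = 3, seed = 7,
                   var_direct = 0.4, var_maternal = 0, var_litter = 0,
                   var_residual = 0.6)
  phen <- d$phen[seq_len(min(30, nrow(d$phen))), ]
  form <- ibw_kg ~ litter_size
  fit <- reml_animal(form, phen, d$ped, spec = eq_model(1), se = FALSE)
  ids <- phen$id[1:10]
  rel <- reliability(fit, ids)
  A <- build_A(d$ped)
  des <- fit$design
  n <- des$n
  Za <- matrix(0, n, nrow(A)); Za[cbind(seq_len(n), des$animal)] <- 1
  X <- des$X
  ga <- fit$gamma[["direct"]]
  Cm <- rbind(cbind(t(X) %*% X, t(X) %*% Za),
              cbind(t(Za) %*% X, t(Za) %*% Za + solve(A) / ga))
  pev <- fit$varcomp[["residual"]] *
    diag(solve(Cm))[ncol(X) + match(ids, d$ped$id)]
  expect_equal(rel$pev, unname(pev), tolerance = 1e-8)
  expect_equal(rel$r2,
               pmin(pmax(1 - rel$pev / ((1 + rel$F) * fit$varcomp[["direct"]]),
                         0), 1 - 1e-12))
  expect_true(all(rel$r2 >= 0 & rel$r2 < 1))
})

test_that("likelihood-ratio bookkeeping returns both dLogL and chi-square", {
  cmp <- lrt(2156.38, 5835.22, df = 2)
  expect_equal(cmp$delta_logl, 3678.84)
  expect_equal(cmp$chisq, 2 * 3678.84)
  expect_lt(cmp$p_value, 1e-10)

  cmp2 <- lrt(5581.12, 5835.22, df = 1)
  expect_equal(cmp2$delta_logl, 254.10)

  same <- lrt(100, 100, df = 1)
  expect_equal(same$delta_logl, 0)
  expect_equal(same$p_value, 1)

  expect_error(lrt(100, 90, df = 1), "lower log-likelihood")
  expect_error(lrt(100, 101), "df")
})

test_that("heritability is the direct share of the component sum", {
  expect_equal(heritability(c(direct = 0.036, residual = 0.036))$h2, 0.50)
  expect_equal(heritability(c(direct = 0.022, litter = 0.020,
                              residual = 0.027))$h2, 0.32, tolerance = 0.005)
  expect_equal(heritability(c(direct = 0, residual = 1))$h2, 0)
  expect_error(heritability(c(direct = 0, residual = 0)), "zero")
})

test_that("fit methods expose coefficients, logLik, ranefs and residuals", {
  d <- fix_simdata(n_founders = 16, gens = 2, litter = 3, seed = 9)
  fit <- reml_animal(ibw_kg ~ factor(sex) + litter_size, d$phen, d$ped,
                     spec = eq_model(4))
  expect_named(coef(fit))
  expect_s3_class(logLik(fit), "logLik")
  expect_length(ranef(fit), nrow(d$ped))
  expect_length(ranef(fit, "maternal"), nrow(d$ped))
  expect_equal(length(residuals(fit)), nrow(d$phen))
  expect_output(print(fit), "REML animal model")
  expect_output(print(summary(fit)), "sigma2_p")
  ## EBV correlates positively with the simulated breeding values
  tr <- attr(d$phen, "truth")
  expect_gt(stats::cor(fit$ebv, tr$u_a), 0.3)
})
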