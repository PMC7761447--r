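test_that("parent averages combine parental EBVs and reliabilities", {
  ped <- as_pedigree(data.frame(id = 1:4, sire = c(0, 0, 1, 1),
                                dam = c(0, 0, 2, 0)))
  ebv <- c(`1` = 0.2, `2` = -0.1, `3` = 0, `4` = 0)
  r2 <- c(`1` = 0.6, `2` = 0.4, `3` = 0.1, `4` = 0.1)
  pa <- parent_average(ebv, r2, ped, ids = c(3, 4, 1))
  expect_equal(pa$pa, c(0.05, 0.1, 0))
  expect_equal(pa$r2_pa, c(0.25, 0.15, 0))

  ## sire known (0.3, 0.5), dam unknown
  ebv2 <- c(`1` = 0.3, `2` = 0, `3` = 0, `4` = 0)
  r22 <- c(`1` = 0.5, `2` = 0, `3` = 0, `4` = 0)
  pa2 <- parent_average(ebv2, r22, ped, ids = 4)
  expect_equal(pa2$pa, 0.15)
  expect_equal(pa2$r2_pa, 0.125)
})

test_that("deregression matches an independent 2x2 mixed-model oracle", {
  ## oracle: find information contents (zz_pa, zz_i) such that the 2x2 MME
  ## for (g_PA, g_i) with prior precision lambda*[[4,-2],[-2,2]] reproduces
  ## the stated reliabilities (the individual's on the sigma2_a scale, the
  ## parent average's on its own Var(g_PA) = sigma2_a/2 scale), then
  ## deregress from first principles
  oracle <- function(ebv, r2, pa, r2_pa, h2) {
    lambda <- (1 - h2) / h2
    rel_err <- function(zz) {
      C <- matrix(c(zz[1] + 4 * lambda, -2 * lambda,
                    -2 * lambda, zz[2] + 2 * lambda), 2, 2)
      Ci <- solve(C)
      c(r2_pa - (1 - 2 * lambda * Ci[1, 1]) / 2,
        r2 - (1 - lambda * Ci[2, 2]))
    }
    zz <- stats::optim(c(1, 1), function(z) sum(rel_err(z)^2),
                       method = "L-BFGS-B", lower = 1e-8,
                       control = list(factr = 1e3))$par
    C <- matrix(c(zz[1] + 4 * lambda, -2 * lambda,
                  -2 * lambda, zz[2] + 2 * lambda), 2, 2)
    rhs <- C %*% c(pa, ebv)
    list(zz_i = zz[2], debv_exc_pa = rhs[2] / zz[2],
         r2_debv = 1 - lambda / (zz[2] + lambda))
  }
  case <- list(ebv = 0.10, r2 = 0.40, pa = 0.04, r2_pa = 0.20, h2 = 0.13)
  orc <- oracle(case$ebv, case$r2, case$pa, case$r2_pa, case$h2)
  imp <- ibwgp:::deregress_one(case$ebv, case$r2, case$pa, case$r2_pa,
                               (1 - case$h2) / case$h2)
  expect_equal(imp$zz_i, orc$zz_i, tolerance = 1e-5)
  expect_equal(imp$debv_exc_pa, orc$debv_exc_pa, tolerance = 1e-5)
  expect_equal(imp$r2_debv, orc$r2_debv, tolerance = 1e-5)
})

test_that("re-shrinking the deregressed value recovers the EBV exactly", {
  h2 <- 0.13; lambda <- (1 - h2) / h2
  set.seed(21)
  for (k in 1:25) {
    r2_pa <- runif(1, 0, 0.45)
    r2 <- runif(1, r2_pa + 0.02, 0.9)
    pa <- rnorm(1, 0, 0.05); ebv <- rnorm(1, pa, 0.1)
    dr <- ibwgp:::deregress_one(ebv, r2, pa, r2_pa, lambda)
    C <- matrix(c(dr$zz_pa + 4 * lambda, -2 * lambda,
                  -2 * lambda, dr$zz_i + 2 * lambda), 2, 2)
    rhs_pa <- (dr$zz_pa + 4 * lambda) * pa - 2 * lambda * ebv
    sol <- solve(C, c(rhs_pa, dr$zz_i * dr$debv_exc_pa))
    expect_lt(abs(sol[2] - ebv), 1e-10)
    expect_lt(abs(sol[1] - pa), 1e-10)
    ## deregression cannot add information whenever the implied
    ## parent-average information content is nonnegative; with r2 far above
    ## r2_PA the 2x2 system implies zz_PA < 0 and the inequality flips
    if (dr$zz_pa >= 0) expect_lte(dr$r2_debv, r2 + 1e-12)
  }
})

test_that("the two response variables differ by the parent average exactly", {
  d <- fix_simdata(n_founders = 24, gens = 3, litter = 4, seed = 11)
  fit <- reml_animal(ibw_kg ~ factor(sex) + litter_size, d$phen, d$ped,
                     spec = eq_model(4))
  rel <- reliability(fit, ids = d$phen$id)
  deb <- deregress_ebv(stats::setNames(rel$ebv, rel$id),
                       stats::setNames(rel$r2, rel$id),
                       d$ped, h2 = fit$h2)
  ok <- deb[deb$ok, ]
  expect_gt(nrow(ok), 10)
  expect_equal(ok$debv_inc_pa - ok$debv_exc_pa, ok$pa)
  lam <- (1 - attr(deb, "h2")) / attr(deb, "h2")
  zz_pa <- vapply(seq_len(nrow(ok)), function(i)
    ibwgp:::deregress_one(ok$ebv[i], ok$r2[i], ok$pa[i], ok$r2_pa[i],
                          lam)$zz_pa, numeric(1))
  expect_true(all(ok$r2_debv[zz_pa >= 0] <= ok$r2[zz_pa >= 0] + 1e-12))
  expect_true(all(ok$w > 0))

  ## no ancestral information: both responses equal the de-shrunk record
  founders_ped <- as_pedigree(data.frame(id = 1:2, sire = 0, dam = 0))
  deb0 <- deregress_ebv(c(`1` = 0.2, `2` = -0.1), c(`1` = 0.3, `2` = 0.4),
                        founders_ped, h2 = 0.13)
  expect_equal(deb0$pa, c(0, 0))
  expect_equal(deb0$debv_inc_pa, deb0$debv_exc_pa)
})

test_that("weighting factor follows the stated closed form", {
  expect_equal(weighting_factor(0.5, 0.13, 0.5), 0.87 / (1.5 * 0.13),
               tolerance = 1e-12)
  grid <- seq(0.05, 0.95, by = 0.05)
  w <- weighting_factor(grid, 0.13, 0.5)
  expect_true(all(diff(w) > 0))
  expect_lt(weighting_factor(0.5, 0.999, 0.5), 1e-2)
  expect_error(weighting_factor(1, 0.5, 0), "infinite")
})

test_that("reliability filter is strict and reports its removals", {
  rec <- data.frame(id = 1:4, r2_debv = c(0.005, 0.01, 0.5, 0.2),
                    ok = c(TRUE, TRUE, TRUE, FALSE))
  out <- filter_reliability(rec, 0.01)
  expect_equal(out$id, c(2L, 3L))               # 0.01 retained, 0.005 dropped
  rep <- attr(out, "removal_report")
  expect_equal(rep$removed[rep$rule == "low_reliability"], 1L)
  expect_equal(rep$removed[rep$rule == "failed_deregression"], 1L)
  empty <- filter_reliability(rec[0, ], 0.01)
  expect_equal(nrow(empty), 0L)
})
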