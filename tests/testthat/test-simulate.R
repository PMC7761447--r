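test_that("founder-only configuration yields exactly the founders", {
  cfg <- sim_config(n_founders = 10, n_generations = 1, panel = NULL)
  ped <- simulate_pedigree(cfg)
  expect_equal(nrow(ped), 10L)
  expect_true(all(ped$sire == 0L & ped$dam == 0L))
  expect_error(simulate_pedigree(sim_config(n_founders = 0, panel = NULL)),
               "founders")
})

test_that("every non-founder's dam appears earlier in the table", {
  cfg <- sim_config(n_founders = 20, n_generations = 3, litter_size_mean = 8,
                    seed = 1, panel = NULL)
  ped <- simulate_pedigree(cfg)
  pos <- seq_len(nrow(ped))
  for (i in which(ped$dam != 0L))
    expect_lt(match(ped$dam[i], ped$id), i)
  for (i in which(ped$sire != 0L))
    expect_lt(match(ped$sire[i], ped$id), i)
  ## litters group full sibs of one dam and parity
  key <- paste(ped$dam, ped$generation, ped$parity)[ped$generation > 0]
  expect_true(all(tapply(ped$litter[ped$generation > 0], key,
                         function(x) length(unique(x))) == 1L))
})

test_that("simulation is deterministic given the seed", {
  cfg <- sim_config(n_founders = 16, n_generations = 3, litter_size_mean = 4,
                    seed = 5, panel = data.frame(chr = 1, length_bp = 1e7,
                                                 n_snps = 30))
  p1 <- simulate_pedigree(cfg); p2 <- simulate_pedigree(cfg)
  expect_identical(p1, p2)
  g1 <- simulate_genotypes(p1, cfg); g2 <- simulate_genotypes(p2, cfg)
  expect_identical(g1$geno, g2$geno)
  y1 <- simulate_phenotypes(p1, g1, cfg); y2 <- simulate_phenotypes(p2, g2, cfg)
  expect_identical(y1$ibw_kg, y2$ibw_kg)
})

test_that("founder genotypes are in Hardy-Weinberg at the drawn frequencies", {
  cfg <- sim_config(n_founders = 500, n_generations = 1, seed = 8,
                    panel = data.frame(chr = 1, length_bp = 2e8, n_snps = 5000))
  ped <- simulate_pedigree(cfg)
  gen <- simulate_genotypes(ped, cfg)
  p <- attr(gen, "founder_freq")
  counts <- apply(gen$geno, 2L, tabulate, nbins = 3)
  n0 <- 500 - colSums(counts)
  pvals <- vapply(seq_along(p), function(j) {
    obs <- c(n0[j], counts[1, j], counts[2, j])
    expd <- 500 * c((1 - p[j])^2, 2 * p[j] * (1 - p[j]), p[j]^2)
    suppressWarnings(stats::chisq.test(obs, p = expd / sum(expd))$p.value)
  }, numeric(1))
  ## familywise alpha = 0.001 via Bonferroni
  expect_equal(sum(pvals < 0.001 / length(pvals)), 0L)
})

test_that("gene dropping is Mendelian-consistent and drift-neutral", {
  cfg <- sim_config(n_founders = 20, n_generations = 3, litter_size_mean = 5,
                    seed = 3, panel = data.frame(chr = 1, length_bp = 1e8,
                                                 n_snps = 80))
  ped <- simulate_pedigree(cfg)
  gen <- simulate_genotypes(ped, cfg)
  g <- gen$geno
  idx <- ibwgp:::ped_index(ped)
  off <- which(idx$sire > 0L)
  ## no opposing homozygotes between parent and offspring, any SNP
  opp <- 0L
  for (i in off) {
    opp <- opp + sum(abs(g[i, ] - g[idx$sire[i], ]) == 2L) +
      sum(abs(g[i, ] - g[idx$dam[i], ]) == 2L)
  }
  expect_equal(opp, 0L)
  ## both parents homozygous 0 forces offspring 0
  for (i in off) {
    z <- g[idx$sire[i], ] == 0L & g[idx$dam[i], ] == 0L
    expect_true(all(g[i, z] == 0L))
  }

  ## founder vs final-generation allele frequency: drift only, mean change 0
  deltas <- vapply(1:50, function(s) {
    cfg2 <- sim_config(n_founders = 20, n_generations = 3,
                       litter_size_mean = 5, seed = 100 + s,
                       panel = data.frame(chr = 1, length_bp = 1e8,
                                          n_snps = 60))
    p2 <- simulate_pedigree(cfg2)
    g2 <- simulate_genotypes(p2, cfg2)
    last <- p2$generation == max(p2$generation)
    mean(colMeans(g2$geno[p2$generation == 0, ]) / 2 -
           colMeans(g2$geno[last, ]) / 2)
  }, numeric(1))
  expect_lt(abs(mean(deltas)), 5 * stats::sd(deltas) / sqrt(length(deltas)))
})

test_that("degenerate variance configuration yields a constant phenotype", {
  cfg <- sim_config(n_founders = 12, n_generations = 2, litter_size_mean = 3,
                    seed = 2, panel = NULL, var_direct = 0, var_maternal = 0,
                    var_litter = 0, var_residual = 0, covariate_slope = 0,
                    sd_fixef = 0)
  ped <- simulate_pedigree(cfg)
  ph <- simulate_phenotypes(ped, NULL, cfg)
  expect_equal(ph$ibw_kg, rep(cfg$mean_ibw, nrow(ph)))
})

test_that("phenotypic variance net of fixed effects matches the component sum", {
  cfg <- sim_config(n_founders = 500, n_generations = 3, litter_size_mean = 11,
                    litters_per_dam = 2, n_dams_per_gen = c(250, 650),
                    seed = 17, panel = NULL)
  ped <- simulate_pedigree(cfg)
  ph <- simulate_phenotypes(ped, NULL, cfg)
  expect_gt(nrow(ph), 15000)
  tr <- attr(ph, "truth")
  fixed <- tr$fixed$intercept +
    tr$fixed$sex[match(ph$sex, sort(unique(ph$sex)))] +
    tr$fixed$parity[match(ph$parity, sort(unique(ph$parity)))] +
    tr$fixed$cg[match(ph$cg, sort(unique(ph$cg)))] +
    tr$fixed$covariate_slope * (ph$litter_size - mean(ph$litter_size))
  v <- stats::var(ph$ibw_kg - fixed)
  expect_lt(abs(v - 0.066), 0.1 * 0.066)

  ## parent-offspring breeding-value covariance ~ var_direct / 2
  idx <- ibwgp:::ped_index(ped)
  off <- which(idx$dam > 0L)
  u <- tr$u_a
  expect_lt(abs(stats::cov(u[off], u[idx$dam[off]]) - 0.009 / 2), 0.0015)

  ## full-sib (same litter) phenotype covariance ~ sa2/2 + sm2 + sc2
  rec <- ph[order(ph$litter), ]
  first <- !duplicated(rec$litter)
  second <- !duplicated(rec$litter) & FALSE
  ## take the first two piglets of each litter with >= 2 records
  tab <- table(rec$litter)
  big <- names(tab)[tab >= 2]
  i1 <- match(big, as.character(rec$litter))
  i2 <- i1 + 1L
  resid <- rec$ibw_kg - fixed[order(ph$litter)]
  cv <- stats::cov(resid[i1], resid[i2])
  expect_lt(abs(cv - (0.009 / 2 + 0.010 + 0.017)), 0.006)
})

test_that("QTL-generated breeding values carry the requested variance", {
  d <- fix_simdata(n_founders = 60, gens = 2, litter = 6, seed = 4,
                   panel = data.frame(chr = 1:2, length_bp = 1e8, n_snps = 50),
                   n_qtl = 10)
  tr <- attr(d$phen, "truth")
  expect_equal(stats::var(tr$u_a) * (length(tr$u_a) - 1) / length(tr$u_a),
               d$cfg$var_direct, tolerance = 0.05)
  expect_length(attr(d$phen, "qtl"), 10L)
  expect_true(all(attr(d$phen, "qtl") %in% d$gen$map$snp))
})

test_that("simulation files round-trip through the plain-text writers", {
  d <- fix_simdata(n_founders = 12, gens = 2, litter = 3, seed = 6, n_qtl = 4,
                   panel = data.frame(chr = 1, length_bp = 1e6, n_snps = 8))
  dir <- tempfile()
  write_simulation(d$ped, d$phen, d$gen, dir)
  ped2 <- read_pedigree_csv(file.path(dir, "pedigree.csv"))
  expect_equal(ped2$id, d$ped$id)
  expect_equal(ped2$sire, d$ped$sire)
  g2 <- read_plink(file.path(dir, "genotypes"))
  expect_equal(unname(g2$geno), unname(d$gen$geno))
  unlink(dir, recursive = TRUE)
})
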