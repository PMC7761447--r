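## Synthetic-data generator: multi-generation pig pedigrees with litters,
## gene-dropped SNP panels, and birth-weight phenotypes with direct, maternal,
## common-litter and residual variance components.

#' Simulation configuration
#'
#' Defaults mirror the variance structure of the birth-weight evaluation the
#' package implements: direct additive 0.009, maternal genetic 0.010, common
#' litter 0.017 and residual 0.030 kg^2 (phenotypic 0.066 kg^2, direct
#' heritability 0.14), an overall mean of 1.372 kg, and a litter-size
#' covariate slope of -0.012 kg per piglet. Litter sizes are
#' \code{max(1, Poisson(litter_size_mean))} with a default mean of 11
#' piglets. Contemporary groups are generation x season blocks (4 seasons).
#'
#' @param n_founders number of founder animals (half sires, half dams).
#' @param n_generations total generations including founders (1 = founders only).
#' @param litter_size_mean mean litter size (piglets).
#' @param litters_per_dam litters (parities) per selected dam per generation.
#' @param n_dams_per_gen vector (recycled) of dams mated each generation;
#'   \code{NULL} = all available females.
#' @param panel data frame with columns \code{chr}, \code{length_bp},
#'   \code{n_snps} describing the SNP map, or \code{NULL} for no genotypes.
#' @param n_qtl number of panel SNPs used as QTL when genotypes generate the
#'   direct additive effect.
#' @param var_direct,var_maternal,var_litter,var_residual variance components (kg^2).
#' @param mean_ibw overall mean birth weight (kg).
#' @param covariate_slope fixed regression on litter size (kg per piglet).
#' @param sd_fixef standard deviation of the drawn fixed-effect level values (kg).
#' @param seed master seed; every sub-generator draws from a named stream of it.
#' @return list of class \code{sim_config}.
#' @export
sim_config <- function(n_founders = 100, n_generations = 3,
                       litter_size_mean = 11, litters_per_dam = 2,
                       n_dams_per_gen = NULL,
                       panel = default_panel(), n_qtl = 10,
                       var_direct = 0.009, var_maternal = 0.010,
                       var_litter = 0.017, var_residual = 0.030,
                       mean_ibw = 1.372, covariate_slope = -0.012,
                       sd_fixef = 0.05, seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(n_founders >= 0, n_generations >= 1, litter_size_mean > 0,
            litters_per_dam >= 1,
            var_direct >= 0, var_maternal >= 0, var_litter >= 0,
            var_residual >= 0)
  if (!is.null(panel)) {
    stopifnot(all(c("chr", "length_bp", "n_snps") %in% names(panel)))
    if (n_qtl > sum(panel$n_snps)) stop_ibwgp("n_qtl exceeds total SNPs in panel")
  }
  class(cfg) <- "sim_config"
  cfg
}

#' @rdname sim_config
#' @export
default_panel <- function() {
  data.frame(chr = 1:5, length_bp = 150e6, n_snps = 200)
}

#' Simulate a multi-generation litter-structured pedigree
#'
#' Founders form generation 0 with unknown parents. Each later generation
#' mates dams from the previous generation (each to a random sire of that
#' generation) for \code{litters_per_dam} consecutive parities; litter ids
#' group full sibs born to one dam in one parity, and contemporary groups are
#' generation x season blocks.
#'
#' @param config a [sim_config()].
#' @return a [as_pedigree()] table with columns id, sire, dam, sex (1=M, 2=F),
#'   parity (of the dam at the animal's birth; 0 for founders), cg, litter,
#'   generation.
#' @export
simulate_pedigree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_founders < 1L) stop_ibwgp("invalid config: zero founders")
  with_stream(config$seed, "pedigree", {
    nf <- config$n_founders
    id <- seq_len(nf)
    sire <- dam <- rep(0L, nf)
    sex <- rep_len(c(1L, 2L), nf)
    parity <- rep(0L, nf); gen <- rep(0L, nf)
    litter <- rep(NA_integer_, nf); cg <- rep("0_0", nf)
    next_litter <- 1L
    if (config$n_generations > 1L) {
      for (g in seq_len(config$n_generations - 1L)) {
        prev <- which(gen == g - 1L)
        sires <- id[prev][sex[prev] == 1L]
        dams <- id[prev][sex[prev] == 2L]
        if (length(sires) == 0L || length(dams) == 0L)
          stop_ibwgp("generation %d has no available sires or dams", g)
        ndam <- length(dams)
        if (!is.null(config$n_dams_per_gen))
          ndam <- min(ndam, rep_len(config$n_dams_per_gen, g)[g])
        dsel <- if (ndam < length(dams)) sample(dams, ndam) else dams
        for (p in seq_len(config$litters_per_dam)) {
          season <- sample.int(4L, length(dsel), replace = TRUE)
          mates <- sample(sires, length(dsel), replace = TRUE)
          sizes <- pmax(1L, stats::rpois(length(dsel), config$litter_size_mean))
          tot <- sum(sizes)
          id <- c(id, max(id) + seq_len(tot))
          sire <- c(sire, rep.int(mates, sizes))
          dam <- c(dam, rep.int(dsel, sizes))
          sex <- c(sex, sample(1:2, tot, replace = TRUE))
          parity <- c(parity, rep.int(rep(p, length(dsel)), sizes))
          gen <- c(gen, rep(g, tot))
          litter <- c(litter, rep.int(next_litter - 1L + seq_along(dsel), sizes))
          cg <- c(cg, rep.int(paste0(g, "_", season), sizes))
          next_litter <- next_litter + length(dsel)
        }
      }
    }
    as_pedigree(data.frame(id = id, sire = sire, dam = dam, sex = sex,
                           parity = parity, cg = cg, litter = litter,
                           generation = gen, stringsAsFactors = FALSE))
  })
}

#' Gene-drop SNP genotypes down a pedigree
#'
#' Founder alleles are drawn from per-SNP allele frequencies
#' ~ Uniform(0.05, 0.95); descendants receive one uniformly chosen allele from
#' each known parent (an unknown parent contributes a population allele).
#' Dosages count the "2" allele: 0/1/2.
#'
#' @param pedigree a [simulate_pedigree()] result (or any ordered pedigree).
#' @param config a [sim_config()] with a non-NULL panel.
#' @return a [genotype_panel()] in raw 0/1/2 coding with the founder allele
#'   frequencies attached as attribute \code{founder_freq}.
#' @export
simulate_genotypes <- function(pedigree, config) {
  stopifnot(inherits(config, "sim_config"), !is.null(config$panel))
  pedigree <- as_pedigree(pedigree)
  with_stream(config$seed, "genotypes", {
    map <- do.call(rbind, lapply(seq_len(nrow(config$panel)), function(r) {
      p <- config$panel[r, ]
      data.frame(snp = sprintf("SNP%d_%d", p$chr, seq_len(p$n_snps)),
                 chr = p$chr,
                 pos = sort(sample.int(p$length_bp, p$n_snps)),
                 stringsAsFactors = FALSE)
    }))
    map <- map[order(map$chr, map$pos), , drop = FALSE]
    m <- nrow(map); n <- nrow(pedigree)
    freq <- stats::runif(m, 0.05, 0.95)
    idx <- ped_index(pedigree)
    h1 <- matrix(0L, n, m); h2 <- matrix(0L, n, m)
    for (i in seq_len(n)) {
      s <- idx$sire[i]; d <- idx$dam[i]
      h1[i, ] <- if (s > 0L) {
        pick <- stats::runif(m) < 0.5
        ifelse(pick, h1[s, ], h2[s, ])
      } else as.integer(stats::runif(m) < freq)
      h2[i, ] <- if (d > 0L) {
        pick <- stats::runif(m) < 0.5
        ifelse(pick, h1[d, ], h2[d, ])
      } else as.integer(stats::runif(m) < freq)
    }
    geno <- h1 + h2
    dimnames(geno) <- list(pedigree$id, map$snp)
    panel <- genotype_panel(geno, map)
    attr(panel, "founder_freq") <- freq
    panel
  })
}

#' Simulate birth-weight phenotypes under the full animal model
#'
#' \code{y = Xb + Za u_a + Zm u_m + Wc + e}: direct additive values are
#' either generated from \code{n_qtl} panel SNPs (effects scaled so their
#' realised variance equals \code{var_direct}) or, without genotypes, by the
#' recursive pedigree rule \code{u_i = (u_s + u_d)/2 + m_i} with
#' Mendelian-sampling variance \code{d_i * var_direct}. Maternal genetic
#' values always follow the pedigree rule; each record carries its dam's
#' maternal value. Fixed-effect level values (sex, parity, contemporary
#' group) are drawn once from N(0, sd_fixef^2), and the dam's litter size
#' enters as a covariate. Records are generated for all non-founders.
#'
#' @param pedigree a [simulate_pedigree()] table.
#' @param genotypes optional [genotype_panel()] aligned with the pedigree.
#' @param config a [sim_config()].
#' @param qtl_exclude drop the QTL columns from the returned panel attribute
#'   \code{qtl} bookkeeping (the panel itself is never modified here).
#' @return data frame of class \code{phenotypes} with columns id, ibw_kg, sex,
#'   parity, cg, litter, litter_size, plus attributes \code{truth} (data frame
#'   of true u_a, u_m per animal and c per litter) and \code{qtl} (QTL SNP ids,
#'   if used).
#' @export
simulate_phenotypes <- function(pedigree, genotypes = NULL, config,
                                qtl_exclude = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  pedigree <- as_pedigree(pedigree)
  n <- nrow(pedigree)
  idx <- ped_index(pedigree)
  F <- cpp_inbreeding(idx$sire, idx$dam)

  rec <- which(pedigree$generation > 0L)
  if (length(rec) == 0L) stop_ibwgp("no non-founder records to phenotype")
  if (config$var_maternal > 0 && any(idx$dam[rec] == 0L))
    stop_ibwgp("record with unknown dam but var_maternal > 0")

  with_stream(config$seed, "phenotypes", {
    ## direct additive values
    qtl <- NULL
    if (!is.null(genotypes) && config$n_qtl > 0L) {
      m <- ncol(genotypes$geno)
      qtl <- sort(sample.int(m, config$n_qtl))
      alpha <- stats::rnorm(config$n_qtl)
      g <- drop(scale(genotypes$geno[, qtl, drop = FALSE],
                      center = TRUE, scale = FALSE) %*% alpha)
      sdg <- stats::sd(g)
      u_a <- if (sdg > 0) g / sdg * sqrt(config$var_direct) else g * 0
      qtl <- colnames(genotypes$geno)[qtl]
    } else {
      u_a <- drop_genetic_values(idx, F, config$var_direct)
    }
    u_m <- drop_genetic_values(idx, F, config$var_maternal)

    litters <- unique(pedigree$litter[rec])
    c_lit <- stats::rnorm(length(litters), 0, sqrt(config$var_litter))
    names(c_lit) <- litters

    ## fixed-effect level values, drawn once
    sex_lev <- sort(unique(pedigree$sex[rec]))
    par_lev <- sort(unique(pedigree$parity[rec]))
    cg_lev <- sort(unique(pedigree$cg[rec]))
    b_sex <- stats::rnorm(length(sex_lev), 0, config$sd_fixef)
    b_par <- stats::rnorm(length(par_lev), 0, config$sd_fixef)
    b_cg <- stats::rnorm(length(cg_lev), 0, config$sd_fixef)

    ## litter size actually born (covariate value, shared by littermates)
    lit_size <- table(pedigree$litter[rec])
    ls <- as.integer(lit_size[as.character(pedigree$litter[rec])])

    e <- stats::rnorm(length(rec), 0, sqrt(config$var_residual))
    y <- config$mean_ibw +
      b_sex[match(pedigree$sex[rec], sex_lev)] +
      b_par[match(pedigree$parity[rec], par_lev)] +
      b_cg[match(pedigree$cg[rec], cg_lev)] +
      config$covariate_slope * (ls - mean(ls)) +
      u_a[rec] + u_m[idx$dam[rec]] +
      c_lit[as.character(pedigree$litter[rec])] + e

    phen <- data.frame(id = pedigree$id[rec], ibw_kg = y,
                       sex = pedigree$sex[rec], parity = pedigree$parity[rec],
                       cg = pedigree$cg[rec], litter = pedigree$litter[rec],
                       litter_size = ls, stringsAsFactors = FALSE)
    attr(phen, "truth") <- list(
      u_a = stats::setNames(u_a, pedigree$id),
      u_m = stats::setNames(u_m, pedigree$id),
      c_litter = c_lit,
      fixed = list(sex = b_sex, parity = b_par, cg = b_cg,
                   intercept = config$mean_ibw,
                   covariate_slope = config$covariate_slope))
    attr(phen, "qtl") <- if (isTRUE(qtl_exclude)) NULL else qtl
    class(phen) <- c("phenotypes", class(phen))
    phen
  })
}

## recursive breeding values down an ordered pedigree:
## u_i = (u_s + u_d)/2 + m_i, Var(m_i) = d_i * sigma2
drop_genetic_values <- function(idx, F, sigma2) {
  n <- length(idx$sire)
  if (sigma2 == 0) return(numeric(n))
  d <- rep(1, n)
  s <- idx$sire; dd <- idx$dam
  both <- s > 0L & dd > 0L
  d[both] <- 0.5 - 0.25 * (F[s[both]] + F[dd[both]])
  one <- xor(s > 0L, dd > 0L)
  Fp <- ifelse(s > 0L, F[pmax(s, 1L)], F[pmax(dd, 1L)])
  d[one] <- 0.75 - 0.25 * Fp[one]
  m <- stats::rnorm(n, 0, sqrt(d * sigma2))
  u <- numeric(n)
  for (i in seq_len(n)) {
    u[i] <- m[i] +
      (if (s[i] > 0L) u[s[i]] / 2 else 0) +
      (if (dd[i] > 0L) u[dd[i]] / 2 else 0)
  }
  u
}

#' Write simulated data to plain-text files
#'
#' Pedigree and phenotype CSVs, PLINK text .ped/.map, and a truth-values CSV.
#' @param pedigree,phenotypes,genotypes simulated objects.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_simulation <- function(pedigree, phenotypes, genotypes = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(pedigree = file.path(dir, "pedigree.csv"),
             phenotypes = file.path(dir, "phenotypes.csv"),
             truth = file.path(dir, "truth.csv"))
  write_pedigree_csv(pedigree, paths[["pedigree"]])
  utils::write.csv(as.data.frame(phenotypes), paths[["phenotypes"]],
                   row.names = FALSE, quote = FALSE)
  tr <- attr(phenotypes, "truth")
  truth <- data.frame(id = names(tr$u_a), u_a = tr$u_a, u_m = tr$u_m,
                      stringsAsFactors = FALSE)
  utils::write.csv(truth, paths[["truth"]], row.names = FALSE, quote = FALSE)
  if (!is.null(genotypes)) {
    write_plink(genotypes, file.path(dir, "genotypes"))
    paths <- c(paths, genotypes = file.path(dir, "genotypes.ped"))
  }
  invisible(paths)
}
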