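## End-to-end orchestration: each stage reads its inputs from the output
## directory of the stages before it, writes plain-text results plus a
## manifest (input hashes, config echo, seed), and can be re-run
## idempotently.

#' Pipeline configuration
#'
#' A nested list of per-stage settings with a global seed and output
#' directory. Any stage block may be omitted to use its defaults.
#'
#' @param out_dir output directory.
#' @param seed global seed; stages derive named sub-streams from it.
#' @param simulate a [sim_config()] (its seed is overridden by \code{seed}).
#' @param qc list(min_call_rate_snp, min_call_rate_animal, center).
#' @param reml list(formula; models = which of 1:4 to fit).
#' @param deregress list(c_frac, reliability_threshold).
#' @param bayes an [mcmc_config()] plus method.
#' @param cv list(k, n_init).
#' @param gwas list(window_size, threshold, top_n).
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(out_dir, seed = 1L,
                            simulate = sim_config(seed = seed),
                            qc = list(min_call_rate_snp = 0.90,
                                      min_call_rate_animal = 0.90,
                                      center = TRUE),
                            reml = list(formula = ibw_kg ~ factor(sex) +
                                          factor(parity) + factor(cg) +
                                          litter_size,
                                        models = 1:4),
                            deregress = list(c_frac = 0.5,
                                             reliability_threshold = 0.01),
                            bayes = list(method = "BayesB",
                                         config = mcmc_config(seed = seed)),
                            cv = list(k = 5L, n_init = 10L),
                            gwas = list(window_size = 1e6, threshold = 0.5,
                                        top_n = 0L)) {
  simulate$seed <- seed
  structure(list(out_dir = out_dir, seed = seed, simulate = simulate,
                 qc = qc, reml = reml, deregress = deregress, bayes = bayes,
                 cv = cv, gwas = gwas),
            class = "pipeline_config")
}

stage_order <- c("simulate", "qc", "reml", "deregress", "bayes", "gwas", "cv")

pipe_path <- function(config, ...) file.path(config$out_dir, ...)

need_artifact <- function(config, file, producer) {
  p <- pipe_path(config, file)
  if (!file.exists(p))
    stop_ibwgp("missing artifact '%s': run stage '%s' first", file, producer)
  p
}

write_manifest <- function(config, stage, inputs, outputs) {
  files <- c(inputs, outputs)
  hashes <- tools::md5sum(files[file.exists(files)])
  man <- c(sprintf("stage: %s", stage),
           sprintf("seed: %d", config$seed),
           sprintf("time: %s", "(not hashed)"),
           sprintf("file: %s md5: %s", names(hashes), unname(hashes)))
  writeLines(man, pipe_path(config, paste0("manifest_", stage, ".txt")))
}

#' Run one pipeline stage
#'
#' Stages: \code{simulate} (pedigree/phenotypes/genotypes), \code{qc}
#' (genotype QC + analysis recoding), \code{reml} (the model ladder +
#' comparison table), \code{deregress} (response variables + weights),
#' \code{bayes} (marker model on DEBVincPA), \code{gwas} (window report),
#' \code{cv} (fold accuracies for both responses). Each stage writes TSV/CSV
#' outputs and a manifest into \code{config$out_dir}; re-running a stage with
#' unchanged inputs reproduces identical outputs.
#'
#' @param name stage name.
#' @param config a [pipeline_config()].
#' @return the stage's principal result, invisibly.
#' @export
run_stage <- function(name, config) {
  stopifnot(inherits(config, "pipeline_config"), name %in% stage_order)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- switch(name,
                simulate = stage_simulate(config),
                qc = stage_qc(config),
                reml = stage_reml(config),
                deregress = stage_deregress(config),
                bayes = stage_bayes(config),
                gwas = stage_gwas(config),
                cv = stage_cv(config))
  invisible(res)
}

#' @rdname run_stage
#' @param stages stages to run, in order.
#' @export
run_pipeline <- function(config, stages = stage_order) {
  for (s in stage_order[stage_order %in% stages]) run_stage(s, config)
  invisible(config$out_dir)
}

stage_simulate <- function(config) {
  ped <- simulate_pedigree(config$simulate)
  gen <- if (!is.null(config$simulate$panel))
    simulate_genotypes(ped, config$simulate) else NULL
  phen <- simulate_phenotypes(ped, gen, config$simulate)
  paths <- write_simulation(ped, phen, gen, config$out_dir)
  write_manifest(config, "simulate", character(0), paths)
  list(pedigree = ped, phenotypes = phen, genotypes = gen)
}

stage_qc <- function(config) {
  prefix <- sub("\\.ped$", "", need_artifact(config, "genotypes.ped", "simulate"))
  panel <- read_plink(prefix)
  panel <- qc_snps(panel, min_call_rate = config$qc$min_call_rate_snp)
  rep_snp <- attr(panel, "removal_report")
  panel <- qc_animals(panel, min_call_rate = config$qc$min_call_rate_animal)
  rep_ani <- attr(panel, "removal_report")
  panel <- complete_missing(panel)
  z <- recode_analysis(panel, center = isTRUE(config$qc$center))
  out1 <- pipe_path(config, "geno_qc.tsv")
  write_geno_tsv(panel, out1)
  out2 <- pipe_path(config, "geno_analysis.tsv")
  write_geno_tsv(z, out2)
  rep <- rbind(cbind(unit = "snp", rep_snp), cbind(unit = "animal", rep_ani))
  out3 <- pipe_path(config, "qc_report.tsv")
  utils::write.table(rep, out3, sep = "\t", row.names = FALSE, quote = FALSE)
  message(sprintf("qc: %d SNPs, %d animals retained", ncol(panel$geno),
                  nrow(panel$geno)))
  write_manifest(config, "qc", paste0(prefix, c(".ped", ".map")),
                 c(out1, out2, out3))
  z
}

stage_reml <- function(config) {
  ped <- read_pedigree_csv(need_artifact(config, "pedigree.csv", "simulate"))
  phen <- utils::read.csv(need_artifact(config, "phenotypes.csv", "simulate"))
  fits <- lapply(config$reml$models, function(m)
    reml_animal(config$reml$formula, phen, ped, spec = eq_model(m)))
  names(fits) <- paste0("eq", config$reml$models)
  tab <- varcomp_table(fits)
  out <- pipe_path(config, "varcomp_table.tsv")
  utils::write.table(tab, out, sep = "\t", row.names = FALSE, quote = FALSE)
  full <- fits[[length(fits)]]
  rel <- reliability(full)
  out2 <- pipe_path(config, "ebv.tsv")
  utils::write.table(rel, out2, sep = "\t", row.names = FALSE, quote = FALSE)
  write_manifest(config, "reml",
                 pipe_path(config, c("pedigree.csv", "phenotypes.csv")),
                 c(out, out2))
  list(fits = fits, table = tab, reliability = rel)
}

stage_deregress <- function(config) {
  ped <- read_pedigree_csv(need_artifact(config, "pedigree.csv", "simulate"))
  rel <- utils::read.table(need_artifact(config, "ebv.tsv", "reml"),
                           header = TRUE, sep = "\t")
  tab <- utils::read.table(need_artifact(config, "varcomp_table.tsv", "reml"),
                           header = TRUE, sep = "\t")
  h2 <- tab$h2[nrow(tab)]
  ebv <- stats::setNames(rel$ebv, rel$id)
  r2 <- stats::setNames(rel$r2, rel$id)
  ids <- if (file.exists(pipe_path(config, "geno_qc.tsv"))) {
    g <- read_geno_tsv(pipe_path(config, "geno_qc.tsv"))
    intersect(rownames(g$geno), names(ebv))
  } else names(ebv)
  deb <- deregress_ebv(ebv, r2, ped, h2 = h2,
                       c_frac = config$deregress$c_frac, ids = ids)
  deb <- filter_reliability(deb, config$deregress$reliability_threshold)
  out <- pipe_path(config, "debv.tsv")
  utils::write.table(deb, out, sep = "\t", row.names = FALSE, quote = FALSE)
  message(sprintf("deregress: %d records retained", nrow(deb)))
  write_manifest(config, "deregress",
                 pipe_path(config, c("ebv.tsv", "varcomp_table.tsv")), out)
  deb
}

read_debv <- function(config) {
  deb <- utils::read.table(need_artifact(config, "debv.tsv", "deregress"),
                           header = TRUE, sep = "\t")
  z <- read_geno_tsv(need_artifact(config, "geno_analysis.tsv", "qc"))
  keep <- intersect(rownames(z$geno), deb$id)
  list(deb = deb[match(keep, deb$id), ], z = z,
       Z = z$geno[keep, , drop = FALSE])
}

stage_bayes <- function(config) {
  inp <- read_debv(config)
  fit <- bayes_fit(inp$Z, inp$deb$debv_inc_pa, inp$deb$w,
                   method = config$bayes$method,
                   config = config$bayes$config, store_samples = TRUE)
  out <- pipe_path(config, "posterior.tsv")
  post <- data.frame(snp = fit$snp,
                     inp$z$map[match(fit$snp, inp$z$map$snp), c("chr", "pos")],
                     post_mean_effect = fit$post_mean_effect,
                     model_freq = fit$model_freq)
  utils::write.table(post, out, sep = "\t", row.names = FALSE, quote = FALSE)
  dgv_tab <- data.frame(id = rownames(inp$Z), dgv = dgv(fit, inp$Z))
  out2 <- pipe_path(config, "dgv.tsv")
  utils::write.table(dgv_tab, out2, sep = "\t", row.names = FALSE, quote = FALSE)
  saveRDS_path <- pipe_path(config, "effect_samples.tsv")
  utils::write.table(fit$effect_samples, saveRDS_path, sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  write_manifest(config, "bayes",
                 pipe_path(config, c("debv.tsv", "geno_analysis.tsv")),
                 c(out, out2, saveRDS_path))
  fit
}

stage_gwas <- function(config) {
  inp <- read_debv(config)
  post <- utils::read.table(need_artifact(config, "posterior.tsv", "bayes"),
                            header = TRUE, sep = "\t")
  samples <- as.matrix(utils::read.table(
    need_artifact(config, "effect_samples.tsv", "bayes"), sep = "\t"))
  rownames(samples) <- post$snp
  wins <- assign_windows(inp$z$map, config$gwas$window_size)
  rep <- window_variance(inp$Z, samples, wins, model_freq = post$model_freq,
                         threshold = config$gwas$threshold)
  tab <- gwas_table(rep, inp$z$map, top_n = config$gwas$top_n)
  out <- pipe_path(config, "window_report.tsv")
  utils::write.table(as.data.frame(rep), out, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  out2 <- pipe_path(config, "gwas_table.tsv")
  utils::write.table(tab, out2, sep = "\t", row.names = FALSE, quote = FALSE)
  write_manifest(config, "gwas",
                 pipe_path(config, c("posterior.tsv", "effect_samples.tsv")),
                 c(out, out2))
  rep
}

stage_cv <- function(config) {
  inp <- read_debv(config)
  ped <- read_pedigree_csv(need_artifact(config, "pedigree.csv", "simulate"))
  A <- build_A(ped, subset = as.integer(rownames(inp$Z)))
  folds <- kmeans_folds(A, k = config$cv$k, n_init = config$cv$n_init,
                        seed = config$seed)
  rows <- list()
  for (resp in c("debv_exc_pa", "debv_inc_pa")) {
    y <- stats::setNames(inp$deb[[resp]], inp$deb$id)
    w <- stats::setNames(inp$deb$w, inp$deb$id)
    acc <- cv_run(folds, inp$Z, y, w, method = config$bayes$method,
                  config = config$bayes$config)
    rows[[resp]] <- data.frame(response = resp, method = acc$method,
                               pi = acc$pi, accuracy = acc$mean_accuracy,
                               se = acc$se, stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  out <- pipe_path(config, "cv_accuracy.tsv")
  utils::write.table(tab, out, sep = "\t", row.names = FALSE, quote = FALSE)
  out2 <- pipe_path(config, "cv_cluster_stats.tsv")
  utils::write.table(folds$stats, out2, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  write_manifest(config, "cv",
                 pipe_path(config, c("debv.tsv", "geno_analysis.tsv")),
                 c(out, out2))
  list(folds = folds, accuracy = tab)
}
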