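## 1-Mb window decomposition of posterior genetic variance and
## model-frequency-ranked SNP reporting.

#' Assign SNPs to fixed-width genomic windows
#'
#' Half-open windows \code{[k*size, (k+1)*size)} per chromosome, labelled
#' \code{"chr_k"} (chromosome_megabase for the default 1-Mb width).
#'
#' @param map data frame with columns \code{chr} and \code{pos} (bp).
#' @param window_size window width in bp (default 1 Mb).
#' @return character vector of window labels, one per SNP.
#' @export
assign_windows <- function(map, window_size = 1e6) {
  stopifnot(all(c("chr", "pos") %in% names(map)), all(map$pos >= 0))
  paste0(map$chr, "_", floor(map$pos / window_size))
}

#' Posterior window-variance decomposition
#'
#' For each saved sample s, the genetic values \code{g_w(s) = Z_w u_w(s)} of
#' every window are computed and their variance across animals taken; the
#' window's share is \code{100 * var(g_w)/var(g_total)}. \code{GV\%} is the
#' posterior mean of these per-sample percentages (the ratio of posterior
#' means is also reported). Samples with zero total genetic variance are
#' skipped and counted.
#'
#' @param Z analysis-coded marker matrix used in training (animals x SNPs).
#' @param effect_samples SNPs x samples matrix of saved marker effects (from
#'   [bayes_fit()] with \code{store_samples = TRUE}).
#' @param windows window label per SNP (from [assign_windows()]).
#' @param model_freq optional per-SNP model frequencies to carry into the
#'   report.
#' @param threshold informative-window threshold on GV\% (strictly greater;
#'   default 0.5).
#' @return data frame of class \code{window_report}: window, n_snps, gv_pct,
#'   gv_pct_ratio_of_means, informative; attribute \code{n_skipped} counts
#'   zero-variance samples; attribute \code{snp} holds the per-SNP table.
#' @export
window_variance <- function(Z, effect_samples, windows, model_freq = NULL,
                            threshold = 0.5) {
  if (inherits(Z, "genotype_panel")) Z <- Z$geno
  stopifnot(ncol(Z) == nrow(effect_samples),
            length(windows) == ncol(Z))
  wins <- factor(windows, levels = unique(windows))
  S <- ncol(effect_samples)
  G <- Z %*% effect_samples                    # animals x samples, total
  vtot <- apply(G, 2L, stats::var)
  ok <- vtot > 0
  n_skipped <- sum(!ok)
  ratios <- matrix(0, nlevels(wins), S,
                   dimnames = list(levels(wins), NULL))
  vw_mean <- numeric(nlevels(wins))
  for (k in seq_len(nlevels(wins))) {
    j <- which(as.integer(wins) == k)
    Gw <- Z[, j, drop = FALSE] %*% effect_samples[j, , drop = FALSE]
    vw <- apply(Gw, 2L, stats::var)
    ratios[k, ok] <- 100 * vw[ok] / vtot[ok]
    vw_mean[k] <- mean(vw)
  }
  gv <- rowMeans(ratios[, ok, drop = FALSE])
  gv_rom <- 100 * vw_mean / mean(vtot[ok])
  out <- data.frame(window = levels(wins),
                    n_snps = as.integer(table(wins)),
                    gv_pct = gv, gv_pct_ratio_of_means = gv_rom,
                    informative = gv > threshold,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$gv_pct), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skipped
  if (!is.null(model_freq))
    attr(out, "snp") <- data.frame(window = as.character(wins),
                                   snp = rownames(effect_samples) %||%
                                     colnames(Z) %||% seq_along(windows),
                                   model_freq = model_freq,
                                   post_mean_effect = rowMeans(effect_samples),
                                   stringsAsFactors = FALSE)
  class(out) <- c("window_report", class(out))
  out
}

#' Rank SNPs within windows by model frequency
#'
#' Stable sort, descending model frequency, ties broken by position
#' ascending.
#'
#' @param snp_table data frame with columns \code{window}, \code{snp},
#'   \code{model_freq} and \code{pos} (bp).
#' @param windows optional subset of window labels to keep.
#' @return the table sorted within windows.
#' @export
rank_snps <- function(snp_table, windows = NULL) {
  if (!is.null(windows))
    snp_table <- snp_table[snp_table$window %in% windows, , drop = FALSE]
  o <- order(snp_table$window, -snp_table$model_freq, snp_table$pos)
  out <- snp_table[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Association-scan report over informative windows
#'
#' Combines the window-variance decomposition with the per-window SNP ranking
#' into a single table: one row per SNP in each reported window, carrying the
#' window's GV\%. By default only informative windows (GV\% above the
#' threshold) appear; \code{top_n} additionally keeps the highest-GV\%
#' windows regardless of the threshold.
#'
#' @param report a [window_variance()] result (with the snp attribute).
#' @param map SNP map with \code{snp} and \code{pos} columns.
#' @param top_n also include this many top windows even if below threshold.
#' @return data frame: window, gv_pct, snp, pos_mb, post_mean_effect,
#'   model_freq.
#' @export
gwas_table <- function(report, map, top_n = 0L) {
  snp <- attr(report, "snp")
  if (is.null(snp)) stop_ibwgp("report lacks the per-SNP table")
  keep <- report$window[report$informative]
  if (top_n > 0L) keep <- union(keep, report$window[seq_len(min(top_n, nrow(report)))])
  snp$pos <- map$pos[match(snp$snp, map$snp)]
  ranked <- rank_snps(snp, windows = keep)
  ranked$gv_pct <- report$gv_pct[match(ranked$window, report$window)]
  o <- order(-ranked$gv_pct, ranked$window, -ranked$model_freq, ranked$pos)
  out <- ranked[o, c("window", "gv_pct", "snp", "pos", "post_mean_effect",
                     "model_freq")]
  out$pos_mb <- out$pos / 1e6
  out$pos <- NULL
  rownames(out) <- NULL
  out
}
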