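## Genotype container, quality control, -10/0/10 recoding, mode completion,
## and PLINK-text / TSV input-output.

#' Genotype panel
#'
#' @param geno integer matrix, animals x SNPs, dosages 0/1/2 (raw coding) with
#'   NA for missing calls; rownames = animal ids, colnames = SNP ids.
#' @param map data frame with columns \code{snp}, \code{chr}, \code{pos} (bp);
#'   \code{chr} may be NA for unmapped SNPs. Sorted by (chr, pos) on creation.
#' @param coding \code{"raw"} (0/1/2) or \code{"analysis"} (-10/0/10, possibly
#'   column-centred).
#' @return list of class \code{genotype_panel} with elements \code{geno},
#'   \code{map}, \code{coding}.
#' @export
genotype_panel <- function(geno, map, coding = "raw") {
  stopifnot(is.matrix(geno), is.data.frame(map),
            all(c("snp", "chr", "pos") %in% names(map)),
            ncol(geno) == nrow(map),
            coding %in% c("raw", "analysis"))
  if (is.null(colnames(geno))) colnames(geno) <- map$snp
  stopifnot(identical(colnames(geno), as.character(map$snp)))
  o <- order(is.na(map$chr), map$chr, map$pos)
  map <- map[o, , drop = FALSE]
  geno <- geno[, o, drop = FALSE]
  rownames(map) <- NULL
  structure(list(geno = geno, map = map, coding = coding),
            class = "genotype_panel")
}

#' @exportS3Method print genotype_panel
print.genotype_panel <- function(x, ...) {
  cat(sprintf("genotype_panel: %d animals x %d SNPs (%s coding), %d missing\n",
              nrow(x$geno), ncol(x$geno), x$coding, sum(is.na(x$geno))))
  invisible(x)
}

snp_call_rate <- function(panel) colMeans(!is.na(panel$geno))
animal_call_rate <- function(panel) rowMeans(!is.na(panel$geno))

#' SNP quality control
#'
#' Removes, in order of reporting: unmapped SNPs (missing chromosome or
#' position), sex-chromosome SNPs, SNPs with call rate below
#' \code{min_call_rate}, and duplicate map positions (the SNP with the higher
#' call rate is kept; ties keep the first).
#'
#' @param panel a raw-coded [genotype_panel()].
#' @param min_call_rate minimum per-SNP call rate (default 0.90).
#' @param sex_chromosomes chromosome labels treated as sex chromosomes.
#' @param drop_unmapped,drop_duplicate_positions toggles for those rules.
#' @return the filtered panel, with attribute \code{removal_report}, a data
#'   frame of counts per rule.
#' @export
qc_snps <- function(panel, min_call_rate = 0.90,
                    sex_chromosomes = c("X", "Y"),
                    drop_unmapped = TRUE, drop_duplicate_positions = TRUE) {
  stopifnot(inherits(panel, "genotype_panel"), panel$coding == "raw")
  cr <- snp_call_rate(panel)
  drop <- rep(FALSE, ncol(panel$geno))
  report <- list()
  if (drop_unmapped) {
    r <- is.na(panel$map$chr) | is.na(panel$map$pos)
    report$unmapped <- sum(r & !drop); drop <- drop | r
  }
  r <- as.character(panel$map$chr) %in% sex_chromosomes
  report$sex_chromosome <- sum(r & !drop); drop <- drop | r
  r <- cr < min_call_rate
  report$low_call_rate <- sum(r & !drop); drop <- drop | r
  if (drop_duplicate_positions) {
    keep_idx <- which(!drop)
    key <- paste(panel$map$chr[keep_idx], panel$map$pos[keep_idx])
    ## order by call rate descending within key, keep the first of each
    o <- keep_idx[order(key, -cr[keep_idx])]
    dupes <- o[duplicated(paste(panel$map$chr[o], panel$map$pos[o]))]
    report$duplicate_position <- length(dupes)
    drop[dupes] <- TRUE
  }
  if (all(drop)) warning("no SNPs remain after QC")
  out <- genotype_panel(panel$geno[, !drop, drop = FALSE],
                        panel$map[!drop, , drop = FALSE], coding = "raw")
  attr(out, "removal_report") <-
    data.frame(rule = names(report), removed = unlist(report, use.names = FALSE))
  out
}

#' Animal quality control
#'
#' Removes animals with call rate below \code{min_call_rate}, animals not in
#' \code{registered_ids} (when supplied), and duplicate genotypes of one
#' animal (the copy with the higher call rate is kept).
#'
#' @param panel a raw-coded [genotype_panel()].
#' @param min_call_rate minimum per-animal call rate (default 0.90).
#' @param registered_ids optional vector of valid (registered) animal ids.
#' @return filtered panel with attribute \code{removal_report}.
#' @export
qc_animals <- function(panel, min_call_rate = 0.90, registered_ids = NULL) {
  stopifnot(inherits(panel, "genotype_panel"), panel$coding == "raw")
  cr <- animal_call_rate(panel)
  ids <- rownames(panel$geno)
  drop <- rep(FALSE, length(ids))
  report <- list()
  r <- cr < min_call_rate
  report$low_call_rate <- sum(r); drop <- drop | r
  if (!is.null(registered_ids)) {
    r <- !(ids %in% as.character(registered_ids))
    report$unregistered <- sum(r & !drop); drop <- drop | r
  }
  keep_idx <- which(!drop)
  o <- keep_idx[order(ids[keep_idx], -cr[keep_idx])]
  dupes <- o[duplicated(ids[o])]
  report$duplicate_animal <- length(dupes)
  drop[dupes] <- TRUE
  out <- genotype_panel(panel$geno[!drop, , drop = FALSE], panel$map,
                        coding = "raw")
  attr(out, "removal_report") <-
    data.frame(rule = names(report), removed = unlist(report, use.names = FALSE))
  out
}

#' Fill residual missing calls with the per-SNP modal dosage
#'
#' Deterministic: ties between modal dosages break to the smaller dosage.
#' @param panel a raw-coded [genotype_panel()].
#' @return completed panel.
#' @export
complete_missing <- function(panel) {
  stopifnot(inherits(panel, "genotype_panel"), panel$coding == "raw")
  g <- panel$geno
  for (j in which(colSums(is.na(g)) > 0L)) {
    x <- g[, j]
    obs <- x[!is.na(x)]
    if (length(obs) == 0L)
      stop_ibwgp("SNP %s is entirely missing; remove it in QC first",
                 colnames(g)[j])
    tab <- table(obs)
    mode <- as.integer(names(tab)[which.max(tab)]) # ties: smallest (table is sorted)
    x[is.na(x)] <- mode
    g[, j] <- x
  }
  genotype_panel(g, panel$map, coding = "raw")
}

#' Recode dosages to the -10/0/10 analysis scale
#'
#' 0 -> -10, 1 -> 0, 2 -> +10; with \code{center = TRUE} each SNP column is
#' shifted to mean zero (the model intercept absorbs the shift).
#'
#' @param panel a complete raw-coded [genotype_panel()].
#' @param center centre columns to mean zero (default TRUE).
#' @return panel in analysis coding (numeric matrix).
#' @export
recode_analysis <- function(panel, center = TRUE) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (panel$coding != "raw") stop_ibwgp("panel already in analysis coding")
  if (anyNA(panel$geno))
    stop_ibwgp("panel has missing calls; run complete_missing() first")
  z <- panel$geno * 10 - 10
  storage.mode(z) <- "double"
  if (center) z <- scale(z, center = TRUE, scale = FALSE)[, , drop = FALSE]
  out <- genotype_panel(z, panel$map, coding = "analysis")
  out
}

#' Write / read PLINK text files
#'
#' Biallelic .ped/.map with alleles coded 1/2; the dosage counts allele "2".
#' Missing calls are written as "0 0". The .map columns are chromosome, SNP
#' id, genetic distance (0), bp position.
#'
#' @param panel a raw-coded [genotype_panel()].
#' @param prefix path prefix; \code{.ped} and \code{.map} are appended.
#' @export
write_plink <- function(panel, prefix) {
  stopifnot(inherits(panel, "genotype_panel"), panel$coding == "raw")
  g <- panel$geno
  n <- nrow(g); m <- ncol(g)
  a1 <- matrix("0", n, m); a2 <- matrix("0", n, m)
  a1[g == 0] <- "1"; a2[g == 0] <- "1"
  a1[g == 1] <- "1"; a2[g == 1] <- "2"
  a1[g == 2] <- "2"; a2[g == 2] <- "2"
  alleles <- matrix("", n, 2L * m)
  alleles[, seq(1L, 2L * m, by = 2L)] <- a1
  alleles[, seq(2L, 2L * m, by = 2L)] <- a2
  ped <- cbind("FAM", rownames(g), "0", "0", "0", "-9", alleles)
  utils::write.table(ped, paste0(prefix, ".ped"), row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  map <- data.frame(chr = ifelse(is.na(panel$map$chr), 0, panel$map$chr),
                    snp = panel$map$snp, cm = 0,
                    pos = ifelse(is.na(panel$map$pos), 0, panel$map$pos))
  utils::write.table(map, paste0(prefix, ".map"), row.names = FALSE,
                     col.names = FALSE, quote = FALSE, sep = "\t")
  invisible(prefix)
}

#' @rdname write_plink
#' @export
read_plink <- function(prefix) {
  map <- utils::read.table(paste0(prefix, ".map"), header = FALSE,
                           col.names = c("chr", "snp", "cm", "pos"),
                           colClasses = c("character", "character",
                                          "numeric", "numeric"))
  ped <- utils::read.table(paste0(prefix, ".ped"), header = FALSE,
                           colClasses = "character")
  m <- nrow(map)
  if (ncol(ped) != 6L + 2L * m)
    stop_ibwgp(".ped has %d columns; expected %d for %d SNPs",
               ncol(ped), 6L + 2L * m, m)
  ids <- ped[[2L]]
  a1 <- as.matrix(ped[, 6L + seq(1L, 2L * m, by = 2L), drop = FALSE])
  a2 <- as.matrix(ped[, 6L + seq(2L, 2L * m, by = 2L), drop = FALSE])
  miss <- a1 == "0" | a2 == "0"
  g <- (a1 == "2") + (a2 == "2")
  g[miss] <- NA_integer_
  storage.mode(g) <- "integer"
  dimnames(g) <- list(ids, map$snp)
  chr <- map$chr; chr[chr == "0"] <- NA
  chr_num <- suppressWarnings(as.numeric(chr))
  map2 <- data.frame(snp = map$snp,
                     chr = ifelse(is.na(chr_num) & !is.na(chr), chr,
                                  chr_num),
                     pos = ifelse(map$pos == 0, NA_real_, map$pos),
                     stringsAsFactors = FALSE)
  genotype_panel(g, map2)
}

#' Write / read the internal genotype-matrix TSV
#'
#' Animals x SNPs dosage matrix with a header row of SNP ids and an \code{id}
#' first column; the map is stored alongside as \code{<path>.map.tsv}.
#' @param panel a [genotype_panel()].
#' @param path file path for the matrix TSV.
#' @export
write_geno_tsv <- function(panel, path) {
  df <- data.frame(id = rownames(panel$geno), panel$geno,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(panel$map, paste0(path, ".map.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_geno_tsv
#' @export
read_geno_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  map <- utils::read.table(paste0(path, ".map.tsv"), sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  g <- as.matrix(df[, -1L, drop = FALSE])
  rownames(g) <- df$id
  coding <- if (any(g < 0, na.rm = TRUE) || !all(g[!is.na(g)] %% 1 == 0))
    "analysis" else "raw"
  if (coding == "raw") storage.mode(g) <- "integer"
  genotype_panel(g, map, coding = coding)
}
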