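## Relationship-aware k-means cross-validation folds and fold-wise accuracy
## of direct genomic values.

#' k-means folds on pedigree relationships
#'
#' Clusters genotyped animals with k-means on the rows of their numerator
#' relationship matrix (Euclidean distance, best of \code{n_init} restarts),
#' so that training and validation sets are as unrelated as the pedigree
#' allows. Relationship summaries of the accepted assignment come from
#' [cluster_relationship_stats()].
#'
#' @param A relationship matrix over the genotyped animals (dimnames = ids).
#' @param k number of folds (default 5).
#' @param n_init k-means restarts (default 10).
#' @param seed RNG seed for the restarts.
#' @return list of class \code{fold_assignment}: \code{fold} (named integer
#'   vector), \code{sizes}, \code{stats}.
#' @export
kmeans_folds <- function(A, k = 5L, n_init = 10L, seed = 1L) {
  n <- nrow(A)
  if (k > n) stop_ibwgp("more folds than animals")
  if (k == 1L) {
    fold <- stats::setNames(rep(1L, n), rownames(A))
  } else {
    with_stream(seed, "kmeans", {
      km <- tryCatch(
        stats::kmeans(A, centers = k, nstart = n_init, iter.max = 100L),
        error = function(e)
          stats::kmeans(A, centers = k, nstart = n_init, iter.max = 100L,
                        algorithm = "Lloyd"))
      fold <- stats::setNames(km$cluster, rownames(A))
    })
  }
  if (length(unique(fold)) < k) stop_ibwgp("empty fold after clustering")
  structure(list(fold = fold, sizes = as.integer(table(fold)),
                 stats = cluster_relationship_stats(A, fold)),
            class = "fold_assignment")
}

#' @exportS3Method print fold_assignment
print.fold_assignment <- function(x, ...) {
  cat("fold assignment:", length(x$fold), "animals in",
      length(x$sizes), "folds of sizes", paste(x$sizes, collapse = "/"), "\n")
  print(x$stats, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Cross-validated accuracy of direct genomic values
#'
#' For each fold, the marker model is trained on all other folds and DGVs of
#' the fold's animals are correlated with their responses (Pearson). The mean
#' accuracy and its SE (sd across folds / sqrt(k)) are reported. Folds with
#' fewer than 3 validation animals are an error; a fold with zero-variance
#' DGV or response is flagged and excluded from the mean.
#'
#' @param folds a [kmeans_folds()] assignment.
#' @param Z analysis-coded marker matrix (rownames = animal ids).
#' @param response named response vector (deregressed breeding values).
#' @param weights named weight vector (default 1).
#' @param method \code{"BayesB"} or \code{"BayesC"}.
#' @param config an [mcmc_config()].
#' @return object of class \code{accuracy_report}: per-fold table, mean
#'   accuracy, SE, labels.
#' @export
cv_run <- function(folds, Z, response, weights = NULL,
                   method = c("BayesB", "BayesC"), config = mcmc_config()) {
  method <- match.arg(method)
  if (inherits(Z, "genotype_panel")) Z <- Z$geno
  ids <- rownames(Z)
  stopifnot(!is.null(ids), all(ids %in% names(folds$fold)),
            all(ids %in% names(response)))
  if (is.null(weights)) weights <- stats::setNames(rep(1, length(ids)), ids)
  fold <- folds$fold[ids]
  ks <- sort(unique(fold))
  for (f in ks)
    if (sum(fold == f) < 3L)
      stop_ibwgp("fold %s has < 3 validation animals", f)
  rows <- lapply(ks, function(f) {
    val <- ids[fold == f]; trn <- ids[fold != f]
    fit <- bayes_fit(Z[trn, , drop = FALSE], response[trn], weights[trn],
                     method = method, config = config)
    pred <- dgv(fit, Z[val, , drop = FALSE])
    obs <- response[val]
    ok <- stats::sd(pred) > 0 && stats::sd(obs) > 0
    data.frame(fold = f, n_train = length(trn), n_val = length(val),
               r = if (ok) stats::cor(pred, obs) else NA_real_,
               ok = ok, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  r <- tab$r[tab$ok]
  structure(list(folds = tab, mean_accuracy = mean(r),
                 se = stats::sd(r) / sqrt(length(r)),
                 method = method, pi = config$pi, k = length(ks)),
            class = "accuracy_report")
}

#' @exportS3Method print accuracy_report
print.accuracy_report <- function(x, ...) {
  cat(sprintf("%s (pi = %g), %d-fold CV: accuracy %.3f (SE %.3f)\n",
              x$method, x$pi, x$k, x$mean_accuracy, x$se))
  print(x$folds, row.names = FALSE, digits = 3)
  invisible(x)
}
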