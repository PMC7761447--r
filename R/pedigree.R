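## Pedigree container, numerator relationship matrix A, its sparse inverse,
## inbreeding coefficients, and within/between-cluster relationship summaries.

#' Validate and classify a pedigree table
#'
#' A pedigree is a data frame with integer columns \code{id}, \code{sire} and
#' \code{dam} (0 = unknown parent) in topological order: every known parent
#' appears in an earlier row than its offspring. Additional columns (sex,
#' parity, contemporary group \code{cg}, \code{litter}, \code{generation})
#' are carried along untouched.
#'
#' @param x data frame with at least columns \code{id}, \code{sire}, \code{dam}.
#' @return \code{x} with class \code{c("pedigree", "data.frame")}.
#' @export
as_pedigree <- function(x) {
  stopifnot(is.data.frame(x), all(c("id", "sire", "dam") %in% names(x)))
  x$id <- as.integer(x$id); x$sire <- as.integer(x$sire); x$dam <- as.integer(x$dam)
  if (anyDuplicated(x$id)) stop_ibwgp("duplicated animal ids in pedigree")
  if (any(x$id == 0L)) stop_ibwgp("id 0 is reserved for unknown parents")
  pos <- match(x$sire, x$id); pos[x$sire == 0L] <- 0L
  if (anyNA(pos)) stop_ibwgp("sire id absent from pedigree")
  if (any(pos >= seq_len(nrow(x)), na.rm = TRUE))
    stop_ibwgp("pedigree not topologically ordered: a sire follows its offspring")
  posd <- match(x$dam, x$id); posd[x$dam == 0L] <- 0L
  if (anyNA(posd)) stop_ibwgp("dam id absent from pedigree")
  if (any(posd >= seq_len(nrow(x)), na.rm = TRUE))
    stop_ibwgp("pedigree not topologically ordered: a dam follows its offspring")
  class(x) <- unique(c("pedigree", class(x)))
  x
}

## 1-based row indices of parents (0 = unknown)
ped_index <- function(ped) {
  si <- match(ped$sire, ped$id); si[ped$sire == 0L] <- 0L
  di <- match(ped$dam, ped$id); di[ped$dam == 0L] <- 0L
  list(sire = as.integer(si), dam = as.integer(di))
}

#' Inbreeding coefficients
#'
#' \eqn{F_i = a(sire_i, dam_i)/2}; founders and animals with an unknown parent
#' have \eqn{F = 0}. Computed by the Meuwissen & Luo ancestor-tracing
#' algorithm, linear in pedigree depth per animal.
#'
#' @param pedigree a [as_pedigree()] table.
#' @return named numeric vector of inbreeding coefficients, one per animal.
#' @export
inbreeding <- function(pedigree) {
  pedigree <- as_pedigree(pedigree)
  idx <- ped_index(pedigree)
  F <- cpp_inbreeding(idx$sire, idx$dam)
  names(F) <- pedigree$id
  F
}

#' Numerator relationship matrix A
#'
#' Tabular method: \eqn{a_{ii} = 1 + a_{sd}/2}, \eqn{a_{ij} = (a_{j,s} +
#' a_{j,d})/2}, unknown parents contributing 0. When \code{subset} is given,
#' the pedigree is first pruned to the subset and its ancestors, and only the
#' requested rows/columns are returned (the A entries among subset animals do
#' not depend on their descendants).
#'
#' @param pedigree a [as_pedigree()] table.
#' @param subset animal ids to return (default all).
#' @return dense symmetric matrix with dimnames = animal ids; diagonal
#'   \eqn{1 + F_i}.
#' @export
build_A <- function(pedigree, subset = NULL) {
  pedigree <- as_pedigree(pedigree)
  if (!is.null(subset)) {
    subset <- as.integer(subset)
    if (!all(subset %in% pedigree$id)) stop_ibwgp("subset id absent from pedigree")
    keep <- ancestor_closure(pedigree, subset)
    ped2 <- prune_pedigree(pedigree, keep)
    idx <- ped_index(ped2)
    A <- cpp_tabular_A(idx$sire, idx$dam)
    dimnames(A) <- list(ped2$id, ped2$id)
    j <- match(subset, ped2$id)
    return(A[j, j, drop = FALSE])
  }
  idx <- ped_index(pedigree)
  A <- cpp_tabular_A(idx$sire, idx$dam)
  dimnames(A) <- list(pedigree$id, pedigree$id)
  A
}

## ids of `subset` plus all their ancestors
ancestor_closure <- function(ped, subset) {
  idx <- ped_index(ped)
  keep <- logical(nrow(ped))
  keep[match(subset, ped$id)] <- TRUE
  for (i in rev(seq_len(nrow(ped)))) {
    if (keep[i]) {
      if (idx$sire[i] > 0L) keep[idx$sire[i]] <- TRUE
      if (idx$dam[i] > 0L) keep[idx$dam[i]] <- TRUE
    }
  }
  ped$id[keep]
}

## restrict a pedigree to `ids` (must be ancestor-closed), preserving order
prune_pedigree <- function(ped, ids) {
  out <- ped[ped$id %in% ids, , drop = FALSE]
  as_pedigree(out)
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Henderson's rules with inbreeding: each animal contributes
#' \eqn{\alpha_i = 1/d_i} to the inverse, where \eqn{d_i = 0.5 - 0.25(F_s +
#' F_d)} for two known parents, \eqn{0.75 - 0.25 F_p} for one, and 1 for
#' founders (the Mendelian-sampling variance coefficient).
#'
#' @param pedigree a [as_pedigree()] table.
#' @param F optional precomputed inbreeding coefficients (in pedigree order).
#' @return sparse symmetric \code{Matrix::dsCMatrix} with dimnames = ids.
#' @export
build_A_inverse <- function(pedigree, F = NULL) {
  pedigree <- as_pedigree(pedigree)
  idx <- ped_index(pedigree)
  n <- nrow(pedigree)
  if (is.null(F)) F <- cpp_inbreeding(idx$sire, idx$dam)
  Fs <- ifelse(idx$sire > 0L, F[pmax(idx$sire, 1L)], NA_real_)
  Fd <- ifelse(idx$dam > 0L, F[pmax(idx$dam, 1L)], NA_real_)
  d <- rep(1, n)
  both <- idx$sire > 0L & idx$dam > 0L
  sonly <- idx$sire > 0L & idx$dam == 0L
  donly <- idx$dam > 0L & idx$sire == 0L
  d[both] <- 0.5 - 0.25 * (Fs[both] + Fd[both])
  d[sonly] <- 0.75 - 0.25 * Fs[sonly]
  d[donly] <- 0.75 - 0.25 * Fd[donly]
  alpha <- 1 / d
  i <- seq_len(n)
  ti <- i; tj <- i; tx <- alpha
  for (p in c("sire", "dam")) {
    h <- idx[[p]] > 0L
    ti <- c(ti, i[h], idx[[p]][h])
    tj <- c(tj, idx[[p]][h], idx[[p]][h])
    tx <- c(tx, -alpha[h] / 2, alpha[h] / 4)
  }
  ti <- c(ti, idx$sire[both]); tj <- c(tj, idx$dam[both]); tx <- c(tx, alpha[both] / 4)
  keep_lower <- ti >= tj
  Ainv <- Matrix::sparseMatrix(
    i = c(ti[keep_lower], tj[!keep_lower]),
    j = c(tj[keep_lower], ti[!keep_lower]),
    x = c(tx[keep_lower], tx[!keep_lower]),
    dims = c(n, n), symmetric = TRUE,
    dimnames = list(pedigree$id, pedigree$id))
  Ainv
}

#' Within/between-cluster relationship statistics
#'
#' Summaries of a relationship matrix under a clustering of the animals:
#' per cluster, the mean inbreeding coefficient (\code{inBreC}), the mean over
#' animals of their maximum relationship to another animal in the same
#' cluster (\code{a_max_within}) and in any other cluster
#' (\code{a_max_between}), and the mean pairwise (off-diagonal) relationship
#' within (\code{a_ij_within}) and between (\code{a_ij_between}) clusters.
#' A final \code{Avg.} row holds the unweighted mean over clusters. The
#' self-relationship is excluded from all maxima and means; with a single
#' cluster the between-cluster columns are \code{NA}.
#'
#' @param A relationship matrix (dense, dimnames = ids) from [build_A()].
#' @param assignment cluster label per animal, in the order of \code{A}'s rows.
#' @return data frame with one row per cluster plus the \code{Avg.} row.
#' @export
cluster_relationship_stats <- function(A, assignment) {
  n <- nrow(A)
  stopifnot(length(assignment) == n)
  cl <- as.factor(assignment)
  k <- nlevels(cl)
  F <- diag(A) - 1
  offd <- A; diag(offd) <- NA_real_
  rows <- lapply(levels(cl), function(g) {
    inn <- which(cl == g); out <- which(cl != g)
    Ain <- offd[inn, inn, drop = FALSE]
    amax_w <- if (length(inn) > 1L) mean(apply(Ain, 1L, max, na.rm = TRUE)) else NA_real_
    aij_w <- if (length(inn) > 1L) mean(Ain[upper.tri(Ain)]) else NA_real_
    if (length(out) > 0L) {
      Abt <- A[inn, out, drop = FALSE]
      amax_b <- mean(apply(Abt, 1L, max))
      aij_b <- mean(Abt)
    } else amax_b <- aij_b <- NA_real_
    data.frame(cluster = g, n = length(inn), inBreC = mean(F[inn]),
               a_max_within = amax_w, a_max_between = amax_b,
               a_ij_within = aij_w, a_ij_between = aij_b,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  avg <- data.frame(cluster = "Avg.", n = NA_integer_,
                    inBreC = mean(out$inBreC),
                    a_max_within = mean(out$a_max_within),
                    a_max_between = mean(out$a_max_between),
                    a_ij_within = mean(out$a_ij_within),
                    a_ij_between = mean(out$a_ij_between),
                    stringsAsFactors = FALSE)
  rbind(out, avg)
}

#' Read / write pedigree CSV
#'
#' Columns \code{id,sire,dam,sex,parity,cg,litter} (extra columns preserved).
#' @param path file path.
#' @param pedigree a pedigree table.
#' @export
read_pedigree_csv <- function(path) {
  as_pedigree(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_pedigree_csv
#' @export
write_pedigree_csv <- function(pedigree, path) {
  utils::write.csv(as.data.frame(pedigree), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
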