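## Deregression of EBVs into the two genomic response variables (parent
## average excluded / included) with per-record weighting factors.
##
## The deregression solves, per animal, the 2x2 parent-average/individual
## mixed-model system for the information content of the animal's own data,
## removing both the shrinkage and the parent-average contribution from the
## EBV. With lambda = (1 - h2)/h2, alpha = 1/(0.5 - r2_PA) and
## delta = (0.5 - r2_PA)/(1 - r2):
##   Z'Z_PA = lambda * (0.5*alpha - 4) + 0.5*lambda*sqrt(alpha^2 + 16/delta)
##   Z'Z_i  = delta * Z'Z_PA + 2*lambda*(2*delta - 1)
## the right-hand sides come from applying the coefficient matrix
## [[Z'Z_PA + 4*lambda, -2*lambda], [-2*lambda, Z'Z_i + 2*lambda]] to
## (PA, EBV); DEBVexcPA = rhs_i / Z'Z_i and the deregressed reliability is
## r2_DEBV = 1 - lambda/(Z'Z_i + lambda).

#' Parent-average EBV and its reliability
#'
#' \code{PA = (EBV_sire + EBV_dam)/2}, \code{r2_PA = (r2_sire + r2_dam)/4};
#' an unknown parent contributes EBV 0 with reliability 0.
#'
#' @param ebv named numeric vector of EBVs (names = animal ids).
#' @param r2 named numeric vector of reliabilities, same ids.
#' @param pedigree a [as_pedigree()] table.
#' @param ids animals to evaluate (default: all ids in \code{ebv}).
#' @return data frame with id, pa, r2_pa.
#' @export
parent_average <- function(ebv, r2, pedigree, ids = names(ebv)) {
  pedigree <- as_pedigree(pedigree)
  look <- function(v, id) ifelse(id == 0L, 0,
                                 ifelse(is.na(v[as.character(id)]), 0,
                                        v[as.character(id)]))
  j <- match(as.integer(ids), pedigree$id)
  if (anyNA(j)) stop_ibwgp("id absent from pedigree")
  s <- pedigree$sire[j]; d <- pedigree$dam[j]
  data.frame(id = as.integer(ids),
             pa = (look(ebv, s) + look(ebv, d)) / 2,
             r2_pa = (look(r2, s) + look(r2, d)) / 4,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Deregress EBVs
#'
#' Produces DEBVexcPA (deregressed, parent-average information removed),
#' DEBVincPA (= DEBVexcPA + PA), the deregressed reliability, and the record
#' weight for the marker model. Records whose own reliability does not exceed
#' the parent-average reliability (no own information) are flagged and
#' excluded.
#'
#' @param ebv,r2 named vectors of EBV and reliability (names = ids).
#' @param pedigree pedigree for the parent averages.
#' @param h2 heritability of the trait under the evaluation model.
#' @param c_frac fraction of genetic variance not captured by markers used in
#'   the weighting factor (default 0.5).
#' @param ids animals to deregress (default all in \code{ebv}).
#' @return data frame of class \code{debv} with columns id, ebv, r2, pa,
#'   r2_pa, debv_exc_pa, debv_inc_pa, r2_debv, info (own-record information
#'   content), w, ok, reason.
#' @export
deregress_ebv <- function(ebv, r2, pedigree, h2, c_frac = 0.5,
                          ids = names(ebv)) {
  stopifnot(h2 > 0, h2 < 1)
  pa <- parent_average(ebv, r2, pedigree, ids)
  ebv_i <- unname(ebv[as.character(pa$id)])
  r2_i <- unname(r2[as.character(pa$id)])
  out <- data.frame(pa, ebv = ebv_i, r2 = r2_i)[
    , c("id", "ebv", "r2", "pa", "r2_pa")]
  n <- nrow(out)
  out$debv_exc_pa <- out$debv_inc_pa <- out$r2_debv <- out$w <- NA_real_
  out$info <- NA_real_  # own-record information content Z'Z_i (lambda units)
  out$ok <- TRUE; out$reason <- ""
  lambda <- (1 - h2) / h2
  for (i in seq_len(n)) {
    r2i <- out$r2[i]; r2pa <- out$r2_pa[i]
    if (!is.finite(r2i) || r2i >= 1 || r2i <= r2pa) {
      out$ok[i] <- FALSE
      out$reason[i] <- if (!is.finite(r2i)) "missing reliability"
                       else if (r2i >= 1) "reliability >= 1"
                       else "no own information (r2 <= r2_PA)"
      next
    }
    dr <- deregress_one(out$ebv[i], r2i, out$pa[i], r2pa, lambda)
    out$debv_exc_pa[i] <- dr$debv_exc_pa
    out$debv_inc_pa[i] <- dr$debv_exc_pa + out$pa[i]
    out$r2_debv[i] <- dr$r2_debv
    out$info[i] <- dr$zz_i
    out$w[i] <- weighting_factor(dr$r2_debv, h2, c_frac)
  }
  attr(out, "h2") <- h2
  attr(out, "c_frac") <- c_frac
  class(out) <- c("debv", class(out))
  out
}

## single-record deregression, Garrick-style 2x2 system
deregress_one <- function(ebv, r2, pa, r2_pa, lambda) {
  alpha <- 1 / (0.5 - r2_pa)
  delta <- (0.5 - r2_pa) / (1 - r2)
  zz_pa <- lambda * (0.5 * alpha - 4) +
    0.5 * lambda * sqrt(alpha^2 + 16 / delta)
  zz_i <- delta * zz_pa + 2 * lambda * (2 * delta - 1)
  rhs_i <- -2 * lambda * pa + (zz_i + 2 * lambda) * ebv
  list(debv_exc_pa = rhs_i / zz_i,
       r2_debv = 1 - lambda / (zz_i + lambda),
       zz_i = zz_i, zz_pa = zz_pa)
}

#' Weighting factor for deregressed records
#'
#' \eqn{w_i = (1 - h^2) / ((c + (1 - r^2_{DEBV})/r^2_{DEBV}) h^2)}: records
#' with more of their own information get more weight in the marker model;
#' \code{c} is the fraction of genetic variance not captured by markers.
#'
#' @param r2_debv deregressed reliability in (0, 1).
#' @param h2 heritability in (0, 1).
#' @param c_frac genomic-incompleteness fraction in [0, 1).
#' @return numeric weight(s).
#' @export
weighting_factor <- function(r2_debv, h2, c_frac = 0.5) {
  stopifnot(all(r2_debv > 0), h2 > 0, h2 < 1, c_frac >= 0, c_frac < 1)
  if (any(r2_debv >= 1) && c_frac == 0)
    stop_ibwgp("infinite weight: r2_debv = 1 with c = 0")
  (1 - h2) / ((c_frac + (1 - r2_debv) / r2_debv) * h2)
}

#' Drop deregressed records below a reliability threshold
#'
#' Records with deregressed reliability strictly below \code{threshold} (or
#' flagged invalid during deregression) are removed; counts are reported in
#' the \code{removal_report} attribute.
#'
#' @param records a [deregress_ebv()] table.
#' @param threshold minimum deregressed reliability (default 0.01; records
#'   exactly at the threshold are retained).
#' @return filtered table.
#' @export
filter_reliability <- function(records, threshold = 0.01) {
  bad_dereg <- !records$ok
  low <- records$ok & records$r2_debv < threshold
  out <- records[!(bad_dereg | low), , drop = FALSE]
  attr(out, "removal_report") <-
    data.frame(rule = c("failed_deregression", "low_reliability"),
               removed = c(sum(bad_dereg), sum(low)))
  attr(out, "h2") <- attr(records, "h2")
  out
}
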