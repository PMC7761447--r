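## REML animal models for birth weight: direct additive genetic effect with
## optional maternal genetic and common-litter effects, fitted against the
## pedigree numerator relationship matrix.
##
## The restricted likelihood is evaluated on a reduced system in which the
## breeding-value equations of non-parent animals are integrated out
## analytically (reduced animal model): a record on a non-parent contributes
## 0.5*u_sire + 0.5*u_dam to the linear predictor and its Mendelian-sampling
## variance d_i*sigma2_a is folded into the residual, so the coefficient
## matrix only spans parents + fixed effects + litters. This is an exact
## reparameterisation, not an approximation; BLUP solutions for all animals
## are recovered afterwards from the full mixed-model equations at the
## converged variance ratios.

#' Model specification for the animal-model ladder
#'
#' The four standard models: (1) direct only; (2) direct + maternal;
#' (3) direct + common litter; (4) direct + maternal + common litter.
#'
#' @param maternal include a maternal genetic effect (dam's breeding value).
#' @param litter include a common-litter environmental effect.
#' @return list of class \code{model_spec}.
#' @export
model_spec <- function(maternal = FALSE, litter = FALSE) {
  structure(list(maternal = maternal, litter = litter), class = "model_spec")
}

#' @rdname model_spec
#' @param eq model number 1-4.
#' @export
eq_model <- function(eq) {
  stopifnot(eq %in% 1:4)
  switch(eq,
         model_spec(FALSE, FALSE), model_spec(TRUE, FALSE),
         model_spec(FALSE, TRUE), model_spec(TRUE, TRUE))
}

#' Build the mixed-model design for a phenotype table
#'
#' Constructs the full-rank fixed-effects matrix from \code{formula} (aliased
#' columns dropped via QR, as in \code{lm}) and the record-to-animal,
#' record-to-dam and record-to-litter index maps. Each record's animal and
#' (when maternal is on) dam must be present in the pedigree.
#'
#' @param formula fixed-effects formula, e.g.
#'   \code{ibw_kg ~ factor(sex) + factor(parity) + factor(cg) + litter_size}.
#' @param data phenotype data frame with an \code{id} column (and
#'   \code{litter} when the litter effect is on).
#' @param pedigree a [as_pedigree()] table.
#' @param spec a [model_spec()].
#' @return list with the response, X, index maps and bookkeeping.
#' @export
build_design <- function(formula, data, pedigree, spec = model_spec()) {
  pedigree <- as_pedigree(pedigree)
  stopifnot(inherits(spec, "model_spec"), "id" %in% names(data))
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    X <- X[, sort(keep), drop = FALSE]
  }
  ai <- match(data$id, pedigree$id)
  if (anyNA(ai)) stop_ibwgp("phenotyped animal absent from pedigree")
  if (anyDuplicated(data$id)) stop_ibwgp("duplicate phenotype records per animal")
  idx <- ped_index(pedigree)
  di <- idx$dam[ai]
  if (spec$maternal && any(di == 0L))
    stop_ibwgp("record with unknown dam under a maternal-effect model")
  lit <- NULL
  if (spec$litter) {
    if (!"litter" %in% names(data)) stop_ibwgp("litter column required")
    lit <- as.integer(factor(data$litter))
  }
  list(y = as.numeric(y), X = X, animal = ai, dam = di, litter = lit,
       n = length(y), p = ncol(X), spec = spec, pedigree = pedigree,
       formula = formula)
}

## ---- absorbed-system likelihood machinery ---------------------------------

## Precompute everything that does not depend on the variance ratios.
absorbed_system <- function(design) {
  ped <- design$pedigree
  idx <- ped_index(ped)
  n_all <- nrow(ped)
  F <- cpp_inbreeding(idx$sire, idx$dam)
  is_parent <- logical(n_all)
  is_parent[idx$sire[idx$sire > 0L]] <- TRUE
  is_parent[idx$dam[idx$dam > 0L]] <- TRUE
  kept <- which(is_parent)
  kidx <- integer(n_all); kidx[kept] <- seq_along(kept)
  qK <- length(kept)

  spec <- design$spec
  np <- design$n
  ai <- design$animal
  ## direct-effect incidence: kept animals link to themselves, absorbed
  ## records to their known parents with coefficient 1/2
  d <- numeric(np)
  ti <- integer(0); tj <- integer(0); tx <- numeric(0)
  for (r in seq_len(np)) {
    a <- ai[r]
    if (is_parent[a]) {
      ti <- c(ti, r); tj <- c(tj, kidx[a]); tx <- c(tx, 1)
    } else {
      s <- idx$sire[a]; dd <- idx$dam[a]
      dr <- 1
      if (s > 0L) { ti <- c(ti, r); tj <- c(tj, kidx[s]); tx <- c(tx, 0.5)
        dr <- dr - 0.25 * (1 + F[s]) }
      if (dd > 0L) { ti <- c(ti, r); tj <- c(tj, kidx[dd]); tx <- c(tx, 0.5)
        dr <- dr - 0.25 * (1 + F[dd]) }
      d[r] <- dr
    }
  }
  Za <- Matrix::sparseMatrix(i = ti, j = tj, x = tx, dims = c(np, max(qK, 1L)))
  if (qK == 0L) Za <- NULL

  blocks <- list(Matrix::Matrix(design$X, sparse = TRUE))
  if (!is.null(Za)) blocks <- c(blocks, list(Za))
  AinvK <- NULL; ldetAK <- 0
  if (qK > 0L) {
    pedK <- prune_pedigree(ped, ped$id[kept])
    AinvK <- build_A_inverse(pedK)
    ch <- Matrix::Cholesky(AinvK, LDL = TRUE, perm = TRUE)
    ldetAK <- -as.numeric(Matrix::determinant(ch, sqrt = FALSE)$modulus)
  }
  if (spec$maternal) {
    if (qK == 0L) stop_ibwgp("maternal model needs at least one dam in the pedigree")
    Zm <- Matrix::sparseMatrix(i = seq_len(np), j = kidx[design$dam],
                               dims = c(np, qK))
    blocks <- c(blocks, list(Zm))
  }
  nl <- 0L
  if (spec$litter) {
    nl <- max(design$litter)
    W <- Matrix::sparseMatrix(i = seq_len(np), j = design$litter,
                              dims = c(np, nl))
    blocks <- c(blocks, list(W))
  }
  T <- do.call(cbind, blocks)
  p <- design$p
  ncols <- ncol(T)
  ## padded G-inverse skeletons
  pad <- function(M, offset) {
    tm <- as(as(M, "generalMatrix"), "TsparseMatrix")
    Matrix::sparseMatrix(i = tm@i + 1L + offset, j = tm@j + 1L + offset,
                         x = tm@x, dims = c(ncols, ncols))
  }
  Ga <- if (qK > 0L) pad(AinvK, p) else NULL
  Gm <- if (spec$maternal) pad(AinvK, p + qK) else NULL
  Gc <- if (spec$litter)
    pad(Matrix::Diagonal(nl), p + qK * (1L + spec$maternal)) else NULL
  ## tiny ridge on any all-zero diagonal entries never occurs: every column of
  ## T has support or belongs to a G block.
  list(T = T, d = d, y = design$y, p = p, np = np, qK = qK, nl = nl,
       Ga = Ga, Gm = Gm, Gc = Gc, ldetAK = ldetAK, spec = design$spec,
       kept = kept, F = F)
}

## -2 * restricted log-likelihood at variance ratios gamma (named) and
## residual variance sigma2e (NULL = profiled out).
neg2_reml <- function(sys, gamma, sigma2e = NULL, env = NULL) {
  w <- 1 / (1 + sys$d * gamma[["direct"]])
  Tw <- Matrix::Diagonal(x = w) %*% sys$T
  C <- Matrix::forceSymmetric(Matrix::crossprod(sys$T, Tw))
  ldetG <- 0
  if (!is.null(sys$Ga)) {
    C <- C + sys$Ga / gamma[["direct"]]
    ldetG <- ldetG + sys$qK * log(gamma[["direct"]]) + sys$ldetAK
  }
  if (sys$spec$maternal) {
    C <- C + sys$Gm / gamma[["maternal"]]
    ldetG <- ldetG + sys$qK * log(gamma[["maternal"]]) + sys$ldetAK
  }
  if (sys$spec$litter) {
    C <- C + sys$Gc / gamma[["litter"]]
    ldetG <- ldetG + sys$nl * log(gamma[["litter"]])
  }
  C <- as(Matrix::forceSymmetric(C), "CsparseMatrix")
  ch <- NULL
  if (!is.null(env)) {
    if (is.null(env$ch)) env$ch <- Matrix::Cholesky(C, LDL = TRUE, perm = TRUE,
                                                    super = FALSE)
    else env$ch <- Matrix::update(env$ch, C)
    ch <- env$ch
  } else ch <- Matrix::Cholesky(C, LDL = TRUE, perm = TRUE, super = FALSE)
  ldetC <- as.numeric(Matrix::determinant(ch, sqrt = FALSE)$modulus)
  rhs <- Matrix::crossprod(sys$T, w * sys$y)
  sol <- Matrix::solve(ch, rhs)
  ypy <- sum(w * sys$y^2) - sum(sol * rhs)
  nmp <- sys$np - sys$p
  if (ypy <= 0) return(list(value = Inf))
  if (is.null(sigma2e)) {
    sigma2e <- ypy / nmp
    quad <- nmp
  } else quad <- ypy / sigma2e
  val <- nmp * (log(2 * pi) + log(sigma2e)) + quad -
    sum(log(w)) + ldetG + ldetC
  list(value = val, sigma2e = sigma2e, sol = sol, ch = ch, w = w)
}

#' Fit an animal model by REML
#'
#' Variance components for the direct additive genetic effect and, per
#' \code{spec}, maternal genetic and common-litter effects, estimated by
#' maximising the profiled restricted log-likelihood over log variance ratios
#' (L-BFGS-B), with the likelihood evaluated on the absorbed (reduced animal
#' model) system. Reported \code{logLik} is the full REML log-likelihood
#' including all constants, so differences between nested models are
#' likelihood-ratio statistics. Standard errors come from the numerical
#' observed-information matrix at the optimum; the heritability SE by the
#' delta method.
#'
#' @param formula fixed-effects formula (see [build_design()]).
#' @param data phenotype data frame with \code{id} (and \code{litter}) columns.
#' @param pedigree a [as_pedigree()] table.
#' @param spec a [model_spec()]; default the direct-only model.
#' @param start optional named start values for the variance ratios.
#' @param se compute SEs (numerical Hessian; a few extra likelihood
#'   evaluations). Default TRUE.
#' @param tol relative convergence tolerance passed to the optimizer.
#' @param blup solve the full mixed-model equations for fixed-effect and
#'   breeding-value solutions (default TRUE).
#' @return object of class \code{reml_animal}: variance components
#'   (\code{$varcomp}, kg^2), \code{$h2}, \code{$h2_se}, \code{$logLik},
#'   solutions (\code{$fixef}, \code{$ebv}, \code{$maternal_ebv},
#'   \code{$litter_effects}), convergence metadata, and the design/pedigree
#'   needed by downstream stages.
#' @export
reml_animal <- function(formula, data, pedigree, spec = model_spec(),
                        start = NULL, se = TRUE, tol = 1e-8, blup = TRUE) {
  design <- build_design(formula, data, pedigree, spec)
  sys <- absorbed_system(design)
  terms <- c("direct",
             if (spec$maternal) "maternal",
             if (spec$litter) "litter")
  g0 <- c(direct = 0.5, maternal = 0.5, litter = 0.5)[terms]
  if (!is.null(start)) g0[names(start)] <- start
  env <- new.env()
  obj <- function(lg) {
    g <- stats::setNames(exp(lg), terms)
    neg2_reml(sys, g, env = env)$value
  }
  opt <- stats::optim(log(g0), obj, method = "L-BFGS-B",
                      lower = rep(log(1e-6), length(terms)),
                      upper = rep(log(1e4), length(terms)),
                      control = list(factr = tol / .Machine$double.eps,
                                     maxit = 200L))
  gamma <- stats::setNames(exp(opt$par), terms)
  fin <- neg2_reml(sys, gamma, env = env)
  sigma2e <- fin$sigma2e
  vc <- c(gamma * sigma2e, residual = sigma2e)
  boundary <- gamma <= 1.5e-6
  names(boundary) <- terms

  vcov_vc <- NULL; h2_se <- NA_real_
  if (se) {
    theta <- vc
    f <- function(th) {
      g <- stats::setNames(th[terms] / th[["residual"]], terms)
      neg2_reml(sys, g, sigma2e = th[["residual"]], env = env)$value
    }
    ## retry with a coarser step if the finite-difference Hessian comes out
    ## indefinite (can happen when a component sits near its boundary)
    for (step in c(1e-4, 1e-3)) {
      H <- num_hessian(f, theta, rel = step)
      vcov_try <- tryCatch(2 * solve(H), error = function(e) NULL)
      if (is.null(vcov_try)) next
      S <- sum(theta)
      gr <- -theta[["direct"]] / S^2 + (names(theta) == "direct") / S
      q <- drop(t(gr) %*% vcov_try %*% gr)
      if (is.finite(q) && q > 0 && all(diag(vcov_try) > 0)) {
        dimnames(vcov_try) <- list(names(theta), names(theta))
        vcov_vc <- vcov_try
        h2_se <- sqrt(q)
        break
      }
    }
  }

  fit <- list(varcomp = vc, gamma = gamma, sigma2p = sum(vc),
              h2 = vc[["direct"]] / sum(vc), h2_se = h2_se,
              vcov_varcomp = vcov_vc,
              logLik = -fin$value / 2, n = design$n, p = design$p,
              converged = opt$convergence == 0L, boundary = boundary,
              optim = opt[c("convergence", "counts", "message")],
              spec = spec, formula = formula, design = design,
              F = sys$F)
  class(fit) <- "reml_animal"
  if (blup) fit <- add_blup(fit)
  fit
}

## central-difference Hessian with relative steps
num_hessian <- function(f, x, rel = 1e-4) {
  k <- length(x)
  h <- pmax(abs(x) * rel, 1e-9)
  H <- matrix(0, k, k)
  f0 <- f(x)
  for (i in seq_len(k)) {
    ei <- replace(numeric(k), i, h[i])
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / h[i]^2
    if (i < k) for (j in (i + 1L):k) {
      ej <- replace(numeric(k), j, h[j])
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
        (4 * h[i] * h[j])
    }
  }
  H
}

## full mixed-model equations at the converged ratios: solutions for every
## animal, stored together with the coefficient matrix for later PEV work
add_blup <- function(fit) {
  design <- fit$design
  ped <- design$pedigree
  spec <- fit$spec
  np <- design$n; n_all <- nrow(ped); p <- design$p
  X <- Matrix::Matrix(design$X, sparse = TRUE)
  Za <- Matrix::sparseMatrix(i = seq_len(np), j = design$animal,
                             dims = c(np, n_all))
  blocks <- list(X, Za)
  Ainv <- build_A_inverse(ped)
  if (spec$maternal)
    blocks <- c(blocks, list(Matrix::sparseMatrix(
      i = seq_len(np), j = design$dam, dims = c(np, n_all))))
  nl <- if (spec$litter) max(design$litter) else 0L
  if (spec$litter)
    blocks <- c(blocks, list(Matrix::sparseMatrix(
      i = seq_len(np), j = design$litter, dims = c(np, nl))))
  T <- do.call(cbind, blocks)
  ncols <- ncol(T)
  pad <- function(M, offset) {
    tm <- as(as(M, "generalMatrix"), "TsparseMatrix")
    Matrix::sparseMatrix(i = tm@i + 1L + offset, j = tm@j + 1L + offset,
                         x = tm@x, dims = c(ncols, ncols))
  }
  C <- Matrix::forceSymmetric(Matrix::crossprod(T)) +
    pad(Ainv, p) / fit$gamma[["direct"]]
  if (spec$maternal) C <- C + pad(Ainv, p + n_all) / fit$gamma[["maternal"]]
  if (spec$litter)
    C <- C + pad(Matrix::Diagonal(nl),
                 p + n_all * (1L + spec$maternal)) / fit$gamma[["litter"]]
  rhs <- Matrix::crossprod(T, design$y)
  ch <- Matrix::Cholesky(as(Matrix::forceSymmetric(C), "CsparseMatrix"), LDL = TRUE, perm = TRUE)
  sol <- as.numeric(Matrix::solve(ch, rhs))
  fit$fixef <- stats::setNames(sol[seq_len(p)], colnames(design$X))
  fit$ebv <- stats::setNames(sol[p + seq_len(n_all)], ped$id)
  off <- p + n_all
  if (spec$maternal) {
    fit$maternal_ebv <- stats::setNames(sol[off + seq_len(n_all)], ped$id)
    off <- off + n_all
  }
  if (spec$litter) fit$litter_effects <- sol[off + seq_len(nl)]
  fit$mme <- list(C = C, rhs = rhs, T = T, p = p, n_all = n_all, sol = sol)
  fit$fitted <- as.numeric(T %*% sol)
  fit
}

#' Prediction error variance and reliability of EBVs
#'
#' \eqn{r^2_i = 1 - PEV_i / ((1 + F_i)\sigma^2_a)}, clipped to [0, 1); PEV
#' from the corresponding diagonal entries of the inverse coefficient matrix
#' (obtained by sparse column solves for the requested animals only).
#'
#' @param fit a [reml_animal()] fit (with \code{blup = TRUE}).
#' @param ids animal ids to evaluate (default: all phenotyped animals).
#' @return data frame with id, ebv, pev, F and reliability \code{r2}.
#' @export
reliability <- function(fit, ids = NULL) {
  stopifnot(inherits(fit, "reml_animal"), !is.null(fit$mme))
  sigma2a <- fit$varcomp[["direct"]]
  if (sigma2a <= 0) stop_ibwgp("direct genetic variance is zero")
  ped <- fit$design$pedigree
  if (is.null(ids)) ids <- ped$id[fit$design$animal]
  j <- match(ids, ped$id)
  if (anyNA(j)) stop_ibwgp("id absent from pedigree")
  cols <- fit$mme$p + j
  nc <- ncol(fit$mme$C)
  ch <- Matrix::Cholesky(as(fit$mme$C, "CsparseMatrix"), LDL = TRUE, perm = TRUE)
  E <- Matrix::sparseMatrix(i = cols, j = seq_along(cols),
                            dims = c(nc, length(cols)))
  Cinv_cols <- Matrix::solve(ch, E)
  pev <- fit$varcomp[["residual"]] *
    vapply(seq_along(cols), function(k) Cinv_cols[cols[k], k], numeric(1))
  F <- fit$F[j]
  r2 <- pmin(pmax(1 - pev / ((1 + F) * sigma2a), 0), 1 - 1e-12)
  data.frame(id = ids, ebv = fit$ebv[as.character(ids)], pev = pev, F = F,
             r2 = r2, row.names = NULL, stringsAsFactors = FALSE)
}

#' Likelihood-ratio comparison of nested animal models
#'
#' Reports both the raw log-likelihood difference \eqn{\Delta LogL =
#' LogL_{full} - LogL_{reduced}} and the chi-square statistic
#' \eqn{2\Delta LogL} with its p-value on \code{df} degrees of freedom
#' (df = number of extra variance components; no boundary mixture
#' correction).
#'
#' @param reduced,full fitted [reml_animal()] objects or plain log-likelihood
#'   values.
#' @param df degrees of freedom; inferred from the model specs when both
#'   arguments are fits.
#' @param tol tolerance for a negative \eqn{\Delta LogL} before erroring.
#' @return data frame with delta_logl, chisq, df, p_value.
#' @export
lrt <- function(reduced, full, df = NULL, tol = 1e-3) {
  ll <- function(x) if (inherits(x, "reml_animal")) x$logLik else as.numeric(x)
  nterms <- function(x) 1L + x$spec$maternal + x$spec$litter
  if (is.null(df)) {
    if (inherits(reduced, "reml_animal") && inherits(full, "reml_animal"))
      df <- nterms(full) - nterms(reduced)
    else stop_ibwgp("df must be given when comparing raw log-likelihoods")
  }
  delta <- ll(full) - ll(reduced)
  if (delta < -tol)
    stop_ibwgp("full model has lower log-likelihood (%.4f): non-nested or non-converged",
               delta)
  chisq <- 2 * max(delta, 0)
  p <- if (df > 0) stats::pchisq(chisq, df, lower.tail = FALSE) else NA_real_
  data.frame(delta_logl = delta, chisq = chisq, df = df, p_value = p)
}

#' Direct heritability
#'
#' \eqn{h^2 = \sigma^2_a / \sigma^2_p} with \eqn{\sigma^2_p} the sum of all
#' fitted components.
#'
#' @param x a [reml_animal()] fit, or a named numeric vector of variance
#'   components containing \code{direct} (others summed into the phenotypic
#'   variance).
#' @return list with \code{h2} and \code{se} (SE is NA for plain vectors).
#' @export
heritability <- function(x) {
  if (inherits(x, "reml_animal"))
    return(list(h2 = x$h2, se = x$h2_se))
  stopifnot(is.numeric(x), "direct" %in% names(x))
  s <- sum(x, na.rm = TRUE)
  if (s <= 0) stop_ibwgp("phenotypic variance is zero")
  list(h2 = unname(x[["direct"]] / s), se = NA_real_)
}

## ---- methods ---------------------------------------------------------------

#' @exportS3Method print reml_animal
print.reml_animal <- function(x, ...) {
  eff <- c("direct", if (x$spec$maternal) "maternal",
           if (x$spec$litter) "litter")
  cat("REML animal model (", paste(eff, collapse = " + "),
      " + residual), n = ", x$n, "\n", sep = "")
  print(round(x$varcomp, 5))
  cat(sprintf("h2 = %.3f (SE %.3f), logLik = %.2f, %s\n", x$h2,
              x$h2_se, x$logLik,
              if (x$converged) "converged" else "NOT converged"))
  if (any(x$boundary)) cat("component at zero boundary:",
                           names(x$boundary)[x$boundary], "\n")
  invisible(x)
}

#' @exportS3Method summary reml_animal
summary.reml_animal <- function(object, ...) {
  se <- if (!is.null(object$vcov_varcomp))
    sqrt(pmax(diag(object$vcov_varcomp), 0)) else rep(NA_real_, length(object$varcomp))
  out <- data.frame(component = names(object$varcomp),
                    estimate = unname(object$varcomp), se = unname(se))
  structure(list(varcomp = out, h2 = object$h2, h2_se = object$h2_se,
                 logLik = object$logLik, n = object$n,
                 converged = object$converged),
            class = "summary.reml_animal")
}

#' @exportS3Method print summary.reml_animal
print.summary.reml_animal <- function(x, ...) {
  print(x$varcomp, row.names = FALSE)
  cat(sprintf("sigma2_p = %.5f, h2 = %.3f (SE %.3f), logLik = %.2f (n = %d)\n",
              sum(x$varcomp$estimate), x$h2, x$h2_se, x$logLik, x$n))
  invisible(x)
}

#' @exportS3Method coef reml_animal
coef.reml_animal <- function(object, ...) object$fixef

#' @exportS3Method logLik reml_animal
logLik.reml_animal <- function(object, ...) {
  structure(object$logLik, df = length(object$varcomp) + object$p,
            class = "logLik")
}

#' Breeding values and other random-effect solutions
#' @param object a [reml_animal()] fit.
#' @param effect which random effect to return.
#' @param ... unused.
#' @exportS3Method ranef reml_animal
ranef.reml_animal <- function(object,
                              effect = c("direct", "maternal", "litter"),
                              ...) {
  effect <- match.arg(effect)
  switch(effect, direct = object$ebv, maternal = object$maternal_ebv,
         litter = object$litter_effects)
}

#' @rdname ranef.reml_animal
#' @export
ranef <- function(object, ...) UseMethod("ranef")

#' @exportS3Method fitted reml_animal
fitted.reml_animal <- function(object, ...) object$fitted

#' @exportS3Method residuals reml_animal
residuals.reml_animal <- function(object, ...) object$design$y - object$fitted

#' Variance-component table in the shape of a model-comparison report
#'
#' One row per fitted model with components, heritability, logLik, the
#' log-likelihood difference to the fullest model, the chi-square statistic
#' and its p-value.
#'
#' @param fits named list of [reml_animal()] fits (the last one is taken as
#'   the full model).
#' @return data frame, one row per model.
#' @export
varcomp_table <- function(fits) {
  full <- fits[[length(fits)]]
  rows <- lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    cmp <- if (i < length(fits)) lrt(f, full) else
      data.frame(delta_logl = NA_real_, chisq = NA_real_, df = NA_integer_,
                 p_value = NA_real_)
    data.frame(model = names(fits)[i] %||% paste0("model", i),
               sigma2_a = f$varcomp[["direct"]],
               sigma2_m = if (f$spec$maternal) f$varcomp[["maternal"]] else NA,
               sigma2_c = if (f$spec$litter) f$varcomp[["litter"]] else NA,
               sigma2_e = f$varcomp[["residual"]],
               sigma2_p = sum(f$varcomp),
               h2 = f$h2, h2_se = f$h2_se, logLik = f$logLik,
               delta_logl = cmp$delta_logl, chisq = cmp$chisq,
               p_value = cmp$p_value, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
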