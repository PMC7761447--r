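## Small pedigrees and panels built in code, shared across test files.

## founders S(1) D(2); full sibs 3,4; 5 = offspring of full-sib mating; 6 from 5 x 4
fix_ped6 <- function() {
  as_pedigree(data.frame(id = 1:6, sire = c(0, 0, 1, 1, 3, 5),
                         dam = c(0, 0, 2, 2, 4, 4)))
}

## random valid pedigree: founders then offspring with parents drawn earlier
fix_random_ped <- function(n, n_founders = 10, seed = 1) {
  set.seed(seed)
  sire <- dam <- integer(n)
  sex <- c(rep(1:2, length.out = n_founders),
           sample(1:2, n - n_founders, replace = TRUE))
  for (i in (n_founders + 1):n) {
    males <- which(sex[1:(i - 1)] == 1L); females <- which(sex[1:(i - 1)] == 2L)
    sire[i] <- if (length(males)) sample(males, 1) else 0L
    dam[i] <- if (length(females)) sample(females, 1) else 0L
  }
  as_pedigree(data.frame(id = seq_len(n), sire = sire, dam = dam, sex = sex))
}

## small raw genotype panel with controllable missingness
fix_panel <- function(n = 6, m = 10, seed = 1, chr = NULL, pos = NULL) {
  set.seed(seed)
  g <- matrix(sample(0:2, n * m, replace = TRUE), n, m,
              dimnames = list(seq_len(n), paste0("S", seq_len(m))))
  map <- data.frame(snp = colnames(g),
                    chr = chr %||% rep(1L, m),
                    pos = pos %||% seq_len(m) * 1000L)
  genotype_panel(g, map)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## simulated dataset for model-fitting tests
fix_simdata <- function(n_founders = 30, gens = 3, litter = 4, seed = 2,
                        panel = NULL, ...) {
  cfg <- sim_config(n_founders = n_founders, n_generations = gens,
                    litter_size_mean = litter, seed = seed, panel = panel, ...)
  ped <- simulate_pedigree(cfg)
  gen <- if (!is.null(panel)) simulate_genotypes(ped, cfg)
  phen <- simulate_phenotypes(ped, gen, cfg)
  list(cfg = cfg, ped = ped, gen = gen, phen = phen)
}

## dense REML -2logL oracle built directly from V = sum_i theta_i Z_i A_i Z_i'
dense_neg2_reml <- function(theta, design, A) {
  n <- design$n
  X <- design$X; y <- design$y
  V <- theta[["residual"]] * diag(n)
  Za <- matrix(0, n, nrow(A)); Za[cbind(seq_len(n), design$animal)] <- 1
  V <- V + theta[["direct"]] * Za %*% A %*% t(Za)
  if (!is.null(design$dam) && "maternal" %in% names(theta)) {
    Zm <- matrix(0, n, nrow(A)); Zm[cbind(seq_len(n), design$dam)] <- 1
    V <- V + theta[["maternal"]] * Zm %*% A %*% t(Zm)
  }
  if (!is.null(design$litter) && "litter" %in% names(theta)) {
    W <- matrix(0, n, max(design$litter))
    W[cbind(seq_len(n), design$litter)] <- 1
    V <- V + theta[["litter"]] * W %*% t(W)
  }
  cV <- chol(V); Vi <- chol2inv(cV)
  XVX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XVX, t(X) %*% Vi)
  as.numeric(2 * sum(log(diag(cV))) + determinant(XVX)$modulus +
               t(y) %*% P %*% y + (n - ncol(X)) * log(2 * pi))
}

## two unrelated families: founders + offspring, no cross-family matings
two_family_ped <- function(per_family = 50, seed = 61) {
  set.seed(seed)
  rows <- list()
  nid <- 0L
  for (fam in 1:2) {
    f <- data.frame(id = nid + 1:10, sire = 0L, dam = 0L,
                    sex = rep(1:2, 5))
    sires <- f$id[f$sex == 1]; dams <- f$id[f$sex == 2]
    off <- data.frame(id = nid + 10L + seq_len(per_family - 10),
                      sire = sample(sires, per_family - 10, TRUE),
                      dam = sample(dams, per_family - 10, TRUE),
                      sex = sample(1:2, per_family - 10, TRUE))
    rows[[fam]] <- rbind(f, off)
    nid <- nid + per_family
  }
  as_pedigree(do.call(rbind, rows))
}
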