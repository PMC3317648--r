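# Independent oracles used across the suite.

# Monte-Carlo gene-dropping estimate of pairwise kinship: founders get two
# uniquely labelled alleles, every child inherits one random allele from
# each parent, and Phi_ij is estimated as the probability that one allele
# drawn from i matches one drawn from j.  Independent of the package's
# recursive computation.
gene_drop_kinship <- function(ped, ndrops = 20000) {
  n <- nrow(ped)
  A <- vector("list", n); B <- vector("list", n)
  idx <- stats::setNames(seq_len(n), ped$individual_id)
  lab <- 0L
  for (i in seq_len(n)) {
    if (is.na(ped$father_id[i])) {
      A[[i]] <- rep(lab + 1L, ndrops)
      B[[i]] <- rep(lab + 2L, ndrops)
      lab <- lab + 2L
    } else {
      f <- idx[[ped$father_id[i]]]; m <- idx[[ped$mother_id[i]]]
      pick <- stats::runif(ndrops) < 0.5
      A[[i]] <- ifelse(pick, A[[f]], B[[f]])
      pick <- stats::runif(ndrops) < 0.5
      B[[i]] <- ifelse(pick, A[[m]], B[[m]])
    }
  }
  phi <- matrix(0, n, n,
                dimnames = list(ped$individual_id, ped$individual_id))
  for (i in seq_len(n)) for (j in seq_len(i)) {
    phi[i, j] <- phi[j, i] <-
      mean((A[[i]] == A[[j]]) + (A[[i]] == B[[j]]) +
             (B[[i]] == A[[j]]) + (B[[i]] == B[[j]])) / 4
  }
  phi
}

# Whole-matrix multivariate-normal log-likelihood, built from scratch in
# R: assembles the full covariance sigma_q*Pi + sigma_g*2*Phi + sigma_e*I
# over all individuals at once and evaluates the density by Cholesky.
mvn_loglik_whole <- function(y, X, beta, sigma2, Phi, Pi = NULL) {
  n <- length(y)
  V <- diag(sigma2[["sigma2_e"]], n)
  if (!is.null(Phi)) V <- V + sigma2[["sigma2_g"]] * 2 * Phi
  if (!is.null(Pi)) V <- V + sigma2[["sigma2_q"]] * Pi
  L <- chol(V)
  e <- y - drop(X %*% beta)
  z <- backsolve(L, e, transpose = TRUE)
  -0.5 * (n * log(2 * pi) + 2 * sum(log(diag(L))) + sum(z^2))
}

# Direct transcription of the LD pruning rule for small sets: sweep pairs
# in ascending position order over a precomputed r2 matrix, remove the
# higher-missingness member (ties: higher position), restart until clean.
prune_rule_reference <- function(R2, miss) {
  k <- nrow(R2)
  alive <- rep(TRUE, k)
  repeat {
    hit <- FALSE
    for (i in seq_len(k - 1)) {
      if (!alive[i]) next
      for (j in (i + 1):k) {
        if (!alive[j]) next
        if (R2[i, j] > 0.7) {
          if (miss[j] > miss[i] || miss[j] == miss[i]) alive[j] <- FALSE
          else alive[i] <- FALSE
          hit <- TRUE
          break
        }
      }
      if (hit) break
    }
    if (!hit) break
  }
  which(alive)
}

# small nuclear-family pedigree records, used all over
nuclear_records <- function(n_fam, n_sib = 3) {
  do.call(rbind, lapply(seq_len(n_fam), function(f) {
    fid <- sprintf("F%03d", f)
    data.frame(
      fam = fid,
      id = paste0(fid, "-", seq_len(2 + n_sib)),
      fa = c("0", "0", rep(paste0(fid, "-1"), n_sib)),
      mo = c("0", "0", rep(paste0(fid, "-2"), n_sib)),
      sex = c(1, 2, rep(0, n_sib)))
  }))
}

# fully aligned small analysis set straight from the generator; small
# panels need proportionally few causal variants
small_aset <- function(seed, n_families = 120, n_snps = 40,
                       n_causal = 4, causal_share_total = 0.15,
                       cluster_fraction = 1, ...) {
  cfg <- sim_config(n_families = n_families, n_snps = n_snps,
                    n_causal = n_causal,
                    causal_share_total = causal_share_total,
                    cluster_fraction = cluster_fraction, ...)
  co <- simulate_cohort(cfg, seed = seed)
  phen <- prepare_phenotype(co$phen)
  aset <- align_datasets(co$ped, phen, co$geno, co$map, co$ibd,
                         kinship = co$kinship)
  list(aset = aset, cohort = co)
}
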