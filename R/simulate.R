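#' Configuration for the synthetic family cohort
#'
#' Bundles every knob of the synthetic-data generator.  The defaults
#' emulate a lipid family study: ~400 families of mean size 5 (range
#' roughly 3--27), a 5 Mb region carrying five gene clusters of high LD,
#' 1,048 tag SNPs of which ~31\% fall inside the gene windows, an
#' ln-triglyceride-like trait with mean 4.71 and SD 0.53, a locus
#' (QTL) variance share of 0.26 spread over 13 clustered causal variants
#' of ~2\% each, a small polygenic background, and ~5\% of variance from
#' standard covariates.
#'
#' @param n_families number of families.
#' @param sibship_lambda Poisson rate of the zero-truncated sibship-size
#'   law; 2.03 calibrates the mean total family size to ~5.0 together with
#'   \code{p_extend}.
#' @param sibship_cap upper truncation of sibship size.
#' @param p_extend probability that a family gains a third generation (one
#'   sib marries in a founder spouse and has a sibship of its own).
#' @param region_length region span in base pairs.
#' @param n_genes number of gene clusters.
#' @param gene_length gene span in base pairs.
#' @param window_pad padding added up- and downstream of a gene when
#'   defining its cluster window (10 kb).
#' @param n_snps total SNP panel size.
#' @param cluster_fraction fraction of the panel placed inside gene
#'   windows (default 324/1048, the rest uniform across the region).
#' @param pool_size founder-haplotype pool size per cluster; smaller pools
#'   give stronger within-cluster LD.
#' @param haplotype_noise per-SNP probability that a founder's
#'   cluster-haplotype allele is flipped relative to its pool haplotype
#'   (recent variation).  Keeps the r-squared block structure while
#'   preventing the founder genotype matrix from being exactly low-rank,
#'   which a finite haplotype pool would otherwise force.
#' @param n_causal number of causal variants, spread round-robin over the
#'   clusters.
#' @param causal_share_total total trait-variance fraction carried by the
#'   causal variants (the locus-specific share the linkage scan should
#'   recover).
#' @param h2_polygenic polygenic trait-variance fraction.
#' @param covariate_share trait-variance fraction explained by the
#'   covariates.
#' @param trait_mean,trait_sd ln-scale trait mean and SD.
#' @param missingness per-SNP probability that a genotype is missing.
#' @param cm_per_mb recombination rate (Haldane map function).
#' @param p_male probability that a non-structural individual is male.
#' @return object of class \code{sim_config}.
#' @export
sim_config <- function(n_families = 400,
                       sibship_lambda = 2.03, sibship_cap = 12,
                       p_extend = 0.2,
                       region_length = 5e6, n_genes = 5,
                       gene_length = 1e5, window_pad = 1e4,
                       n_snps = 1048, cluster_fraction = 324 / 1048,
                       pool_size = 6, haplotype_noise = 0.005,
                       n_causal = 13, causal_share_total = 0.26,
                       h2_polygenic = 0.10, covariate_share = 0.05,
                       trait_mean = 4.71, trait_sd = 0.53,
                       missingness = 0.004,
                       cm_per_mb = 1, p_male = 0.235) {
  if (causal_share_total + h2_polygenic + covariate_share >= 1)
    stop("variance shares (locus + polygenic + covariates) must sum below 1")
  if (n_families < 1L) stop("n_families must be at least 1")
  structure(as.list(environment()), class = "sim_config")
}

# zero-truncated, capped Poisson sibship sizes
.rsibship <- function(n, lambda, cap) {
  s <- stats::qpois(stats::runif(n, stats::dpois(0, lambda), 1), lambda)
  pmin(pmax(s, 1L), cap)
}

#' Sample a synthetic pedigree collection
#'
#' Families are a founder couple plus a zero-truncated Poisson sibship;
#' with probability \code{p_extend} one sib marries an incoming founder
#' spouse and contributes a second sibship (three generations).  The
#' default law is calibrated so the mean total family size is ~5.
#'
#' @param cfg \code{\link{sim_config}}.
#' @return validated \code{pedigree}.
#' @export
sample_pedigrees <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  rows <- vector("list", cfg$n_families)
  for (f in seq_len(cfg$n_families)) {
    fid <- sprintf("F%04d", f)
    nid <- 0L
    newid <- function() { nid <<- nid + 1L; sprintf("%s-%02d", fid, nid) }
    fa <- newid(); mo <- newid()
    rec <- data.frame(
      family_id = fid, individual_id = c(fa, mo),
      father_id = "0", mother_id = "0", sex = c(1L, 2L))
    ns <- .rsibship(1L, cfg$sibship_lambda, cfg$sibship_cap)
    sibs <- replicate(ns, newid())
    sibsex <- ifelse(stats::runif(ns) < cfg$p_male, 1L, 2L)
    rec <- rbind(rec, data.frame(
      family_id = fid, individual_id = sibs,
      father_id = fa, mother_id = mo, sex = sibsex))
    if (stats::runif(1) < cfg$p_extend) {
      k <- sample.int(ns, 1L)
      spouse <- newid()
      rec <- rbind(rec, data.frame(
        family_id = fid, individual_id = spouse,
        father_id = "0", mother_id = "0",
        sex = ifelse(sibsex[k] == 1L, 2L, 1L)))
      n2 <- .rsibship(1L, cfg$sibship_lambda, cfg$sibship_cap)
      kids <- replicate(n2, newid())
      rec <- rbind(rec, data.frame(
        family_id = fid, individual_id = kids,
        father_id = if (sibsex[k] == 1L) sibs[k] else spouse,
        mother_id = if (sibsex[k] == 1L) spouse else sibs[k],
        sex = ifelse(stats::runif(n2) < cfg$p_male, 1L, 2L)))
    }
    rows[[f]] <- rec
  }
  validate_pedigree(do.call(rbind, rows))
}

#' Simulate LD-structured genotypes by gene dropping
#'
#' Lays out \code{n_snps} across the region (a \code{cluster_fraction}
#' inside the five gene windows, the rest uniform), draws founder
#' haplotypes -- per cluster from a small haplotype pool, which creates
#' blocks of high pairwise r-squared; background SNPs independently --
#' and drops them through the pedigree with Haldane recombination at
#' \code{cm_per_mb}.  Founder-allele labels are tracked at every locus
#' (including the QTL position at the centre of the gene-cluster span),
#' so realised IBD sharing can be read off exactly.  A missingness mask
#' is applied per SNP to the returned analysis panel; the complete
#' (pre-mask) dosages are retained for trait simulation.
#'
#' @param ped validated \code{pedigree}.
#' @param cfg \code{\link{sim_config}}.
#' @return list with \code{geno} (masked dosage matrix), \code{geno_true}
#'   (complete), \code{founder_haplotypes} (the two founder haplotype
#'   matrices), \code{map}, \code{genes} (name/start/end),
#'   \code{qtl_position}, \code{origins} (founder-allele labels at the
#'   QTL, n x 2), \code{origin_all} (labels at every locus),
#'   \code{loci}, \code{monomorphic} (SNP ids fixed after dropping).
#' @export
simulate_genotypes <- function(ped, cfg = sim_config()) {
  stopifnot(inherits(ped, "pedigree"), inherits(cfg, "sim_config"))
  # gene layout: evenly spaced clusters
  centers <- (seq_len(cfg$n_genes) - 0.5) / cfg$n_genes * cfg$region_length
  genes <- data.frame(
    name = paste0("gene", seq_len(cfg$n_genes)),
    start = round(centers - cfg$gene_length / 2),
    end = round(centers + cfg$gene_length / 2))
  win <- cbind(genes$start - cfg$window_pad, genes$end + cfg$window_pad)
  qtl_position <- round(mean(range(win)))

  n_in <- round(cfg$n_snps * cfg$cluster_fraction)
  per <- diff(round(seq(0, n_in, length.out = cfg$n_genes + 1L)))
  pos_in <- unlist(lapply(seq_len(cfg$n_genes), function(g)
    sort(round(stats::runif(per[g], win[g, 1L], win[g, 2L])))))
  clu_in <- rep(seq_len(cfg$n_genes), per)
  n_out <- cfg$n_snps - n_in
  pos_out <- sort(round(stats::runif(n_out, 1, cfg$region_length)))
  map <- data.frame(snp_id = character(cfg$n_snps), chromosome = "7q36",
                    position = c(pos_in, pos_out),
                    cluster = c(clu_in, rep(0L, n_out)))
  map <- map[order(map$position), , drop = FALSE]
  # unique strictly increasing positions
  while (any(d <- duplicated(map$position)))
    map$position[d] <- map$position[d] + 1L
  map <- map[order(map$position), , drop = FALSE]
  map$snp_id <- sprintf("snp%04d", seq_len(cfg$n_snps))
  rownames(map) <- NULL

  # founder haplotype distribution: per-cluster pools + independent rest
  L <- cfg$n_snps
  pools <- lapply(seq_len(cfg$n_genes), function(g) {
    m <- sum(map$cluster == g)
    h <- matrix(stats::rbinom(cfg$pool_size * m, 1L,
                              stats::runif(m, 0.2, 0.8)[col(matrix(0, cfg$pool_size, m))]),
                cfg$pool_size, m)
    w <- stats::rexp(cfg$pool_size); w <- w / sum(w)
    list(h = h, w = w, cols = which(map$cluster == g))
  })
  maf_bg <- stats::runif(L, 0.05, 0.5)
  bg_cols <- which(map$cluster == 0L)

  draw_founder_hap <- function() {
    h <- integer(L)
    h[bg_cols] <- stats::rbinom(length(bg_cols), 1L, maf_bg[bg_cols])
    for (p in pools) {
      hp <- p$h[sample.int(cfg$pool_size, 1L, prob = p$w), ]
      if (cfg$haplotype_noise > 0) {
        flip <- stats::runif(length(hp)) < cfg$haplotype_noise
        hp[flip] <- 1L - hp[flip]
      }
      h[p$cols] <- hp
    }
    h
  }

  # loci = SNPs plus the QTL slot; Haldane recombination fractions
  loci <- sort(c(map$position, qtl_position))
  qtl_idx <- which(loci == qtl_position)[1L]
  snp_of_locus <- setdiff(seq_along(loci), qtl_idx)
  nl <- length(loci)
  d_morgan <- diff(loci) * cfg$cm_per_mb * 1e-8
  theta <- 0.5 * (1 - exp(-2 * d_morgan))

  n <- nrow(ped)
  ids <- ped$individual_id
  idx <- stats::setNames(seq_len(n), ids)
  hapA <- matrix(0L, nl, n); hapB <- matrix(0L, nl, n)
  orgA <- matrix(0L, nl, n); orgB <- matrix(0L, nl, n)
  next_label <- 0L
  gamete <- function(h1, h2, o1, o2) {
    s <- cumsum(c(sample.int(2L, 1L) - 1L,
                  stats::rbinom(nl - 1L, 1L, theta))) %% 2L
    pick <- s == 0L
    list(h = ifelse(pick, h1, h2), o = ifelse(pick, o1, o2))
  }
  for (i in seq_len(n)) {
    if (ped$founder[i]) {
      hap <- draw_founder_hap()
      hapA[snp_of_locus, i] <- hap
      hapA[qtl_idx, i] <- 0L
      hap <- draw_founder_hap()
      hapB[snp_of_locus, i] <- hap
      orgA[, i] <- next_label + 1L
      orgB[, i] <- next_label + 2L
      next_label <- next_label + 2L
    } else {
      fi <- idx[[ped$father_id[i]]]; mi <- idx[[ped$mother_id[i]]]
      g <- gamete(hapA[, fi], hapB[, fi], orgA[, fi], orgB[, fi])
      hapA[, i] <- g$h; orgA[, i] <- g$o
      g <- gamete(hapA[, mi], hapB[, mi], orgA[, mi], orgB[, mi])
      hapB[, i] <- g$h; orgB[, i] <- g$o
    }
  }

  dos <- t(hapA[snp_of_locus, , drop = FALSE] +
             hapB[snp_of_locus, , drop = FALSE])
  dimnames(dos) <- list(ids, map$snp_id)
  af <- colMeans(dos) / 2
  monomorphic <- map$snp_id[af == 0 | af == 1]

  geno <- dos
  if (cfg$missingness > 0) {
    mask <- matrix(stats::runif(length(geno)) < cfg$missingness,
                   nrow(geno), ncol(geno))
    geno[mask] <- NA_real_
  }

  fcol <- which(ped$founder)
  hapsA <- t(hapA[snp_of_locus, fcol, drop = FALSE])
  hapsB <- t(hapB[snp_of_locus, fcol, drop = FALSE])
  dimnames(hapsA) <- dimnames(hapsB) <- list(ids[fcol], map$snp_id)

  list(geno = geno, geno_true = dos,
       founder_haplotypes = list(A = hapsA, B = hapsB),
       map = map[, c("snp_id", "chromosome", "position", "cluster")],
       genes = genes, qtl_position = qtl_position,
       origins = cbind(orgA[qtl_idx, ], orgB[qtl_idx, ]),
       origin_all = list(A = orgA, B = orgB), loci = loci,
       ids = ids, monomorphic = monomorphic)
}

#' True locus IBD matrix from a gene-dropping record
#'
#' Reads realised identity-by-descent off the founder-allele labels
#' tracked during gene dropping: \eqn{\Pi_{ij}} is the number of allele
#' pairs shared IBD between i and j divided by two (0, 0.5 or 1 in an
#' outbred pedigree), with \eqn{\Pi_{ii} = 1} and zero across families.
#'
#' @param drop result of \code{\link{simulate_genotypes}}.
#' @param ped the pedigree the record was generated from.
#' @param position locus position in base pairs; defaults to the QTL
#'   position of the record.  Must lie inside the simulated region.
#' @return symmetric IBD matrix with id dimnames.
#' @export
true_ibd_matrix <- function(drop, ped, position = NULL) {
  stopifnot(inherits(ped, "pedigree"))
  if (is.null(position)) {
    lab <- drop$origins
  } else {
    if (position < min(drop$loci) || position > max(drop$loci))
      stop("position ", position, " outside the simulated region [",
           min(drop$loci), ", ", max(drop$loci), "]")
    li <- which.min(abs(drop$loci - position))
    lab <- cbind(drop$origin_all$A[li, ], drop$origin_all$B[li, ])
  }
  ids <- drop$ids
  n <- length(ids)
  pi_mat <- matrix(0, n, n, dimnames = list(ids, ids))
  fam <- ped$family_id[match(ids, ped$individual_id)]
  for (f in unique(fam)) {
    ii <- which(fam == f)
    for (a in seq_along(ii)) for (b in seq_len(a)) {
      i <- ii[a]; j <- ii[b]
      if (i == j) { pi_mat[i, i] <- 1; next }
      m <- (lab[i, 1L] == lab[j, 1L]) + (lab[i, 1L] == lab[j, 2L]) +
           (lab[i, 2L] == lab[j, 1L]) + (lab[i, 2L] == lab[j, 2L])
      pi_mat[i, j] <- pi_mat[j, i] <- m / 2
    }
  }
  pi_mat
}

#' Simulate the quantitative trait
#'
#' Generates the trait the analysis model assumes:
#' \deqn{y = \mu + covariates + \sum_k a_k s_k + polygenic + environment}
#' with causal SNP scores \eqn{s_k} coded -1/0/+1 from the complete
#' genotypes, polygenic values drawn per family from
#' \eqn{MVN(0, 2\Phi\sigma^2_g)} and i.i.d. environmental noise.  Causal
#' variants are picked from the gene clusters (round-robin, realised
#' minor-allele frequency at least 0.1, preferring mutually weakly
#' correlated SNPs), each sized to contribute
#' \code{causal_share_total / n_causal} of the trait variance; effect
#' signs alternate, and the effect vector is jointly rescaled so the
#' realised locus share equals \code{causal_share_total} exactly --
#' otherwise LD covariance between clustered causal variants would make
#' the locus share drift far from its target from replicate to
#' replicate.  Covariates follow the cohort
#' marginals (age ~ N(48.12, 15.1) truncated to [18, 90], binary
#' covariates at their cohort frequencies) and jointly explain
#' \code{covariate_share} of the variance.  The returned trait is on the
#' raw (exponentiated) scale so the standard preparation (ln transform,
#' outlier screen) applies downstream.
#'
#' @param ped validated \code{pedigree}.
#' @param drop result of \code{\link{simulate_genotypes}}.
#' @param cfg \code{\link{sim_config}}.
#' @param kinship optional precomputed kinship matrix.
#' @return list with \code{phen} (raw phenotype table: individual_id,
#'   trait_raw, covariates) and \code{truth} (causal SNPs, effects,
#'   target and realised variance shares, variance components).
#' @export
simulate_trait <- function(ped, drop, cfg = sim_config(), kinship = NULL) {
  stopifnot(inherits(ped, "pedigree"))
  ids <- drop$ids
  n <- length(ids)
  total_var <- cfg$trait_sd^2

  # covariates at cohort marginals
  sex <- as.integer(ped$sex[match(ids, ped$individual_id)] == "male")
  age <- stats::qnorm(stats::runif(n, stats::pnorm(18, 48.12, 15.1),
                                   stats::pnorm(90, 48.12, 15.1)),
                      48.12, 15.1)
  female <- sex == 0L
  cov <- data.frame(
    age = age, sex = sex,
    age_sex = age * sex, age2 = age^2, age2_sex = age^2 * sex,
    asthma = stats::rbinom(n, 1L, 0.085),
    menopause = ifelse(female, stats::rbinom(n, 1L, 0.52), 0L),
    estrogen = ifelse(female, stats::rbinom(n, 1L, 0.23), 0L),
    smoking = stats::rbinom(n, 1L, 0.22),
    lipid_med = stats::rbinom(n, 1L, 0.035),
    diabetes = stats::rbinom(n, 1L, 0.159))
  w <- c(age = 1, sex = 0.8, diabetes = 0.8, menopause = 0.5,
         smoking = 0.3, estrogen = 0.3, asthma = 0.1, lipid_med = 0.2)
  lp_cov <- rowSums(vapply(names(w), function(v) {
    x <- cov[[v]]
    s <- stats::sd(x)
    if (s == 0) rep(0, n) else w[[v]] * (x - mean(x)) / s
  }, numeric(n)))
  lp_cov <- if (cfg$covariate_share > 0 && stats::sd(lp_cov) > 0)
    lp_cov * sqrt(cfg$covariate_share * total_var) / stats::sd(lp_cov)
  else numeric(n)

  # causal variants from the clusters, round-robin, preferring mutually
  # weakly correlated picks so that LD cross-covariance does not swamp
  # the per-variant shares
  af <- colMeans(drop$geno_true) / 2
  maf <- pmin(af, 1 - af)
  cand <- which(drop$map$cluster > 0L & maf >= 0.1)
  no_causal <- cfg$n_causal == 0L || cfg$causal_share_total == 0
  if (!no_causal && length(cand) < cfg$n_causal)
    stop("not enough polymorphic cluster SNPs for ", cfg$n_causal,
         " causal variants")
  picks <- integer(0)
  turn <- if (no_causal) integer(0)
          else rep(sort(unique(drop$map$cluster[cand])),
                   length.out = cfg$n_causal)
  for (g in turn) {
    pool_g <- setdiff(cand[drop$map$cluster[cand] == g], picks)
    if (!length(pool_g)) pool_g <- setdiff(cand, picks)
    pool_g <- sample(pool_g)
    pick <- pool_g[1L]
    for (r2max in c(0.2, 0.5, 1)) {
      okc <- pool_g[vapply(pool_g, function(j) {
        if (!length(picks)) return(TRUE)
        all(suppressWarnings(stats::cor(drop$geno_true[, j],
                                        drop$geno_true[, picks]))^2 <
              r2max, na.rm = TRUE)
      }, logical(1))]
      if (length(okc)) { pick <- okc[1L]; break }
    }
    picks <- c(picks, pick)
  }
  picks <- sort(picks)

  share_k <- if (no_causal) 0 else cfg$causal_share_total / cfg$n_causal
  scores <- drop$geno_true[, picks, drop = FALSE] - 1
  sds <- if (length(picks)) apply(scores, 2L, stats::sd) else numeric(0)
  signs <- rep(c(1, -1), length.out = length(picks))
  a <- signs * sqrt(share_k * total_var) / sds
  lp_gen <- if (length(picks)) drop(scores %*% a) else numeric(n)
  # joint rescale: the realized locus share equals the configured total
  if (length(picks) && stats::var(lp_gen) > 0) {
    a <- a * sqrt(cfg$causal_share_total * total_var / stats::var(lp_gen))
    lp_gen <- drop(scores %*% a)
  }

  # polygenic component, per family
  if (is.null(kinship)) kinship <- kinship_matrix(ped)
  sigma2_g <- cfg$h2_polygenic * total_var
  fam <- ped$family_id[match(ids, ped$individual_id)]
  poly <- numeric(n)
  if (sigma2_g > 0) {
    for (f in unique(fam)) {
      ii <- which(fam == f)
      G <- 2 * kinship[ids[ii], ids[ii], drop = FALSE] * sigma2_g
      poly[ii] <- drop(crossprod(chol(G), stats::rnorm(length(ii))))
    }
  }

  sigma2_e <- total_var * (1 - cfg$causal_share_total - cfg$h2_polygenic -
                             cfg$covariate_share)
  y <- cfg$trait_mean + lp_cov + (lp_gen - mean(lp_gen)) + poly +
    stats::rnorm(n, 0, sqrt(sigma2_e))

  phen <- cbind(data.frame(individual_id = ids, trait_raw = exp(y)), cov)
  truth <- list(
    causal = data.frame(
      snp_id = drop$map$snp_id[picks],
      cluster = drop$map$cluster[picks],
      effect = a, target_share = rep(share_k, length(picks)),
      realized_share = (a * sds)^2 / total_var),
    locus_share_target = cfg$causal_share_total,
    locus_share_realized = stats::var(lp_gen) / total_var,
    sigma2_g = sigma2_g, sigma2_e = sigma2_e,
    covariate_share = cfg$covariate_share)
  list(phen = phen, truth = truth)
}

#' Simulate a complete synthetic cohort
#'
#' Runs the full generator: pedigrees, LD-structured genotypes with
#' missingness, trait and covariates, and the true locus IBD matrix at
#' the QTL position.  Everything the analysis pipeline consumes.
#'
#' @param cfg \code{\link{sim_config}}.
#' @param seed optional integer seed (sets the R RNG).
#' @return object of class \code{sim_cohort}: list with \code{ped},
#'   \code{phen} (raw), \code{geno}, \code{geno_true}, \code{map},
#'   \code{genes}, \code{ibd}, \code{qtl_position}, \code{truth},
#'   \code{kinship}, \code{config}.
#' @examples
#' \donttest{
#' cohort <- simulate_cohort(sim_config(n_families = 30, n_snps = 60), seed = 1)
#' cohort$truth$locus_share_realized
#' }
#' @export
simulate_cohort <- function(cfg = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ped <- sample_pedigrees(cfg)
  drop <- simulate_genotypes(ped, cfg)
  kin <- kinship_matrix(ped)
  tr <- simulate_trait(ped, drop, cfg, kinship = kin)
  ibd <- true_ibd_matrix(drop, ped)
  structure(list(
    ped = ped, phen = tr$phen, geno = drop$geno, geno_true = drop$geno_true,
    map = drop$map, genes = drop$genes, ibd = ibd,
    qtl_position = drop$qtl_position, truth = tr$truth,
    kinship = kin, config = cfg),
    class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf(paste0(
    "Synthetic cohort: %d individuals, %d families, %d SNPs ",
    "(%d in %d gene clusters)\n  locus share (realized): %.3f over %d ",
    "causal variants; QTL at %.2f Mb\n"),
    nrow(x$ped), length(unique(x$ped$family_id)), ncol(x$geno),
    sum(x$map$cluster > 0L), nrow(x$genes),
    x$truth$locus_share_realized, nrow(x$truth$causal),
    x$qtl_position / 1e6))
  invisible(x)
}

#' Default covariate set for the triglyceride models
#'
#' The covariate list used in every analysis stage: age, sex, age-by-sex,
#' age squared, age squared by sex, asthma, menopause, estrogen/birth
#' control use, smoking, lipid-lowering medication and diabetes.
#'
#' @return one-sided formula.
#' @export
tg_covariates <- function()
  ~ age + sex + age_sex + age2 + age2_sex + asthma + menopause +
    estrogen + smoking + lipid_med + diabetes
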