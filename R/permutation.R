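#' Permute trait values across individuals
#'
#' Shuffles the trait column uniformly at random across the rows of a
#' phenotype/analysis data.frame (or within families when
#' \code{within_family} is set); genotypes, covariates and pedigree
#' attachments are untouched.
#'
#' @param data data.frame with the trait column (and \code{family_id}
#'   when permuting within families).
#' @param trait trait column name.
#' @param within_family permute within family blocks only.
#' @return the data.frame with the trait column permuted.
#' @export
permute_phenotypes <- function(data, trait = "trait",
                               within_family = FALSE) {
  n <- nrow(data)
  if (n < 2L) stop("need at least 2 individuals to permute")
  if (within_family) {
    stopifnot("family_id" %in% names(data))
    for (f in unique(data$family_id)) {
      ii <- which(data$family_id == f)
      if (length(ii) > 1L)
        data[[trait]][ii] <- data[[trait]][sample(ii)]
    }
  } else {
    data[[trait]] <- data[[trait]][sample.int(n)]
  }
  data
}

#' The permutation-analysis empirical p-value
#'
#' \code{(count_below + 1) / n_perm}: the number of permuted replicates
#' whose adjusted LOD fell below the threshold, plus one, divided by the
#' number of permutations performed.
#'
#' @param count_below replicates below the threshold.
#' @param n_perm number of permutations.
#' @return empirical p-value.
#' @examples
#' empirical_p(3, 500)   # 0.008
#' @export
empirical_p <- function(count_below, n_perm) {
  stopifnot(n_perm >= 1, count_below >= 0, count_below <= n_perm)
  (count_below + 1) / n_perm
}

#' Permutation test for abolished linkage
#'
#' Asks whether forcing the full SNP set into the model abolishes the
#' linkage (adjusted LOD < \code{threshold}) merely through
#' over-parameterisation.  Each replicate refits the all-SNP conditional
#' model on permuted data and records the adjusted LOD; the empirical
#' p-value is \code{(count below threshold + 1) / n_perm}.
#'
#' Under the default \code{mode = "genotype"} the permutation breaks the
#' SNP-trait association while preserving the trait-IBD (linkage)
#' relation: one random permutation reassigns the genotype rows among the
#' analysis individuals, and trait, covariates, kinship and IBD stay in
#' place.  Each replicate therefore carries the genuine linkage signal
#' plus an equally sized set of association-free SNP covariates -- the
#' over-parameterisation null the test is after, under which a low
#' empirical p-value means a LOD collapse like the observed one almost
#' never happens by over-fitting alone.  \code{mode = "trait"} instead
#' shuffles trait values across individuals (optionally within
#' families), which destroys linkage and association alike; it answers a
#' different question (how often an all-null trait yields LOD below the
#' threshold, which is frequent) and is provided for comparison.
#'
#' @param aset \code{analysis_set} with genotypes and locus IBD.
#' @param snp_ids SNP set of the conditional model.
#' @param covariates one-sided covariate formula.
#' @param n_perm number of permutations (default 500).
#' @param threshold LOD threshold for "abolished" (default 0.5).
#' @param mode \code{"genotype"} (default) or \code{"trait"}; see
#'   Details.
#' @param within_family for \code{mode = "trait"}: permute within
#'   families.
#' @param trait trait column name.
#' @param seed optional master seed; replicate seeds are derived from it
#'   deterministically, so results are bit-identical across reruns.
#' @return object of class \code{permutation_result}: list with
#'   \code{n_perm}, \code{threshold}, \code{lods}, \code{count_below},
#'   \code{empirical_p}, \code{max_perm_lod}, \code{observed_lod},
#'   \code{observed} (the observed \code{conditional_result}),
#'   \code{mode}, \code{seed}, \code{n_failed}.
#' @export
permutation_test <- function(aset, snp_ids, covariates, n_perm = 500,
                             threshold = 0.5,
                             mode = c("genotype", "trait"),
                             within_family = FALSE, trait = "trait",
                             seed = NULL) {
  mode <- match.arg(mode)
  observed <- conditional_lod(aset, snp_ids, covariates, trait)
  prep <- .conditional_prep(aset, snp_ids, covariates, trait)
  dcc <- prep$dcc
  n <- nrow(dcc)

  seeds <- if (!is.null(seed)) seed + seq_len(n_perm)
  lods <- rep(NA_real_, n_perm)
  for (b in seq_len(n_perm)) {
    if (!is.null(seeds)) set.seed(seeds[b])
    dp <- dcc
    if (mode == "genotype") {
      perm <- sample.int(n)
      dp[, prep$score_cols] <- dcc[perm, prep$score_cols, drop = FALSE]
    } else {
      dp <- permute_phenotypes(dp, trait = trait,
                               within_family = within_family)
    }
    fit1 <- try(vc_fit(prep$f_full, dp, kinship = prep$kinship,
                       ibd = prep$ibd), silent = TRUE)
    fit0 <- try(vc_fit(prep$f_full, dp, kinship = prep$kinship,
                       ibd = prep$ibd, constrain = "sigma2_q"),
                silent = TRUE)
    if (inherits(fit1, "try-error") || inherits(fit0, "try-error") ||
        !fit1$converged || !fit0$converged) {
      warning("permutation replicate ", b, " did not converge; excluded")
      next
    }
    lods[b] <- lod_linkage(fit1, fit0)
  }
  failed <- sum(is.na(lods))
  lods <- lods[!is.na(lods)]
  n_eff <- n_perm - failed
  if (n_eff < 1L) stop("no permutation replicate converged")
  count_below <- sum(lods < threshold)

  structure(list(
    n_perm = n_eff, threshold = threshold, lods = lods,
    count_below = count_below,
    empirical_p = empirical_p(count_below, n_eff),
    max_perm_lod = max(lods),
    observed_lod = observed$adjusted_lod, observed = observed,
    mode = mode, seed = seed, n_failed = failed),
    class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(paste0(
    "Permutation test (%s mode): %d permutations, threshold LOD < %g\n",
    "  observed adjusted LOD %.3f; permuted LODs below threshold: %d\n",
    "  empirical p = %.4g; max permuted LOD %.2f\n"),
    x$mode, x$n_perm, x$threshold, x$observed_lod, x$count_below,
    x$empirical_p, x$max_perm_lod))
  if (x$n_failed > 0)
    cat(sprintf("  (%d replicate(s) excluded for non-convergence)\n",
                x$n_failed))
  invisible(x)
}
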