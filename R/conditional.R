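# shared preparation for the combined linkage-association fits: additive
# scores for the SNP set, one complete-case subset across trait,
# covariates and ALL scores, and collinearity resolution among the
# forced-in scores (the later-position member of a dependent set is
# dropped with a warning; a collinear covariate is an error).
.conditional_prep <- function(aset, snp_ids, covariates, trait = "trait") {
  stopifnot(inherits(aset, "analysis_set"), !is.null(aset$geno),
            !is.null(aset$ibd))
  covs <- attr(stats::terms(covariates), "term.labels")
  d <- aset$data
  keep_snps <- character(0)
  for (sid in snp_ids) {
    s <- try(encode_additive(aset$geno, sid), silent = TRUE)
    if (inherits(s, "try-error")) {
      warning("SNP ", sid, " monomorphic; excluded from the conditional set")
      next
    }
    d[[paste0("s_", sid)]] <- as.numeric(s[match(d$individual_id, names(s))])
    keep_snps <- c(keep_snps, sid)
  }
  if (!length(keep_snps)) stop("no usable SNPs in the conditional set")
  score_cols <- paste0("s_", keep_snps)
  cc <- stats::complete.cases(d[, c(trait, covs, score_cols)])
  dcc <- d[cc, , drop = FALSE]
  n_fixed <- 1L + length(covs) + length(score_cols)
  if (nrow(dcc) <= n_fixed)
    stop("complete-case subset too small: n = ", nrow(dcc),
         " for ", n_fixed, " fixed effects")

  # resolve rank deficiency in the design
  dropped <- character(0)
  repeat {
    rhs <- paste(c(covs, score_cols), collapse = " + ")
    X <- stats::model.matrix(stats::as.formula(paste("~", rhs)), dcc)
    qrX <- qr(X)
    if (qrX$rank == ncol(X)) break
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    bad_scores <- bad[bad %in% score_cols]
    if (!length(bad_scores))
      stop("collinear covariate column(s): ", paste(bad, collapse = ", "))
    # drop the later-position (later-ordered) offending score
    drop_col <- bad_scores[length(bad_scores)]
    warning("collinear SNP score dropped from the conditional set: ",
            sub("^s_", "", drop_col))
    dropped <- c(dropped, sub("^s_", "", drop_col))
    score_cols <- setdiff(score_cols, drop_col)
    if (!length(score_cols)) stop("all SNP scores collinear; nothing to fit")
  }

  rhs0 <- if (length(covs)) paste(covs, collapse = " + ") else "1"
  list(dcc = dcc, trait = trait,
       f_base = stats::as.formula(paste(trait, "~", rhs0)),
       f_full = stats::as.formula(paste(trait, "~",
                                        paste(c(if (length(covs)) covs,
                                                score_cols),
                                              collapse = " + "))),
       kinship = aset$kinship, ibd = aset$ibd,
       score_cols = score_cols,
       snp_ids = sub("^s_", "", score_cols), dropped = dropped)
}

#' Combined linkage-association: conditional LOD for a SNP set
#'
#' Quantifies how much of the linkage evidence at the QTL a set of SNPs
#' accounts for.  Four models are fitted on one identical complete-case
#' subset (complete across trait, covariates and every listed SNP): the
#' linked and no-linkage models with the SNP scores included as additive
#' fixed effects (adjusted LOD), and the same pair with all SNP effects
#' constrained to zero (base LOD).  All SNPs are forced into the adjusted
#' model; no per-SNP significance testing is performed.  The linkage is
#' called abolished when the adjusted LOD falls below 0.5.
#'
#' @param aset \code{analysis_set} with genotypes and a locus IBD matrix.
#' @param snp_ids SNPs to condition on.
#' @param covariates one-sided covariate formula.
#' @param trait trait column name.
#' @param set_id label for the SNP set.
#' @return object of class \code{conditional_result}: list with
#'   \code{set_id}, \code{n_snps}, \code{base_lod}, \code{adjusted_lod},
#'   \code{pct_decline} (100 (base - adjusted)/base; NA when base is 0),
#'   \code{abolished}, \code{n_used}, \code{var_explained_with},
#'   \code{var_explained_without}, \code{dropped_snps} and the four fits.
#' @export
conditional_lod <- function(aset, snp_ids, covariates, trait = "trait",
                            set_id = NULL) {
  prep <- .conditional_prep(aset, snp_ids, covariates, trait)
  fit <- function(f, constrain = character())
    vc_fit(f, prep$dcc, kinship = prep$kinship, ibd = prep$ibd,
           constrain = constrain)
  adj_linked  <- fit(prep$f_full)
  adj_null    <- fit(prep$f_full, "sigma2_q")
  base_linked <- fit(prep$f_base)
  base_null   <- fit(prep$f_base, "sigma2_q")
  stopifnot(adj_linked$n_used == base_linked$n_used)

  adjusted <- lod_linkage(adj_linked, adj_null)
  base <- lod_linkage(base_linked, base_null)
  ve <- variance_explained(adj_linked, base_linked)

  structure(list(
    set_id = if (is.null(set_id)) paste0(length(prep$snp_ids), "_snps")
             else set_id,
    snp_ids = prep$snp_ids, n_snps = length(prep$snp_ids),
    base_lod = base, adjusted_lod = adjusted,
    pct_decline = if (base > 0) 100 * (base - adjusted) / base else NA_real_,
    abolished = adjusted < 0.5, n_used = adj_linked$n_used,
    var_explained_with = ve[["with"]],
    var_explained_without = ve[["without"]],
    dropped_snps = prep$dropped,
    fits = list(adj_linked = adj_linked, adj_null = adj_null,
                base_linked = base_linked, base_null = base_null)),
    class = "conditional_result")
}

#' @export
print.conditional_result <- function(x, ...) {
  cat(sprintf(paste0(
    "Conditional linkage [%s]: %d SNPs, n = %d\n",
    "  base LOD %.2f -> adjusted LOD %.2f (%% decline %.1f)%s\n",
    "  variance explained by fixed effects: %.1f%% with SNPs, ",
    "%.1f%% without\n"),
    x$set_id, x$n_snps, x$n_used, x$base_lod, x$adjusted_lod,
    x$pct_decline, if (x$abolished) "; linkage abolished (LOD < 0.5)" else "",
    100 * x$var_explained_with, 100 * x$var_explained_without))
  invisible(x)
}

#' Percent decline of a LOD score
#'
#' \code{100 * (base - adjusted) / base}; \code{NA} when the base LOD is
#' zero.
#'
#' @param base,adjusted LOD scores before and after conditioning.
#' @return percentage decline.
#' @examples
#' pct_decline(5.78, 1.08)   # 81.3
#' @export
pct_decline <- function(base, adjusted) {
  ifelse(base > 0, 100 * (base - adjusted) / base, NA_real_)
}

#' Variance explained by the fixed effects
#'
#' Fraction of the trait variance explained by the fixed effects of a
#' fit: \code{1 - var(residuals)/var(trait)}, computed on the analysis
#' subset.  Compares a fit with SNP covariates against one without, on
#' the same individuals.
#'
#' @param fit_with,fit_without \code{vc_fit} objects on identical
#'   individuals (with and without the SNP scores).
#' @return named vector \code{c(with =, without =)} of fractions.
#' @export
variance_explained <- function(fit_with, fit_without) {
  stopifnot(inherits(fit_with, "vc_fit"), inherits(fit_without, "vc_fit"))
  if (!identical(sort(fit_with$ids), sort(fit_without$ids)))
    stop("fits must use identical individuals")
  vt <- stats::var(fit_with$y)
  if (vt == 0) stop("trait variance is zero on the analysis subset")
  c(with = 1 - stats::var(stats::residuals(fit_with)) / vt,
    without = 1 - stats::var(stats::residuals(fit_without)) / vt)
}

#' Per-gene and pooled conditional linkage accounting
#'
#' Splits a pruned SNP panel by gene-cluster membership and runs the
#' combined linkage-association analysis once per gene and once for the
#' pooled all-genes set.  Each gene is analysed on its own complete-case
#' subset, so base LODs differ across rows (fewer forced-in SNPs leave
#' more complete cases).  SNPs falling in overlapping windows enter the
#' pooled set once.
#'
#' @param aset \code{analysis_set} with genotypes and locus IBD.
#' @param clusters \code{gene_clusters} from \code{\link{cluster_hits}}.
#' @param pruned \code{prune_result} from \code{\link{prune_ld}}.
#' @param covariates one-sided covariate formula.
#' @param trait trait column name.
#' @return data.frame (class \code{gene_conditioning}) with one row per
#'   gene plus a pooled \code{all_genes} row: gene, n_snps, base_lod,
#'   adjusted_lod, pct_decline, n_used, abolished.  The full
#'   \code{conditional_result} objects are attached as attribute
#'   \code{"results"}.
#' @export
per_gene_conditioning <- function(aset, clusters, pruned, covariates,
                                  trait = "trait") {
  stopifnot(inherits(clusters, "gene_clusters"),
            inherits(pruned, "prune_result"))
  sets <- lapply(clusters$clusters, function(cl)
    intersect(pruned$retained, cl$members))
  names(sets) <- names(clusters$clusters)
  pooled <- unique(unlist(sets))
  results <- list()
  rows <- list()
  for (g in names(sets)) {
    if (!length(sets[[g]])) {
      warning("gene ", g, " has no retained SNPs; skipped")
      next
    }
    r <- conditional_lod(aset, sets[[g]], covariates, trait, set_id = g)
    results[[g]] <- r
    rows[[g]] <- data.frame(
      gene = g, n_snps = r$n_snps, base_lod = r$base_lod,
      adjusted_lod = r$adjusted_lod, pct_decline = r$pct_decline,
      n_used = r$n_used, abolished = r$abolished)
  }
  if (length(pooled)) {
    r <- conditional_lod(aset, pooled, covariates, trait,
                         set_id = "all_genes")
    results$all_genes <- r
    rows$all_genes <- data.frame(
      gene = "all_genes", n_snps = r$n_snps, base_lod = r$base_lod,
      adjusted_lod = r$adjusted_lod, pct_decline = r$pct_decline,
      n_used = r$n_used, abolished = r$abolished)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "results") <- results
  class(out) <- c("gene_conditioning", "data.frame")
  out
}
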