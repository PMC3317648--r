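#' Additive measured-genotype score for one SNP
#'
#' Codes genotypes additively for the measured-genotype model: the
#' minor-allele homozygote scores +1, the major-allele homozygote -1 and
#' heterozygotes 0.  Missing dosages stay missing.  The allele designated
#' as minor (by frequency among non-missing dosages) is recorded in the
#' \code{"minor_is_counted"} attribute: \code{TRUE} when the dosage-counted
#' allele is the minor one, in which case score = dosage - 1, else
#' score = 1 - dosage.
#'
#' @param geno dosage matrix (ids x SNPs).
#' @param snp_id SNP column to encode.
#' @return named numeric score vector in \{-1, 0, +1, NA\} with
#'   attributes \code{maf} and \code{minor_is_counted}.
#' @export
encode_additive <- function(geno, snp_id) {
  if (!snp_id %in% colnames(geno)) stop("SNP not in genotype matrix: ", snp_id)
  d <- geno[, snp_id]
  af <- mean(d, na.rm = TRUE) / 2
  if (is.nan(af) || af == 0 || af == 1)
    stop("SNP is monomorphic (or fully missing): ", snp_id)
  minor_counted <- af <= 0.5
  s <- if (minor_counted) d - 1 else 1 - d
  attr(s, "maf") <- min(af, 1 - af)
  attr(s, "minor_is_counted") <- minor_counted
  s
}

#' Single-SNP measured-genotype association scan
#'
#' For each SNP, fits the polygenic model (\eqn{\sigma^2_g, \sigma^2_e}
#' free, no locus component) with and without the SNP score as a fixed
#' effect, on the SNP's complete cases, and tests the SNP by the
#' chi-square(1) likelihood-ratio test.  Null fits are shared between
#' SNPs with identical complete-case sets.  Monomorphic and degenerate
#' (all-heterozygote) SNPs are flagged and carry no p-value.
#'
#' @param aset \code{analysis_set} from \code{\link{align_datasets}}.
#' @param covariates one-sided formula of covariate terms, e.g.
#'   \code{\link{tg_covariates}()}.
#' @param snp_ids SNPs to test (default: all genotyped).
#' @param trait trait column name in \code{aset$data}.
#' @return data.frame with one row per SNP: \code{snp_id},
#'   \code{position}, \code{maf}, \code{beta}, \code{lrt}, \code{p},
#'   \code{n_used}, \code{status} ("ok", "monomorphic", "degenerate",
#'   "not_converged").
#' @export
single_snp_scan <- function(aset, covariates, snp_ids = NULL,
                            trait = "trait") {
  stopifnot(inherits(aset, "analysis_set"), !is.null(aset$geno))
  if (is.null(snp_ids)) snp_ids <- colnames(aset$geno)
  covs <- attr(stats::terms(covariates), "term.labels")
  rhs0 <- if (length(covs)) paste(covs, collapse = " + ") else "1"
  base_f <- stats::as.formula(paste(trait, "~", rhs0))

  null_cache <- new.env(parent = emptyenv())
  res <- vector("list", length(snp_ids))
  for (k in seq_along(snp_ids)) {
    sid <- snp_ids[k]
    pos <- if (!is.null(aset$map))
      aset$map$position[match(sid, aset$map$snp_id)] else NA_real_
    row <- data.frame(snp_id = sid, position = pos, maf = NA_real_,
                      beta = NA_real_, lrt = NA_real_, p = NA_real_,
                      n_used = NA_integer_, status = "ok")
    s <- try(encode_additive(aset$geno, sid), silent = TRUE)
    if (inherits(s, "try-error")) {
      row$status <- "monomorphic"; res[[k]] <- row; next
    }
    row$maf <- attr(s, "maf")
    d <- aset$data
    d$.score <- as.numeric(s[match(d$individual_id, names(s))])
    full_f <- stats::as.formula(paste(trait, "~", rhs0, "+ .score"))
    cc <- stats::complete.cases(d[, c(trait, covs, ".score")])
    dcc <- d[cc, , drop = FALSE]
    if (length(unique(dcc$.score)) < 2L) {
      row$status <- "degenerate"; res[[k]] <- row; next
    }
    key <- paste(which(cc), collapse = ",")
    fit0 <- null_cache[[key]]
    ok <- TRUE
    if (is.null(fit0)) {
      fit0 <- try(vc_fit(base_f, dcc, kinship = aset$kinship), silent = TRUE)
      if (inherits(fit0, "try-error")) ok <- FALSE else null_cache[[key]] <- fit0
    }
    fit1 <- if (ok) try(vc_fit(full_f, dcc, kinship = aset$kinship),
                        silent = TRUE) else NULL
    if (!ok || inherits(fit1, "try-error") || !fit1$converged) {
      row$status <- "not_converged"; res[[k]] <- row; next
    }
    lrt <- vc_lrt(fit1, fit0)
    row$beta <- unname(stats::coef(fit1)[".score"])
    row$lrt <- lrt$statistic
    row$p <- lrt$p_value
    row$n_used <- fit1$n_used
    res[[k]] <- row
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Cluster nominal association hits into gene windows
#'
#' Assigns every nominally significant SNP (p below \code{alpha}) to each
#' gene window containing it, where a window is the gene span padded by
#' \code{pad} base pairs on both sides, boundaries closed.  A SNP inside
#' several overlapping windows is counted once in the summary totals, so
#' the in-window percentage cannot exceed 100.
#'
#' @param results scan results from \code{\link{single_snp_scan}}.
#' @param map SNP map (\code{snp_id}, \code{position}).
#' @param genes data.frame with \code{name}, \code{start}, \code{end}.
#' @param alpha nominal significance level (default 0.05).
#' @param pad window padding in base pairs (default 10 kb).
#' @return list of class \code{gene_clusters}: per-gene data.frames of
#'   member/hit SNPs and a \code{summary} with \code{n_hits},
#'   \code{n_in_windows} and \code{pct_in_windows} (rounded to integer;
#'   \code{NA} when there are no hits).
#' @export
cluster_hits <- function(results, map, genes, alpha = 0.05, pad = 1e4) {
  pos <- map$position[match(results$snp_id, map$snp_id)]
  hits <- !is.na(results$p) & results$p < alpha
  clusters <- lapply(seq_len(nrow(genes)), function(g) {
    lo <- genes$start[g] - pad
    hi <- genes$end[g] + pad
    member <- !is.na(pos) & pos >= lo & pos <= hi
    list(gene = genes$name[g], window = c(lo, hi),
         members = results$snp_id[member],
         hits = results$snp_id[member & hits])
  })
  names(clusters) <- genes$name
  in_any <- rep(FALSE, nrow(results))
  for (cl in clusters) in_any <- in_any | results$snp_id %in% cl$members
  n_hits <- sum(hits)
  n_in <- sum(hits & in_any)
  structure(list(
    clusters = clusters,
    summary = data.frame(
      n_hits = n_hits, n_in_windows = n_in,
      pct_in_windows = if (n_hits > 0) round(100 * n_in / n_hits)
                       else NA_integer_)),
    class = "gene_clusters")
}

#' @export
print.gene_clusters <- function(x, ...) {
  for (cl in x$clusters)
    cat(sprintf("%-8s window [%d, %d]: %d SNPs, %d hits\n", cl$gene,
                cl$window[1L], cl$window[2L], length(cl$members),
                length(cl$hits)))
  s <- x$summary
  if (is.na(s$pct_in_windows)) {
    cat("No nominal hits; in-window percentage not applicable\n")
  } else {
    cat(sprintf("%d of %d hits (%d%%) inside gene windows\n",
                s$n_in_windows, s$n_hits, s$pct_in_windows))
  }
  invisible(x)
}

#' Pairwise linkage disequilibrium r-squared from dosages
#'
#' Squared Pearson correlation of the two SNPs' dosages over
#' pairwise-complete individuals (genotypic r-squared; no phasing is
#' assumed or required).  Undefined when fewer than two complete pairs
#' remain or either SNP has zero variance on them; such pairs return
#' \code{NA} with a warning and are treated as below any pruning
#' threshold.
#'
#' @param geno dosage matrix.
#' @param snp_a,snp_b SNP column names.
#' @return r-squared in [0, 1], or NA.
#' @export
pairwise_r2 <- function(geno, snp_a, snp_b) {
  a <- geno[, snp_a]; b <- geno[, snp_b]
  cc <- !is.na(a) & !is.na(b)
  if (sum(cc) < 2L || stats::sd(a[cc]) == 0 || stats::sd(b[cc]) == 0) {
    warning("r-squared undefined for pair (", snp_a, ", ", snp_b, ")")
    return(NA_real_)
  }
  stats::cor(a[cc], b[cc])^2
}

#' Prune a SNP set by linkage disequilibrium
#'
#' Removes SNPs until no retained pair exceeds the r-squared threshold.
#' Pairs are visited in ascending genomic position order; at each
#' violating pair the member with the higher missingness is removed
#' (ties: the higher-position member), and the sweep repeats until
#' clean.  The output is verified post hoc: the maximum pairwise
#' r-squared among retained SNPs is asserted to be at or below the
#' threshold on every run.
#'
#' @param geno dosage matrix.
#' @param candidates SNP ids to prune.
#' @param threshold r-squared threshold (default 0.7): pairs strictly
#'   above it are in substantial LD and one member is removed.
#' @param map optional SNP map supplying positions; defaults to the
#'   column order of \code{geno}.
#' @return object of class \code{prune_result}: list with
#'   \code{retained} (ids), \code{removed} (data.frame: snp_id, partner,
#'   r2, reason) and \code{threshold}.
#' @export
prune_ld <- function(geno, candidates, threshold = 0.7, map = NULL) {
  if (!length(candidates))
    return(structure(list(retained = character(0),
                          removed = data.frame(snp_id = character(0),
                                               partner = character(0),
                                               r2 = numeric(0),
                                               reason = character(0)),
                          threshold = threshold),
                     class = "prune_result"))
  stopifnot(all(candidates %in% colnames(geno)))
  pos <- if (!is.null(map)) map$position[match(candidates, map$snp_id)]
         else match(candidates, colnames(geno))
  ord <- order(pos)
  snps <- candidates[ord]
  G <- geno[, snps, drop = FALSE]
  R2 <- suppressWarnings(stats::cor(G, use = "pairwise.complete.obs")^2)
  if (anyNA(R2))
    warning("undefined r-squared for some pair(s); treated as below threshold")
  R2[is.na(R2)] <- 0
  miss <- snp_missingness(G)

  alive <- rep(TRUE, length(snps))
  removed <- list()
  repeat {
    clean <- TRUE
    idx <- which(alive)
    for (ai in seq_along(idx)) {
      i <- idx[ai]
      if (!alive[i]) next
      for (bi in seq_along(idx)) {
        if (bi <= ai) next
        j <- idx[bi]
        if (!alive[j]) next
        if (R2[i, j] > threshold) {
          # drop the higher-missingness member; ties drop higher position
          drop_j <- miss[j] > miss[i] || (miss[j] == miss[i])
          rm_i <- if (drop_j) j else i
          keep_i <- if (drop_j) i else j
          alive[rm_i] <- FALSE
          removed[[length(removed) + 1L]] <- data.frame(
            snp_id = snps[rm_i], partner = snps[keep_i],
            r2 = R2[i, j],
            reason = if (miss[i] == miss[j]) "tie_higher_position"
                     else "higher_missingness")
          clean <- FALSE
          if (rm_i == i) break
        }
      }
    }
    if (clean) break
  }
  retained <- snps[alive]
  if (length(retained) > 1L) {
    mx <- max(R2[alive, alive][upper.tri(R2[alive, alive])])
    stopifnot(mx <= threshold)
  }
  structure(list(
    retained = retained,
    removed = if (length(removed)) do.call(rbind, removed)
              else data.frame(snp_id = character(0), partner = character(0),
                              r2 = numeric(0), reason = character(0)),
    threshold = threshold),
    class = "prune_result")
}

#' @export
print.prune_result <- function(x, ...) {
  cat(sprintf("LD pruning at r2 > %g: %d retained, %d removed\n",
              x$threshold, length(x$retained), nrow(x$removed)))
  invisible(x)
}
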