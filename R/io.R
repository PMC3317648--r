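#' Prepare a phenotype table for analysis
#'
#' Natural-log transforms the raw trait and removes outliers in a single
#' pass: the mean and standard deviation are computed once on the ln scale
#' over all non-missing values, and rows whose ln-trait lies more than
#' \code{sd_bound} standard deviations from the mean are dropped.  The
#' pass is not iterated, so the operation is idempotent: re-applying it
#' with the same bound removes nothing further.
#'
#' @param raw data.frame with columns \code{individual_id} and
#'   \code{trait_raw} (strictly positive, e.g. triglycerides in mg/dL)
#'   plus any covariate columns, which are carried through unchanged.
#' @param sd_bound outlier bound in standard-deviation units (default 4).
#' @return The table with a \code{trait} column (\code{ln(trait_raw)}),
#'   outlier rows removed, and attributes \code{n_removed} and
#'   \code{removed_ids}.
#' @export
prepare_phenotype <- function(raw, sd_bound = 4) {
  stopifnot(is.data.frame(raw),
            all(c("individual_id", "trait_raw") %in% names(raw)))
  tr <- raw$trait_raw
  bad <- !is.na(tr) & tr <= 0
  if (any(bad))
    stop("non-positive trait_raw for individual(s): ",
         paste(raw$individual_id[bad], collapse = ", "))
  lt <- log(tr)
  mu <- mean(lt, na.rm = TRUE)
  sdv <- stats::sd(lt, na.rm = TRUE)
  if (is.na(sdv) || sdv == 0) {
    warning("trait standard deviation is zero; no outlier removal performed")
    keep <- rep(TRUE, nrow(raw))
  } else {
    keep <- is.na(lt) | abs(lt - mu) / sdv <= sd_bound
  }
  out <- raw[keep, , drop = FALSE]
  out$trait <- lt[keep]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(!keep)
  attr(out, "removed_ids") <- raw$individual_id[!keep]
  out
}

#' Read and write pipeline file formats
#'
#' Tab-delimited text formats that round-trip bit-exactly for ids and
#' values: phenotype tables (header row, \code{individual_id} column
#' required), SNP maps (\code{snp_id}, \code{chromosome}, \code{position};
#' 1-based positions, rows sorted by chromosome then position on read,
#' duplicate SNP ids rejected), genotype matrices (first column
#' \code{individual_id}, one column per SNP holding reference-allele
#' dosage 0/1/2 with \code{NA} for missing), and square matrices with ids
#' as both header and first column (locus IBD, kinship).
#'
#' @param path file path.
#' @name io
NULL

#' @rdname io
#' @export
read_phenotypes <- function(path) {
  out <- utils::read.delim(path, check.names = FALSE, comment.char = "#")
  if (!"individual_id" %in% names(out))
    stop("phenotype file must have an 'individual_id' column: ", path)
  out$individual_id <- as.character(out$individual_id)
  out
}

#' @rdname io
#' @param phen phenotype data.frame.
#' @export
write_phenotypes <- function(phen, path) {
  utils::write.table(phen, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_map <- function(path) {
  map <- utils::read.delim(path, check.names = FALSE, comment.char = "#")
  need <- c("snp_id", "chromosome", "position")
  if (!all(need %in% names(map)))
    stop("map file must have columns ", paste(need, collapse = ", "))
  map$snp_id <- as.character(map$snp_id)
  dup <- duplicated(map$snp_id)
  if (any(dup))
    stop("duplicate snp_id(s) in map: ",
         paste(unique(map$snp_id[dup]), collapse = ", "))
  map <- map[order(map$chromosome, map$position), , drop = FALSE]
  rownames(map) <- NULL
  map
}

#' @rdname io
#' @param map SNP map data.frame.
#' @export
write_map <- function(map, path) {
  utils::write.table(map, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_genotypes <- function(path) {
  g <- utils::read.delim(path, check.names = FALSE, comment.char = "#")
  if (names(g)[1L] != "individual_id")
    stop("genotype file must start with an 'individual_id' column: ", path)
  ids <- as.character(g[[1L]])
  m <- as.matrix(g[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  bad <- !(m %in% c(0, 1, 2) | is.na(m))
  if (any(bad))
    stop("genotype dosages must be 0, 1, 2 or NA (",
         sum(bad), " offending entries)")
  rownames(m) <- ids
  m
}

#' @rdname io
#' @param geno genotype dosage matrix (ids x SNPs).
#' @export
write_genotypes <- function(geno, path) {
  out <- data.frame(individual_id = rownames(geno), geno,
                    check.names = FALSE)
  utils::write.table(out, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_matrix <- function(path) {
  m <- as.matrix(utils::read.delim(path, row.names = 1L,
                                   check.names = FALSE, comment.char = "#"))
  storage.mode(m) <- "double"
  colnames(m) <- rownames(m)
  m
}

#' @rdname io
#' @param mat square matrix with id dimnames.
#' @export
write_matrix <- function(mat, path) {
  out <- data.frame(id = rownames(mat), mat, check.names = FALSE)
  utils::write.table(out, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}

#' Per-SNP missingness of a genotype matrix
#'
#' @param geno dosage matrix (ids x SNPs).
#' @return named vector, fraction missing per SNP in [0, 1].
#' @export
snp_missingness <- function(geno) colMeans(is.na(geno))

#' Align pedigree, phenotypes, genotypes and IBD into one analysis set
#'
#' Intersects individual ids across the supplied sources, computes the
#' kinship matrix from the full pedigree (so that relationships through
#' unphenotyped connectors are preserved) and subsets every matrix to the
#' common ids in a single shared order.  Per-source exclusion counts are
#' recorded.
#'
#' @param ped validated \code{pedigree}.
#' @param phen prepared phenotype table (see
#'   \code{\link{prepare_phenotype}}).
#' @param geno optional genotype dosage matrix (ids x SNPs).
#' @param map optional SNP map matching \code{geno} columns.
#' @param ibd optional locus IBD matrix with id dimnames.
#' @param kinship optional precomputed kinship matrix; computed from
#'   \code{ped} when omitted.
#' @return An \code{analysis_set}: list with \code{data} (phenotypes plus
#'   \code{family_id}), \code{geno}, \code{map}, \code{kinship},
#'   \code{ibd}, \code{ids}, \code{excluded}.
#' @export
align_datasets <- function(ped, phen, geno = NULL, map = NULL, ibd = NULL,
                           kinship = NULL) {
  stopifnot(inherits(ped, "pedigree"))
  ids <- intersect(ped$individual_id, phen$individual_id)
  if (!is.null(geno)) ids <- intersect(ids, rownames(geno))
  if (!is.null(ibd))  ids <- intersect(ids, rownames(ibd))
  if (!length(ids))
    stop("no individuals shared across the supplied data sources")
  ids <- ped$individual_id[ped$individual_id %in% ids]  # pedigree order

  excluded <- list(
    pedigree   = sum(!ped$individual_id %in% ids),
    phenotypes = sum(!phen$individual_id %in% ids),
    genotypes  = if (!is.null(geno)) sum(!rownames(geno) %in% ids),
    ibd        = if (!is.null(ibd)) sum(!rownames(ibd) %in% ids))

  if (is.null(kinship)) kinship <- kinship_matrix(ped)
  data <- phen[match(ids, phen$individual_id), , drop = FALSE]
  data$family_id <- ped$family_id[match(ids, ped$individual_id)]
  rownames(data) <- NULL

  if (!is.null(map) && !is.null(geno)) {
    if (!all(colnames(geno) %in% map$snp_id))
      stop("genotype SNP(s) absent from map: ",
           paste(utils::head(setdiff(colnames(geno), map$snp_id), 5L),
                 collapse = ", "))
    map <- map[match(colnames(geno), map$snp_id), , drop = FALSE]
    ord <- order(map$chromosome, map$position)
    map <- map[ord, , drop = FALSE]
    geno <- geno[, map$snp_id, drop = FALSE]
    rownames(map) <- NULL
  }

  structure(list(
    data = data,
    geno = if (!is.null(geno)) geno[ids, , drop = FALSE],
    map = map,
    kinship = kinship[ids, ids],
    ibd = if (!is.null(ibd)) ibd[ids, ids],
    ids = ids, excluded = excluded),
    class = "analysis_set")
}

#' @export
print.analysis_set <- function(x, ...) {
  cat(sprintf("Analysis set: %d individuals in %d families",
              length(x$ids), length(unique(x$data$family_id))))
  if (!is.null(x$geno)) cat(sprintf(", %d SNPs", ncol(x$geno)))
  cat(if (is.null(x$ibd)) "\n" else "; locus IBD attached\n")
  invisible(x)
}
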