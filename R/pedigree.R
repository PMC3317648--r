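#' Validate raw pedigree records
#'
#' Builds a validated, topologically ordered pedigree from raw records in
#' the PED/FAM first-five-column dialect (family, individual, father,
#' mother, sex).  Parent codes \code{"0"}, \code{""} and \code{NA} are
#' normalised to missing; sex codes 1/2/0 become
#' \code{"male"}/\code{"female"}/\code{"unknown"}.
#'
#' An individual must have either both parents known (non-founder) or
#' neither (founder); half-known parents are rejected rather than imputed,
#' since inventing a dummy parent silently changes kinship.  Parents must
#' be records of the same family: families are the connected components of
#' the pedigree, so cross-family marriages are not representable.
#' Individual ids must be unique across the whole pedigree because every
#' downstream matrix (kinship, IBD, genotypes) is keyed by individual id.
#'
#' @param records data.frame with at least five columns, interpreted as
#'   family id, individual id, father id, mother id, sex (1 = male,
#'   2 = female, 0 = unknown).  Extra columns are ignored.
#' @return A \code{pedigree}: a data.frame with columns \code{family_id},
#'   \code{individual_id}, \code{father_id}, \code{mother_id}, \code{sex},
#'   \code{founder}, ordered so that parents precede offspring.
#' @examples
#' ped <- validate_pedigree(data.frame(
#'   fam = "1", id = c("dad", "mom", "kid"),
#'   fa = c("0", "0", "dad"), mo = c("0", "0", "mom"), sex = c(1, 2, 2)))
#' sum(ped$founder)
#' @export
validate_pedigree <- function(records) {
  records <- as.data.frame(records)
  if (ncol(records) < 5L)
    stop("pedigree records need at least 5 columns (family, individual, ",
         "father, mother, sex)")
  ped <- data.frame(
    family_id     = as.character(records[[1L]]),
    individual_id = as.character(records[[2L]]),
    father_id     = as.character(records[[3L]]),
    mother_id     = as.character(records[[4L]]),
    sex           = .decode_sex(records[[5L]]),
    stringsAsFactors = FALSE)

  for (col in c("family_id", "individual_id"))
    if (anyNA(ped[[col]]) || any(!nzchar(ped[[col]])))
      stop("empty or missing ", col, " in pedigree records")

  miss <- function(x) is.na(x) | x == "0" | !nzchar(x)
  ped$father_id[miss(ped$father_id)] <- NA_character_
  ped$mother_id[miss(ped$mother_id)] <- NA_character_

  dup <- duplicated(ped$individual_id)
  if (any(dup))
    stop("duplicated individual id(s): ",
         paste(unique(ped$individual_id[dup]), collapse = ", "))

  half <- xor(is.na(ped$father_id), is.na(ped$mother_id))
  if (any(half))
    stop("individual(s) with exactly one known parent (not supported, ",
         "parents must be both known or both missing): ",
         paste(ped$individual_id[half], collapse = ", "))
  ped$founder <- is.na(ped$father_id)

  self_par <- !ped$founder &
    (ped$father_id == ped$individual_id | ped$mother_id == ped$individual_id)
  if (any(self_par))
    stop("individual(s) listed as their own parent: ",
         paste(ped$individual_id[self_par], collapse = ", "))

  # parents must exist, in the same family
  fam_of <- stats::setNames(ped$family_id, ped$individual_id)
  for (side in c("father_id", "mother_id")) {
    ref <- ped[[side]][!ped$founder]
    absent <- !(ref %in% ped$individual_id)
    if (any(absent))
      stop("referenced ", sub("_id", "", side), "(s) absent from pedigree: ",
           paste(unique(ref[absent]), collapse = ", "))
    cross <- fam_of[ref] != ped$family_id[!ped$founder]
    if (any(cross))
      stop("parent(s) referenced across families: ",
           paste(unique(ref[cross]), collapse = ", "))
  }

  ped <- ped[.topological_order(ped), , drop = FALSE]
  rownames(ped) <- NULL
  class(ped) <- c("pedigree", "data.frame")
  ped
}

.decode_sex <- function(x) {
  x <- as.character(x)
  out <- rep("unknown", length(x))
  out[x %in% c("1", "m", "M", "male")]   <- "male"
  out[x %in% c("2", "f", "F", "female")] <- "female"
  out
}

# Kahn's algorithm; detects cycles and names an individual on one.
.topological_order <- function(ped) {
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$individual_id)
  indeg <- integer(n)
  kids <- vector("list", n)   # kids[[i]]: rows whose parent is row i
  for (i in which(!ped$founder)) {
    for (p in c(ped$father_id[i], ped$mother_id[i])) {
      j <- idx[[p]]
      kids[[j]] <- c(kids[[j]], i)
      indeg[i] <- indeg[i] + 1L
    }
  }
  queue <- which(indeg == 0L)
  order <- integer(0)
  while (length(queue)) {
    i <- queue[1L]; queue <- queue[-1L]
    order <- c(order, i)
    for (j in kids[[i]]) {
      indeg[j] <- indeg[j] - 1L
      if (indeg[j] == 0L) queue <- c(queue, j)
    }
  }
  if (length(order) < n) {
    bad <- setdiff(seq_len(n), order)
    stop("pedigree cycle detected involving individual(s): ",
         paste(ped$individual_id[bad], collapse = ", "))
  }
  order
}

#' @export
print.pedigree <- function(x, ...) {
  cat(sprintf("Pedigree: %d individuals in %d families (%d founders)\n",
              nrow(x), length(unique(x$family_id)), sum(x$founder)))
  invisible(x)
}

#' Kinship matrix of a pedigree
#'
#' Computes the kinship coefficients \eqn{\Phi_{ij}} (the probability that
#' a random allele drawn from i is identical by descent with one drawn
#' from j) by the standard recursion in topological order:
#' \eqn{\Phi_{ij} = (\Phi_{f(i),j} + \Phi_{m(i),j})/2} for non-founder i
#' with \eqn{j} already processed, \eqn{\Phi_{ii} = (1 + F_i)/2} with
#' inbreeding \eqn{F_i = \Phi_{f(i),m(i)}}, and founders unrelated
#' (\eqn{\Phi = 1/2} on, 0 off the diagonal).  Individuals in different
#' families have kinship zero, so the matrix is block-diagonal by family.
#' The polygenic covariance used by \code{\link{vc_fit}} is \eqn{2\Phi}.
#'
#' @param ped a \code{pedigree} from \code{\link{validate_pedigree}}.
#' @return Symmetric numeric matrix of kinship coefficients with
#'   individual ids as dimnames, rows in pedigree (topological) order.
#' @examples
#' ped <- validate_pedigree(data.frame(
#'   fam = "1", id = c("p1", "p2", "s1", "s2"),
#'   fa = c("0", "0", "p1", "p1"), mo = c("0", "0", "p2", "p2"),
#'   sex = c(1, 2, 0, 0)))
#' kinship_matrix(ped)["s1", "s2"]   # full sibs: 0.25
#' @export
kinship_matrix <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  ids <- ped$individual_id
  n <- length(ids)
  phi <- matrix(0, n, n, dimnames = list(ids, ids))
  idx <- stats::setNames(seq_len(n), ids)
  for (i in seq_len(n)) {
    if (ped$founder[i]) {
      phi[i, i] <- 0.5
    } else {
      f <- idx[[ped$father_id[i]]]
      m <- idx[[ped$mother_id[i]]]
      if (i > 1L) {
        prev <- seq_len(i - 1L)
        phi[i, prev] <- 0.5 * (phi[f, prev] + phi[m, prev])
        phi[prev, i] <- phi[i, prev]
      }
      phi[i, i] <- 0.5 * (1 + phi[f, m])
    }
  }
  phi
}

#' Read / write pedigrees in PED/FAM dialect
#'
#' Whitespace-delimited text, first five columns family, individual,
#' father, mother, sex; \code{"0"} codes a missing parent, sex is 1 = male,
#' 2 = female, 0 = unknown.  \code{read_ped} validates on read.
#'
#' @param path file path.
#' @return \code{read_ped}: a validated \code{pedigree}.
#' @export
read_ped <- function(path) {
  raw <- utils::read.table(path, header = FALSE, colClasses = "character",
                           comment.char = "#")
  validate_pedigree(raw)
}

#' @rdname read_ped
#' @param ped pedigree to write.
#' @export
write_ped <- function(ped, path) {
  stopifnot(inherits(ped, "pedigree"))
  out <- data.frame(
    ped$family_id, ped$individual_id,
    ifelse(is.na(ped$father_id), "0", ped$father_id),
    ifelse(is.na(ped$mother_id), "0", ped$mother_id),
    c(male = 1L, female = 2L, unknown = 0L)[ped$sex])
  utils::write.table(out, path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write kinship coefficients as sparse three-column text
#'
#' Emits one line per pair with nonzero kinship (upper triangle including
#' the diagonal): \code{id1 id2 phi}.
#'
#' @param phi kinship matrix from \code{\link{kinship_matrix}}.
#' @param path output file.
#' @export
write_kinship <- function(phi, path) {
  ids <- rownames(phi)
  up <- which(upper.tri(phi, diag = TRUE) & phi != 0, arr.ind = TRUE)
  out <- data.frame(id1 = ids[up[, 1L]], id2 = ids[up[, 2L]],
                    phi = phi[up])
  utils::write.table(out, path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
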