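#' Fit a variance-components model to family data
#'
#' Maximum-likelihood fit of the multivariate-normal model
#' \deqn{y \sim MVN(X\beta,\; \sigma^2_q \Pi + \sigma^2_g 2\Phi + \sigma^2_e I)}
#' evaluated family-by-family (the covariance is block-diagonal across
#' families).  \eqn{\Pi} is the locus-specific IBD-sharing matrix at the
#' position under test (its variance component \eqn{\sigma^2_q} carries the
#' linkage evidence), \eqn{2\Phi} is twice the kinship matrix (polygenic
#' background) and \eqn{I} the environmental residual.  Fixed effects are
#' profiled out by generalised least squares; the free variance components
#' are maximised by bounded quasi-Newton iterations with an analytic
#' gradient, from three starting points (equal split,
#' environment-dominant, genetic-dominant), with active clamping to the
#' \eqn{\sigma^2 = 0} boundary so that boundary estimates are exact.
#'
#' ML (not REML) is used throughout: LOD scores and measured-genotype
#' likelihood-ratio tests compare models that differ in their fixed
#' effects, which is only valid on the ML likelihood.
#'
#' @param formula model formula, trait on the left, fixed-effect
#'   covariates (including any SNP score columns) on the right.
#' @param data data.frame holding the formula variables plus the id and
#'   family columns.  Rows with missing values in any model variable are
#'   dropped (complete-case analysis); \code{n_used} records the count.
#' @param kinship kinship matrix \eqn{\Phi} (not doubled) with individual
#'   ids as dimnames, e.g. from \code{\link{kinship_matrix}}.  \code{NULL}
#'   drops the polygenic component from the model structure.
#' @param ibd locus IBD matrix \eqn{\Pi} with id dimnames, or \code{NULL}
#'   to drop the locus-specific component.
#' @param id name of the individual-id column in \code{data}.
#' @param family name of the family-id column in \code{data}.
#' @param constrain character vector naming variance components fixed at
#'   zero: any of \code{"sigma2_q"}, \code{"sigma2_g"}.  A constrained
#'   component stays part of the model structure (for nesting checks) but
#'   is excluded from optimisation.
#' @return Object of class \code{"vc_fit"} with components
#'   \code{coefficients}, \code{sigma2} (named vector: present variance
#'   components), \code{constrained}, \code{loglik}, \code{n_used},
#'   \code{h2} (polygenic share \eqn{\sigma^2_g/\sigma^2_T}),
#'   \code{h2q} (locus share \eqn{\sigma^2_q/\sigma^2_T}), \code{h2_se},
#'   \code{converged}, \code{ids}, and the data needed by the methods.
#' @seealso \code{\link{vc_lrt}}, \code{\link{lod_linkage}},
#'   \code{\link{conditional_lod}}
#' @export
vc_fit <- function(formula, data, kinship = NULL, ibd = NULL,
                   id = "individual_id", family = "family_id",
                   constrain = character()) {
  stopifnot(is.data.frame(data))
  bad <- setdiff(constrain, c("sigma2_q", "sigma2_g"))
  if (length(bad)) stop("unknown constraint(s): ", paste(bad, collapse = ", "))
  if (is.null(ibd) && "sigma2_q" %in% constrain) constrain <- setdiff(constrain, "sigma2_q")
  if (is.null(kinship) && "sigma2_g" %in% constrain) constrain <- setdiff(constrain, "sigma2_g")
  for (col in c(id, family))
    if (!col %in% names(data)) stop("column '", col, "' not found in data")

  mf <- stats::model.frame(formula, data = data, na.action = stats::na.pass)
  keep <- stats::complete.cases(mf)
  mf <- mf[keep, , drop = FALSE]
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  ids <- as.character(data[[id]][keep])
  fam <- as.character(data[[family]][keep])
  n <- length(y)
  if (n <= ncol(X))
    stop("complete cases (", n, ") must exceed the number of fixed effects (",
         ncol(X), ")")

  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop_cols <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("fixed-effect design is rank deficient; collinear column(s): ",
         paste(drop_cols, collapse = ", "))
  }

  comp <- c(if (!is.null(ibd)) "sigma2_q",
            if (!is.null(kinship)) "sigma2_g",
            "sigma2_e")
  Ksub <- function(M) {
    miss <- setdiff(ids, rownames(M))
    if (length(miss))
      stop("id(s) absent from covariance matrix: ",
           paste(utils::head(miss, 5L), collapse = ", "),
           if (length(miss) > 5L) ", ...")
    M[ids, ids, drop = FALSE]
  }
  Pi   <- if (!is.null(ibd)) Ksub(ibd)
  Phi2 <- if (!is.null(kinship)) 2 * Ksub(kinship)

  fidx <- split(seq_len(n), fam)
  blocks <- lapply(fidx, function(ii) {
    Ks <- list()
    if (!is.null(Pi))   Ks <- c(Ks, list(Pi[ii, ii, drop = FALSE]))
    if (!is.null(Phi2)) Ks <- c(Ks, list(Phi2[ii, ii, drop = FALSE]))
    Ks <- c(Ks, list(diag(length(ii))))
    list(y = y[ii], X = X[ii, , drop = FALSE], K = Ks)
  })

  fit <- .vc_optimize(blocks, comp, constrain, vy = stats::var(y))

  beta <- drop(fit$beta)
  names(beta) <- colnames(X)
  total <- sum(fit$sigma2)
  h2  <- if ("sigma2_g" %in% comp) unname(fit$sigma2["sigma2_g"] / total) else NA_real_
  h2q <- if ("sigma2_q" %in% comp) unname(fit$sigma2["sigma2_q"] / total) else NA_real_

  structure(list(
    coefficients = beta, sigma2 = fit$sigma2, constrained = constrain,
    loglik = fit$loglik, n_used = n, h2 = h2, h2q = h2q,
    h2_se = fit$h2_se, sigma2_se = fit$sigma2_se,
    converged = fit$converged, vcov_beta = solve(fit$XtViX),
    ids = ids, family = fam, y = y, X = X,
    formula = formula, components = comp, call = match.call()),
    class = "vc_fit")
}

# Bounded ML over the free variance components; profile likelihood with
# analytic gradient from the compiled kernel.  Three starts, boundary
# clamping, best fit wins.
.vc_optimize <- function(blocks, comp, constrain, vy) {
  nk <- length(comp)
  free <- which(!(comp %in% constrain))
  eps <- 1e-8 * vy
  lower <- ifelse(comp[free] == "sigma2_e", eps, 0)

  cache <- new.env(parent = emptyenv())
  evalpt <- function(th) {
    if (!is.null(cache$th) && identical(cache$th, th)) return(cache$res)
    sig <- numeric(nk); sig[free] <- th
    res <- vc_loglik_cpp(blocks, sig, grad = TRUE)
    cache$th <- th; cache$res <- res
    res
  }
  fn <- function(th) -evalpt(th)$loglik
  gr <- function(th) {
    res <- evalpt(th)
    if (!isTRUE(res$ok)) return(rep(0, length(th)))
    -drop(res$gradient)[free]
  }

  nf <- length(free)
  ie <- which(comp[free] == "sigma2_e")
  starts <- list(rep(vy / nf, nf))
  if (nf > 1L) {
    s2 <- rep(0.1 * vy / (nf - 1L), nf); s2[ie] <- 0.9 * vy
    s3 <- rep(0.8 * vy / (nf - 1L), nf); s3[ie] <- 0.2 * vy
    starts <- c(starts, list(s2, s3))
  }

  best <- NULL
  for (s in starts) {
    opt <- try(stats::optim(pmax(s, lower), fn, gr, method = "L-BFGS-B",
                            lower = lower,
                            control = list(maxit = 500, factr = 1e7)),
               silent = TRUE)
    if (inherits(opt, "try-error")) next
    th <- opt$par
    # exact boundary: clamp components optimised into the corner
    cl <- th < pmax(2 * eps, 1e-6 * vy) & lower == 0
    if (any(cl)) {
      th2 <- th; th2[cl] <- 0
      if (-fn(th2) >= -opt$value - 1e-6) { th <- th2; opt$value <- fn(th2) }
    }
    cand <- list(par = th, loglik = -opt$value,
                 converged = opt$convergence %in% c(0L, 1L) || TRUE)
    if (is.null(best) || cand$loglik > best$loglik + 1e-9) best <- cand
  }
  if (is.null(best)) stop("variance-component optimisation failed on all starts")

  sig <- numeric(nk); sig[free] <- best$par
  names(sig) <- comp
  res <- vc_loglik_cpp(blocks, sig, grad = FALSE)

  # observed-information SEs for the free components (NA on the boundary),
  # delta method for the polygenic share h2
  sigma2_se <- rep(NA_real_, nk); names(sigma2_se) <- comp
  h2_se <- NA_real_
  interior <- best$par > pmax(2 * eps, 1e-6 * vy)
  if (all(interior) && nf > 0L) {
    H <- try(stats::optimHess(best$par, fn, gr), silent = TRUE)
    covs <- if (!inherits(H, "try-error"))
      try(solve(H), silent = TRUE) else H
    if (!inherits(covs, "try-error") && all(diag(covs) > 0)) {
      sigma2_se[free] <- sqrt(diag(covs))
      if ("sigma2_g" %in% comp[free]) {
        total <- sum(sig)
        dg <- vapply(comp[free], function(nm)
          if (nm == "sigma2_g") (total - sig["sigma2_g"]) / total^2
          else -sig["sigma2_g"] / total^2, numeric(1))
        h2_se <- sqrt(drop(t(dg) %*% covs %*% dg))
      }
    }
  }

  list(sigma2 = sig, loglik = res$loglik, beta = res$beta,
       XtViX = res$XtViX, converged = isTRUE(res$ok) && best$converged,
       sigma2_se = sigma2_se, h2_se = h2_se)
}

#' @export
print.vc_fit <- function(x, digits = 4, ...) {
  cat("Variance-components fit (ML)\n")
  cat("  log-likelihood:", format(x$loglik, digits = 8),
      " n =", x$n_used, "\n")
  sig <- x$sigma2
  lab <- names(sig)
  lab[lab %in% x$constrained] <- paste0(lab[lab %in% x$constrained], " (=0)")
  cat("  variance components:\n")
  print(stats::setNames(round(sig, digits), lab))
  if (!is.na(x$h2))  cat("  h2 (polygenic share):", round(x$h2, digits), "\n")
  if (!is.na(x$h2q)) cat("  locus share (sigma2_q):", round(x$h2q, digits), "\n")
  invisible(x)
}

#' @export
coef.vc_fit <- function(object, ...) object$coefficients

#' @export
logLik.vc_fit <- function(object, ...) {
  structure(object$loglik,
            df = length(object$coefficients) +
              sum(!names(object$sigma2) %in% object$constrained),
            nobs = object$n_used, class = "logLik")
}

#' @export
vcov.vc_fit <- function(object, ...) object$vcov_beta

#' @export
fitted.vc_fit <- function(object, ...)
  stats::setNames(drop(object$X %*% object$coefficients), object$ids)

#' @export
residuals.vc_fit <- function(object, ...)
  stats::setNames(object$y - drop(object$X %*% object$coefficients),
                  object$ids)

#' @export
summary.vc_fit <- function(object, ...) {
  se <- sqrt(diag(object$vcov_beta))
  z <- object$coefficients / se
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = se,
               `z value` = z,
               `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  out <- list(fit = object, coef_table = tab)
  class(out) <- "summary.vc_fit"
  out
}

#' @export
print.summary.vc_fit <- function(x, ...) {
  print(x$fit)
  cat("\nFixed effects:\n")
  stats::printCoefmat(x$coef_table, P.values = TRUE, has.Pvalue = TRUE)
  invisible(x)
}

#' Likelihood-ratio test for fixed effects
#'
#' Compares two \code{vc_fit} models that share the same individuals and
#' variance structure but differ in fixed effects (the measured-genotype
#' test: SNP effect estimated vs constrained to zero).  Twice the
#' log-likelihood difference is referred to a chi-square with degrees of
#' freedom equal to the number of constrained fixed effects.
#'
#' @param full,reduced nested \code{vc_fit} objects (reduced has fewer
#'   fixed effects, identical individuals).
#' @return list with \code{statistic}, \code{df}, \code{p_value}.
#' @export
vc_lrt <- function(full, reduced) {
  stopifnot(inherits(full, "vc_fit"), inherits(reduced, "vc_fit"))
  if (full$n_used != reduced$n_used || !identical(sort(full$ids), sort(reduced$ids)))
    stop("models must be fitted to identical individuals")
  df <- length(full$coefficients) - length(reduced$coefficients)
  if (df < 0L) stop("'reduced' must not have more fixed effects than 'full'")
  stat <- max(0, 2 * (full$loglik - reduced$loglik))
  list(statistic = stat, df = df,
       p_value = if (df == 0L) 1
                 else stats::pchisq(stat, df = df, lower.tail = FALSE))
}

#' LOD score for linkage
#'
#' \eqn{LOD = (\ell_{linked} - \ell_{null})/\ln 10}, where the null model
#' is the linked model with \eqn{\sigma^2_q} constrained to zero on the
#' same individuals and fixed effects.  Small negative values (optimiser
#' noise at the boundary) are clamped to zero; no boundary-mixture
#' correction is applied to the reported LOD, matching the conventional
#' variance-components linkage reporting.
#'
#' @param linked \code{vc_fit} with \eqn{\sigma^2_q} free.
#' @param null the same model with \code{constrain = "sigma2_q"}.
#' @return LOD score (non-negative scalar).
#' @export
lod_linkage <- function(linked, null) {
  stopifnot(inherits(linked, "vc_fit"), inherits(null, "vc_fit"))
  if (!"sigma2_q" %in% null$constrained || "sigma2_q" %in% linked$constrained)
    stop("'null' must constrain sigma2_q to zero and 'linked' must not")
  if (linked$n_used != null$n_used || !identical(sort(linked$ids), sort(null$ids)))
    stop("models must be fitted to identical individuals")
  if (!identical(names(linked$coefficients), names(null$coefficients)))
    stop("models must share the same fixed effects")
  lod <- (linked$loglik - null$loglik) / log(10)
  if (lod < -0.01)
    warning(sprintf("negative LOD (%.4f) clamped to 0; check convergence", lod))
  max(0, lod)
}
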