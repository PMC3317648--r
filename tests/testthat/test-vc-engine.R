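# fixtures: a polygenic cohort small enough for whole-matrix oracles
make_vc_data <- function(seed, n_fam = 40, h2 = 0.4, q2 = 0,
                         with_ibd = FALSE) {
  set.seed(seed)
  cfg <- sim_config(n_families = n_fam, n_snps = 12, cluster_fraction = 0.5,
                    n_causal = 0, causal_share_total = 0, h2_polygenic = h2,
                    covariate_share = 0, missingness = 0)
  co <- simulate_cohort(cfg)
  phen <- prepare_phenotype(co$phen)
  align_datasets(co$ped, phen, co$geno, co$map,
                 ibd = if (with_ibd) co$ibd, kinship = co$kinship)
}

test_that("the diagonal-covariance limit equals the OLS closed form", {
  aset <- make_vc_data(101)
  fit <- vc_fit(trait ~ age + sex, aset$data, kinship = aset$kinship,
                constrain = "sigma2_g")
  ols <- lm(trait ~ age + sex, aset$data)
  s2 <- mean(resid(ols)^2)                       # ML variance estimate
  ll <- sum(dnorm(aset$data$trait, fitted(ols), sqrt(s2), log = TRUE))
  expect_equal(fit$loglik, ll, tolerance = 1e-6)
  expect_equal(unname(coef(fit)), unname(coef(ols)), tolerance = 1e-6)
  expect_equal(unname(fit$sigma2["sigma2_g"]), 0)
})

test_that("block-diagonal likelihood matches whole-matrix evaluation", {
  aset <- make_vc_data(103, n_fam = 25, with_ibd = TRUE)
  fit <- vc_fit(trait ~ age, aset$data, kinship = aset$kinship,
                ibd = aset$ibd)
  ids <- aset$data$individual_id
  X <- model.matrix(~age, aset$data)
  ll <- mvn_loglik_whole(aset$data$trait, X, coef(fit), fit$sigma2,
                         Phi = aset$kinship[ids, ids],
                         Pi = aset$ibd[ids, ids])
  expect_equal(fit$loglik, ll, tolerance = 1e-8)
})

test_that("duplicating every family doubles the log-likelihood exactly", {
  aset <- make_vc_data(107, n_fam = 20)
  d <- aset$data
  d2 <- rbind(d, transform(d, individual_id = paste0(individual_id, "_b"),
                           family_id = paste0(family_id, "_b")))
  k <- aset$kinship
  k2 <- rbind(cbind(k, 0 * k), cbind(0 * k, k))
  ids2 <- d2$individual_id
  dimnames(k2) <- list(ids2, ids2)
  f1 <- vc_fit(trait ~ age, d, kinship = aset$kinship)
  f2 <- vc_fit(trait ~ age, d2, kinship = k2)
  expect_equal(f2$loglik, 2 * f1$loglik, tolerance = 1e-6)
  expect_equal(coef(f2), coef(f1), tolerance = 1e-5)
})

test_that("singleton families reduce to the least-squares closed form", {
  set.seed(11)
  n <- 150
  d <- data.frame(individual_id = paste0("i", 1:n),
                  family_id = paste0("i", 1:n),
                  x = rnorm(n))
  d$trait <- 1 + 0.5 * d$x + rnorm(n)
  phi <- diag(0.5, n)
  dimnames(phi) <- list(d$individual_id, d$individual_id)
  fit <- vc_fit(trait ~ x, d, kinship = phi)
  ols <- lm(trait ~ x, d)
  s2 <- mean(resid(ols)^2)
  ll <- sum(dnorm(d$trait, fitted(ols), sqrt(s2), log = TRUE))
  expect_equal(fit$loglik, ll, tolerance = 1e-6)
  expect_equal(unname(coef(fit)), unname(coef(ols)), tolerance = 1e-5)
})

test_that("likelihood at the generating parameters never beats the ML fit", {
  for (seed in c(211, 223, 227)) {
    set.seed(seed)
    ped <- validate_pedigree(nuclear_records(30, n_sib = 3))
    phi <- kinship_matrix(ped)
    n <- nrow(ped)
    sig <- c(sigma2_g = 0.12, sigma2_e = 0.18)
    V <- sig["sigma2_g"] * 2 * phi + diag(sig["sigma2_e"], n)
    y <- drop(crossprod(chol(V), rnorm(n))) + 3
    d <- data.frame(individual_id = ped$individual_id,
                    family_id = ped$family_id, trait = y)
    fit <- vc_fit(trait ~ 1, d, kinship = phi)
    X <- matrix(1, n, 1)
    ll_truth <- mvn_loglik_whole(y, X, 3, as.list(sig), Phi = phi)
    expect_lte(ll_truth, fit$loglik + 1e-6)
  }
})

test_that("nesting is monotone in fixed effects and variance structure", {
  aset <- make_vc_data(109, n_fam = 30, with_ibd = TRUE)
  d <- aset$data
  f_small <- vc_fit(trait ~ age, d, kinship = aset$kinship)
  f_big   <- vc_fit(trait ~ age + sex + smoking, d, kinship = aset$kinship)
  expect_gte(f_big$loglik, f_small$loglik - 1e-6)
  f_con  <- vc_fit(trait ~ age, d, kinship = aset$kinship, ibd = aset$ibd,
                   constrain = "sigma2_q")
  f_free <- vc_fit(trait ~ age, d, kinship = aset$kinship, ibd = aset$ibd)
  expect_gte(f_free$loglik, f_con$loglik - 1e-6)
  expect_equal(f_con$loglik, f_small$loglik, tolerance = 1e-6)
})

test_that("refitting is deterministic", {
  aset <- make_vc_data(113, n_fam = 25)
  f1 <- vc_fit(trait ~ age, aset$data, kinship = aset$kinship)
  f2 <- vc_fit(trait ~ age, aset$data, kinship = aset$kinship)
  expect_identical(f1$loglik, f2$loglik)
  expect_identical(f1$sigma2, f2$sigma2)
})

test_that("degenerate designs raise the specified errors", {
  aset <- make_vc_data(127, n_fam = 20)
  d <- aset$data
  d$age_copy <- d$age
  expect_error(vc_fit(trait ~ age + age_copy, d, kinship = aset$kinship),
               "rank deficient.*age_copy")
  expect_error(vc_fit(trait ~ age, d[1:2, ], kinship = aset$kinship),
               "exceed")
})

test_that("the fixed-effect LRT has chi-square calibration and guards", {
  aset <- make_vc_data(131, n_fam = 30)
  d <- aset$data
  full <- vc_fit(trait ~ age + sex + smoking, d, kinship = aset$kinship)
  red  <- vc_fit(trait ~ age, d, kinship = aset$kinship)
  lrt <- vc_lrt(full, red)
  expect_equal(lrt$df, 2L)
  expect_gte(lrt$statistic, 0)
  # chi-square(2) tail has the exact closed form exp(-s/2)
  expect_equal(lrt$p_value, exp(-lrt$statistic / 2), tolerance = 1e-10)
  # same model twice: zero statistic, p = 1
  same <- vc_lrt(full, full)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  # chi-square(1) critical value sanity
  expect_equal(pchisq(qchisq(0.95, 1), 1, lower.tail = FALSE), 0.05)
  # different individuals refuse to compare
  red_sub <- vc_fit(trait ~ age, d[-1, ], kinship = aset$kinship)
  expect_error(vc_lrt(full, red_sub), "identical individuals")
})

test_that("LOD scores follow the definition and its guards", {
  aset <- make_vc_data(137, n_fam = 30, with_ibd = TRUE)
  d <- aset$data
  linked <- vc_fit(trait ~ age, d, kinship = aset$kinship, ibd = aset$ibd)
  null <- vc_fit(trait ~ age, d, kinship = aset$kinship, ibd = aset$ibd,
                 constrain = "sigma2_q")
  lod <- lod_linkage(linked, null)
  expect_equal(lod, max(0, (linked$loglik - null$loglik) / log(10)),
               tolerance = 1e-12)
  expect_gte(lod, 0)
  expect_error(lod_linkage(null, linked), "constrain")
  other <- vc_fit(trait ~ age + sex, d, kinship = aset$kinship,
                  ibd = aset$ibd, constrain = "sigma2_q")
  expect_error(lod_linkage(linked, other), "same fixed effects")
})

test_that("null-locus LODs follow the boundary half-mixture", {
  set.seed(149)
  cfg <- sim_config(n_families = 100, n_snps = 10, cluster_fraction = 0.5,
                    n_causal = 0, causal_share_total = 0,
                    h2_polygenic = 0.3, covariate_share = 0,
                    missingness = 0)
  lods <- replicate(100, {
    co <- simulate_cohort(cfg)
    phen <- prepare_phenotype(co$phen)
    aset <- align_datasets(co$ped, phen, co$geno, co$map, co$ibd,
                           kinship = co$kinship)
    linked <- vc_fit(trait ~ 1, aset$data, kinship = aset$kinship,
                     ibd = aset$ibd)
    null <- vc_fit(trait ~ 1, aset$data, kinship = aset$kinship,
                   ibd = aset$ibd, constrain = "sigma2_q")
    lod_linkage(linked, null)
  })
  # median of the half-mixture is 0; 0.83 is its upper 5% point
  expect_lte(median(lods), 0.15)
  expect_lte(mean(lods > 0.83), 0.12)
})

test_that("heritability estimates carry delta-method uncertainty", {
  aset <- make_vc_data(151, n_fam = 80, h2 = 0.4)
  fit <- vc_fit(trait ~ age, aset$data, kinship = aset$kinship)
  if (fit$sigma2["sigma2_g"] > 1e-4) {
    expect_true(is.finite(fit$h2_se))
    expect_gt(fit$h2_se, 0)
    expect_lt(fit$h2_se, 0.5)
  }
  expect_equal(fit$h2,
               unname(fit$sigma2["sigma2_g"] / sum(fit$sigma2)))
})
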