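test_that("additive coding maps homozygotes to +/-1 with the minor allele", {
  g <- matrix(c(0, 1, 2, 2, 2, 1), ncol = 1,
              dimnames = list(paste0("i", 1:6), "s1"))
  s <- encode_additive(g, "s1")            # counted allele is the major one
  expect_equal(as.numeric(s), c(1, 0, -1, -1, -1, 0))
  expect_false(attr(s, "minor_is_counted"))
  expect_equal(attr(s, "maf"), 1 - mean(g) / 2)

  gf <- g; gf[, 1] <- 2 - gf[, 1]          # allele-label flip
  sf <- encode_additive(gf, "s1")
  expect_equal(as.numeric(sf), as.numeric(s))  # same minor-allele coding
  expect_true(attr(sf, "minor_is_counted"))

  mono <- matrix(2, 4, 1, dimnames = list(paste0("i", 1:4), "s1"))
  expect_error(encode_additive(mono, "s1"), "monomorphic")
})

test_that("the scan detects a causal SNP and matches the LRT code path", {
  fx <- small_aset(301, n_families = 150, n_snps = 30, cluster_fraction = 1,
                   n_causal = 4, causal_share_total = 0.2, missingness = 0)
  aset <- fx$aset
  causal <- fx$cohort$truth$causal$snp_id
  scan <- single_snp_scan(aset, ~ age + sex, snp_ids = causal)
  expect_true(all(scan$status == "ok"))
  expect_lt(min(scan$p), 1e-4)             # ~5% of variance each, n ~ 780

  # identical to an explicit vc_fit + vc_lrt reconstruction
  sid <- causal[1]
  s <- encode_additive(aset$geno, sid)
  d <- aset$data
  d$.score <- as.numeric(s[match(d$individual_id, names(s))])
  d <- d[complete.cases(d[, c("trait", "age", "sex", ".score")]), ]
  f1 <- vc_fit(trait ~ age + sex + .score, d, kinship = aset$kinship)
  f0 <- vc_fit(trait ~ age + sex, d, kinship = aset$kinship)
  lrt <- vc_lrt(f1, f0)
  i <- match(sid, scan$snp_id)
  expect_equal(scan$p[i], lrt$p_value, tolerance = 1e-8)
  expect_equal(scan$beta[i], unname(coef(f1)[".score"]), tolerance = 1e-6)
  expect_equal(scan$n_used[i], f1$n_used)
})

test_that("allele-label flips leave the scan invariant and negating the
           score negates beta with identical p", {
  fx <- small_aset(307, n_families = 100, n_snps = 20, missingness = 0)
  aset <- fx$aset
  sid <- fx$cohort$truth$causal$snp_id[1]
  s1 <- single_snp_scan(aset, ~ age, snp_ids = sid)
  # relabelling the counted allele changes nothing: coding is minor-based
  aset2 <- aset
  aset2$geno[, sid] <- 2 - aset2$geno[, sid]
  s2 <- single_snp_scan(aset2, ~ age, snp_ids = sid)
  expect_equal(s2$beta, s1$beta, tolerance = 1e-5)
  expect_equal(s2$p, s1$p, tolerance = 1e-6)
  # flipping the score designation itself negates beta, p unchanged
  d <- aset$data
  sc <- encode_additive(aset$geno, sid)
  d$.score <- as.numeric(sc[match(d$individual_id, names(sc))])
  f0 <- vc_fit(trait ~ age, d, kinship = aset$kinship)
  fp <- vc_fit(trait ~ age + .score, d, kinship = aset$kinship)
  d$.score <- -d$.score
  fm <- vc_fit(trait ~ age + .score, d, kinship = aset$kinship)
  expect_equal(unname(coef(fm)[".score"]), -unname(coef(fp)[".score"]),
               tolerance = 1e-6)
  expect_equal(vc_lrt(fm, f0)$p_value, vc_lrt(fp, f0)$p_value,
               tolerance = 1e-8)
})

test_that("null SNPs hit the nominal rate and degenerate SNPs are flagged", {
  fx <- small_aset(311, n_families = 150, n_snps = 120,
                   cluster_fraction = 0, n_causal = 0,
                   causal_share_total = 0, h2_polygenic = 0.2,
                   missingness = 0)
  aset <- fx$aset
  scan <- single_snp_scan(aset, ~ age, snp_ids = colnames(aset$geno)[1:120])
  ok <- scan$status == "ok"
  rate <- mean(scan$p[ok] < 0.05)
  # binomial band around 0.05 at ~120 tests (correlated only weakly here)
  expect_lt(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / sum(ok)) + 0.01)

  # an all-heterozygote SNP has a constant score: flagged, no p
  aset$geno[, 1] <- 1
  scan1 <- single_snp_scan(aset, ~ age, snp_ids = colnames(aset$geno)[1])
  expect_equal(scan1$status, "degenerate")
  expect_true(is.na(scan1$p))
})

test_that("hits cluster into closed gene windows, counted once", {
  genes <- data.frame(name = c("gA", "gB"),
                      start = c(50000, 52000), end = c(60000, 70000))
  n <- 109
  map <- data.frame(snp_id = sprintf("s%03d", 1:n), chromosome = "7q36",
                    position = 0L)
  # 89 hits inside windows (one exactly on the padded boundary), 20 outside
  map$position[1:89] <- seq(45000, 70000, length.out = 89)
  map$position[89] <- 70000 + 10000          # gB end + pad: still inside
  map$position[90:109] <- seq(200000, 400000, length.out = 20)
  res <- data.frame(snp_id = map$snp_id, p = 0.01)
  cl <- cluster_hits(res, map, genes, alpha = 0.05)
  expect_equal(cl$summary$n_hits, 109L)
  expect_equal(cl$summary$n_in_windows, 89L)
  expect_equal(cl$summary$pct_in_windows, 82)
  # order invariance
  shuf <- sample(n)
  cl3 <- cluster_hits(res[shuf, ], map[shuf, ], genes, alpha = 0.05)
  expect_equal(cl3$summary, cl$summary)
  # one bp past the closed boundary falls out
  map$position[89] <- 70000 + 10001
  cl2 <- cluster_hits(res, map, genes, alpha = 0.05)
  expect_equal(cl2$summary$n_in_windows, 88L)
  # no hits at all
  res$p <- 0.5
  cl4 <- cluster_hits(res, map, genes)
  expect_true(is.na(cl4$summary$pct_in_windows))
})

test_that("r2 equals the hand-computed correlation on a printed toy", {
  g <- cbind(a = c(0, 0, 1, 1, 2, 2), b = c(0, 2, 0, 2, 0, 2),
             c = c(0, 0, 1, 1, 2, 2))
  rownames(g) <- paste0("i", 1:6)
  # brute-force Pearson correlation from first principles
  brute <- function(x, y) {
    sxy <- sum((x - mean(x)) * (y - mean(y)))
    (sxy / sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2)))^2
  }
  expect_equal(pairwise_r2(g, "a", "b"), brute(g[, "a"], g[, "b"]),
               tolerance = 1e-12)
  expect_equal(pairwise_r2(g, "a", "c"), 1)
  # allele-label flip leaves r2 unchanged
  gf <- g; gf[, "b"] <- 2 - gf[, "b"]
  expect_equal(pairwise_r2(gf, "a", "b"), pairwise_r2(g, "a", "b"))
  # zero-variance partner is undefined
  gz <- cbind(g, d = rep(1, 6))
  expect_warning(r <- pairwise_r2(gz, "a", "d"), "undefined")
  expect_true(is.na(r))
})

test_that("pruning keeps the least-missing member of correlated sets", {
  set.seed(331)
  base <- rbinom(200, 2, 0.4)
  g <- cbind(s1 = base, s2 = base, s3 = base)   # pairwise r2 = 1
  rownames(g) <- paste0("i", 1:200)
  g[sample(200, 4), "s1"] <- NA                 # missingness 2%
  g[sample(200, 2), "s2"] <- NA                 # 1%
  g[sample(200, 6), "s3"] <- NA                 # 3%
  pr <- prune_ld(g, c("s1", "s2", "s3"))
  expect_equal(pr$retained, "s2")
  expect_setequal(pr$removed$snp_id, c("s1", "s3"))

  # nothing above threshold: identity
  g2 <- cbind(a = rbinom(200, 2, .5), b = rbinom(200, 2, .5))
  rownames(g2) <- paste0("i", 1:200)
  pr2 <- prune_ld(g2, c("a", "b"))
  expect_equal(pr2$retained, c("a", "b"))
  expect_equal(nrow(pr2$removed), 0L)

  # empty candidate set
  pr3 <- prune_ld(g2, character(0))
  expect_equal(length(pr3$retained), 0L)
})

test_that("pruning agrees with the reference rule on random small sets", {
  set.seed(337)
  for (r in 1:25) {
    k <- sample(2:5, 1)
    n <- 80
    # build correlated columns by copying with noise
    g <- matrix(rbinom(n, 2, 0.4), n, 1)
    for (j in seq_len(k - 1)) {
      src <- g[, sample(ncol(g), 1)]
      flip <- runif(n) < runif(1, 0, 0.5)
      g <- cbind(g, ifelse(flip, rbinom(n, 2, 0.4), src))
    }
    colnames(g) <- sprintf("s%02d", seq_len(k))
    rownames(g) <- paste0("i", 1:n)
    miss <- sample(0:3, k, replace = TRUE)
    for (j in seq_len(k)) if (miss[j] > 0) g[sample(n, miss[j]), j] <- NA
    pr <- suppressWarnings(prune_ld(g, colnames(g)))
    R2 <- suppressWarnings(cor(g, use = "pairwise.complete.obs")^2)
    R2[is.na(R2)] <- 0
    ref <- colnames(g)[prune_rule_reference(R2, colMeans(is.na(g)))]
    expect_equal(pr$retained, ref)
    # post-hoc invariant: no retained pair above threshold
    if (length(pr$retained) > 1) {
      rr <- R2[pr$retained, pr$retained]
      expect_lte(max(rr[upper.tri(rr)]), 0.7)
    }
  }
})

test_that("pruning a fixed panel is reproducible", {
  fx <- small_aset(347, n_families = 80, n_snps = 60, cluster_fraction = 1)
  cand <- colnames(fx$aset$geno)
  p1 <- suppressWarnings(prune_ld(fx$aset$geno, cand, map = fx$aset$map))
  p2 <- suppressWarnings(prune_ld(fx$aset$geno, cand, map = fx$aset$map))
  expect_identical(p1$retained, p2$retained)
})
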