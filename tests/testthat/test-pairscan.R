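test_that("rank-based AUC matches its definition and rejects degenerate input", {
  expect_equal(auc(c(1, 2, 3, 4), c("good", "good", "poor", "poor")), 1.0)
  expect_equal(auc(rep(2, 6), c("good", "poor", "good", "poor", "good", "poor")),
               0.5)
  # brute-force count over the four good-poor pairs (oracle-verified):
  # poor scores {2, 4} beat good scores {3, 1} in 3 of 4 comparisons
  expect_equal(auc(c(3, 1, 2, 4), c("good", "good", "poor", "poor")), 0.75)
  expect_equal(auc(c(3, 1, 2, 4), c("good", "poor", "good", "poor")),
               auc_brute(c(3, 1, 2, 4), c(0, 1, 0, 1)))
  # orientation is not folded: anti-predictive scores fall below 0.5
  expect_equal(auc(c(4, 3, 2, 1), c("good", "good", "poor", "poor")), 0.0)
  expect_error(auc(1:3, c("poor", "poor", "poor")), "both outcome classes")
})

test_that("AUC equals the O(n^2) pair-counting oracle on random instances", {
  for (s in 1:25) {
    set.seed(s)
    n <- sample(5:200, 1)
    score <- sample(rnorm(n %/% 2 + 1), n, replace = TRUE)  # force ties
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    expect_identical(auc(score, y), auc_brute(score, y))
  }
})

test_that("compiled batch AUC agrees with the R implementation", {
  set.seed(1)
  Z <- matrix(rnorm(40 * 6), 40, 6)
  y <- rbinom(40, 1, 0.5); y[1:2] <- c(0, 1)
  W <- matrix(rnorm(10 * 2), 10, 2)
  prs <- cbind(sample(1:6, 10, TRUE), sample(1:6, 10, TRUE))
  got <- synetr:::cpp_pair_auc(Z, prs, W, y)
  want <- sapply(1:10, function(k)
    auc(W[k, 1] * Z[, prs[k, 1]] + W[k, 2] * Z[, prs[k, 2]], y))
  expect_equal(got, want, tolerance = 1e-12)
  gw <- rnorm(6)
  expect_equal(synetr:::cpp_gene_auc(Z, gw, y),
               sapply(1:6, function(j) auc(gw[j] * Z[, j], y)),
               tolerance = 1e-12)
})

test_that("synergy has its closed-form identities", {
  expect_equal(synergy(0.7, 0.7, 0.7), 1.0)
  expect_equal(synergy(0.77, 0.6, 0.7), 1.1)
  expect_equal(synergy(0.77, 0.7, 0.6), 1.1)   # symmetric in (A_i, A_j)
  expect_error(synergy(0.5, 0, 0), "positive")
})

test_that("meta-gene fitting is symmetric and degrades gracefully", {
  set.seed(4)
  x <- rnorm(60); y <- as.integer(x + rnorm(60, 0, 0.5) > 0)
  noise <- rnorm(60)
  # duplicated gene scores exactly like the single gene
  f_dup <- fit_metagene(x, x, y)
  sc_dup <- metagene_score(f_dup, x, x)
  expect_equal(auc(sc_dup, y), auc(x, y), tolerance = 1e-9)

  # swap symmetry
  fa <- fit_metagene(x, noise, y)
  fb <- fit_metagene(noise, x, y)
  expect_equal(metagene_score(fa, x, noise), metagene_score(fb, noise, x),
               tolerance = 1e-12)

  # constant gene gets weight zero
  expect_message(fc <- fit_metagene(x, rep(1, 60), y), "constant gene")
  expect_equal(fc$w_j, 0)

  # pure-noise partner does not wreck holdout performance
  set.seed(9)
  xt <- rnorm(400); yt <- as.integer(xt + rnorm(400, 0, 0.5) > 0)
  nz <- rnorm(400)
  fit <- fit_metagene(xt[1:200], nz[1:200], yt[1:200])
  a_pair <- auc(metagene_score(fit, xt[201:400], nz[201:400]), yt[201:400])
  a_single <- auc(xt[201:400], yt[201:400])
  expect_gte(a_pair, a_single - 0.05)
})

test_that("pair enumeration is canonical and counts genome-scale pairs", {
  expect_equal(pair_count(11748), 69001878)
  e3 <- enumerate_pairs(c("g2", "g1", "g3"))
  expect_equal(e3$gene_i, c("g1", "g1", "g2"))
  expect_equal(e3$gene_j, c("g2", "g3", "g3"))
  # chunk arithmetic against direct enumeration on a bigger set
  genes <- sprintf("G%03d", 1:57)
  all_pairs <- enumerate_pairs(genes)
  expect_equal(nrow(all_pairs), pair_count(57))
  mid <- enumerate_pairs(genes, from = 1000, to = 1200)
  expect_equal(mid, all_pairs[1000:1200, ], ignore_attr = TRUE)
})

test_that("chunked scans concatenate into the full scan bit-identically", {
  sim <- small_sim(6, n_studies = 3, samples_per_study = 40, n_genes = 12,
                   n_marginal = 2, n_synergy_pairs = 2, n_corr_blocks = 0)
  cmp <- sim$compendium
  full <- scan_pairs(cmp, seed = 21)
  m <- pair_count(12)
  parts <- rbind(scan_pairs(cmp, chunk = c(1, 30), seed = 21),
                 scan_pairs(cmp, chunk = c(31, m), seed = 21))
  rownames(parts) <- NULL
  expect_identical(full, parts)
  # determinism
  expect_identical(full, scan_pairs(cmp, seed = 21))
  # scores live in their domains
  expect_true(all(full$A_i >= 0 & full$A_i <= 1))
  expect_true(all(full$A_ij >= 0 & full$A_ij <= 1))
  expect_true(all(full$C >= 0 & full$C <= 1))
  expect_true(all(full$S > 0))
  expect_true(all((full$S > 1) == (full$A_ij > pmax(full$A_i, full$A_j))))
})

test_that("Spearman co-expression is invariant under monotone transforms", {
  sim <- small_sim(8, n_studies = 2, samples_per_study = 40, n_genes = 6,
                   n_marginal = 0, n_synergy_pairs = 1, n_corr_blocks = 1,
                   block_size = 3)
  cmp <- sim$compendium
  sc1 <- scan_pairs(cmp, seed = 3)
  cmp2 <- cmp
  cmp2$values[, 1] <- exp(cmp2$values[, 1])        # strictly monotone
  sc2 <- scan_pairs(cmp2, seed = 3)
  expect_equal(sc1$C, sc2$C, tolerance = 1e-12)
})

test_that("single-pair cross-validation is deterministic in its seed", {
  sim <- small_sim(9, n_studies = 3, samples_per_study = 40, n_genes = 10,
                   n_marginal = 1, n_synergy_pairs = 1, n_corr_blocks = 0)
  cmp <- sim$compendium
  tp <- sim$truth$synergy_pairs
  a <- pair_auc_cv(cmp, tp$gene_a[1], tp$gene_b[1], seed = 5)
  b <- pair_auc_cv(cmp, tp$gene_a[1], tp$gene_b[1], seed = 5)
  expect_identical(a, b)
})
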