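# Independent oracles and tiny fixture builders used across the suite.

# O(n^2) AUC oracle: count good-poor pairs won by the poor sample, ties 1/2
auc_brute <- function(score, poor01) {
  ip <- which(poor01 == 1)
  ig <- which(poor01 == 0)
  wins <- 0
  for (a in ip) for (b in ig)
    wins <- wins + (score[a] > score[b]) + 0.5 * (score[a] == score[b])
  wins / (length(ip) * length(ig))
}

# reference L1-logistic solver: IRLS outer loop + coordinate descent inner
# loop on the weighted least squares problem (penalty lambda * sum|w|,
# loss mean negative log-likelihood, unpenalized intercept)
lasso_cd_oracle <- function(X, y, lambda, tol = 1e-12, max_outer = 200) {
  n <- nrow(X); p <- ncol(X)
  w <- numeric(p); w0 <- qlogis(max(min(mean(y), 1 - 1e-6), 1e-6))
  soft <- function(z, g) sign(z) * pmax(abs(z) - g, 0)
  for (outer in seq_len(max_outer)) {
    eta <- w0 + drop(X %*% w)
    pr <- 1 / (1 + exp(-eta))
    Wt <- pmax(pr * (1 - pr), 1e-10)
    z <- eta + (y - pr) / Wt
    for (inner in 1:500) {
      w_old <- c(w0, w)
      r <- z - w0 - drop(X %*% w)
      w0 <- w0 + sum(Wt * r) / sum(Wt)
      r <- z - w0 - drop(X %*% w)
      for (j in seq_len(p)) {
        rj <- r + X[, j] * w[j]
        num <- mean(Wt * X[, j] * rj)
        den <- mean(Wt * X[, j]^2)
        wj_new <- soft(num, lambda) / den
        r <- rj - X[, j] * wj_new
        w[j] <- wj_new
      }
      if (max(abs(c(w0, w) - w_old)) < tol) break
    }
    eta_new <- w0 + drop(X %*% w)
    if (max(abs(eta_new - eta)) < 1e-10) break
  }
  list(intercept = w0, weights = w)
}

# hand-built 3-study compendium with known labels, no randomness
tiny_compendium <- function() {
  vals <- matrix(c(1, 2, 3, 4, 5, 6,
                   6, 5, 4, 3, 2, 1,
                   1, 1, 2, 2, 3, 3), nrow = 6,
                 dimnames = list(paste0("s", 1:6), c("GA", "GB", "GC")))
  ann <- data.frame(sample_id = paste0("s", 1:6),
                    study = rep(c("st1", "st2", "st3"), each = 2),
                    survival_time = c(2, 8, 3, 9, 1, 10),
                    event = c(1, 0, 1, 0, 1, 0))
  new_compendium(vals, ann)
}

# simulated compendium small enough for fast harness tests
small_sim <- function(seed, n_studies = 3, samples_per_study = 80,
                      n_genes = 60, n_marginal = 6, n_synergy_pairs = 5,
                      n_corr_blocks = 2, block_size = 5, ...) {
  simulate_compendium(synth_config(
    n_studies = n_studies, samples_per_study = samples_per_study,
    n_genes = n_genes, n_marginal = n_marginal,
    n_synergy_pairs = n_synergy_pairs, n_corr_blocks = n_corr_blocks,
    block_size = block_size, seed = seed, ...))
}

pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
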