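#' Number of unordered gene pairs
#' @param n_genes gene count.
#' @return `choose(n_genes, 2)` as a double (exceeds integer range for
#'   genome-scale inputs).
#' @export
pair_count <- function(n_genes) n_genes * (n_genes - 1) / 2

#' Canonical pair enumeration
#'
#' Pairs (i, j), i < j over the lexicographically sorted gene vector, in
#' row-major order of the upper triangle: (1,2), (1,3), ..., (1,p), (2,3),
#' ... This ordering is the contract that makes chunked scans concatenate
#' into a full scan.
#'
#' @param genes character vector of gene symbols (sorted internally).
#' @param from,to 1-based linear pair-index range; defaults to all pairs.
#' @return data.frame with columns `idx_i`, `idx_j` (indices into the
#'   sorted gene vector) and `gene_i`, `gene_j`.
#' @export
enumerate_pairs <- function(genes, from = 1, to = pair_count(length(genes))) {
  gs <- sort(genes)
  p <- length(gs)
  m <- pair_count(p)
  if (from < 1 || to > m || from > to + 1)
    stop("pair index range out of bounds")
  if (from > to)
    return(data.frame(idx_i = integer(), idx_j = integer(),
                      gene_i = character(), gene_j = character()))
  k <- seq(from, to)
  # first index i solves cum(i-1) < k <= cum(i), cum(i) = i*p - i*(i+1)/2
  i <- floor(((2 * p - 1) - sqrt((2 * p - 1)^2 - 8 * k)) / 2) + 1
  cum_prev <- (i - 1) * p - (i - 1) * i / 2
  # guard against floating-point boundary error
  too_big <- cum_prev >= k
  while (any(too_big)) {
    i[too_big] <- i[too_big] - 1
    cum_prev <- (i - 1) * p - (i - 1) * i / 2
    too_big <- cum_prev >= k
  }
  too_small <- k > i * p - i * (i + 1) / 2
  while (any(too_small)) {
    i[too_small] <- i[too_small] + 1
    cum_prev <- (i - 1) * p - (i - 1) * i / 2
    too_small <- k > i * p - i * (i + 1) / 2
  }
  j <- i + (k - cum_prev)
  data.frame(idx_i = as.integer(i), idx_j = as.integer(j),
             gene_i = gs[i], gene_j = gs[j], stringsAsFactors = FALSE)
}

# deterministic sub-seed per (master seed, fold, repeat); independent of
# which pairs are being scanned so chunks see identical subsamples
subsample_seed <- function(seed, fold, rep) {
  ((as.double(seed) %% 100000) * 1000003 + fold * 10007 + rep * 101) %%
    2147483647
}

# draw-with-replacement of a fraction of the training samples, keyed so the
# identical draw is reused across every gene and pair
draw_subsample <- function(train_idx, fraction, seed, fold, rep) {
  n <- ceiling(fraction * length(train_idx))
  with_seed(subsample_seed(seed, fold, rep),
            sample(train_idx, n, replace = TRUE))
}

#' Fit a two-gene linear meta-gene
#'
#' Ordinary least squares of the 0/1 outcome on the two z-scored expression
#' vectors. Z-scoring parameters are learned on the supplied (training)
#' samples only and stored in the fit, so scoring new samples uses training
#' statistics. A constant gene gets weight 0. Collinear genes are handled
#' by rank-revealing least squares (redundant coordinate dropped), so a
#' duplicated gene scores identically to the single gene.
#'
#' @param x_i,x_j numeric expression vectors (training samples).
#' @param label outcome labels (`good`/`poor` or 0/1, 1 = poor).
#' @return object of class `metagene_fit` with intercept `w0`, weights
#'   `w_i`, `w_j` and the z-scoring parameters.
#' @export
fit_metagene <- function(x_i, x_j, label) {
  y <- as_poor01(label)
  if (sum(y == 1) < 2 || sum(y == 0) < 2)
    stop("need at least 2 training samples per class")
  stat <- function(x) {
    mu <- mean(x); sd <- stats::sd(x)
    if (!is.finite(sd) || sd == 0) { sd <- 1; attr(sd, "constant") <- TRUE }
    c(mu = mu, sd = as.numeric(sd), const = isTRUE(attr(sd, "constant")))
  }
  si <- stat(x_i); sj <- stat(x_j)
  zi <- (x_i - si["mu"]) / si["sd"]
  zj <- (x_j - sj["mu"]) / sj["sd"]
  fit <- stats::lm.fit(cbind(intercept = 1, zi, zj), y)
  w <- fit$coefficients
  w[is.na(w)] <- 0
  if (si["const"] == 1) { w[2] <- 0; message("constant gene i: weight set to 0") }
  if (sj["const"] == 1) { w[3] <- 0; message("constant gene j: weight set to 0") }
  structure(list(w0 = unname(w[1]), w_i = unname(w[2]), w_j = unname(w[3]),
                 center = c(si["mu"], sj["mu"]),
                 scale = c(si["sd"], sj["sd"])),
            class = "metagene_fit")
}

#' Score samples with a fitted meta-gene
#' @param fit a [fit_metagene()] result.
#' @param x_i,x_j expression vectors of the two genes for the samples to
#'   score.
#' @return numeric meta-gene score (higher = poorer predicted outcome when
#'   the fit's orientation is positive).
#' @export
metagene_score <- function(fit, x_i, x_j) {
  fit$w0 + fit$w_i * (x_i - fit$center[1]) / fit$scale[1] +
    fit$w_j * (x_j - fit$center[2]) / fit$scale[2]
}

# Core of the pair scan: for every leave-one-study-out fold and every
# repeat, draw the shared 70%-with-replacement training subsample, fit all
# single-gene and requested pair regressions in closed form from the
# subsample cross-products, and evaluate AUCs on the held-out study.
scan_core <- function(c, pair_idx, seed, n_repeats, subsample) {
  gs <- sort(compendium_genes(c))
  X <- c$values[, gs, drop = FALSE]
  use <- usable_samples(c)
  y01 <- as_poor01(c$samples$outcome[use])
  study <- c$samples$study[use]
  X <- X[use, , drop = FALSE]
  p <- ncol(X)
  m <- nrow(pair_idx)
  studies <- sort(unique(study))
  if (length(studies) < 2) stop("need >= 2 studies for cross-study scanning")

  per_fold <- list()
  for (f in seq_along(studies)) {
    test <- which(study == studies[f])
    train <- which(study != studies[f])
    if (length(unique(y01[test])) < 2) {
      message(sprintf("fold %s skipped: held-out study has a single class",
                      studies[f]))
      next
    }
    # |Spearman| on the full training partition, once per fold
    rho <- suppressWarnings(
      stats::cor(X[train, , drop = FALSE], method = "spearman"))
    rho[!is.finite(rho)] <- 0   # constant genes
    C_f <- abs(rho[cbind(pair_idx$idx_i, pair_idx$idx_j)])

    gene_cells <- matrix(NA_real_, p, n_repeats)
    pair_cells <- matrix(NA_real_, m, n_repeats)
    for (r in seq_len(n_repeats)) {
      sub <- draw_subsample(train, subsample, seed, f, r)
      mu <- colMeans(X[sub, , drop = FALSE])
      sd <- apply(X[sub, , drop = FALSE], 2, stats::sd)
      const <- !is.finite(sd) | sd == 0
      sd[const] <- 1
      Zs <- scale(X[sub, , drop = FALSE], center = mu, scale = sd)
      Zt <- scale(X[test, , drop = FALSE], center = mu, scale = sd)
      yc <- y01[sub] - mean(y01[sub])
      b <- drop(crossprod(Zs, yc))
      b[const] <- 0
      G <- crossprod(Zs)
      dG <- diag(G)
      dG[dG == 0] <- 1
      w_gene <- b / dG
      gene_cells[, r] <- cpp_gene_auc(Zt, w_gene, y01[test])

      if (m > 0) {
        ii <- pair_idx$idx_i; jj <- pair_idx$idx_j
        Gii <- dG[ii]; Gjj <- dG[jj]
        Gij <- G[cbind(ii, jj)]
        det <- Gii * Gjj - Gij^2
        wi <- (Gjj * b[ii] - Gij * b[jj]) / det
        wj <- (Gii * b[jj] - Gij * b[ii]) / det
        # collinear pair: fall back to the stronger single gene
        bad <- !is.finite(wi) | !is.finite(wj) |
          det < 1e-8 * Gii * Gjj
        if (any(bad)) {
          use_i <- abs(b[ii][bad]) >= abs(b[jj][bad])
          wi[bad] <- ifelse(use_i, w_gene[ii][bad], 0)
          wj[bad] <- ifelse(use_i, 0, w_gene[jj][bad])
        }
        pair_cells[, r] <- cpp_pair_auc(
          Zt, cbind(pair_idx$idx_i, pair_idx$idx_j), cbind(wi, wj),
          y01[test])
      }
    }
    per_fold[[studies[f]]] <- list(gene = gene_cells, pair = pair_cells,
                                   C = C_f)
  }
  if (!length(per_fold)) stop("no usable fold: every held-out study was single-class")
  list(genes = gs, per_fold = per_fold)
}

row_medians <- function(x) apply(x, 1, stats::median)

# assemble a PairScore data.frame from per-gene/per-pair AUC summaries
make_pairscore <- function(pair_idx, A_gene, A_pair, C) {
  data.frame(gene_i = pair_idx$gene_i, gene_j = pair_idx$gene_j,
             A_i = A_gene[pair_idx$idx_i], A_j = A_gene[pair_idx$idx_j],
             A_ij = A_pair,
             S = synergy(A_pair, A_gene[pair_idx$idx_i],
                         A_gene[pair_idx$idx_j]),
             M = (A_gene[pair_idx$idx_i] + A_gene[pair_idx$idx_j]) / 2,
             C = C, stringsAsFactors = FALSE)
}

#' Scan gene pairs for synergy
#'
#' For every pair in the requested chunk of the canonical enumeration,
#' computes the median holdout AUC of the two single genes (`A_i`, `A_j`)
#' and of their linear meta-gene (`A_ij`) over all leave-one-study-out
#' folds and repeats, the synergy `S = A_ij / max(A_i, A_j)`, the mean AUC
#' `M`, and the absolute Spearman co-expression `C` (median over folds,
#' each computed on that fold's full training partition).
#'
#' Chunks are independent: the subsample drawn for a given (fold, repeat)
#' is keyed by the master seed only, so concatenating chunk results equals
#' a single full scan bit-for-bit.
#'
#' @param c an ExpressionCompendium (at least 2 studies).
#' @param chunk `c(from, to)` linear pair-index range, or NULL for all
#'   pairs.
#' @param seed master seed.
#' @param n_repeats subsample repeats per fold (default 5).
#' @param subsample fraction drawn with replacement from the training
#'   samples (default 0.7).
#' @param per_fold if TRUE, return one score table per fold (medians over
#'   that fold's repeats) instead of the pooled table; this is the input
#'   for per-fold fitness normalization.
#' @return a PairScore data.frame (columns `gene_i`, `gene_j`, `A_i`,
#'   `A_j`, `A_ij`, `S`, `M`, `C`), or a named list of them when
#'   `per_fold = TRUE`.
#' @export
scan_pairs <- function(c, chunk = NULL, seed = 1, n_repeats = 5,
                       subsample = 0.7, per_fold = FALSE) {
  gs <- sort(compendium_genes(c))
  m_all <- pair_count(length(gs))
  if (is.null(chunk)) chunk <- c(1, m_all)
  pair_idx <- enumerate_pairs(gs, chunk[1], chunk[2])
  if (nrow(pair_idx) == 0)
    return(if (per_fold) list() else make_pairscore(pair_idx, numeric(),
                                                    numeric(), numeric()))
  res <- scan_core(c, pair_idx, seed, n_repeats, subsample)
  if (per_fold) {
    lapply(res$per_fold, function(f)
      make_pairscore(pair_idx, row_medians(f$gene), row_medians(f$pair),
                     f$C))
  } else {
    gene_all <- do.call(cbind, lapply(res$per_fold, `[[`, "gene"))
    pair_all <- do.call(cbind, lapply(res$per_fold, `[[`, "pair"))
    C_all <- do.call(cbind, lapply(res$per_fold, function(f) f$C))
    make_pairscore(pair_idx, row_medians(gene_all), row_medians(pair_all),
                   row_medians(C_all))
  }
}

#' Cross-validated AUCs for one gene pair
#'
#' Convenience wrapper around [scan_pairs()] for a single pair: returns the
#' median single-gene and meta-gene holdout AUCs under the
#' leave-one-study-out, repeated-subsample design.
#'
#' @param c an ExpressionCompendium.
#' @param i,j gene symbols.
#' @param n_repeats,subsample,seed as in [scan_pairs()].
#' @return named numeric vector `c(A_i, A_j, A_ij)` where `A_i` refers to
#'   the lexicographically smaller of the two genes.
#' @export
pair_auc_cv <- function(c, i, j, n_repeats = 5, subsample = 0.7, seed = 1) {
  gs <- sort(compendium_genes(c))
  ii <- match(min(i, j), gs); jj <- match(max(i, j), gs)
  if (is.na(ii) || is.na(jj)) stop("gene not found in compendium")
  p <- length(gs)
  k <- (ii - 1) * p - (ii - 1) * ii / 2 + (jj - ii)
  sc <- scan_pairs(c, chunk = c(k, k), seed = seed, n_repeats = n_repeats,
                   subsample = subsample)
  c(A_i = sc$A_i, A_j = sc$A_j, A_ij = sc$A_ij)
}
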