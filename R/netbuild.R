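#' Min-max normalize pair measures and compute fitness
#'
#' Each of synergy `S`, mean AUC `M` and absolute co-expression `C` is
#' min-max scaled to \[0, 1\] over the supplied pair collection, and the
#' fitness is the negative Euclidean distance to the ideal point (1, 1, 1)
#' in that normalized space:
#' `F = -sqrt((1 - S)^2 + (1 - M)^2 + (1 - C)^2)`, so `F` ranges over
#' `[-sqrt(3), 0]` with 0 attained only by a pair that is best on all three
#' measures.
#'
#' @param scores a PairScore data.frame from [scan_pairs()].
#' @return FitnessRecord data.frame: `gene_i`, `gene_j`, `S_bar`, `M_bar`,
#'   `C_bar`, `F`.
#' @export
normalize_measures <- function(scores) {
  minmax <- function(x, name) {
    rng <- range(x)
    if (rng[1] == rng[2]) {
      message(sprintf("measure %s is constant; normalized value set to 1", name))
      return(rep(1, length(x)))
    }
    (x - rng[1]) / (rng[2] - rng[1])
  }
  out <- data.frame(gene_i = scores$gene_i, gene_j = scores$gene_j,
                    S_bar = minmax(scores$S, "S"),
                    M_bar = minmax(scores$M, "M"),
                    C_bar = minmax(scores$C, "C"),
                    stringsAsFactors = FALSE)
  out$F <- -sqrt((1 - out$S_bar)^2 + (1 - out$M_bar)^2 + (1 - out$C_bar)^2)
  out
}

#' Per-pair median fitness across folds
#'
#' Each fold's score table is normalized within itself first (see
#' [normalize_measures()]); this takes the per-pair median of `F` across
#' folds. All folds must cover the identical canonical pair set.
#'
#' @param per_fold list of FitnessRecord data.frames, one per fold/study.
#' @return FitnessRecord data.frame with the median `F` (the `*_bar`
#'   columns carry the per-measure medians for reference).
#' @export
median_fitness <- function(per_fold) {
  stopifnot(length(per_fold) >= 1)
  ref <- per_fold[[1]][, c("gene_i", "gene_j")]
  key <- function(d) paste(d$gene_i, d$gene_j, sep = "\r")
  k0 <- key(ref)
  for (d in per_fold) {
    if (nrow(d) != nrow(ref) || !identical(key(d), k0))
      stop("folds do not cover the identical canonical pair set")
  }
  agg <- function(col) row_medians(do.call(cbind, lapply(per_fold, `[[`, col)))
  data.frame(ref, S_bar = agg("S_bar"), M_bar = agg("M_bar"),
             C_bar = agg("C_bar"), F = agg("F"), stringsAsFactors = FALSE)
}

#' Assemble the synergy network from fitness records
#'
#' Keeps the `n_links` pairs with highest fitness (ties broken by
#' lexicographic (gene_i, gene_j) order). Because fitness is non-positive
#' while network-guided group building wants positive edge weights, the
#' edge weight is the fitness rank scaled to (0, 1]: the best pair gets
#' weight 1 and the weakest kept pair gets `1/n_links`; fitness order is
#' preserved exactly.
#'
#' @param fitness FitnessRecord data.frame ([normalize_measures()] or
#'   [median_fitness()] output).
#' @param n_links edges to keep (50,000 at full scale).
#' @return a GeneNetwork.
#' @export
build_synet <- function(fitness, n_links = 50000) {
  if (n_links > nrow(fitness))
    stop("n_links exceeds the number of scored pairs")
  o <- order(-fitness$F, fitness$gene_i, fitness$gene_j)
  top <- fitness[o[seq_len(n_links)], , drop = FALSE]
  new_network(data.frame(gene_a = top$gene_i, gene_b = top$gene_j,
                         weight = rev(seq_len(n_links)) / n_links,
                         stringsAsFactors = FALSE))
}

#' Rank all pairs by fitness
#'
#' @param fitness FitnessRecord data.frame.
#' @return the data.frame sorted by decreasing fitness with a `rank`
#'   column (1 = best).
#' @export
rank_fitness <- function(fitness) {
  o <- order(-fitness$F, fitness$gene_i, fitness$gene_j)
  out <- fitness[o, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Infer the synergy network from a compendium
#'
#' End-to-end convenience: scans all pairs per leave-one-study-out fold,
#' normalizes the three measures within each fold, takes the per-pair
#' median fitness across folds, and keeps the top pairs as the network.
#'
#' @param c an ExpressionCompendium.
#' @param n_links edges to keep.
#' @param seed master seed for the scan subsampling.
#' @param n_repeats,subsample as in [scan_pairs()].
#' @return list with `network` (GeneNetwork) and `fitness` (the pooled
#'   FitnessRecord table used to rank pairs).
#' @export
infer_synet <- function(c, n_links = 50000, seed = 1, n_repeats = 5,
                        subsample = 0.7) {
  per_fold <- scan_pairs(c, seed = seed, n_repeats = n_repeats,
                         subsample = subsample, per_fold = TRUE)
  fitness <- median_fitness(lapply(per_fold, normalize_measures))
  list(network = build_synet(fitness, n_links), fitness = fitness)
}

#' Build a co-expression network
#'
#' Edge weight is the absolute Spearman correlation over the supplied
#' (training) samples; the top `n_links` pairs are retained. Constant
#' genes get zero correlation with everything.
#'
#' @param c an ExpressionCompendium (training partition; >= 3 samples).
#' @param n_links edges to keep.
#' @return a GeneNetwork.
#' @export
build_corr_network <- function(c, n_links) {
  if (nrow(c$values) < 3) stop("need >= 3 samples")
  gs <- sort(compendium_genes(c))
  rho <- suppressWarnings(
    stats::cor(c$values[, gs, drop = FALSE], method = "spearman"))
  rho[!is.finite(rho)] <- 0
  pidx <- enumerate_pairs(gs)
  w <- abs(rho[cbind(pidx$idx_i, pidx$idx_j)])
  o <- order(-w, pidx$gene_i, pidx$gene_j)
  keep <- o[seq_len(min(n_links, length(o)))]
  keep <- keep[w[keep] > 0]
  new_network(data.frame(gene_a = pidx$gene_i[keep],
                         gene_b = pidx$gene_j[keep],
                         weight = w[keep], stringsAsFactors = FALSE))
}
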