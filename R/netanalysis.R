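#' Shuffle node labels of a network
#'
#' Permutes gene identities uniformly at random while leaving the topology
#' (as an unlabeled graph) untouched: degree multiset, clustering, and
#' component structure are all preserved; only which gene sits where is
#' destroyed.
#'
#' @param n a GeneNetwork.
#' @param seed integer seed.
#' @return a GeneNetwork on the same node set.
#' @export
shuffle_node_labels <- function(n, seed = 1) {
  perm <- with_seed(seed, sample(n$nodes))
  map <- stats::setNames(perm, n$nodes)
  e <- n$edges
  e$gene_a <- unname(map[e$gene_a])
  e$gene_b <- unname(map[e$gene_b])
  new_network(e, nodes = n$nodes)
}

#' Degree-preserving edge rewiring (double edge swap)
#'
#' Randomizes which genes are connected while keeping every node's degree
#' exactly intact, by repeated double-edge swaps that never introduce
#' self-loops or multi-edges. Edge weights are reassigned to the rewired
#' edges in shuffled order. On rigid graphs (e.g. a triangle) no valid
#' swap exists and the topology is returned unchanged.
#'
#' @param n a GeneNetwork with >= 2 edges.
#' @param n_swaps swap attempts (default 10 per edge).
#' @param seed integer seed.
#' @return a GeneNetwork with the identical degree sequence.
#' @export
rewire_preserving_degree <- function(n, n_swaps = 10 * nrow(n$edges),
                                     seed = 1) {
  if (nrow(n$edges) < 2) stop("need >= 2 edges to rewire")
  g <- network_to_igraph(n)
  out <- with_seed(seed, {
    g2 <- igraph::rewire(g, igraph::keeping_degseq(loops = FALSE,
                                                   niter = n_swaps))
    igraph::E(g2)$weight <- sample(n$edges$weight)
    g2
  })
  net <- network_from_igraph(out)
  net$nodes <- n$nodes
  net
}

#' Overlap z-score of a target network against a reference
#'
#' For each fraction of the grid, the target is thresholded (top links or
#' the links touching the top genes), the overlap with the reference is
#' counted (shared genes or shared links), and the count is standardized
#' against a null of `n_null` degree-preserving rewires of the target
#' (weights reshuffled, then re-thresholded the same way):
#' `z = (observed - mean_null) / sd_null`.
#'
#' @param reference a GeneNetwork (e.g. the synergy network).
#' @param target a GeneNetwork sharing the symbol universe.
#' @param unit `"links"` or `"genes"`.
#' @param fractions numeric grid in (0, 1\]: fraction of the target's
#'   links (or genes) retained at each threshold.
#' @param n_null null replicates.
#' @param seed integer seed.
#' @return data.frame: `fraction`, `observed`, `mean_null`, `sd_null`,
#'   `z` (NA when the null is degenerate).
#' @export
overlap_zscore <- function(reference, target, unit = c("links", "genes"),
                           fractions = c(0.05, 0.1, 0.25, 0.5, 1),
                           n_null = 1000, seed = 1) {
  unit <- match.arg(unit)
  count_overlap <- function(net) {
    if (unit == "genes") {
      ref_genes <- unique(c(reference$edges$gene_a, reference$edges$gene_b))
      length(intersect(unique(c(net$edges$gene_a, net$edges$gene_b)),
                       ref_genes))
    } else {
      key <- function(x) paste(x$edges$gene_a, x$edges$gene_b)
      length(intersect(key(net), key(reference)))
    }
  }
  thr <- function(net, frac) {
    k <- if (unit == "genes")
      max(1, round(frac * length(unique(c(net$edges$gene_a,
                                          net$edges$gene_b)))))
    else max(1, round(frac * nrow(net$edges)))
    suppressWarnings(threshold_network(
      net, if (unit == "genes") "top_genes" else "top_links", k))
  }
  nulls <- lapply(seq_len(n_null), function(b)
    rewire_preserving_degree(target, seed = seed + b))
  out <- lapply(fractions, function(fr) {
    obs <- count_overlap(thr(target, fr))
    null_counts <- vapply(nulls, function(nb) count_overlap(thr(nb, fr)), 0)
    mu <- mean(null_counts); sdv <- stats::sd(null_counts)
    data.frame(fraction = fr, observed = obs, mean_null = mu, sd_null = sdv,
               z = if (is.na(sdv) || sdv == 0) NA_real_ else (obs - mu) / sdv)
  })
  do.call(rbind, out)
}

#' Graph-topological features of gene pairs
#'
#' For every pair and every named network: direct link indicator, mean and
#' absolute difference of degree, shortest-path length, Jaccard overlap of
#' neighborhoods, and mean/absolute-difference of PageRank (one pair of
#' columns per damping factor), closeness, clustering coefficient and
#' eigenvector centrality. Pairs that are disconnected (or absent from a
#' network) get the bounded coding: shortest path is the largest finite
#' shortest path in that network plus one, centralities are 0.
#'
#' @param pairs data.frame with columns `gene_i`, `gene_j` (canonical
#'   order).
#' @param networks named list of GeneNetwork objects.
#' @param dampings PageRank damping factors.
#' @return data.frame: the pair columns then one block of columns per
#'   network, named `<network>.<feature>`.
#' @export
topo_features <- function(pairs, networks,
                          dampings = c(0.1, 0.3, 0.5, 0.85)) {
  stopifnot(is.list(networks), !is.null(names(networks)))
  blocks <- lapply(names(networks), function(nm) {
    net <- networks[[nm]]
    g <- network_to_igraph(net)
    nodes <- igraph::V(g)$name
    deg <- stats::setNames(igraph::degree(g), nodes)
    clus <- stats::setNames(
      igraph::transitivity(g, type = "localundirected", isolates = "zero"),
      nodes)
    clo <- suppressWarnings(stats::setNames(
      igraph::closeness(g, normalized = TRUE), nodes))
    clo[!is.finite(clo)] <- 0
    eig <- stats::setNames(
      igraph::eigen_centrality(g, weights = NA)$vector, nodes)
    prs <- lapply(dampings, function(d)
      stats::setNames(igraph::page_rank(g, damping = d, weights = NA)$vector,
                      nodes))
    dmat <- igraph::distances(g, weights = NA)
    sp_code <- max(dmat[is.finite(dmat)], 1) + 1   # disconnected coding
    adj <- igraph::as_adj_list(g)
    names(adj) <- nodes

    val <- function(tab, gene) ifelse(gene %in% nodes, tab[gene], 0)
    i <- pairs$gene_i; j <- pairs$gene_j
    in_i <- i %in% nodes; in_j <- j %in% nodes
    both <- in_i & in_j

    sp <- rep(sp_code, nrow(pairs))
    if (any(both)) {
      spb <- dmat[cbind(i[both], j[both])]
      spb[!is.finite(spb)] <- sp_code
      sp[both] <- spb
    }
    nj <- numeric(nrow(pairs))
    if (any(both)) {
      nj[both] <- mapply(function(a, b) {
        na <- names(adj[[a]]); nb <- names(adj[[b]])
        u <- union(na, nb)
        if (!length(u)) 0 else length(intersect(na, nb)) / length(u)
      }, i[both], j[both])
    }
    pairfeat <- function(tab) {
      vi <- val(tab, i); vj <- val(tab, j)
      list(avg = (vi + vj) / 2, diff = abs(vi - vj))
    }
    out <- data.frame(direct_link = as.numeric(sp == 1),
                      shortest_path = sp, neighbor_jaccard = nj)
    for (feat in list(c("degree", "deg"), c("closeness", "clo"),
                      c("clustering", "clus"), c("eigenvector", "eig"))) {
      pf <- pairfeat(get(feat[2]))
      out[[paste0(feat[1], "_avg")]] <- pf$avg
      out[[paste0(feat[1], "_diff")]] <- pf$diff
    }
    for (d in seq_along(dampings)) {
      pf <- pairfeat(prs[[d]])
      out[[sprintf("pagerank%g_avg", dampings[d])]] <- pf$avg
      out[[sprintf("pagerank%g_diff", dampings[d])]] <- pf$diff
    }
    names(out) <- paste(nm, names(out), sep = ".")
    out
  })
  cbind(pairs[, c("gene_i", "gene_j")], do.call(cbind, blocks))
}

#' Sample negative (non-network) gene pairs
#'
#' Uniform pairs over the genes occurring in the reference network,
#' excluding its own links; used as the negative class for link
#' prediction.
#'
#' @param net the reference GeneNetwork.
#' @param n_pairs how many to draw.
#' @param seed integer seed.
#' @return data.frame `gene_i`, `gene_j` in canonical order.
#' @export
sample_negative_pairs <- function(net, n_pairs, seed = 1) {
  genes <- sort(unique(c(net$edges$gene_a, net$edges$gene_b)))
  pos_key <- paste(net$edges$gene_a, net$edges$gene_b)
  with_seed(seed, {
    out <- data.frame(gene_i = character(), gene_j = character())
    guard <- 0
    while (nrow(out) < n_pairs && guard < 50) {
      a <- sample(genes, 2 * n_pairs, replace = TRUE)
      b <- sample(genes, 2 * n_pairs, replace = TRUE)
      keep <- a != b
      gi <- pmin(a[keep], b[keep]); gj <- pmax(a[keep], b[keep])
      cand <- data.frame(gene_i = gi, gene_j = gj,
                         stringsAsFactors = FALSE)
      cand <- cand[!paste(gi, gj) %in% pos_key, , drop = FALSE]
      out <- rbind(out, cand)
      out <- out[!duplicated(paste(out$gene_i, out$gene_j)), , drop = FALSE]
      guard <- guard + 1
    }
    utils::head(out, n_pairs)
  })
}

#' Predict network links from topological features
#'
#' Cross-validated L1-logistic classification of pairs (positives = links
#' of the reference network, negatives = sampled non-links) from their
#' topological features in other networks. Folds partition the pairs; a
#' gene-leakage filter removes every training pair that shares a gene with
#' any test pair, so performance cannot come from memorizing gene
#' identity. Reports AUC per feature block (network) and for all features
#' combined, plus how often each feature was selected.
#'
#' @param features a [topo_features()] matrix covering positives and
#'   negatives.
#' @param positives data.frame `gene_i`, `gene_j` of true links.
#' @param n_folds cross-validation folds (50 at full scale).
#' @param lambda L1 penalty of the per-fold classifier.
#' @param seed integer seed for fold assignment.
#' @return list: `auc` (named, per network and `"combined"`),
#'   `selection_frequency`, `fold_auc` (combined, per fold), and `folds`
#'   (the post-filter train/test pair indices per fold, so the leakage
#'   contract can be audited).
#' @export
predict_links <- function(features, positives, n_folds = 50, lambda = 0.01,
                          seed = 1) {
  key <- function(d) paste(d$gene_i, d$gene_j)
  y <- as.integer(key(features) %in% key(positives))
  if (sum(y) == 0 || sum(1 - y) == 0)
    stop("features must contain both linked and non-linked pairs")
  featcols <- setdiff(names(features), c("gene_i", "gene_j"))
  X <- as.matrix(features[, featcols, drop = FALSE])
  nets <- unique(sub("\\..*$", "", featcols))
  fold_of <- with_seed(seed,
    sample(rep(seq_len(n_folds), length.out = nrow(features))))

  fold_idx <- vector("list", n_folds)
  run_block <- function(cols, record_folds = FALSE) {
    sel <- integer(length(cols)); names(sel) <- cols
    fold_auc <- rep(NA_real_, n_folds)
    scores <- rep(NA_real_, nrow(features))
    for (fo in seq_len(n_folds)) {
      te <- which(fold_of == fo)
      test_genes <- unique(c(features$gene_i[te], features$gene_j[te]))
      tr <- which(fold_of != fo &
                    !(features$gene_i %in% test_genes) &
                    !(features$gene_j %in% test_genes))
      if (record_folds) fold_idx[[fo]] <<- list(train = tr, test = te)
      if (length(tr) < 10 || length(unique(y[tr])) < 2 ||
          length(unique(y[te])) < 2) {
        message("fold ", fo, " skipped (emptied by gene-leakage removal)")
        next
      }
      zs <- zscore_fit(X[tr, cols, drop = FALSE])
      m <- train_lasso(zscore_apply(X[tr, cols, drop = FALSE], zs),
                       y[tr], lambda)
      sel[m$signature] <- sel[m$signature] + 1L
      sc <- predict_outcome_score(m, zscore_apply(X[te, cols, drop = FALSE],
                                                  zs))
      scores[te] <- sc
      fold_auc[fo] <- auc(sc, y[te])
    }
    ok <- !is.na(scores)
    list(auc = auc(scores[ok], y[ok]), sel = sel, fold_auc = fold_auc)
  }

  per_net <- vapply(nets, function(nm)
    run_block(featcols[startsWith(featcols, paste0(nm, "."))])$auc, 0)
  comb <- run_block(featcols, record_folds = TRUE)
  list(auc = c(per_net, combined = comb$auc),
       selection_frequency = comb$sel / sum(!is.na(comb$fold_auc)),
       fold_auc = comb$fold_auc,
       folds = fold_idx, pairs = features[, c("gene_i", "gene_j")],
       labels = y)
}
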