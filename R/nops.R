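#' Correlation-clustering outcome predictor (Park-style)
#'
#' Average-linkage hierarchical clustering of genes on correlation distance
#' `1 - |rho|`, cut into `n_clusters` clusters; each cluster is averaged
#' into a meta-gene and a Lasso is trained on the meta-genes. With
#' `n_clusters` equal to the gene count (a zero-height cut) this reduces to
#' plain Lasso on all genes.
#'
#' @param X samples x genes matrix (training, z-scored).
#' @param y outcome labels.
#' @param n_clusters number of clusters to cut the dendrogram into; tune
#'   via [tune_model()].
#' @param lambda Lasso penalty on the meta-genes.
#' @return a `synet_model` (type `metagene_nop`).
#' @export
park_nop <- function(X, y, n_clusters, lambda) {
  p <- ncol(X)
  n_clusters <- min(n_clusters, p)
  rho <- suppressWarnings(stats::cor(X))
  rho[!is.finite(rho)] <- 0
  hc <- stats::hclust(stats::as.dist(1 - abs(rho)), method = "average")
  cl <- stats::cutree(hc, k = n_clusters)
  groups <- split(colnames(X), cl)
  names(groups) <- paste0("cluster", names(groups))
  fit_metagene_nop(X, y, groups, lambda)
}

#' Greedy subnetwork outcome predictor (Chuang-style)
#'
#' Starting from every seed gene, greedily adds the neighboring gene (in
#' the supplied network) that most improves the training AUC of the
#' averaged meta-gene, halting when no candidate improves it. Duplicate
#' subnetworks are merged; meta-genes are member averages; a Lasso is
#' trained on the meta-genes. The training criterion folds orientation
#' (`max(AUC, 1 - AUC)`) since a meta-gene's sign is learned downstream.
#'
#' @param X samples x genes matrix (training, z-scored).
#' @param y outcome labels.
#' @param net a GeneNetwork over (a subset of) the genes.
#' @param lambda Lasso penalty on the meta-genes.
#' @param max_size optional cap on subnetwork size.
#' @return a `synet_model` (type `metagene_nop`) whose `expansion_scores`
#'   record each seed's strictly increasing score sequence.
#' @export
chuang_nop <- function(X, y, net, lambda, max_size = 20) {
  y01 <- as_poor01(y)
  genes <- intersect(net$nodes, colnames(X))
  if (!length(genes)) stop("no network gene present in the feature matrix")
  nbrs <- adjacency_list(net, genes)
  train_auc <- function(members) {
    a <- auc(rowMeans(X[, members, drop = FALSE]), y01)
    max(a, 1 - a)
  }
  seeds <- genes[genes %in% c(net$edges$gene_a, net$edges$gene_b)]
  traces <- list()
  groups <- list()
  for (s in seeds) {
    members <- s
    score <- train_auc(members)
    trace <- score
    repeat {
      cand <- setdiff(unique(unlist(nbrs[members], use.names = FALSE)), members)
      if (!length(cand) || length(members) >= max_size) break
      cand_scores <- vapply(cand, function(g) train_auc(c(members, g)), 0)
      best <- which.max(cand_scores)
      if (cand_scores[best] <= score) break
      members <- c(members, cand[best])
      score <- cand_scores[best]
      trace <- c(trace, score)
    }
    groups[[s]] <- sort(members)
    traces[[s]] <- trace
  }
  keep <- !duplicated(vapply(groups, paste, "", collapse = "\r"))
  groups <- groups[keep]
  model <- fit_metagene_nop(X, y, groups, lambda)
  model$expansion_scores <- traces
  model
}

#' Hub-dysregulation outcome predictor (Taylor-style)
#'
#' Hubs are genes with network degree above 5. For each hub and each of its
#' neighbors, the Pearson correlation is computed separately within the
#' good and poor outcome classes; the hub's dysregulation score is the mean
#' absolute correlation change over its neighbors. The top-ranked fraction
#' of hubs (default half) define subnetworks (hub plus neighbors) that are
#' averaged into meta-genes for a Lasso.
#'
#' @param X samples x genes matrix (training, z-scored).
#' @param y outcome labels (>= 3 samples per class required).
#' @param net a GeneNetwork.
#' @param lambda Lasso penalty on the meta-genes.
#' @param hub_fraction fraction of hubs (by dysregulation rank) kept.
#' @param degree_cutoff hub definition: degree strictly above this.
#' @return a `synet_model` (type `metagene_nop`) with `hub_scores`.
#' @export
taylor_nop <- function(X, y, net, lambda, hub_fraction = 0.5,
                       degree_cutoff = 5) {
  y01 <- as_poor01(y)
  if (sum(y01 == 1) < 3 || sum(y01 == 0) < 3)
    stop("need >= 3 samples per outcome class")
  genes <- intersect(net$nodes, colnames(X))
  deg <- network_degree(net)[genes]
  nbrs <- adjacency_list(net, genes)
  hubs <- genes[deg > degree_cutoff]
  if (!length(hubs)) stop("no hub (degree > ", degree_cutoff, ") in network")
  delta_rho <- function(h) {
    nn <- intersect(nbrs[[h]], colnames(X))
    if (!length(nn)) return(0)
    cg <- suppressWarnings(stats::cor(X[y01 == 0, h], X[y01 == 0, nn]))
    cp <- suppressWarnings(stats::cor(X[y01 == 1, h], X[y01 == 1, nn]))
    cg[!is.finite(cg)] <- 0; cp[!is.finite(cp)] <- 0
    mean(abs(cg - cp))
  }
  scores <- vapply(hubs, delta_rho, 0)
  n_keep <- max(1L, ceiling(hub_fraction * length(hubs)))
  top <- hubs[order(-scores, hubs)][seq_len(n_keep)]
  groups <- lapply(top, function(h)
    intersect(c(h, nbrs[[h]]), colnames(X)))
  names(groups) <- top
  model <- fit_metagene_nop(X, y, groups, lambda)
  model$hub_scores <- sort(scores, decreasing = TRUE)
  model
}

# neighbor lookup restricted to genes of interest
adjacency_list <- function(net, genes) {
  e <- net$edges
  adj <- rbind(data.frame(from = e$gene_a, to = e$gene_b),
               data.frame(from = e$gene_b, to = e$gene_a))
  adj <- adj[adj$from %in% genes & adj$to %in% genes, ]
  out <- split(adj$to, factor(adj$from, levels = genes))
  lapply(out, as.character)
}

# shared tail of the three classical NOPs: average member columns into
# meta-genes, train a Lasso on them, remember the grouping for prediction
fit_metagene_nop <- function(X, y, groups, lambda) {
  M <- metagene_matrix(X, groups)
  sub <- train_lasso(M, y, lambda)
  structure(list(type = "metagene_nop", meta_groups = groups,
                 submodel = sub,
                 signature = sort(unique(unlist(
                   groups[names(groups) %in% sub$signature]))),
                 lambda = lambda),
            class = "synet_model")
}

#' Grid-search hyperparameter tuning on inner folds
#'
#' Exhaustive search over a config grid: each config is trained on every
#' inner fold's training samples and scored by AUC on the inner fold's
#' test samples; the config with the highest mean inner AUC wins and is
#' refit on the full supplied data. Ties prefer the sparser model: larger
#' `lambda` first, then smaller `K` (or `n_clusters`), then grid order.
#'
#' @param train_fn function(X, y, config) returning a `synet_model`.
#' @param grid data.frame of configs, one row each (columns are passed as
#'   a named list to `train_fn`).
#' @param inner_folds list of `list(train = idx, test = idx)` row-index
#'   pairs into `X`.
#' @param X samples x features matrix (z-scored on the full supplied
#'   data).
#' @param y outcome labels.
#' @return list: `config` (winning row), `model` (refit on all data),
#'   `surface` (grid with mean inner AUC per config).
#' @export
tune_model <- function(train_fn, grid, inner_folds, X, y) {
  if (nrow(grid) == 0) stop("empty tuning grid")
  y01 <- as_poor01(y)
  mean_auc <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    cfg <- as.list(grid[g, , drop = FALSE])
    aucs <- vapply(inner_folds, function(fo) {
      tr <- fo$train; te <- fo$test
      if (length(unique(y01[te])) < 2) return(NA_real_)
      m <- train_fn(X[tr, , drop = FALSE], y01[tr], cfg)
      auc(predict_outcome_score(m, X[te, , drop = FALSE]), y01[te])
    }, 0)
    mean_auc[g] <- mean(aucs, na.rm = TRUE)
  }
  lam <- if ("lambda" %in% names(grid)) grid$lambda else rep(0, nrow(grid))
  kk <- if ("K" %in% names(grid)) grid$K
        else if ("n_clusters" %in% names(grid)) grid$n_clusters
        else rep(0, nrow(grid))
  best <- order(-mean_auc, -lam, kk)[1]
  cfg <- as.list(grid[best, , drop = FALSE])
  list(config = cfg, model = train_fn(X, y01, cfg),
       surface = cbind(grid, inner_auc = mean_auc))
}
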