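#' Construct a weighted undirected gene network
#'
#' A `GeneNetwork` is an undirected weighted graph over gene symbols. Edges
#' are stored in canonical form (`gene_a < gene_b` lexicographically), with
#' no self-loops and no duplicates; duplicate input edges keep the maximum
#' weight. Node set may exceed the set of edge endpoints.
#'
#' @param edges data.frame with columns `gene_a`, `gene_b`, `weight`
#'   (positive). A missing `weight` column defaults to 1.
#' @param nodes optional character vector of node symbols; endpoints are
#'   always included.
#' @return an object of class `GeneNetwork`.
#' @export
new_network <- function(edges, nodes = NULL) {
  if (nrow(edges) == 0) {
    edges <- data.frame(gene_a = character(), gene_b = character(),
                        weight = numeric())
  } else {
    if (!"weight" %in% names(edges)) edges$weight <- 1
    edges$gene_a <- as.character(edges$gene_a)
    edges$gene_b <- as.character(edges$gene_b)
    if (any(!is.finite(edges$weight)) || any(edges$weight <= 0))
      stop("edge weights must be positive and finite")
    n_loops <- sum(edges$gene_a == edges$gene_b)
    if (n_loops > 0) {
      message(sprintf("dropped %d self-loop(s)", n_loops))
      edges <- edges[edges$gene_a != edges$gene_b, , drop = FALSE]
    }
    swap <- edges$gene_a > edges$gene_b
    tmp <- edges$gene_a[swap]
    edges$gene_a[swap] <- edges$gene_b[swap]
    edges$gene_b[swap] <- tmp
    # duplicates keep the maximum weight
    key <- paste(edges$gene_a, edges$gene_b, sep = "\r")
    if (anyDuplicated(key)) {
      o <- order(key, -edges$weight)
      edges <- edges[o, , drop = FALSE]
      edges <- edges[!duplicated(key[o]), , drop = FALSE]
    }
    edges <- edges[order(edges$gene_a, edges$gene_b),
                   c("gene_a", "gene_b", "weight"), drop = FALSE]
    rownames(edges) <- NULL
  }
  nodes <- sort(unique(c(as.character(nodes), edges$gene_a, edges$gene_b)))
  structure(list(edges = edges, nodes = nodes), class = "GeneNetwork")
}

#' @export
print.GeneNetwork <- function(x, ...) {
  cat(sprintf("GeneNetwork: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Number of edges / nodes
#' @param n a GeneNetwork.
#' @return integer count.
#' @export
network_size <- function(n) c(nodes = length(n$nodes), edges = nrow(n$edges))

#' Per-node degree of a network
#' @param n a GeneNetwork.
#' @return named integer vector over all nodes (isolated nodes have 0).
#' @export
network_degree <- function(n) {
  d <- table(factor(c(n$edges$gene_a, n$edges$gene_b), levels = n$nodes))
  stats::setNames(as.integer(d), names(d))
}

#' Convert a GeneNetwork to an igraph graph
#' @param n a GeneNetwork.
#' @return an igraph undirected weighted graph carrying all nodes.
#' @export
network_to_igraph <- function(n) {
  g <- igraph::graph_from_data_frame(
    n$edges[, c("gene_a", "gene_b")], directed = FALSE,
    vertices = data.frame(name = n$nodes))
  igraph::E(g)$weight <- n$edges$weight
  g
}

#' Convert an igraph graph to a GeneNetwork
#' @param g an undirected igraph graph with vertex names; missing weights
#'   default to 1.
#' @return a GeneNetwork.
#' @export
network_from_igraph <- function(g) {
  el <- igraph::as_data_frame(g, what = "edges")
  names(el)[1:2] <- c("gene_a", "gene_b")
  if (!"weight" %in% names(el)) el$weight <- rep(1, nrow(el))
  new_network(el[, c("gene_a", "gene_b", "weight")],
              nodes = igraph::V(g)$name)
}

#' Read a gene network from an edge-list TSV
#'
#' Format: one edge per line, `gene_a<TAB>gene_b[<TAB>weight]`. Two-column
#' input is unweighted and requires `weighting = "degree_average"`, which
#' assigns each link the average degree of its endpoints computed on the
#' unweighted graph (the convention used for unweighted interactome
#' networks). Self-loops are dropped with a logged count; duplicate edges
#' keep the maximum weight. Gene symbols are uppercased so they match
#' compendium gene ids exactly.
#'
#' @param path edge-list TSV path.
#' @param weighting `"given"` (third column required) or
#'   `"degree_average"`.
#' @return a GeneNetwork.
#' @export
read_network <- function(path, weighting = c("given", "degree_average")) {
  weighting <- match.arg(weighting)
  raw <- readLines(path)
  raw <- raw[nzchar(trimws(raw))]
  parts <- strsplit(raw, "\t", fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf < 2 | nf > 3)
  if (length(bad))
    stop(sprintf("malformed network row at line %d: '%s'", bad[1], raw[bad[1]]))
  has_w <- all(nf == 3)
  if (!has_w && any(nf == 3))
    stop("mixed 2- and 3-column rows in edge list")
  if (!has_w && weighting == "given")
    stop("2-column edge list requires weighting = 'degree_average'")
  edges <- data.frame(
    gene_a = toupper(vapply(parts, `[[`, "", 1)),
    gene_b = toupper(vapply(parts, `[[`, "", 2)),
    stringsAsFactors = FALSE)
  if (has_w) {
    w <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3)))
    if (anyNA(w))
      stop(sprintf("non-numeric weight at line %d", which(is.na(w))[1]))
    edges$weight <- w
  }
  if (weighting == "degree_average") {
    net0 <- new_network(edges[, c("gene_a", "gene_b")])
    deg <- network_degree(net0)
    e <- net0$edges
    e$weight <- (deg[e$gene_a] + deg[e$gene_b]) / 2
    return(new_network(e))
  }
  new_network(edges)
}

#' Write a gene network to an edge-list TSV
#' @param n a GeneNetwork.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_network <- function(n, path) {
  data.table::fwrite(n$edges, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Threshold a network to its strongest part
#'
#' `top_links` keeps the `k` highest-weight edges; `top_genes` adds edges in
#' descending weight order until `k` distinct genes are touched, then stops.
#' Isolated nodes are dropped in both modes. Weight ties are broken by
#' lexicographic order of (gene_a, gene_b) for reproducibility.
#'
#' @param n a GeneNetwork.
#' @param mode `"top_links"` or `"top_genes"`.
#' @param k number of links (or genes) to retain; if it exceeds what is
#'   available the whole network is returned with a warning.
#' @return a GeneNetwork that is a subgraph of `n`.
#' @export
threshold_network <- function(n, mode = c("top_links", "top_genes"), k) {
  mode <- match.arg(mode)
  if (k < 1) stop("k must be >= 1")
  e <- n$edges
  o <- order(-e$weight, e$gene_a, e$gene_b)
  e <- e[o, , drop = FALSE]
  if (mode == "top_links") {
    if (k >= nrow(e)) {
      if (k > nrow(e)) warning("k exceeds available links; returning all")
      keep <- e
    } else keep <- e[seq_len(k), , drop = FALSE]
  } else {
    if (k > length(unique(c(e$gene_a, e$gene_b)))) {
      warning("k exceeds available genes; returning all")
      keep <- e
    } else {
      seen <- character(0)
      last <- 0L
      for (i in seq_len(nrow(e))) {
        seen <- union(seen, c(e$gene_a[i], e$gene_b[i]))
        if (length(seen) >= k) { last <- i; break }
        last <- i
      }
      keep <- e[seq_len(last), , drop = FALSE]
    }
  }
  new_network(keep)
}
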