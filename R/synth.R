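#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed`, so package functions are reproducible
#' from their `seed` arguments without disturbing the caller's RNG stream.
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

#' Configuration for the synthetic compendium generator
#'
#' Defaults describe a desk-scale multi-study breast-cancer-like compendium:
#' 4 studies of 250 samples over 300 genes, with 20 individually predictive
#' genes, 10 planted synergistic pairs, 5 correlated co-expression blocks of
#' 10 genes, unit effect size, study batch shifts of SD 0.3 and 20%
#' censoring.
#'
#' @param n_studies number of studies.
#' @param samples_per_study samples per study.
#' @param n_genes total genes.
#' @param n_marginal individually predictive genes (mean shift
#'   `effect_size` between outcome classes).
#' @param n_synergy_pairs planted synergistic pairs: each pair shares a
#'   strong latent factor, and the outcome signal lives only in the
#'   contrast between the two genes, so marginal AUCs stay near 0.5 while
#'   the fitted linear meta-gene is predictive.
#' @param n_corr_blocks,block_size co-expressed blocks sharing a
#'   non-outcome latent factor.
#' @param effect_size scale of outcome-related signal (SD units).
#' @param batch_shift_sd SD of per-study, per-gene additive shifts.
#' @param censor_rate fraction of samples censored.
#' @param synergy_mechanism `"contrast"` (default; linear meta-genes can
#'   capture it) or `"xor"` (sign-interaction signal that no linear
#'   meta-gene can capture; for negative controls).
#' @param seed integer seed; the compendium is a pure function of the
#'   config.
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_studies = 4, samples_per_study = 250,
                         n_genes = 300, n_marginal = 20,
                         n_synergy_pairs = 10, n_corr_blocks = 5,
                         block_size = 10, effect_size = 1,
                         batch_shift_sd = 0.3, censor_rate = 0.2,
                         synergy_mechanism = c("contrast", "xor"),
                         seed = 1) {
  cfg <- list(n_studies = n_studies, samples_per_study = samples_per_study,
              n_genes = n_genes, n_marginal = n_marginal,
              n_synergy_pairs = n_synergy_pairs,
              n_corr_blocks = n_corr_blocks, block_size = block_size,
              effect_size = effect_size, batch_shift_sd = batch_shift_sd,
              censor_rate = censor_rate,
              synergy_mechanism = match.arg(synergy_mechanism),
              seed = as.integer(seed))
  counts <- unlist(cfg[c("n_studies", "samples_per_study", "n_genes",
                         "n_marginal", "n_synergy_pairs", "n_corr_blocks",
                         "block_size")])
  if (any(counts < 0)) stop("counts must be non-negative")
  used <- n_marginal + 2 * n_synergy_pairs + n_corr_blocks * block_size
  if (used > n_genes)
    stop(sprintf("gene budget infeasible: %d structured genes > %d genes",
                 used, n_genes))
  if (censor_rate < 0 || censor_rate > 1) stop("censor_rate must be in [0,1]")
  class(cfg) <- "synth_config"
  cfg
}

# Exponential survival rates chosen so that 5-year dichotomization recovers
# the latent class for >= 95% of uncensored samples:
# P(T < 5 | poor) = 1 - exp(-5*0.7)  ~ 0.97
# P(T >= 5 | good) =     exp(-5*0.008) ~ 0.96
.rate_poor <- 0.7
.rate_good <- 0.008

#' Simulate a multi-study survival-labelled expression compendium
#'
#' Draws a latent binary outcome per sample, plants the structure described
#' in [synth_config()], adds per-study batch shifts, and generates censored
#' exponential survival times whose 5-year dichotomization recovers the
#' latent outcome.
#'
#' @param cfg a [synth_config()].
#' @return list with elements `compendium` (an ExpressionCompendium) and
#'   `truth` (marginal gene ids, synergy pair table, correlation block
#'   membership, latent outcome per sample).
#' @export
simulate_compendium <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  with_seed(cfg$seed, {
    n <- cfg$n_studies * cfg$samples_per_study
    p <- cfg$n_genes
    gene_ids <- sprintf("G%04d", seq_len(p))
    sample_ids <- sprintf("S%05d", seq_len(n))
    study <- rep(sprintf("study%02d", seq_len(cfg$n_studies)),
                 each = cfg$samples_per_study)
    y <- stats::rbinom(n, 1, 0.5)              # 1 = latent poor outcome
    s <- y - 0.5

    X <- matrix(stats::rnorm(n * p), n, p,
                dimnames = list(sample_ids, gene_ids))
    cursor <- 0L
    take <- function(k) {
      idx <- cursor + seq_len(k); cursor <<- cursor + k; idx
    }

    marg_idx <- take(cfg$n_marginal)
    for (j in marg_idx) X[, j] <- X[, j] + cfg$effect_size * s

    syn_pairs <- NULL
    if (cfg$n_synergy_pairs > 0) {
      syn_idx <- matrix(take(2 * cfg$n_synergy_pairs), ncol = 2, byrow = TRUE)
      # The shared factor (weight 3) dwarfs each gene's slice of the
      # contrast (0.3 * effect), so single-gene AUCs sit near 0.5; the
      # contrast g_i - g_j cancels the factor and carries the full signal
      # (0.6 * effect against residual noise 0.4 per gene), so the fitted
      # pair is clearly predictive. Keeping the signal in the difference
      # (rather than the sum) also makes it robust to per-study quantile
      # normalization, whose per-sample monotone maps cancel in local
      # differences of strongly correlated genes.
      for (k in seq_len(cfg$n_synergy_pairs)) {
        f <- stats::rnorm(n)                   # shared latent factor
        contrast <- 0.6 * cfg$effect_size * s  # signal only in g_i - g_j
        if (cfg$synergy_mechanism == "xor") {
          # sign interaction: only the product of the two genes carries
          # outcome signal; no linear meta-gene can capture it
          a <- sign(stats::rnorm(n))
          X[, syn_idx[k, 1]] <- 3 * f + 0.3 * cfg$effect_size * a +
            0.4 * stats::rnorm(n)
          X[, syn_idx[k, 2]] <- 3 * f + 0.3 * cfg$effect_size * a *
            (2 * y - 1) + 0.4 * stats::rnorm(n)
        } else {
          X[, syn_idx[k, 1]] <- 3 * f + contrast / 2 + 0.4 * stats::rnorm(n)
          X[, syn_idx[k, 2]] <- 3 * f - contrast / 2 + 0.4 * stats::rnorm(n)
        }
      }
      syn_pairs <- data.frame(gene_a = gene_ids[syn_idx[, 1]],
                              gene_b = gene_ids[syn_idx[, 2]])
    }

    corr_blocks <- list()
    if (cfg$n_corr_blocks > 0) {
      for (b in seq_len(cfg$n_corr_blocks)) {
        idx <- take(cfg$block_size)
        fb <- stats::rnorm(n)                  # non-outcome latent factor
        for (j in idx) X[, j] <- fb + 0.5 * stats::rnorm(n)
        corr_blocks[[b]] <- gene_ids[idx]
      }
    }

    # additive per-study, per-gene batch shifts
    if (cfg$batch_shift_sd > 0) {
      for (st in unique(study)) {
        shift <- stats::rnorm(p, 0, cfg$batch_shift_sd)
        rows <- which(study == st)
        X[rows, ] <- sweep(X[rows, , drop = FALSE], 2, shift, "+")
      }
    }

    t_true <- stats::rexp(n, rate = ifelse(y == 1, .rate_poor, .rate_good))
    censored <- stats::rbinom(n, 1, cfg$censor_rate) == 1
    time <- ifelse(censored, stats::runif(n, 0, t_true), t_true)
    event <- as.integer(!censored)

    ann <- data.frame(sample_id = sample_ids, study = study,
                      survival_time = time, event = event,
                      stringsAsFactors = FALSE)
    comp <- new_compendium(X, ann)
    list(compendium = comp,
         truth = list(marginal = gene_ids[marg_idx],
                      synergy_pairs = syn_pairs,
                      corr_blocks = corr_blocks,
                      latent_outcome = stats::setNames(y, sample_ids)))
  })
}

#' Simulate a weighted gene network
#'
#' @param n_genes node count; nodes are named `G0001 ...` to match the
#'   synthetic compendium gene ids.
#' @param model `"scale_free"` (static power-law degree fitness) or
#'   `"erdos_renyi"` (uniform random graph), both with exactly `n_links`
#'   edges.
#' @param n_links edge count, at most `choose(n_genes, 2)`.
#' @param seed integer seed.
#' @param pl_exponent power-law exponent of the fitness sequence for the
#'   scale-free model.
#' @return a GeneNetwork with edge weights drawn Uniform(0, 1].
#' @export
simulate_network <- function(n_genes, model = c("scale_free", "erdos_renyi"),
                             n_links, seed = 1, pl_exponent = 2.3) {
  model <- match.arg(model)
  if (n_links > n_genes * (n_genes - 1) / 2)
    stop("n_links exceeds the number of possible undirected edges")
  with_seed(seed, {
    g <- if (n_links == 0) {
      igraph::make_empty_graph(n_genes, directed = FALSE)
    } else if (model == "erdos_renyi") {
      igraph::sample_gnm(n_genes, n_links)
    } else {
      igraph::sample_fitness_pl(n_genes, n_links, exponent.out = pl_exponent)
    }
    igraph::V(g)$name <- sprintf("G%04d", seq_len(n_genes))
    if (n_links > 0) igraph::E(g)$weight <- 1 - stats::runif(igraph::ecount(g))
    net <- network_from_igraph(g)
    net$nodes <- sprintf("G%04d", seq_len(n_genes))
    net
  })
}

#' Build the ground-truth synergy network of a simulated compendium
#'
#' Convenience for benchmarking network-guided classifiers: edges connect
#' the members of each planted synergistic pair (weight 1), optionally
#' diluted with random background edges over the remaining genes (weight
#' drawn Uniform(0, 0.5]) so the graph has non-trivial topology.
#'
#' @param truth the `truth` element returned by [simulate_compendium()].
#' @param all_genes all compendium gene ids (network node universe).
#' @param n_background random extra edges to add.
#' @param seed integer seed for the background edges.
#' @return a GeneNetwork.
#' @export
truth_network <- function(truth, all_genes, n_background = 0, seed = 1) {
  edges <- truth$synergy_pairs
  if (is.null(edges) || nrow(edges) == 0)
    stop("no planted synergy pairs in this truth object")
  edges$weight <- 1
  if (n_background > 0) {
    bg <- with_seed(seed, {
      a <- sample(all_genes, n_background * 4, replace = TRUE)
      b <- sample(all_genes, n_background * 4, replace = TRUE)
      keep <- a != b
      data.frame(gene_a = a[keep], gene_b = b[keep],
                 weight = 0.5 * (1 - stats::runif(sum(keep))))
    })
    key_pair <- function(x, y) paste(pmin(x, y), pmax(x, y))
    bg <- bg[!duplicated(key_pair(bg$gene_a, bg$gene_b)), , drop = FALSE]
    bg <- bg[!key_pair(bg$gene_a, bg$gene_b) %in%
               key_pair(edges$gene_a, edges$gene_b), , drop = FALSE]
    bg <- utils::head(bg, n_background)
    edges <- rbind(edges, bg)
  }
  new_network(edges, nodes = all_genes)
}
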