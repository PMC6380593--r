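#' Abort on train/test sample overlap
#'
#' The harness checks every training call: if any held-out test sample id
#' appears among the training ids, the run is aborted. This is the leakage
#' guard that keeps cross-study validation honest.
#'
#' @param train_ids,test_ids character sample ids.
#' @return invisibly TRUE; stops on overlap.
#' @export
assert_no_leakage <- function(train_ids, test_ids) {
  bad <- intersect(train_ids, test_ids)
  if (length(bad))
    stop("leakage detected: ", length(bad),
         " test sample(s) present in training data, e.g. ", bad[1])
  invisible(TRUE)
}

# restrict a network to genes available in the feature matrix (exact
# uppercased symbol match; dropped genes counted in a message)
restrict_network <- function(net, genes) {
  e <- net$edges
  keep <- e$gene_a %in% genes & e$gene_b %in% genes
  n_drop <- length(setdiff(net$nodes, genes))
  if (n_drop > 0)
    message(sprintf("%d network gene(s) absent from compendium dropped", n_drop))
  new_network(e[keep, , drop = FALSE], nodes = intersect(net$nodes, genes))
}

#' Default hyperparameter grids per method
#'
#' Desk-scale grids: `lambda` log-spaced, `K` neighbor budgets for the
#' group lasso, `n_clusters` for correlation clustering. Pass a trimmed
#' grid for quick runs.
#'
#' @param n_lambda points on the lambda grid.
#' @return named list of config data.frames.
#' @export
default_grids <- function(n_lambda = 6) {
  lambda <- exp(seq(log(1e-3), log(0.5), length.out = n_lambda))
  list(lasso = data.frame(lambda = lambda),
       gl = expand.grid(lambda = lambda, K = c(1, 3, 5)),
       park = expand.grid(lambda = lambda, n_clusters = c(10, 30, 100)),
       chuang = data.frame(lambda = lambda),
       taylor = data.frame(lambda = lambda))
}

# build the train_fn closure for a method given its (restricted) network
method_train_fn <- function(method, net) {
  switch(method,
    lasso = function(X, y, cfg) train_lasso(X, y, cfg$lambda),
    gl = {
      cache <- new.env(parent = emptyenv())
      function(X, y, cfg) {
        key <- paste0("K", cfg$K)
        if (is.null(cache[[key]])) cache[[key]] <- build_groups(net, cfg$K)
        groups <- cache[[key]]
        groups <- lapply(groups, function(g) intersect(g, colnames(X)))
        groups <- groups[lengths(groups) > 0]
        train_group_lasso(X, y, groups, cfg$lambda, tol = 1e-7,
                          max_iter = 1500)
      }
    },
    park = function(X, y, cfg) park_nop(X, y, cfg$n_clusters, cfg$lambda),
    chuang = function(X, y, cfg) chuang_nop(X, y, net, cfg$lambda),
    taylor = function(X, y, cfg) taylor_nop(X, y, net, cfg$lambda),
    stop("unknown method: ", method))
}

# per-(fold, repeat) redraw of the outer training samples, keyed only by
# (plan seed, fold, repeat) so every task sees the identical draw
harness_draw <- function(plan, fold, rep, train_rows) {
  n <- ceiling(plan$subsample * length(train_rows))
  with_seed(subsample_seed(plan$seed + 500009, fold, rep),
            sample(train_rows, n, replace = TRUE))
}

#' Cross-study evaluation of outcome predictors
#'
#' Runs each task (a method plus its guiding network) through the shared
#' fold plan. Per outer fold: the held-out study is untouched; any
#' data-driven network (`"synet"`, `"corr"`) is inferred from the outer
#' training studies only. Per repeat: a fresh 70%-with-replacement draw of
#' the outer training samples is taken, hyperparameters are tuned on the
#' inner leave-one-study-out folds, the winning config is refit on the
#' draw, and AUC is measured on the held-out study. The leakage guard is
#' asserted before every training call.
#'
#' @param c an ExpressionCompendium.
#' @param tasks named list; each element is
#'   `list(method = "lasso"|"gl"|"park"|"chuang"|"taylor",
#'   network = GeneNetwork | "synet" | "corr" | NULL,
#'   grid = data.frame (optional))`.
#' @param plan a [make_fold_plan()] result.
#' @param grids default grids by method for tasks without their own
#'   (see [default_grids()]).
#' @param n_links link budget for in-fold `"synet"`/`"corr"` inference.
#' @param scan_repeats subsample repeats inside the in-fold pair scan.
#' @param verbose print fold progress.
#' @return an `EvalResult`: per task, the fold x repeat AUC matrix, the
#'   signature per cell, and the tuned config per cell.
#' @export
run_cross_study <- function(c, tasks, plan, grids = default_grids(),
                            n_links = 1000, scan_repeats = 5,
                            verbose = FALSE) {
  genes <- compendium_genes(c)
  use <- usable_samples(c)
  cu <- subset_compendium(c, samples = use)
  y01 <- as_poor01(cu$samples$outcome)
  study <- cu$samples$study
  ids <- cu$samples$sample_id
  nf <- length(plan$outer); nr <- plan$n_repeats

  res <- lapply(tasks, function(t)
    list(method = t$method,
         auc = matrix(NA_real_, nf, nr,
                      dimnames = list(vapply(plan$outer, `[[`, "",
                                             "test_study"), NULL)),
         signatures = vector("list", nf * nr),
         configs = vector("list", nf * nr),
         predictions = vector("list", nf * nr)))

  for (f in seq_len(nf)) {
    fold <- plan$outer[[f]]
    test_rows <- which(study == fold$test_study)
    train_rows <- which(study != fold$test_study)
    test_ids <- ids[test_rows]
    if (length(unique(y01[test_rows])) < 2) {
      message("outer fold ", fold$test_study, " skipped: single-class test study")
      next
    }
    if (verbose) message("outer fold ", f, "/", nf, ": test = ", fold$test_study)

    # data-driven networks are inferred from the outer training studies only
    ct <- subset_compendium(cu, samples = train_rows)
    assert_no_leakage(ct$samples$sample_id, test_ids)
    # the synergy network is inferred once per outer fold (its own scan
    # already repeats subsampling internally); the correlation network is
    # inferred per repeat from that repeat's 70% redraw, below
    fold_nets <- new.env(parent = emptyenv())
    get_fold_net <- function(spec, draw_comp) {
      if (is.null(spec)) return(NULL)
      if (inherits(spec, "GeneNetwork")) return(restrict_network(spec, genes))
      if (spec == "corr") return(build_corr_network(draw_comp, n_links))
      if (is.null(fold_nets[[spec]])) {
        fold_nets[[spec]] <- switch(spec,
          synet = infer_synet(ct, n_links = min(n_links,
                                                pair_count(length(genes))),
                              seed = plan$seed + f,
                              n_repeats = scan_repeats)$network,
          stop("unknown network spec: ", spec))
      }
      fold_nets[[spec]]
    }

    for (r in seq_len(nr)) {
      draw <- harness_draw(plan, f, r, train_rows)
      assert_no_leakage(ids[draw], test_ids)
      zs <- zscore_fit(cu$values[draw, , drop = FALSE])
      Xd <- zscore_apply(cu$values[draw, , drop = FALSE], zs)
      Xt <- zscore_apply(cu$values[test_rows, , drop = FALSE], zs)
      yd <- y01[draw]
      if (length(unique(yd)) < 2) next
      # inner folds: train on the draw minus the inner test study,
      # evaluate on the full inner test study (rows of the outer training
      # partition, standardized with the draw statistics)
      Xtr_all <- zscore_apply(cu$values[train_rows, , drop = FALSE], zs)
      inner_folds <- lapply(fold$inner, function(infold) {
        list(train_draw = which(study[draw] != infold$test_study),
             test_rows = which(study[train_rows] == infold$test_study))
      })

      for (tk in names(tasks)) {
        task <- tasks[[tk]]
        net <- get_fold_net(task$network,
                            subset_compendium(cu, samples = draw))
        train_fn <- method_train_fn(task$method, net)
        grid <- if (!is.null(task$grid)) task$grid else grids[[task$method]]
        cell <- (f - 1) * nr + r
        tuned <- tune_inner(train_fn, grid, inner_folds, Xd, yd, Xtr_all,
                            y01[train_rows])
        model <- tuned$model
        sc <- predict_outcome_score(model, Xt)
        res[[tk]]$auc[f, r] <- auc(sc, y01[test_rows])
        res[[tk]]$signatures[[cell]] <- model$signature
        res[[tk]]$configs[[cell]] <- tuned$config
        res[[tk]]$predictions[[cell]] <- data.frame(
          sample_id = test_ids, score = sc,
          predicted = ifelse(sc > stats::median(sc), "poor", "good"),
          fold = f, repeat_ = r, stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(tasks = res, plan = plan), class = "EvalResult")
}

# grid search where inner training uses draw rows and inner evaluation
# uses the full inner-test-study rows of the outer training partition
tune_inner <- function(train_fn, grid, inner_folds, Xd, yd, Xtr_all, ytr) {
  mean_auc <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    cfg <- as.list(grid[g, , drop = FALSE])
    aucs <- vapply(inner_folds, function(fo) {
      tr <- fo$train_draw; te <- fo$test_rows
      if (length(unique(yd[tr])) < 2 || length(unique(ytr[te])) < 2)
        return(NA_real_)
      m <- train_fn(Xd[tr, , drop = FALSE], yd[tr], cfg)
      auc(predict_outcome_score(m, Xtr_all[te, , drop = FALSE]), ytr[te])
    }, 0)
    mean_auc[g] <- mean(aucs, na.rm = TRUE)
  }
  lam <- if ("lambda" %in% names(grid)) grid$lambda else rep(0, nrow(grid))
  kk <- if ("K" %in% names(grid)) grid$K
        else if ("n_clusters" %in% names(grid)) grid$n_clusters
        else rep(0, nrow(grid))
  best <- order(-mean_auc, -lam, kk)[1]
  cfg <- as.list(grid[best, , drop = FALSE])
  list(config = cfg, model = train_fn(Xd, yd, cfg),
       surface = cbind(grid, inner_auc = mean_auc))
}

#' Tidy AUC table of an evaluation
#' @param r an EvalResult.
#' @return data.frame with columns task, method, fold (test study),
#'   repeat_, auc.
#' @export
results_table <- function(r) {
  do.call(rbind, lapply(names(r$tasks), function(tk) {
    t <- r$tasks[[tk]]
    df <- expand.grid(fold = rownames(t$auc),
                      repeat_ = seq_len(ncol(t$auc)),
                      stringsAsFactors = FALSE)
    df$auc <- as.vector(t$auc)
    cbind(task = tk, method = t$method, df)
  }))
}

#' Mean and standard deviation of cross-study AUC
#'
#' The mean summarizes performance and the SD across fold x repeat cells
#' summarizes stability (lower is more stable).
#'
#' @param auc_matrix fold x repeat AUC matrix (or an EvalResult task).
#' @return named vector `c(mean_auc, sd_auc)`.
#' @export
stability_metrics <- function(auc_matrix) {
  if (is.list(auc_matrix)) auc_matrix <- auc_matrix$auc
  cells <- auc_matrix[!is.na(auc_matrix)]
  if (length(cells) < 2) stop("need >= 2 fold x repeat cells")
  c(mean_auc = mean(cells), sd_auc = stats::sd(cells))
}

#' Pairwise Jaccard stability of gene signatures
#'
#' Jaccard index `|A intersect B| / |A union B|` over every unordered pair
#' of signatures selected across folds and repeats. Two empty signatures
#' count as identical (J = 1, with a message).
#'
#' @param signatures list of character vectors.
#' @return named vector `c(mean_jaccard, sd_jaccard)`.
#' @export
signature_jaccard <- function(signatures) {
  signatures <- signatures[!vapply(signatures, is.null, TRUE)]
  if (length(signatures) < 2) stop("need >= 2 signatures")
  pairs <- utils::combn(length(signatures), 2)
  j <- apply(pairs, 2, function(pr) {
    a <- signatures[[pr[1]]]; b <- signatures[[pr[2]]]
    u <- length(union(a, b))
    if (u == 0) {
      message("two empty signatures: Jaccard defined as 1")
      return(1)
    }
    length(intersect(a, b)) / u
  })
  c(mean_jaccard = mean(j), sd_jaccard = stats::sd(j))
}

#' Majority-vote prognosis over repeats
#'
#' Each sample is assigned the class predicted most often across repeats;
#' exact ties are broken by a seeded coin flip. The grouping feeds a
#' log-rank test against the survival data.
#'
#' @param predictions data.frame with columns `sample_id`, `predicted`
#'   (`good`/`poor`), e.g. stacked from an EvalResult task.
#' @param seed tie-break seed.
#' @return data.frame `sample_id`, `votes_poor`, `votes_total`, `group`.
#' @export
majority_vote_prognosis <- function(predictions, seed = 1) {
  sp <- split(predictions$predicted, predictions$sample_id)
  votes_poor <- vapply(sp, function(v) sum(v == "poor"), 0L)
  votes_total <- lengths(sp)
  group <- ifelse(votes_poor * 2 > votes_total, "poor",
                  ifelse(votes_poor * 2 < votes_total, "good", NA))
  ties <- which(is.na(group))
  if (length(ties)) {
    flips <- with_seed(seed, stats::rbinom(length(ties), 1, 0.5))
    group[ties] <- ifelse(flips == 1, "poor", "good")
  }
  data.frame(sample_id = names(sp), votes_poor = as.integer(votes_poor),
             votes_total = as.integer(votes_total), group = group,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Log-rank test between predicted prognosis groups
#'
#' @param c the ExpressionCompendium holding survival times and events.
#' @param groups a [majority_vote_prognosis()] result.
#' @return list with `chisq`, `p_value`, and the survdiff fit.
#' @export
logrank_groups <- function(c, groups) {
  idx <- match(groups$sample_id, c$samples$sample_id)
  if (anyNA(idx)) stop("unknown sample id in groups")
  d <- data.frame(time = c$samples$survival_time[idx],
                  event = c$samples$event[idx],
                  group = groups$group)
  fit <- survival::survdiff(survival::Surv(time, event) ~ group, data = d)
  p <- stats::pchisq(fit$chisq, df = 1, lower.tail = FALSE)
  list(chisq = unname(fit$chisq), p_value = p, fit = fit)
}
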