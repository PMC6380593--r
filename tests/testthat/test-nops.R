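make_xy <- function(seed = 20, n = 100, p = 12) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, sprintf("g%02d", 1:p)))
  y <- rbinom(n, 1, plogis(X[, 1] - X[, 2]))
  if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
  list(X = scale(X), y = y)
}

test_that("correlation clustering with singleton cut collapses to plain lasso", {
  d <- make_xy(21)
  m_park <- park_nop(d$X, d$y, n_clusters = ncol(d$X), lambda = 0.05)
  m_lasso <- train_lasso(d$X, d$y, 0.05)
  sc_p <- predict_outcome_score(m_park, d$X)
  sc_l <- predict_outcome_score(m_lasso, d$X)
  expect_equal(sc_p, sc_l, tolerance = 1e-9, ignore_attr = TRUE)
  expect_setequal(m_park$signature, m_lasso$signature)
})

test_that("correlation clustering recovers duplicated blocks and averages them", {
  set.seed(22)
  n <- 80
  base1 <- rnorm(n); base2 <- rnorm(n)
  X <- cbind(a1 = base1 + rnorm(n, 0, 0.05), a2 = base1 + rnorm(n, 0, 0.05),
             a3 = base1 + rnorm(n, 0, 0.05),
             b1 = base2 + rnorm(n, 0, 0.05), b2 = base2 + rnorm(n, 0, 0.05),
             b3 = base2 + rnorm(n, 0, 0.05))
  y <- as.integer(base1 > 0)
  Xs <- scale(X)
  m <- park_nop(Xs, y, n_clusters = 2, lambda = 0.01)
  blocks <- lapply(m$meta_groups, sort)
  expect_true(list(c("a1", "a2", "a3")) %in% blocks ||
                any(sapply(blocks, identical, c("a1", "a2", "a3"))))
  # the meta-gene is exactly the columnwise mean of its members
  g1 <- m$meta_groups[[1]]
  M <- synetr:::metagene_matrix(Xs, m$meta_groups)
  expect_equal(M[, 1], rowMeans(Xs[, g1]), ignore_attr = TRUE)
})

test_that("greedy subnetwork expansion halts and strictly improves", {
  d <- make_xy(23)
  # network: g01 - g02 (the synergistic-ish pair) plus a chain of noise
  net <- new_network(data.frame(
    gene_a = c("g01", "g03", "g04", "g05"),
    gene_b = c("g02", "g04", "g05", "g06"),
    weight = 1))
  m <- chuang_nop(d$X, d$y, net, lambda = 0.05)
  for (tr in m$expansion_scores)
    if (length(tr) > 1) expect_true(all(diff(tr) > 0))
  # an isolated-from-signal seed with no improving neighbor stays singleton
  sizes <- lengths(m$meta_groups)
  expect_true(any(sizes == 1) || all(sapply(m$expansion_scores, length) >= 1))
  expect_s3_class(m, "synet_model")
})

test_that("greedy expansion absorbs partners whose averaged meta-gene improves", {
  # averaging two weakly predictive neighbors beats either alone, so the
  # greedy search should co-group them; pure-noise chain genes stay apart
  set.seed(24)
  n <- 300
  y <- rbinom(n, 1, 0.5)
  X <- matrix(rnorm(n * 30), n, 30,
              dimnames = list(NULL, sprintf("g%02d", 1:30)))
  for (j in 1:10) X[, j] <- X[, j] + 0.8 * (y - 0.5)
  Xs <- scale(X)
  pair_a <- sprintf("g%02d", seq(1, 9, by = 2))
  pair_b <- sprintf("g%02d", seq(2, 10, by = 2))
  net <- new_network(data.frame(
    gene_a = c(pair_a, sprintf("g%02d", 11:19)),
    gene_b = c(pair_b, sprintf("g%02d", 12:20)), weight = 1))
  m <- chuang_nop(Xs, y, net, lambda = 0.05)
  absorbed <- mapply(function(a, b)
    any(sapply(m$meta_groups, function(g) all(c(a, b) %in% g))),
    pair_a, pair_b)
  expect_gte(sum(absorbed), 4)   # at least 4 of 5 pairs co-grouped
})

test_that("hub dysregulation ranks correlation-flipping hubs first", {
  set.seed(25)
  n <- 200
  y <- rep(c(0, 1), each = n / 2)
  hub <- rnorm(n)
  # neighbors correlate +0.8 with the hub in good, -0.8 in poor samples
  flip <- ifelse(y == 0, 1, -1)
  nbr <- sapply(1:6, function(k) flip * hub * 0.8 + rnorm(n, 0, 0.6))
  colnames(nbr) <- paste0("n", 1:6)
  # a null hub with stable correlation
  hub2 <- rnorm(n)
  nbr2 <- sapply(1:6, function(k) hub2 * 0.8 + rnorm(n, 0, 0.6))
  colnames(nbr2) <- paste0("m", 1:6)
  X <- scale(cbind(h1 = hub, nbr, h2 = hub2, nbr2))
  net <- new_network(data.frame(
    gene_a = c(rep("h1", 6), rep("h2", 6)),
    gene_b = c(paste0("n", 1:6), paste0("m", 1:6)), weight = 1))
  m <- taylor_nop(X, y, net, lambda = 0.05, hub_fraction = 0.5)
  expect_equal(names(m$hub_scores)[1], "h1")
  expect_gt(m$hub_scores[["h1"]], 1.2)       # |0.8 - (-0.8)| ~ 1.6 regime
  expect_lt(m$hub_scores[["h2"]], 0.5)
  expect_equal(names(m$meta_groups), "h1")   # top 50% of 2 hubs = 1

  # identical correlation structure in both classes: all scores near zero
  m2 <- taylor_nop(X[, c("h2", paste0("m", 1:6))], y,
                   new_network(data.frame(gene_a = "h2",
                                          gene_b = paste0("m", 1:6),
                                          weight = 1)), lambda = 0.05)
  expect_lt(max(m2$hub_scores), 0.5)

  # degree-5 gene is not a hub (strict inequality)
  net5 <- new_network(data.frame(gene_a = "h1", gene_b = paste0("n", 1:5),
                                 weight = 1))
  expect_error(taylor_nop(X, y, net5, lambda = 0.05), "no hub")
})

test_that("grid search honors the argmax contract and its tie-breaks", {
  d <- make_xy(26)
  folds <- list(list(train = 1:60, test = 61:100),
                list(train = 41:100, test = 1:40))
  grid <- data.frame(lambda = c(0.02, 0.1, 5))
  tuned <- tune_model(function(X, y, cfg) train_lasso(X, y, cfg$lambda),
                      grid, folds, d$X, d$y)
  expect_equal(nrow(tuned$surface), 3)
  best_auc <- tuned$surface$inner_auc[tuned$surface$lambda == tuned$config$lambda]
  expect_true(all(best_auc >= tuned$surface$inner_auc))

  # single-point grid is a passthrough
  t1 <- tune_model(function(X, y, cfg) train_lasso(X, y, cfg$lambda),
                   data.frame(lambda = 0.05), folds, d$X, d$y)
  expect_equal(t1$config$lambda, 0.05)

  # exact tie (duplicated config) resolves to the larger lambda
  grid_tie <- data.frame(lambda = c(0.05, 0.05 * (1 + 1e-15)))
  t2 <- tune_model(function(X, y, cfg) train_lasso(X, y, cfg$lambda),
                   grid_tie, folds, d$X, d$y)
  expect_equal(t2$config$lambda, max(grid_tie$lambda))
  expect_error(tune_model(function(X, y, cfg) NULL, grid[0, , drop = FALSE],
                          folds, d$X, d$y), "empty")
})
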