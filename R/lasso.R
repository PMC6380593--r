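#' Z-scoring parameters from training data
#' @param X samples x features numeric matrix.
#' @return list with `center` and `scale` (constant features get scale 1).
#' @export
zscore_fit <- function(X) {
  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  list(center = center, scale = scale)
}

#' Apply stored z-scoring parameters
#' @param X samples x features matrix with the same columns used in
#'   [zscore_fit()].
#' @param zs a [zscore_fit()] result.
#' @return standardized matrix.
#' @export
zscore_apply <- function(X, zs) {
  scale(X, center = zs$center[colnames(X)], scale = zs$scale[colnames(X)])
}

#' L1-penalized logistic baseline classifier
#'
#' Standard Lasso over all individual genes: minimizes the mean logistic
#' negative log-likelihood plus `lambda * sum(|w|)` (glmnet's
#' parameterization; the intercept is unpenalized). Features are expected
#' to be z-scored with training statistics by the caller, so no internal
#' standardization is applied.
#'
#' @param X samples x features matrix (training, z-scored).
#' @param y outcome (`good`/`poor` or 0/1 with 1 = poor).
#' @param lambda L1 penalty.
#' @return a `synet_model` with `weights` (named, sparse), `intercept` and
#'   `signature` (features with non-zero weight).
#' @export
train_lasso <- function(X, y, lambda) {
  y01 <- as_poor01(y)
  if (length(unique(y01)) < 2) stop("outcome has no class variation")
  # glmnet needs >= 2 columns; pad a single-feature fit with a zero column
  pad <- ncol(X) == 1
  if (pad) X <- cbind(X, .pad. = 0)
  # short decreasing path ending exactly at the requested lambda: glmnet's
  # coordinate descent is warm-started and exact at in-path values
  path <- sort(unique(lambda * c(16, 8, 4, 2, 1)), decreasing = TRUE)
  fit <- glmnet::glmnet(X, y01, family = "binomial", alpha = 1,
                        lambda = path, standardize = FALSE,
                        thresh = 1e-15, maxit = 1e7)
  co <- stats::coef(fit, s = lambda)
  w <- stats::setNames(as.numeric(co[-1]), rownames(co)[-1])
  if (pad) w <- w[setdiff(names(w), ".pad.")]
  structure(list(type = "lasso", intercept = as.numeric(co[1]),
                 weights = w, signature = names(w)[w != 0],
                 lambda = lambda),
            class = "synet_model")
}

#' Linear risk score of a fitted model
#'
#' Higher scores indicate poorer predicted outcome (models are fitted with
#' poor coded 1).
#'
#' @param model a `synet_model` (lasso, group lasso, or a meta-gene NOP).
#' @param X samples x features matrix, z-scored with the training
#'   statistics used at fit time, containing at least the model's
#'   features.
#' @return numeric score per sample.
#' @export
predict_outcome_score <- function(model, X) {
  if (model$type %in% c("lasso", "group_lasso")) {
    feats <- names(model$weights)
    drop(X[, feats, drop = FALSE] %*% model$weights) + model$intercept
  } else if (model$type == "metagene_nop") {
    M <- metagene_matrix(X, model$meta_groups)
    predict_outcome_score(model$submodel, M)
  } else stop("unknown model type: ", model$type)
}

# average the (z-scored) member columns of each group into one meta-gene
metagene_matrix <- function(X, groups) {
  M <- vapply(groups, function(g)
    rowMeans(X[, g, drop = FALSE]), numeric(nrow(X)))
  if (is.null(dim(M))) M <- matrix(M, nrow = 1, dimnames = list(NULL, names(groups)))
  colnames(M) <- names(groups)
  M
}

#' @export
print.synet_model <- function(x, ...) {
  cat(sprintf("synet_model (%s): %d features in signature\n",
              x$type, length(x$signature)))
  invisible(x)
}
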