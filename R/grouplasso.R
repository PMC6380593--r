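#' Build overlapping seed-plus-neighbors groups from a network
#'
#' Every network gene becomes the seed of one group containing itself and
#' its `K` highest-weight neighbors (fewer when the degree is below `K`).
#' Neighbor priority is edge weight, descending; weight ties break by gene
#' name. Genes may appear in many groups — overlap is the point.
#'
#' @param net a GeneNetwork (non-empty).
#' @param K neighbor budget per seed (>= 1).
#' @return a `GroupStructure`: named list (by seed gene) of member vectors,
#'   seed first, with attribute `K`.
#' @export
build_groups <- function(net, K) {
  if (nrow(net$edges) == 0) stop("empty network")
  if (K < 1) stop("K must be >= 1")
  e <- net$edges
  adj <- rbind(data.frame(from = e$gene_a, to = e$gene_b, w = e$weight),
               data.frame(from = e$gene_b, to = e$gene_a, w = e$weight))
  adj <- adj[order(adj$from, -adj$w, adj$to), ]
  by_seed <- split(adj$to, adj$from)
  groups <- lapply(names(by_seed), function(s)
    c(s, utils::head(by_seed[[s]], K)))
  names(groups) <- names(by_seed)
  structure(groups, K = K, class = c("GroupStructure", "list"))
}

# duplicated design: one column copy per (group, member); returns the
# expanded matrix plus bookkeeping for folding copies back onto genes
expand_groups <- function(X, groups) {
  members <- unlist(groups, use.names = FALSE)
  gidx <- rep(seq_along(groups), lengths(groups))
  missing <- setdiff(members, colnames(X))
  if (length(missing))
    stop("group members absent from feature matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  list(Xe = X[, members, drop = FALSE], member = members, group = gidx,
       sizes = lengths(groups))
}

logistic_loss <- function(eta, y) {
  # numerically stable mean of log(1 + exp(eta)) - y * eta
  mean(ifelse(eta > 0, eta + log1p(exp(-eta)), log1p(exp(eta))) - y * eta)
}

#' Overlapping group lasso (latent/duplication formulation)
#'
#' Logistic regression with the group penalty
#' `lambda * sum_g sqrt(|g|) * ||w_g||_2` after giving each group its own
#' copy of its member columns, so overlapping groups are handled exactly
#' (latent group lasso). Solved by proximal gradient (FISTA with
#' backtracking and adaptive restart) followed by a Newton polish on the
#' active groups. For singleton, non-overlapping groups the penalty
#' reduces to the L1 norm and the solution coincides with [train_lasso()].
#'
#' The per-gene effective weight is the sum over all copies of that gene;
#' the signature is the set of genes with non-zero effective weight.
#'
#' @param X samples x features matrix (training, z-scored).
#' @param y outcome (`good`/`poor` or 0/1 with 1 = poor).
#' @param groups a [build_groups()] result (or any named list of member
#'   vectors).
#' @param lambda group penalty.
#' @param tol relative objective-change tolerance.
#' @param max_iter FISTA iteration cap.
#' @return a `synet_model` (type `group_lasso`) with effective `weights`,
#'   `intercept`, `signature`, `selected_groups`, convergence diagnostics,
#'   and the per-copy solution.
#' @export
train_group_lasso <- function(X, y, groups, lambda, tol = 1e-9,
                              max_iter = 5000) {
  y01 <- as_poor01(y)
  if (length(unique(y01)) < 2) stop("outcome has no class variation")
  ex <- expand_groups(X, groups)
  Xe <- ex$Xe
  n <- nrow(Xe); pe <- ncol(Xe)
  gsize <- ex$sizes
  gof <- ex$group                       # group id per expanded column
  glam <- lambda * sqrt(gsize)          # per-group penalty scale

  pen <- function(w) {
    nrm <- sqrt(vapply(split(w^2, gof), sum, 0))
    sum(glam * nrm)
  }
  smooth <- function(w0, w) logistic_loss(w0 + drop(Xe %*% w), y01)
  grads <- function(w0, w) {
    eta <- w0 + drop(Xe %*% w)
    pr <- 1 / (1 + exp(-eta))
    r <- (pr - y01) / n
    list(g0 = sum(r), g = drop(crossprod(Xe, r)))
  }
  prox <- function(w, t) {
    nrm <- sqrt(vapply(split(w^2, gof), sum, 0))
    shrink <- pmax(0, 1 - t * glam / pmax(nrm, 1e-300))
    w * shrink[gof]
  }

  w <- numeric(pe); w0 <- stats::qlogis(max(min(mean(y01), 1 - 1e-6), 1e-6))
  v <- w; v0 <- w0
  t_prev <- 1
  L <- max(colSums(Xe^2)) / (4 * n) * pe + 1  # crude init; backtracking refines
  step <- 1 / L
  obj <- smooth(w0, w) + pen(w)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    gr <- grads(v0, v)
    repeat {
      w0_new <- v0 - step * gr$g0
      w_new <- prox(v - step * gr$g, step)
      f_new <- smooth(w0_new, w_new)
      dq <- sum((w_new - v)^2) + (w0_new - v0)^2
      f_maj <- smooth(v0, v) + gr$g0 * (w0_new - v0) +
        sum(gr$g * (w_new - v)) + dq / (2 * step)
      if (f_new <= f_maj + 1e-14) break
      step <- step / 2
    }
    obj_new <- f_new + pen(w_new)
    t_new <- (1 + sqrt(1 + 4 * t_prev^2)) / 2
    if (obj_new > obj) {            # adaptive restart
      v <- w; v0 <- w0; t_prev <- 1
    } else {
      v <- w_new + ((t_prev - 1) / t_new) * (w_new - w)
      v0 <- w0_new + ((t_prev - 1) / t_new) * (w0_new - w0)
      if (abs(obj - obj_new) < tol * max(1, abs(obj))) {
        w <- w_new; w0 <- w0_new; obj <- obj_new
        converged <- TRUE
        break
      }
      w <- w_new; w0 <- w0_new; obj <- obj_new
      t_prev <- t_new
    }
    step <- step * 1.1              # allow the step to grow back
  }
  polished <- gl_newton_polish(Xe, y01, gof, glam, w0, w)
  w0 <- polished$w0; w <- polished$w
  if (!converged)
    warning(sprintf("group lasso: FISTA stopped at max_iter=%d (rel dObj %.2e)",
                    max_iter, abs(obj - smooth(w0, w) - pen(w))))

  eff <- vapply(split(w, ex$member), sum, 0)
  eff <- eff[colnames(X)[colnames(X) %in% names(eff)]]
  nrm <- sqrt(vapply(split(w^2, gof), sum, 0))
  structure(list(type = "group_lasso", intercept = w0, weights = eff,
                 signature = names(eff)[abs(eff) > 1e-10],
                 selected_groups = names(groups)[nrm > 1e-10],
                 lambda = lambda, converged = converged,
                 copy_weights = w, copy_member = ex$member,
                 copy_group = gof),
            class = "synet_model")
}

# Newton refinement restricted to the active groups (the objective is
# smooth away from zero group norms); brings the solution to near machine
# precision so the singleton-group reduction matches the lasso oracle.
gl_newton_polish <- function(Xe, y01, gof, glam, w0, w, max_steps = 40) {
  n <- nrow(Xe)
  for (s in seq_len(max_steps)) {
    nrm <- sqrt(vapply(split(w^2, gof), sum, 0))
    act <- which(nrm[gof] > 1e-8)
    if (!length(act)) break
    Xa <- Xe[, act, drop = FALSE]
    wa <- w[act]
    eta <- w0 + drop(Xa %*% wa)
    pr <- 1 / (1 + exp(-eta))
    r <- (pr - y01) / n
    gpen <- glam[gof[act]] * wa / nrm[gof[act]]
    g <- c(sum(r), drop(crossprod(Xa, r)) + gpen)
    W <- pr * (1 - pr) / n
    H11 <- sum(W)
    H1a <- drop(crossprod(Xa, W))
    Haa <- crossprod(Xa, Xa * W)
    # penalty Hessian per active group: lam*sqrt|g| (I/||w|| - ww'/||w||^3)
    for (gid in unique(gof[act])) {
      cols <- which(gof[act] == gid)
      wg <- wa[cols]; ng <- nrm[gid]
      Haa[cols, cols] <- Haa[cols, cols] +
        glam[gid] * (diag(length(cols)) / ng - tcrossprod(wg) / ng^3)
    }
    H <- rbind(c(H11, H1a), cbind(H1a, Haa))
    gn <- sqrt(sum(g^2))
    if (gn < 1e-12) break
    d <- tryCatch(solve(H + diag(1e-12, nrow(H)), g), error = function(e) NULL)
    if (is.null(d)) break
    obj_at <- function(w0x, wax) {
      wx <- w; wx[act] <- wax
      nx <- sqrt(vapply(split(wx^2, gof), sum, 0))
      logistic_loss(w0x + drop(Xa %*% wax), y01) + sum(glam * nx)
    }
    cur <- obj_at(w0, wa)
    stepsize <- 1
    ok <- FALSE
    for (h in 1:30) {
      w0_try <- w0 - stepsize * d[1]
      wa_try <- wa - stepsize * d[-1]
      if (all(abs(wa_try) < Inf) && obj_at(w0_try, wa_try) <= cur) {
        ok <- TRUE; break
      }
      stepsize <- stepsize / 2
    }
    if (!ok) break
    w0 <- w0 - stepsize * d[1]
    w[act] <- wa - stepsize * d[-1]
    if (gn < 1e-10) break
  }
  list(w0 = w0, w = w)
}
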