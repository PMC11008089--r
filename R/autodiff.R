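# Minimal reverse-mode automatic differentiation at matrix granularity.
# Nodes are environments carrying a value, an accumulated gradient, parent
# links and a backward closure. Only the ops the VAE and the latent sampler
# need are implemented; gradients are validated against finite differences
# in the test suite.

ad_node <- function(value, parents = list(), backfn = NULL, needs_grad = FALSE) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$grad <- NULL
  e$parents <- parents
  e$backfn <- backfn
  e$needs_grad <- needs_grad ||
    any(vapply(parents, function(p) inherits(p, "ad") && p$needs_grad,
               logical(1)))
  class(e) <- "ad"
  e
}

ad_param <- function(value) ad_node(value, needs_grad = TRUE)
ad_const <- function(value) ad_node(value)

ad_value <- function(x) if (inherits(x, "ad")) x$value else x

ad_acc <- function(n, g) {
  if (!inherits(n, "ad") || !n$needs_grad) return(invisible(NULL))
  if (is.null(n$grad)) n$grad <- g else n$grad <- n$grad + g
  invisible(NULL)
}

# Reverse-mode sweep from a scalar root. Fills $grad on every needs_grad node.
ad_backprop <- function(root) {
  topo <- list()
  visit <- function(n) {
    if (isTRUE(n$.seen)) return(invisible(NULL))
    n$.seen <- TRUE
    for (p in n$parents) if (inherits(p, "ad")) visit(p)
    topo[[length(topo) + 1L]] <<- n
    invisible(NULL)
  }
  visit(root)
  for (n in topo) n$grad <- NULL
  root$grad <- 1
  for (k in rev(seq_along(topo))) {
    n <- topo[[k]]
    if (!is.null(n$backfn) && !is.null(n$grad)) n$backfn(n$grad)
    n$.seen <- NULL
  }
  invisible(root)
}

ad_matmul <- function(a, b) {
  av <- ad_value(a); bv <- ad_value(b)
  ad_node(av %*% bv, list(a, b), function(g) {
    if (inherits(a, "ad") && a$needs_grad) ad_acc(a, g %*% t(bv))
    if (inherits(b, "ad") && b$needs_grad) ad_acc(b, t(av) %*% g)
  })
}

ad_add <- function(a, b) {
  ad_node(ad_value(a) + ad_value(b), list(a, b), function(g) {
    ad_acc(a, g); ad_acc(b, g)
  })
}

ad_sub <- function(a, b) {
  ad_node(ad_value(a) - ad_value(b), list(a, b), function(g) {
    ad_acc(a, g); ad_acc(b, -g)
  })
}

# X (n x d) plus a length-d bias row, broadcast over rows.
ad_add_bias <- function(x, b) {
  xv <- ad_value(x); bv <- ad_value(b)
  ad_node(sweep(xv, 2, as.numeric(bv), "+"), list(x, b), function(g) {
    ad_acc(x, g)
    if (inherits(b, "ad") && b$needs_grad) ad_acc(b, colSums(g))
  })
}

ad_scale <- function(a, k) {
  ad_node(k * ad_value(a), list(a), function(g) ad_acc(a, k * g))
}

ad_mul_const <- function(a, m) {
  ad_node(ad_value(a) * m, list(a), function(g) ad_acc(a, g * m))
}

ad_exp <- function(a) {
  v <- exp(ad_value(a))
  ad_node(v, list(a), function(g) ad_acc(a, g * v))
}

ad_lrelu <- function(a, slope = 0.2) {
  av <- ad_value(a)
  f <- slope + (1 - slope) * (av > 0)
  ad_node(av * f, list(a), function(g) ad_acc(a, g * f))
}

ad_tanh <- function(a) {
  v <- tanh(ad_value(a))
  ad_node(v, list(a), function(g) ad_acc(a, g * (1 - v ^ 2)))
}

ad_clamp <- function(a, lo, hi) {
  av <- ad_value(a)
  inside <- (av >= lo) & (av <= hi)
  ad_node(pmin(pmax(av, lo), hi), list(a), function(g) ad_acc(a, g * inside))
}

ad_sum <- function(a) {
  av <- ad_value(a)
  ad_node(sum(av), list(a), function(g) {
    ad_acc(a, array(as.numeric(g), dim = dim(av) %||% length(av)))
  })
}

# Mean squared error against a target (constant or node); scalar node.
ad_mse <- function(a, target) {
  av <- ad_value(a); tv <- ad_value(target)
  diffv <- av - tv
  n <- length(diffv)
  ad_node(mean(diffv ^ 2), list(a, target), function(g) {
    gg <- as.numeric(g) * 2 * diffv / n
    ad_acc(a, gg)
    if (inherits(target, "ad")) ad_acc(target, -gg)
  })
}

# Weighted mean squared error: sum(w * (a - t)^2) / sum(w); w constant.
ad_wmse <- function(a, target, w) {
  av <- ad_value(a); tv <- ad_value(target)
  diffv <- av - tv
  sw <- sum(w)
  ad_node(sum(w * diffv ^ 2) / sw, list(a, target), function(g) {
    gg <- as.numeric(g) * 2 * w * diffv / sw
    ad_acc(a, gg)
    if (inherits(target, "ad")) ad_acc(target, -gg)
  })
}

# Diagonal-Gaussian KL(q(z|x) || N(0, I)), summed over latent dims, averaged
# over the batch (rows). mu, lv: n x d nodes.
ad_kl <- function(mu, lv) {
  muv <- ad_value(mu); lvv <- ad_value(lv)
  n <- nrow(muv)
  val <- 0.5 * sum(exp(lvv) + muv ^ 2 - 1 - lvv) / n
  ad_node(val, list(mu, lv), function(g) {
    s <- as.numeric(g) / n
    ad_acc(mu, s * muv)
    ad_acc(lv, s * 0.5 * (exp(lvv) - 1))
  })
}

ad_slice_cols <- function(a, idx) {
  av <- ad_value(a)
  ad_node(av[, idx, drop = FALSE], list(a), function(g) {
    G <- matrix(0, nrow(av), ncol(av))
    G[, idx] <- G[, idx] + g
    ad_acc(a, G)
  })
}

# Symmetrize flattened L x L pair columns: out = (x + x[, perm]) / 2 where
# perm is the (i,j) -> (j,i) column permutation (an involution).
ad_sym_cols <- function(a, perm) {
  av <- ad_value(a)
  ad_node((av + av[, perm, drop = FALSE]) / 2, list(a), function(g) {
    ad_acc(a, (g + g[, perm, drop = FALSE]) / 2)
  })
}

pair_transpose_perm <- function(L) {
  # column-major flattening of an L x L matrix: entry (i,j) at (j-1)*L + i
  idx <- expand.grid(i = seq_len(L), j = seq_len(L))
  (idx$i - 1L) * L + idx$j
}

# Fused min-over-references categorical cross-entropy of RBF-binned distances.
# dist: node, n x P matrix of distances (Angstrom), P = L^2 flattened pairs.
# refs: list of P x K reference probability matrices.
# Value: length-n vector of per-sample scores, min over references.
ad_cce_min <- function(dist, refs, centers, sigma, eps = 1e-8) {
  Dv <- ad_value(dist)
  n <- nrow(Dv); P <- ncol(Dv); K <- length(centers)
  A <- vector("list", K)
  for (k in seq_len(K)) A[[k]] <- -(Dv - centers[k]) ^ 2 / (2 * sigma ^ 2)
  M <- Reduce(pmax, A)
  S <- matrix(0, n, P)
  for (k in seq_len(K)) { A[[k]] <- exp(A[[k]] - M); S <- S + A[[k]] }
  for (k in seq_len(K)) A[[k]] <- A[[k]] / S   # now the soft-bin probabilities
  R <- length(refs)
  scores <- matrix(0, n, R)
  for (k in seq_len(K)) {
    lp <- log(A[[k]] + eps)
    for (r in seq_len(R)) scores[, r] <- scores[, r] - (lp %*% refs[[r]][, k]) / P
  }
  best <- max.col(-scores, ties.method = "first")
  val <- scores[cbind(seq_len(n), best)]
  ad_node(val, list(dist), function(g) {
    # Closed-form gradient. With t_k = y_k p_k / (p_k + eps), T = sum_k t_k,
    # cbar = sum_k p_k c_k:  dCCE/dD = (T * cbar - sum_k t_k c_k) / (P sigma^2).
    Tsum <- matrix(0, n, P)
    tc <- matrix(0, n, P)
    cbar <- matrix(0, n, P)
    for (k in seq_len(K)) {
      yk <- vapply(refs, function(y) y[, k], numeric(P))  # P x R
      Yk <- t(yk)[best, , drop = FALSE]                   # n x P (argmin ref)
      tk <- Yk * (A[[k]] / (A[[k]] + eps))
      Tsum <- Tsum + tk
      tc <- tc + tk * centers[k]
      cbar <- cbar + A[[k]] * centers[k]
    }
    gD <- (Tsum * cbar - tc) / (P * sigma ^ 2)
    ad_acc(dist, gD * as.numeric(g))
  })
}
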