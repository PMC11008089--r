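# latent_sampler: distograms, the CCE guidance score, and trust-region
# constrained gradient optimization in the trained latent space.

#' Default distance bin edges
#'
#' 36 half-Angstrom bins from 2 to 20 Angstrom plus one open last bin
#' (37 bins total). The open bin's RBF center sits half a bin width beyond
#' the last finite edge.
#'
#' @return numeric vector of 38 increasing edges (last is \code{Inf}).
#' @export
default_bin_edges <- function() c(seq(2, 20, by = 0.5), Inf)

bin_centers <- function(edges) {
  k <- length(edges) - 1
  ctr <- (edges[-1] + edges[-length(edges)]) / 2
  if (!is.finite(edges[length(edges)])) {
    w <- edges[k] - edges[k - 1]
    ctr[k] <- edges[k] + w / 2
  }
  ctr
}

#' Distogram constructor
#'
#' @param probs L x L x K array of bin probabilities (each (i,j) sums to 1).
#' @param bin_edges K+1 increasing distance edges (Angstrom).
#' @return a \code{distogram}.
#' @export
distogram <- function(probs, bin_edges) {
  stopifnot(length(dim(probs)) == 3, dim(probs)[1] == dim(probs)[2],
            length(bin_edges) == dim(probs)[3] + 1,
            all(diff(bin_edges) > 0))
  structure(list(L = dim(probs)[1], n_bins = dim(probs)[3], probs = probs,
                 bin_edges = bin_edges), class = "distogram")
}

#' @export
print.distogram <- function(x, ...) {
  cat(sprintf("<distogram> L=%d, %d bins [%.1f, %s] A\n", x$L, x$n_bins,
              x$bin_edges[1],
              if (is.finite(x$bin_edges[length(x$bin_edges)]))
                sprintf("%.1f", x$bin_edges[length(x$bin_edges)]) else "Inf"))
  invisible(x)
}

#' Soft (RBF) discretization of a distance matrix into a distogram
#'
#' \code{probs[i,j,k]} is proportional to
#' \code{exp(-(dist[i,j] - center_k)^2 / (2 sigma^2))}, normalized over bins;
#' smooth in the distances, which is what makes the CCE guidance score
#' differentiable.
#'
#' @param dist L x L distance matrix (Angstrom).
#' @param bin_edges increasing bin edges (default \code{\link{default_bin_edges}}).
#' @param sigma RBF width in Angstrom (default half the first bin width).
#' @return a \code{distogram}.
#' @export
soft_distogram <- function(dist, bin_edges = default_bin_edges(), sigma = NULL) {
  dist <- as.matrix(dist)
  if (is.null(sigma)) sigma <- (bin_edges[2] - bin_edges[1]) / 2
  stopifnot(sigma > 0)
  ctr <- bin_centers(bin_edges)
  L <- nrow(dist); K <- length(ctr)
  d <- as.numeric(dist)
  A <- outer(d, ctr, function(x, c) -(x - c) ^ 2 / (2 * sigma ^ 2))
  A <- A - apply(A, 1, max)
  E <- exp(A)
  p <- E / rowSums(E)
  distogram(array(p, c(L, L, K)), bin_edges)
}

# Flatten a distogram to a P x K matrix (P = L^2, column-major pairs).
distogram_matrix <- function(dg) matrix(dg$probs, dg$L * dg$L, dg$n_bins)

#' Categorical cross-entropy guidance score
#'
#' For each reference distogram r computes
#' \code{CCE_r = -(1/P) sum_ij sum_k y_r[i,j,k] log(yhat[i,j,k] + 1e-8)}
#' with \code{P = L^2}, and returns the minimum over references.
#'
#' @param generated a \code{distogram}.
#' @param references a \code{distogram} or list of them, with matching length
#'   and binning.
#' @return nonnegative scalar (the minimum CCE).
#' @export
cce <- function(generated, references) {
  if (inherits(references, "distogram")) references <- list(references)
  stopifnot(length(references) >= 1)
  eps <- 1e-8
  lg <- log(distogram_matrix(generated) + eps)
  vals <- vapply(references, function(r) {
    if (r$L != generated$L || r$n_bins != generated$n_bins ||
        !isTRUE(all.equal(r$bin_edges, generated$bin_edges)))
      stop("reference distogram binning does not match", call. = FALSE)
    -sum(distogram_matrix(r) * lg) / (generated$L ^ 2)
  }, numeric(1))
  min(vals)
}

#' Latent sampler configuration
#'
#' Defaults: 3000 samples, trust-region radius d_max = 10 (Euclidean distance
#' in the latent space), Adam optimization of the CCE score until
#' convergence (score change below \code{tol} over a \code{patience} window)
#' or \code{max_iters}.
#'
#' @param n_samples number of ensemble members to generate.
#' @param d_max trust-region radius around each prior draw.
#' @param max_iters maximum optimization iterations.
#' @param tol convergence tolerance on the best score.
#' @param patience convergence window (iterations).
#' @param lr Adam learning rate on the latent coordinates.
#' @param seed RNG seed.
#' @param rbf_sigma RBF width (Angstrom) for the generated soft distogram;
#'   default half the bin width.
#' @param diversity_tau diversity-filter threshold: a candidate whose decoded
#'   distance map lies within \code{diversity_tau} Angstrom RMS of an
#'   already-accepted sample is rejected.
#' @param retry_factor maximum total prior draws, as a multiple of
#'   \code{n_samples}, before returning a partial ensemble.
#' @param chunk_size samples optimized per batched chunk (memory knob).
#' @return a \code{sampler_config}.
#' @export
sampler_config <- function(n_samples = 3000, d_max = 10, max_iters = 500,
                           tol = 1e-5, patience = 20, lr = 0.05, seed = 1,
                           rbf_sigma = NULL, diversity_tau = 0.25,
                           retry_factor = 5, chunk_size = 100) {
  stopifnot(n_samples >= 0, d_max >= 0, max_iters >= 0, tol > 0, lr > 0)
  structure(as.list(environment()), class = "sampler_config")
}

#' Draw latent prior samples
#'
#' Independent standard-normal vectors (mean 0, standard deviation 1).
#'
#' @param n number of samples (0 gives an empty matrix).
#' @param dim latent dimensionality.
#' @param seed RNG seed.
#' @return n x dim numeric matrix.
#' @export
sample_prior <- function(n, dim, seed = NULL) {
  stopifnot(n >= 0, dim >= 1)
  if (!is.null(seed)) set.seed(seed)
  matrix(stats::rnorm(n * dim), n, dim)
}

# Build the decoded-distance node pipeline for a latent batch: decode,
# slice the distance channel, unscale, symmetrize. Returns the dist node.
decoded_dist_node <- function(model, z_node) {
  L <- model$arch$L; P <- L * L
  # only the distance channel is needed: slice the output head up front
  dec_dist <- model$dec
  dec_dist$W_out <- dec_dist$W_out[, seq_len(P), drop = FALSE]
  dec_dist$b_out <- dec_dist$b_out[seq_len(P)]
  decw <- wrap_params(dec_dist, FALSE)
  out <- ad_add_bias(dec_forward_ad(decw, z_node, model_activation(model)),
                     ad_const(model$x_center[seq_len(P)]))
  dsc <- ad_clamp(out, 0, 1)
  dist <- ad_scale(dsc, model$arch$cutoff)
  offdiag <- rep(1, P)
  offdiag[(seq_len(L) - 1L) * L + seq_len(L)] <- 0   # zero diagonal, as unembed does
  dist <- ad_mul_const(dist, matrix(offdiag, 1, P)[rep(1, nrow(ad_value(dist))), , drop = FALSE])
  ad_sym_cols(dist, pair_transpose_perm(L))
}

#' Trust-region constrained CCE optimization in the latent space
#'
#' Iterates: decode z, soft-discretize the CB distance channel, score by
#' minimum CCE against the references, and take an Adam gradient step on z.
#' After every step z is radially projected back onto the ball of radius
#' \code{d_max} around its starting point, so the returned point always
#' satisfies \code{||z* - z0|| <= d_max}. The iterate with the lowest score
#' seen is returned, guaranteeing final score <= initial score.
#'
#' @param model a trained \code{sivae_model}.
#' @param z0 a latent vector, or an n x latent_dim matrix to optimize a
#'   batch of samples jointly (rows are independent).
#' @param references list of reference \code{distogram}s (shared binning).
#' @param cfg a \code{\link{sampler_config}}.
#' @return list: \code{z} (same shape as \code{z0}; the best iterate),
#'   \code{score} (per-sample best score), \code{initial_score},
#'   \code{trace} (iterations x n score matrix), \code{iterations}.
#' @export
optimize_latent <- function(model, z0, references, cfg = sampler_config()) {
  if (inherits(references, "distogram")) references <- list(references)
  stopifnot(length(references) >= 1)
  single <- is.null(dim(z0))
  Z0 <- rbind(z0)
  n <- nrow(Z0)
  edges <- references[[1]]$bin_edges
  ctr <- bin_centers(edges)
  sigma <- cfg$rbf_sigma %||% ((edges[2] - edges[1]) / 2)
  refs <- lapply(references, distogram_matrix)
  eval_scores <- function(Z, with_grad = TRUE) {
    zn <- if (with_grad) ad_param(Z) else ad_const(Z)
    dist <- decoded_dist_node(model, zn)
    sc <- ad_cce_min(dist, refs, ctr, sigma)
    if (with_grad) {
      ad_backprop(ad_sum(sc))
      list(score = ad_value(sc), grad = zn$grad)
    } else list(score = ad_value(sc), grad = NULL)
  }
  project <- function(Z) {
    delta <- Z - Z0
    nr <- sqrt(rowSums(delta ^ 2))
    over <- nr > cfg$d_max
    if (any(over)) {
      f <- ifelse(over, ifelse(nr > 0, cfg$d_max / nr, 0), 1)
      Z <- Z0 + delta * f
    }
    Z
  }
  Z <- project(Z0)
  st <- list(m = Z * 0, v = Z * 0, t = 0L)
  init <- eval_scores(Z, with_grad = FALSE)$score
  if (any(!is.finite(init)))
    stop("non-finite CCE score at the starting point", call. = FALSE)
  best_z <- Z; best <- init
  trace <- matrix(NA_real_, 0, n)
  since_improve <- numeric(n)
  active <- rep(TRUE, n)
  cur <- init
  iters <- 0L
  while (iters < cfg$max_iters && any(active)) {
    iters <- iters + 1L
    idx <- which(active)
    ev <- eval_scores(Z[idx, , drop = FALSE])
    if (any(!is.finite(ev$score))) {
      warning("non-finite score during latent optimization; ",
              "returning best iterate so far", call. = FALSE)
      break
    }
    cur[idx] <- ev$score
    trace <- rbind(trace, cur)
    improved <- ev$score < best[idx] - cfg$tol
    upd <- idx[ev$score < best[idx]]
    if (length(upd)) {
      sel <- match(upd, idx)
      best_z[upd, ] <- Z[upd, , drop = FALSE]
      best[upd] <- ev$score[sel]
    }
    since_improve[idx] <- ifelse(improved, 0, since_improve[idx] + 1)
    frozen <- since_improve[idx] >= cfg$patience
    active[idx[frozen]] <- FALSE
    st$t <- st$t + 1L
    st$m[idx, ] <- 0.9 * st$m[idx, , drop = FALSE] + 0.1 * ev$grad
    st$v[idx, ] <- 0.999 * st$v[idx, , drop = FALSE] + 0.001 * ev$grad ^ 2
    mh <- st$m[idx, , drop = FALSE] / (1 - 0.9 ^ st$t)
    vh <- st$v[idx, , drop = FALSE] / (1 - 0.999 ^ st$t)
    Z[idx, ] <- Z[idx, , drop = FALSE] - cfg$lr * mh / (sqrt(vh) + 1e-8)
    Z <- project(Z)
  }
  fin <- eval_scores(Z, with_grad = FALSE)$score
  upd <- is.finite(fin) & fin < best
  if (any(upd)) {
    best_z[upd, ] <- Z[upd, , drop = FALSE]
    best[upd] <- fin[upd]
  }
  rownames(trace) <- NULL
  list(z = if (single) best_z[1, ] else best_z,
       score = if (single) best[1] else best,
       initial_score = if (single) init[1] else init,
       trace = trace, iterations = iters)
}

#' Generate a guided conformer ensemble
#'
#' Draws latent prior samples, optimizes each under the trust-region CCE
#' procedure, decodes the survivors to feature maps and applies the
#' diversity filter (reject candidates whose decoded distance map is within
#' \code{diversity_tau} Angstrom RMS of an accepted one). Additional prior
#' draws are made until \code{n_samples} pass the filter, up to
#' \code{retry_factor * n_samples} total draws; if the cap is exhausted a
#' partial ensemble is returned with a warning.
#'
#' @param model a trained \code{sivae_model}.
#' @param references list of reference \code{distogram}s.
#' @param cfg a \code{\link{sampler_config}}.
#' @return list: \code{features} (list of \code{template_features}),
#'   \code{provenance} (per-sample data.frame: initial/final score, latent
#'   displacement, iterations), \code{z0}, \code{z_star} (matrices),
#'   \code{traces} (list of score traces).
#' @export
generate_ensemble <- function(model, references, cfg = sampler_config()) {
  stopifnot(inherits(model, "sivae_model"))
  latent <- model$config$latent_dim
  set.seed(cfg$seed)
  accepted_feats <- list()
  accepted_dist <- list()
  prov <- list(); z0s <- list(); zss <- list(); traces <- list()
  drawn <- 0L
  cap <- max(cfg$n_samples, ceiling(cfg$retry_factor * max(1, cfg$n_samples)))
  while (length(accepted_feats) < cfg$n_samples && drawn < cap) {
    m <- min(cfg$chunk_size, cfg$n_samples - length(accepted_feats), cap - drawn)
    # keep drawing a full chunk so rejection does not stall progress
    m <- max(m, min(cfg$chunk_size, cap - drawn))
    Z0 <- matrix(stats::rnorm(m * latent), m, latent)
    drawn <- drawn + m
    opt <- optimize_latent(model, Z0, references, cfg)
    dec <- sivae_decode(model, opt$z, as_features = TRUE)
    if (inherits(dec, "template_features")) dec <- list(dec)
    for (i in seq_len(m)) {
      if (length(accepted_feats) >= cfg$n_samples) break
      f <- dec[[i]]
      dm <- f$dist
      dup <- FALSE
      for (ad_ in accepted_dist) {
        if (sqrt(mean((dm - ad_) ^ 2)) < cfg$diversity_tau) { dup <- TRUE; break }
      }
      if (dup) next
      k <- length(accepted_feats) + 1L
      accepted_feats[[k]] <- f
      accepted_dist[[k]] <- dm
      z0s[[k]] <- Z0[i, ]
      zss[[k]] <- rbind(opt$z)[i, ]
      traces[[k]] <- opt$trace[, i]
      prov[[k]] <- data.frame(sample = k,
                              initial_score = opt$initial_score[i],
                              final_score = opt$score[i],
                              latent_displacement = sqrt(sum((rbind(opt$z)[i, ] - Z0[i, ]) ^ 2)),
                              iterations = opt$iterations)
    }
  }
  if (length(accepted_feats) < cfg$n_samples)
    warning(sprintf("diversity-filter retry cap exhausted: returning %d of %d samples",
                    length(accepted_feats), cfg$n_samples), call. = FALSE)
  list(features = accepted_feats,
       provenance = do.call(rbind, prov) %||% data.frame(),
       z0 = do.call(rbind, z0s), z_star = do.call(rbind, zss),
       traces = traces)
}

#' Save / load reference distograms
#'
#' References are stored as one RDS container: list of prob arrays plus the
#' shared bin edges.
#'
#' @param references list of \code{distogram}s.
#' @param path file path.
#' @return \code{save_references} returns \code{path} invisibly;
#'   \code{load_references} the list of distograms.
#' @export
save_references <- function(references, path) {
  if (inherits(references, "distogram")) references <- list(references)
  saveRDS(list(probs = lapply(references, function(r) r$probs),
               bin_edges = references[[1]]$bin_edges), path)
  invisible(path)
}

#' @rdname save_references
#' @export
load_references <- function(path) {
  x <- readRDS(path)
  lapply(x$probs, distogram, bin_edges = x$bin_edges)
}
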