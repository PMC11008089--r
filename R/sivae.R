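# sivae: soft-introspective VAE over template feature maps.
#
# The encoder doubles as an implicit discriminator: it is trained to assign
# a high ELBO to real feature maps and an exponentially penalized ELBO to
# generated ones; the decoder is trained to fool it. Objectives follow the
# soft-introspective formulation with per-branch weights:
#
#   ELBO(x)      = -beta_rec * L_r(x) - beta_kl  * KL(q(z|x) || N(0,I))
#   ELBO_neg(x') = -beta_rec * L_r(x') - beta_neg * KL(q(z|x') || N(0,I))
#
#   encoder loss = -ELBO(x) + adv_weight * (1/s) * mean_f exp(s * ELBO_neg(x_f))
#   decoder loss =  beta_rec * L_r(x) + adv_weight * [ beta_kl/2 * (KL_rec + KL_prior)
#                   + gamma_r * beta_rec/2 * (L_r(x_rec') + L_r(x_prior')) ]
#
# where x_f are generated samples (reconstructions of the batch and decodes
# of prior draws), and the decoder's generated-sample terms are computed by
# re-encoding its own outputs through the frozen encoder. L_r is mean squared
# error over all feature channels; KL is the closed diagonal-Gaussian form,
# summed over latent dimensions and averaged over the batch.

#' Soft-introspective VAE configuration
#'
#' Defaults: latent dimension 256, 3 residual blocks of 64 features,
#' beta_rec 10, beta_kl 1e-3, beta_neg = latent dimension, sharpness s = 2,
#' gamma_r 1, Adam (0.9, 0.999) at learning rate 1e-3, batch size 64.
#'
#' @param latent_dim latent dimensionality.
#' @param n_resnet_blocks residual blocks in each network.
#' @param block_features trunk width (features per block).
#' @param beta_rec reconstruction weight.
#' @param beta_kl KL weight on real samples.
#' @param beta_neg KL weight on generated samples (default = latent_dim).
#' @param s sharpness of the exponentiated-ELBO repulsion term.
#' @param gamma_r weight of the generated-sample reconstruction terms in the
#'   decoder objective.
#' @param lr Adam learning rate.
#' @param adam_beta1,adam_beta2 Adam moment decay rates.
#' @param batch_size effective batch size.
#' @param epochs training epochs.
#' @param seed RNG seed for initialization and training.
#' @param weight_decay decoupled L2 weight decay (default 1e-5).
#' @param adv_weight weight of the adversarial branches (1 = full
#'   soft-introspective objective, 0 = plain VAE ELBO).
#' @param use_raw_angles if TRUE the angle channels enter the network as raw
#'   radians; default FALSE uses (sin, cos) pairs to remove the 2*pi
#'   wrap-around discontinuity.
#' @param mask_loss if TRUE the reconstruction loss is restricted to pairs
#'   inside the 20 Angstrom mask; default FALSE (all entries).
#' @param activation trunk activation, "lrelu" (default) or "tanh"; the
#'   smooth option interpolates curved conformational families better and is
#'   used by the toy benchmark.
#' @return a \code{sivae_config} list.
#' @export
sivae_config <- function(latent_dim = 256, n_resnet_blocks = 3,
                         block_features = 64, beta_rec = 10, beta_kl = 1e-3,
                         beta_neg = latent_dim, s = 2, gamma_r = 1.0,
                         lr = 1e-3, adam_beta1 = 0.9, adam_beta2 = 0.999,
                         batch_size = 64, epochs = 20, seed = 1,
                         weight_decay = 1e-5, adv_weight = 1,
                         use_raw_angles = FALSE, mask_loss = FALSE,
                         activation = c("lrelu", "tanh")) {
  activation <- match.arg(activation)
  stopifnot(latent_dim >= 1, beta_rec > 0, beta_kl > 0, beta_neg > 0, s > 0,
            batch_size >= 1, epochs >= 0)
  structure(as.list(environment()), class = "sivae_config")
}

n_feature_channels <- function(use_raw_angles) if (use_raw_angles) 4L else 7L

#' Embed a template feature map as a flat numeric vector
#'
#' Channel layout (column-major L x L blocks): scaled distance
#' (dist / cutoff), then either (sin, cos) pairs of omega/theta/phi
#' (default) or the three raw angle channels.
#'
#' @param f a \code{template_features} object.
#' @param use_raw_angles see \code{\link{sivae_config}}.
#' @return numeric vector of length \code{n_channels * L^2}.
#' @export
embed_features <- function(f, use_raw_angles = FALSE) {
  stopifnot(inherits(f, "template_features"))
  d <- as.numeric(f$dist) / f$cutoff
  if (use_raw_angles) {
    c(d, as.numeric(f$omega), as.numeric(f$theta), as.numeric(f$phi))
  } else {
    c(d, sin(f$omega), cos(f$omega), sin(f$theta), cos(f$theta),
      sin(f$phi), cos(f$phi))
  }
}

#' Invert \code{\link{embed_features}}
#'
#' Distances are unscaled and clamped to [0, cutoff]; angles are recovered by
#' atan2 from the (sin, cos) pairs. The distance and omega channels are
#' symmetrized; the mask is TRUE where the decoded distance lies strictly
#' inside the cutoff, with sentinel values on the remaining entries.
#'
#' @param v numeric vector from \code{embed_features} (or a decoder output).
#' @param L residue count.
#' @param cutoff distance cutoff in Angstrom.
#' @param sequence sequence string to attach.
#' @param use_raw_angles see \code{\link{sivae_config}}.
#' @return a \code{template_features} object.
#' @export
unembed_features <- function(v, L, cutoff = 20, sequence = NULL,
                             use_raw_angles = FALSE) {
  P <- L * L
  if (is.null(sequence)) sequence <- paste(rep("X", L), collapse = "")
  ch <- function(k) matrix(v[((k - 1) * P + 1):(k * P)], L, L)
  dist <- pmin(pmax(ch(1), 0), 1) * cutoff
  if (use_raw_angles) {
    omega <- wrap_angle(ch(2)); theta <- wrap_angle(ch(3))
    phi <- pmin(pmax(ch(4), 0), pi)
  } else {
    omega <- atan2(ch(2), ch(3))
    theta <- atan2(ch(4), ch(5))
    phi <- abs(atan2(ch(6), ch(7)))
  }
  dist <- (dist + t(dist)) / 2
  omega <- (omega + t(omega)) / 2
  diag(dist) <- 0
  mask <- dist < cutoff
  dist[!mask] <- cutoff
  omega[!mask] <- 0; theta[!mask] <- 0; phi[!mask] <- 0
  diag(omega) <- 0; diag(theta) <- 0; diag(phi) <- 0
  template_features(L, sequence, dist, omega, theta, phi, mask, cutoff)
}

wrap_angle <- function(a) {
  w <- (a + pi) %% (2 * pi) - pi
  w[w <= -pi + 1e-15] <- pi
  w
}

# Stack a list of template_features into an n x D matrix.
embed_dataset <- function(maps, use_raw_angles = FALSE) {
  L <- maps[[1]]$L
  if (!all(vapply(maps, function(m) m$L, integer(1)) == L))
    stop("dataset contains feature maps of inconsistent length", call. = FALSE)
  X <- t(vapply(maps, embed_features, numeric(n_feature_channels(use_raw_angles) * L * L),
                use_raw_angles = use_raw_angles))
  attr(X, "L") <- L
  attr(X, "cutoff") <- maps[[1]]$cutoff
  attr(X, "sequence") <- maps[[1]]$sequence
  X
}

#' Create an untrained soft-introspective VAE
#'
#' @param config a \code{\link{sivae_config}}.
#' @param L residue count of the feature maps the model consumes.
#' @param cutoff feature-map distance cutoff (Angstrom).
#' @param sequence sequence string attached to decoded maps.
#' @return a \code{sivae_model}.
#' @export
sivae_new <- function(config, L, cutoff = 20, sequence = NULL) {
  stopifnot(inherits(config, "sivae_config"))
  D <- n_feature_channels(config$use_raw_angles) * L * L
  set.seed(config$seed)
  enc <- nn_init_encoder(D, config$block_features, config$n_resnet_blocks,
                         config$latent_dim)
  dec <- nn_init_decoder(D, config$block_features, config$n_resnet_blocks,
                         config$latent_dim)
  structure(list(enc = enc, dec = dec, config = config,
                 arch = list(D = D, L = L, cutoff = cutoff,
                             n_channels = n_feature_channels(config$use_raw_angles)),
                 sequence = sequence %||% paste(rep("X", L), collapse = ""),
                 x_center = numeric(D),
                 opt_e = adam_new(enc), opt_d = adam_new(dec),
                 log = data.frame(), trained_epochs = 0L),
            class = "sivae_model")
}

#' @export
print.sivae_model <- function(x, ...) {
  cat(sprintf("<sivae_model> L=%d, latent=%d, %d epoch(s) trained\n",
              x$arch$L, x$config$latent_dim, x$trained_epochs))
  invisible(x)
}

as_embedded_matrix <- function(model, x) {
  if (inherits(x, "template_features")) x <- list(x)
  if (is.list(x)) x <- embed_dataset(x, model$config$use_raw_angles)
  x <- rbind(x)
  if (ncol(x) != model$arch$D)
    stop("feature map length does not match the model's trained length",
         call. = FALSE)
  x
}

#' Encode feature maps to the latent posterior
#'
#' Deterministic in evaluation: returns the posterior mean and log-variance.
#'
#' @param model a trained (or untrained) \code{sivae_model}.
#' @param x a \code{template_features}, a list of them, or an embedded matrix.
#' @return list with \code{mu} and \code{logvar} (n x latent_dim matrices).
#' @export
sivae_encode <- function(model, x) {
  X <- sweep(as_embedded_matrix(model, x), 2, model$x_center)
  out <- enc_forward_plain(model$enc, X, model_activation(model))
  list(mu = out$mu, logvar = out$lv)
}

#' Decode latent points to feature maps
#'
#' @param model a \code{sivae_model}.
#' @param z latent vector or n x latent_dim matrix.
#' @param as_features if TRUE (default) returns \code{template_features}
#'   objects (a single one for a vector input); otherwise the raw embedded
#'   matrix.
#' @return feature map(s) or an embedded matrix.
#' @export
sivae_decode <- function(model, z, as_features = TRUE) {
  z <- rbind(z)
  if (ncol(z) != model$config$latent_dim) stop("latent dimension mismatch", call. = FALSE)
  out <- sweep(dec_forward_plain(model$dec, z, model_activation(model)), 2,
               model$x_center, "+")
  if (!as_features) return(out)
  maps <- lapply(seq_len(nrow(out)), function(i)
    unembed_features(out[i, ], model$arch$L, model$arch$cutoff,
                     model$sequence, model$config$use_raw_angles))
  if (nrow(out) == 1) maps[[1]] else maps
}

#' Reparameterization draw
#'
#' \code{z = mu + exp(logvar / 2) * eps}, \code{eps ~ N(0, I)}.
#'
#' @param mu,logvar numeric vectors or matrices of equal shape.
#' @param seed optional RNG seed for reproducibility.
#' @return draw with the shape of \code{mu}.
#' @export
reparameterize <- function(mu, logvar, seed = NULL) {
  stopifnot(length(mu) == length(logvar))
  if (!is.null(seed)) set.seed(seed)
  eps <- stats::rnorm(length(mu))
  dim(eps) <- dim(mu)
  mu + exp(0.5 * logvar) * eps
}

#' Closed-form diagonal-Gaussian KL divergence
#'
#' KL(N(mu, diag(exp(logvar))) || N(0, I)), summed over dimensions. For
#' matrix inputs rows are independent samples and the mean over rows is
#' returned.
#'
#' @param mu,logvar numeric vectors or matrices.
#' @return nonnegative scalar.
#' @export
kl_divergence <- function(mu, logvar) {
  n <- if (is.matrix(mu)) nrow(mu) else 1
  0.5 * sum(exp(logvar) + mu ^ 2 - 1 - logvar) / n
}

#' Reconstruction loss (mean squared error over feature channels)
#'
#' Operates on the embedded representation (scaled distances plus sin/cos
#' angle pairs by default): the mean of squared differences over all entries
#' of all channels.
#'
#' @param x,x_hat feature maps (\code{template_features}) or embedded
#'   numeric vectors/matrices of equal shape.
#' @param use_raw_angles embedding flag (used only when feature maps are
#'   passed).
#' @return nonnegative scalar.
#' @export
reconstruction_loss <- function(x, x_hat, use_raw_angles = FALSE) {
  if (inherits(x, "template_features")) x <- embed_features(x, use_raw_angles)
  if (inherits(x_hat, "template_features")) x_hat <- embed_features(x_hat, use_raw_angles)
  if (length(x) != length(x_hat)) stop("shape mismatch", call. = FALSE)
  mean((x - x_hat) ^ 2)
}

#' Evidence lower bound of a feature map under the model
#'
#' \code{-beta_rec * L_r(x) - beta_kl * KL}; the reconstruction uses one
#' reparameterized draw. Higher is better.
#'
#' @param model a \code{sivae_model}.
#' @param x feature map or embedded vector/matrix.
#' @param seed optional RNG seed for the reparameterization draw.
#' @return scalar ELBO value.
#' @export
elbo <- function(model, x, seed = NULL) {
  cfg <- model$config
  X <- sweep(as_embedded_matrix(model, x), 2, model$x_center)
  act <- model_activation(model)
  e <- enc_forward_plain(model$enc, X, act)
  z <- reparameterize(e$mu, e$lv, seed = seed)
  xr <- dec_forward_plain(model$dec, z, act)
  -cfg$beta_rec * mean((xr - X) ^ 2) - cfg$beta_kl * kl_divergence(e$mu, e$lv)
}

ad_reparam <- function(mu, lv, eps) {
  ad_add(mu, ad_mul_const(ad_exp(ad_scale(lv, 0.5)), eps))
}

model_activation <- function(model) model$config$activation %||% "lrelu"

# Per-entry reconstruction weights for mask_loss: entries of pairs whose
# (scaled) distance sits at the sentinel are excluded from the loss. X must
# be uncentered; channels share a pair's weight.
mask_weights <- function(X, n_channels) {
  P <- ncol(X) / n_channels
  wd <- (X[, seq_len(P), drop = FALSE] < 1 - 1e-9) * 1
  do.call(cbind, rep(list(wd), n_channels))
}

# negative ELBO node: beta_rec * L_r + beta_kl_like * KL
neg_elbo_node <- function(encw, decw, Xc, eps, beta_rec, beta_kl_like,
                          activation = "lrelu", w = NULL) {
  e <- enc_forward_ad(encw, Xc, activation)
  z <- ad_reparam(e$mu, e$lv, eps)
  xr <- dec_forward_ad(decw, z, activation)
  Lr <- if (is.null(w)) ad_mse(xr, Xc) else ad_wmse(xr, Xc, w)
  KL <- ad_kl(e$mu, e$lv)
  list(node = ad_add(ad_scale(Lr, beta_rec), ad_scale(KL, beta_kl_like)),
       recon = ad_value(Lr), kl = ad_value(KL))
}

#' One encoder update (soft-introspective objective)
#'
#' Maximizes the ELBO of the real batch while softly repelling generated
#' samples (reconstructions of the batch and prior decodes) through the
#' exponentiated negative-sample ELBO with sharpness \code{s} and KL weight
#' \code{beta_neg}. Only encoder parameters are updated, via the encoder's
#' dedicated Adam optimizer.
#'
#' @param model a \code{sivae_model}.
#' @param X embedded batch matrix (rows = samples).
#' @return list: updated \code{model}, scalar \code{loss}, diagnostics
#'   \code{recon} and \code{kl}.
#' @export
encoder_step <- function(model, X) {
  cfg <- model$config
  X <- sweep(rbind(X), 2, model$x_center)
  if (nrow(X) == 0) stop("empty batch", call. = FALSE)
  n <- nrow(X); latent <- cfg$latent_dim
  encw <- wrap_params(model$enc, TRUE)
  decw <- wrap_params(model$dec, FALSE)
  act <- model_activation(model)
  w_real <- if (cfg$mask_loss)
    mask_weights(sweep(X, 2, model$x_center, "+"), model$arch$n_channels)
  else NULL
  eps1 <- matrix(stats::rnorm(n * latent), n, latent)
  real <- neg_elbo_node(encw, decw, ad_const(X), eps1, cfg$beta_rec, cfg$beta_kl,
                        act, w_real)
  loss <- real$node
  if (cfg$adv_weight > 0) {
    e <- enc_forward_plain(model$enc, X, act)
    z_det <- e$mu + exp(0.5 * e$lv) * matrix(stats::rnorm(n * latent), n, latent)
    fakes <- list(dec_forward_plain(model$dec, z_det, act),
                  dec_forward_plain(model$dec,
                                    matrix(stats::rnorm(n * latent), n, latent), act))
    for (xf in fakes) {
      epsf <- matrix(stats::rnorm(n * latent), n, latent)
      nf <- neg_elbo_node(encw, decw, ad_const(xf), epsf, cfg$beta_rec,
                          cfg$beta_neg, act)
      # (1/s) exp(s * ELBO_neg) = (1/s) exp(-s * neg_elbo)
      expf <- ad_scale(ad_exp(ad_scale(nf$node, -cfg$s)), 1 / cfg$s)
      loss <- ad_add(loss, ad_scale(expf, cfg$adv_weight * 0.5))
    }
  }
  ad_backprop(loss)
  grads <- extract_grads(encw)
  st <- adam_step(model$enc, grads, model$opt_e, cfg$lr, cfg$adam_beta1,
                  cfg$adam_beta2, cfg$weight_decay)
  model$enc <- st$params
  model$opt_e <- st$state
  list(model = model, loss = ad_value(loss), recon = real$recon, kl = real$kl)
}

#' One decoder update (soft-introspective objective)
#'
#' Minimizes the real-batch reconstruction error while maximizing the ELBO
#' that the frozen encoder assigns to generated samples (reconstructions and
#' prior decodes re-encoded through the encoder), with weight \code{gamma_r}
#' on the generated-sample reconstruction terms. Only decoder parameters are
#' updated, via the decoder's dedicated Adam optimizer.
#'
#' @inheritParams encoder_step
#' @return list: updated \code{model}, scalar \code{loss}, diagnostics
#'   \code{recon}.
#' @export
decoder_step <- function(model, X) {
  cfg <- model$config
  X <- sweep(rbind(X), 2, model$x_center)
  if (nrow(X) == 0) stop("empty batch", call. = FALSE)
  n <- nrow(X); latent <- cfg$latent_dim
  act <- model_activation(model)
  encw <- wrap_params(model$enc, FALSE)
  decw <- wrap_params(model$dec, TRUE)
  e <- enc_forward_plain(model$enc, X, act)
  z <- e$mu + exp(0.5 * e$lv) * matrix(stats::rnorm(n * latent), n, latent)
  xr <- dec_forward_ad(decw, ad_const(z), act)
  w_real <- if (cfg$mask_loss)
    mask_weights(sweep(X, 2, model$x_center, "+"), model$arch$n_channels)
  else NULL
  Lr_real <- if (is.null(w_real)) ad_mse(xr, ad_const(X))
             else ad_wmse(xr, ad_const(X), w_real)
  loss <- ad_scale(Lr_real, cfg$beta_rec)
  if (cfg$adv_weight > 0) {
    zp <- matrix(stats::rnorm(n * latent), n, latent)
    xp <- dec_forward_ad(decw, ad_const(zp), act)
    for (xf in list(xr, xp)) {
      ef <- enc_forward_ad(encw, xf, act)  # gradient flows back into decoder
      zf <- ad_reparam(ef$mu, ef$lv,
                       matrix(stats::rnorm(n * latent), n, latent))
      xff <- dec_forward_ad(decw, zf, act)
      Lrf <- ad_mse(xff, ad_const(ad_value(xf)))   # target detached
      KLf <- ad_kl(ef$mu, ef$lv)
      loss <- ad_add(loss, ad_scale(KLf, cfg$adv_weight * 0.5 * cfg$beta_kl))
      loss <- ad_add(loss, ad_scale(Lrf, cfg$adv_weight * 0.5 * cfg$gamma_r * cfg$beta_rec))
    }
  }
  ad_backprop(loss)
  grads <- extract_grads(decw)
  st <- adam_step(model$dec, grads, model$opt_d, cfg$lr, cfg$adam_beta1,
                  cfg$adam_beta2, cfg$weight_decay)
  model$dec <- st$params
  model$opt_d <- st$state
  list(model = model, loss = ad_value(loss), recon = ad_value(Lr_real))
}

#' Train a soft-introspective VAE
#'
#' Alternates encoder and decoder updates over shuffled mini-batches for the
#' configured number of epochs. Fully reproducible given the config seed.
#'
#' @param config a \code{\link{sivae_config}}.
#' @param dataset list of \code{template_features} (uniform length) or an
#'   embedded matrix from \code{embed_dataset}.
#' @param cutoff feature cutoff (used when an embedded matrix lacks it).
#' @param verbose print per-epoch losses.
#' @return a trained \code{sivae_model} with a per-epoch \code{log}
#'   (reconstruction loss, KL, encoder loss, decoder loss).
#' @export
sivae_train <- function(config, dataset, cutoff = 20, verbose = FALSE) {
  stopifnot(inherits(config, "sivae_config"))
  if (is.list(dataset) && !is.matrix(dataset))
    dataset <- embed_dataset(dataset, config$use_raw_angles)
  n <- nrow(dataset)
  if (n == 0) stop("empty dataset", call. = FALSE)
  P <- ncol(dataset) / n_feature_channels(config$use_raw_angles)
  L <- attr(dataset, "L") %||% as.integer(round(sqrt(P)))
  model <- sivae_new(config, L, attr(dataset, "cutoff") %||% cutoff,
                     attr(dataset, "sequence"))
  model$x_center <- colMeans(dataset)
  if (config$epochs == 0) return(model)
  set.seed(config$seed)
  logs <- vector("list", config$epochs)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    starts <- seq(1, n, by = config$batch_size)
    acc <- c(recon = 0, kl = 0, loss_e = 0, loss_d = 0)
    for (s0 in starts) {
      idx <- ord[s0:min(s0 + config$batch_size - 1, n)]
      B <- dataset[idx, , drop = FALSE]
      se <- encoder_step(model, B)
      model <- se$model
      sd_ <- decoder_step(model, B)
      model <- sd_$model
      acc <- acc + c(se$recon, se$kl, se$loss, sd_$loss)
    }
    acc <- acc / length(starts)
    logs[[ep]] <- data.frame(epoch = ep, recon = acc[1], kl = acc[2],
                             loss_encoder = acc[3], loss_decoder = acc[4])
    if (verbose)
      message(sprintf("epoch %3d | recon %.5f | kl %8.2f | encL %.4f | decL %.4f",
                      ep, acc[1], acc[2], acc[3], acc[4]))
  }
  model$log <- do.call(rbind, logs)
  rownames(model$log) <- NULL
  model$trained_epochs <- config$epochs
  model
}

#' Save / load a model checkpoint
#'
#' A checkpoint is one RDS archive holding both parameter sets, the config,
#' the optimizer states and the training log.
#'
#' @param model a \code{sivae_model}.
#' @param path file path.
#' @return \code{sivae_save} returns \code{path} invisibly; \code{sivae_load}
#'   the model.
#' @export
sivae_save <- function(model, path) {
  stopifnot(inherits(model, "sivae_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname sivae_save
#' @export
sivae_load <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "sivae_model"))
  m
}
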