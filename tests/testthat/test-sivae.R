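test_that("configuration defaults match the published training setup", {
  cfg <- sivae_config()
  expect_equal(cfg$latent_dim, 256)
  expect_equal(cfg$n_resnet_blocks, 3)
  expect_equal(cfg$block_features, 64)
  expect_equal(cfg$beta_rec, 10)
  expect_equal(cfg$beta_kl, 1e-3)
  expect_equal(cfg$beta_neg, 256)
  expect_equal(cfg$s, 2)
  expect_equal(cfg$gamma_r, 1.0)
  expect_equal(cfg$lr, 1e-3)
  expect_equal(cfg$adam_beta1, 0.9)
  expect_equal(cfg$adam_beta2, 0.999)
  expect_equal(cfg$batch_size, 64)
})

test_that("reparameterize: zero-noise limit, reproducibility, variance", {
  mu <- rnorm(8)
  expect_equal(reparameterize(mu, rep(-50, 8), seed = 1), mu,
               tolerance = 1e-10)
  z1 <- reparameterize(mu, rep(0, 8), seed = 42)
  z2 <- reparameterize(mu, rep(0, 8), seed = 42)
  expect_identical(z1, z2)
  draws <- reparameterize(matrix(0, 1e5, 1), matrix(0, 1e5, 1), seed = 7)
  expect_lt(abs(var(as.numeric(draws)) - 1), 0.03)
  expect_lt(abs(mean(draws)), 0.02)
})

test_that("reconstruction loss: zero, single-cell closed form, oracle", {
  f <- coords_to_features(random_backbone(12, seed = 5))
  expect_equal(reconstruction_loss(f, f), 0)
  x <- embed_features(f)
  x_hat <- x
  delta <- 0.37
  x_hat[5] <- x_hat[5] + delta
  expect_equal(reconstruction_loss(x, x_hat), delta^2 / length(x),
               tolerance = 1e-12)
  set.seed(6)
  y <- x + rnorm(length(x), sd = 0.1)
  # brute-force elementwise oracle
  oracle <- sum(vapply(seq_along(x), function(i) (x[i] - y[i])^2, numeric(1))) /
    length(x)
  expect_equal(reconstruction_loss(x, y), oracle, tolerance = 1e-12)
  expect_error(reconstruction_loss(x, y[-1]), "mismatch")
})

test_that("closed-form KL matches numerical quadrature on a 2-dim toy", {
  mu <- c(0.4, -1.1); lv <- c(0.3, -0.8)
  kl_1d <- function(m, s2) {
    f <- function(x) {
      q <- dnorm(x, m, sqrt(s2))
      lr <- dnorm(x, m, sqrt(s2), log = TRUE) - dnorm(x, 0, 1, log = TRUE)
      q * lr
    }
    integrate(f, m - 12 * sqrt(s2), m + 12 * sqrt(s2),
              rel.tol = 1e-10)$value
  }
  ref <- kl_1d(mu[1], exp(lv[1])) + kl_1d(mu[2], exp(lv[2]))
  expect_equal(kl_divergence(mu, lv), ref, tolerance = 1e-4)
  # standard-normal posterior has zero KL
  expect_equal(kl_divergence(c(0, 0), c(0, 0)), 0)
})

test_that("elbo: standard-normal posterior reduces to reconstruction term", {
  fx <- tiny_two_state()
  model <- sivae_new(fx$cfg, L = 24)
  # force a posterior at exactly N(0, I): zero weights/bias on both heads
  model$enc$W_mu[] <- 0; model$enc$b_mu[] <- 0
  model$enc$W_lv[] <- 0; model$enc$b_lv[] <- 0
  x <- embed_features(fx$maps[[1]])
  set.seed(9)
  e <- elbo(model, fx$maps[[1]], seed = 11)
  z <- reparameterize(rep(0, 16), rep(0, 16), seed = 11)
  xr <- sivae_decode(model, z, as_features = FALSE)
  expect_equal(e, -fx$cfg$beta_rec * mean((xr - rbind(x))^2), tolerance = 1e-9)
  # elbo decreases when reconstruction worsens, all else fixed
  model2 <- model
  model2$dec$b_out <- model2$dec$b_out + 1   # ruin the reconstruction
  expect_lt(elbo(model2, fx$maps[[1]], seed = 11),
            elbo(model, fx$maps[[1]], seed = 11))
})

test_that("encode is deterministic and shape-checked", {
  fx <- tiny_two_state()
  e1 <- sivae_encode(fx$model, fx$maps[[1]])
  e2 <- sivae_encode(fx$model, fx$maps[[1]])
  expect_identical(e1, e2)
  expect_true(all(is.finite(e1$mu)))
  expect_true(all(is.finite(e1$logvar)))
  short <- coords_to_features(make_toy_crystal(10, 5))
  expect_error(sivae_encode(fx$model, short), "length")
  # untrained model smoke
  m0 <- sivae_new(fx$cfg, L = 24)
  expect_true(all(is.finite(sivae_encode(m0, fx$maps[[1]])$mu)))
})

test_that("optimizer separation: each step touches only its own network", {
  fx <- tiny_two_state()
  X <- confvae:::embed_dataset(fx$maps[1:8])
  m <- sivae_new(fx$cfg, L = 24)
  set.seed(1)
  se <- encoder_step(m, X)
  expect_identical(unlist(se$model$dec), unlist(m$dec))   # decoder untouched
  expect_false(identical(unlist(se$model$enc), unlist(m$enc)))
  expect_true(is.finite(se$loss))
  set.seed(2)
  sd_ <- decoder_step(m, X)
  expect_identical(unlist(sd_$model$enc), unlist(m$enc))  # encoder untouched
  expect_false(identical(unlist(sd_$model$dec), unlist(m$dec)))
  expect_true(is.finite(sd_$loss))
  expect_error(encoder_step(m, X[0, , drop = FALSE]), "empty")
})

test_that("with the adversarial branch off, the encoder gradient is the plain negative-ELBO gradient", {
  fx <- tiny_two_state()
  cfg0 <- fx$cfg
  cfg0$adv_weight <- 0
  cfg0$weight_decay <- 0
  m <- sivae_new(cfg0, L = 24)
  X <- confvae:::embed_dataset(fx$maps[1:4])
  Xc <- sweep(X, 2, m$x_center)
  n <- nrow(Xc); lat <- cfg0$latent_dim
  # gradient taken by encoder_step (recover it from the Adam state: first
  # step has m_t = (1-beta1) * g)
  set.seed(123)
  se <- encoder_step(m, X)
  g_step <- rapply(se$model$opt_e$m, function(x) x / (1 - 0.9), how = "unlist")
  # oracle: gradient of beta_rec * L_r + beta_kl * KL built independently
  set.seed(123)
  eps <- matrix(rnorm(n * lat), n, lat)
  ew <- confvae:::wrap_params(m$enc, TRUE)
  dw <- confvae:::wrap_params(m$dec, FALSE)
  e <- confvae:::enc_forward_ad(ew, confvae:::ad_const(Xc))
  z <- confvae:::ad_reparam(e$mu, e$lv, eps)
  xr <- confvae:::dec_forward_ad(dw, z)
  node <- confvae:::ad_add(
    confvae:::ad_scale(confvae:::ad_mse(xr, confvae:::ad_const(Xc)), cfg0$beta_rec),
    confvae:::ad_scale(confvae:::ad_kl(e$mu, e$lv), cfg0$beta_kl))
  confvae:::ad_backprop(node)
  g_ref <- rapply(confvae:::extract_grads(ew), identity, how = "unlist")
  expect_lt(max(abs(g_step - g_ref)), 1e-10)
})

test_that("a 1-sample dataset is overfit within 200 alternating steps", {
  f <- coords_to_features(make_toy_crystal(12, 20))
  cfg <- sivae_config(latent_dim = 8, block_features = 16, n_resnet_blocks = 1,
                      batch_size = 1, epochs = 0, seed = 5, lr = 0.01,
                      beta_neg = 8)
  X <- confvae:::embed_dataset(list(f, f))  # duplicated single sample
  m <- sivae_train(cfg, X)                  # untrained (epochs = 0)
  m$x_center[] <- 0                         # learn the raw features directly
  set.seed(99)
  recon0 <- NULL
  for (step in 1:200) {
    se <- encoder_step(m, X)
    m <- se$model
    if (step == 1) recon0 <- se$recon
    m <- decoder_step(m, X)$model
  }
  recon_final <- encoder_step(m, X)$recon
  expect_lt(recon_final, 0.5 * recon0)
})

test_that("training is reproducible and epochs=0 returns an untrained model", {
  fx <- tiny_two_state()
  cfg <- sivae_config(latent_dim = 8, block_features = 16, n_resnet_blocks = 1,
                      batch_size = 16, epochs = 3, seed = 13, lr = 2e-3,
                      beta_neg = 8)
  m1 <- sivae_train(cfg, fx$maps[1:20])
  m2 <- sivae_train(cfg, fx$maps[1:20])
  expect_identical(m1$log, m2$log)
  expect_identical(unlist(m1$enc), unlist(m2$enc))
  cfg0 <- cfg; cfg0$epochs <- 0L
  m0 <- sivae_train(cfg0, fx$maps[1:20])
  expect_equal(m0$trained_epochs, 0L)
  expect_equal(nrow(m0$log), 0L)
})

test_that("training rejects inconsistent lengths and empty datasets", {
  fx <- tiny_two_state()
  bad <- c(fx$maps[1:2], list(coords_to_features(make_toy_crystal(10, 0))))
  expect_error(sivae_train(fx$cfg, bad), "inconsistent")
})

test_that("the trained model separates the two conformational clusters", {
  fx <- tiny_two_state()
  n1 <- 30
  maps1 <- fx$maps[1:n1]; maps2 <- fx$maps[(n1 + 1):(2 * n1)]
  X1 <- confvae:::embed_dataset(maps1); X2 <- confvae:::embed_dataset(maps2)
  c1 <- colMeans(X1); c2 <- colMeans(X2)
  # reconstructions land nearer their own cluster centroid
  own <- other <- 0
  for (i in c(1, 8, 15)) {
    mu <- sivae_encode(fx$model, maps1[[i]])$mu
    xr <- sivae_decode(fx$model, mu[1, ], as_features = FALSE)
    own <- own + mean((xr - rbind(c1))^2)
    other <- other + mean((xr - rbind(c2))^2)
    mu <- sivae_encode(fx$model, maps2[[i]])$mu
    xr <- sivae_decode(fx$model, mu[1, ], as_features = FALSE)
    own <- own + mean((xr - rbind(c2))^2)
    other <- other + mean((xr - rbind(c1))^2)
  }
  expect_lt(own, other)
  # encoder means: within-cluster spread smaller than between-cluster distance
  mus1 <- sivae_encode(fx$model, maps1)$mu
  mus2 <- sivae_encode(fx$model, maps2)$mu
  between <- sqrt(sum((colMeans(mus1) - colMeans(mus2))^2))
  within <- mean(sqrt(rowSums(sweep(mus1, 2, colMeans(mus1))^2)))
  expect_lt(within, between)
})

test_that("reconstruction error on held-in data beats the between-state gap", {
  fx <- tiny_two_state()
  s1 <- fx$ens$snapshots[[1]][[3]]
  f1 <- coords_to_features(s1)
  mu <- sivae_encode(fx$model, f1)$mu
  rec <- sivae_decode(fx$model, mu[1, ])
  rec_rms <- sqrt(mean((rec$dist - f1$dist)^2))
  d1 <- coords_to_features(fx$ens$crystals[[1]])$dist
  d2 <- coords_to_features(fx$ens$crystals[[2]])$dist
  between_rms <- sqrt(mean((d1 - d2)^2))
  expect_lt(rec_rms, between_rms)
})

test_that("checkpoints round-trip through disk", {
  fx <- tiny_two_state()
  path <- tempfile(fileext = ".rds")
  sivae_save(fx$model, path)
  m2 <- sivae_load(path)
  expect_identical(unlist(m2$enc), unlist(fx$model$enc))
  expect_identical(m2$config, fx$model$config)
})
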