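test_that("sampler defaults match the published sampling protocol", {
  cfg <- sampler_config()
  expect_equal(cfg$n_samples, 3000)
  expect_equal(cfg$d_max, 10)
})

test_that("sample_prior: reproducibility, moments, empty case", {
  z1 <- sample_prior(10, 4, seed = 3)
  z2 <- sample_prior(10, 4, seed = 3)
  expect_identical(z1, z2)
  z0 <- sample_prior(0, 4, seed = 1)
  expect_equal(nrow(z0), 0L)
  big <- sample_prior(1e5, 4, seed = 9)
  expect_true(all(abs(colMeans(big)) < 0.02))
  expect_true(all(abs(apply(big, 2, var) - 1) < 0.03))
})

test_that("soft_distogram: normalization, delta limit, oracle", {
  set.seed(41)
  L <- 5
  d <- matrix(runif(L * L, 3, 18), L, L)
  d <- (d + t(d)) / 2; diag(d) <- 0
  dg <- soft_distogram(d)
  expect_s3_class(dg, "distogram")
  sums <- apply(dg$probs, c(1, 2), sum)
  expect_true(all(abs(sums - 1) < 1e-6))
  # symmetric input -> symmetric probabilities
  expect_equal(dg$probs, aperm(dg$probs, c(2, 1, 3)), tolerance = 1e-12)
  # delta limit: sigma -> 0 concentrates all mass at the center's bin
  ctr <- confvae:::bin_centers(default_bin_edges())
  d2 <- matrix(ctr[10], 3, 3); diag(d2) <- ctr[1]
  dg2 <- soft_distogram(d2, sigma = 1e-3)
  expect_gt(dg2$probs[1, 2, 10], 0.999)
  # oracle: independently coded normalized Gaussian over the centers
  sig <- 0.5
  dg3 <- soft_distogram(d, sigma = sig)
  for (pair in list(c(1, 2), c(3, 5))) {
    w <- exp(-(d[pair[1], pair[2]] - ctr)^2 / (2 * sig^2))
    expect_equal(dg3$probs[pair[1], pair[2], ], w / sum(w), tolerance = 1e-12)
  }
})

test_that("cce: one-hot identity, duplicate references, brute-force oracle", {
  L <- 3; K <- 4
  edges <- c(0, 5, 10, 15, 20)
  onehot <- array(0, c(L, L, K))
  onehot[, , 2] <- 1
  ref <- distogram(onehot, edges)
  # generated identical to the single one-hot reference
  expect_lt(cce(ref, ref), 1e-7)   # bounded by the epsilon guard
  set.seed(42)
  probs <- array(runif(L * L * K), c(L, L, K))
  probs <- probs / array(rep(apply(probs, c(1, 2), sum), K), dim(probs))
  gen <- distogram(probs, edges)
  expect_equal(cce(gen, list(ref, ref)), cce(gen, ref))
  # triple-loop oracle on a random 3x3x4 case
  probs2 <- array(runif(L * L * K), c(L, L, K))
  probs2 <- probs2 / array(rep(apply(probs2, c(1, 2), sum), K), dim(probs2))
  ref2 <- distogram(probs2, edges)
  acc <- 0
  for (i in 1:L) for (j in 1:L) for (k in 1:K)
    acc <- acc - probs2[i, j, k] * log(probs[i, j, k] + 1e-8)
  expect_equal(cce(gen, ref2), acc / L^2, tolerance = 1e-12)
  # binning mismatch is an error
  expect_error(cce(gen, distogram(array(1 / 3, c(4, 4, 3)), c(0, 5, 10, 15))),
               "match")
})

test_that("optimize_latent honors the trust region exactly", {
  fx <- tiny_two_state()
  refs <- make_reference_distograms(fx$ens$crystals[[1]], k = 2,
                                    blur_sigma = 0.5, seed = 5)
  z0 <- sample_prior(6, 16, seed = 8)
  # degenerate trust region: z must not move at all
  cfg0 <- sampler_config(n_samples = 6, d_max = 0, max_iters = 10, lr = 0.3,
                         seed = 8)
  o0 <- optimize_latent(fx$model, z0, refs, cfg0)
  expect_identical(rbind(o0$z), z0)
  # standard radius: every sample inside, scores non-increasing
  cfg1 <- sampler_config(n_samples = 6, d_max = 3, max_iters = 30, lr = 0.3,
                         seed = 8)
  o1 <- optimize_latent(fx$model, z0, refs, cfg1)
  disp <- sqrt(rowSums((rbind(o1$z) - z0)^2))
  expect_true(all(disp <= 3 + 1e-9))
  expect_true(all(o1$score <= o1$initial_score))
})

test_that("the returned score is honest bookkeeping", {
  fx <- tiny_two_state()
  refs <- make_reference_distograms(fx$ens$crystals[[2]], k = 3,
                                    blur_sigma = 0.5, seed = 6)
  z0 <- sample_prior(3, 16, seed = 18)
  cfg <- sampler_config(n_samples = 3, d_max = 10, max_iters = 25, lr = 0.3,
                        seed = 18)
  o <- optimize_latent(fx$model, z0, refs, cfg)
  for (i in 1:3) {
    f <- sivae_decode(fx$model, rbind(o$z)[i, ])
    dg <- soft_distogram(f$dist, refs[[1]]$bin_edges, sigma = 0.25)
    expect_lt(abs(cce(dg, refs) - o$score[i]), 1e-9)
  }
})

test_that("vector z0 input returns a vector result with a trace", {
  fx <- tiny_two_state()
  refs <- make_reference_distograms(fx$ens$crystals[[1]], k = 1,
                                    blur_sigma = 0.5, seed = 2)
  z0 <- as.numeric(sample_prior(1, 16, seed = 4))
  o <- optimize_latent(fx$model, z0, refs,
                       sampler_config(n_samples = 1, max_iters = 15, lr = 0.3,
                                      seed = 4))
  expect_null(dim(o$z))
  expect_equal(length(o$z), 16L)
  expect_true(nrow(o$trace) >= 1)
  expect_lte(o$score, o$initial_score)
})

test_that("generate_ensemble: count contract, invariants, provenance", {
  fx <- tiny_two_state()
  refs <- make_reference_distograms(fx$ens$crystals[[1]], k = 2,
                                    blur_sigma = 0.5, seed = 3)
  cfg <- sampler_config(n_samples = 5, max_iters = 12, lr = 0.3, seed = 5,
                        chunk_size = 5)
  gen <- generate_ensemble(fx$model, refs, cfg)
  expect_length(gen$features, 5L)
  expect_equal(nrow(gen$provenance), 5L)
  expect_length(gen$traces, 5L)
  for (f in gen$features) {
    expect_s3_class(f, "template_features")
    expect_equal(f$dist, t(f$dist))
    expect_equal(diag(f$dist), rep(0, f$L))
    expect_equal(f$omega, t(f$omega))
    expect_true(all(f$dist[!f$mask] == f$cutoff))
    expect_true(all(f$phi >= 0 & f$phi <= pi))
  }
  expect_true(all(gen$provenance$final_score <= gen$provenance$initial_score))
  expect_true(all(gen$provenance$latent_displacement <= 10 + 1e-9))
})

test_that("the diversity filter rejects near-duplicate decoded maps", {
  fx <- tiny_two_state()
  refs <- make_reference_distograms(fx$ens$crystals[[1]], k = 1,
                                    blur_sigma = 0.5, seed = 3)
  # an absurdly large threshold forces rejections and a partial ensemble
  cfg <- sampler_config(n_samples = 6, max_iters = 5, lr = 0.2, seed = 5,
                        chunk_size = 6, diversity_tau = 50, retry_factor = 2)
  expect_warning(gen <- generate_ensemble(fx$model, refs, cfg),
                 "retry cap")
  expect_lt(length(gen$features), 6L)
  # pairwise RMS distance between accepted maps respects the threshold
  cfg2 <- sampler_config(n_samples = 4, max_iters = 5, lr = 0.2, seed = 5,
                         chunk_size = 8, diversity_tau = 0.05,
                         retry_factor = 4)
  gen2 <- generate_ensemble(fx$model, refs, cfg2)
  if (length(gen2$features) >= 2) {
    for (i in 1:(length(gen2$features) - 1))
      for (j in (i + 1):length(gen2$features))
        expect_gte(sqrt(mean((gen2$features[[i]]$dist -
                                gen2$features[[j]]$dist)^2)), 0.05)
  }
})

test_that("CCE autodiff gradient through the decoder matches finite differences", {
  fx <- tiny_two_state()
  refs <- make_reference_distograms(fx$ens$crystals[[1]], k = 2,
                                    blur_sigma = 0.5, seed = 9)
  edges <- refs[[1]]$bin_edges
  ctr <- confvae:::bin_centers(edges)
  refs_m <- lapply(refs, confvae:::distogram_matrix)
  z <- as.numeric(sample_prior(1, 16, seed = 10))
  score_of <- function(z) {
    zn <- confvae:::ad_const(rbind(z))
    confvae:::ad_value(confvae:::ad_cce_min(
      confvae:::decoded_dist_node(fx$model, zn), refs_m, ctr, 0.25))
  }
  zn <- confvae:::ad_param(rbind(z))
  sc <- confvae:::ad_cce_min(confvae:::decoded_dist_node(fx$model, zn),
                             refs_m, ctr, 0.25)
  confvae:::ad_backprop(confvae:::ad_sum(sc))
  g <- zn$grad
  for (i in c(1, 7, 16)) {
    h <- 1e-5
    zp <- z; zp[i] <- zp[i] + h
    zm <- z; zm[i] <- zm[i] - h
    fd <- (score_of(zp) - score_of(zm)) / (2 * h)
    expect_equal(as.numeric(g[1, i]), fd, tolerance = 1e-4)
  }
})

test_that("reference distograms round-trip through disk", {
  fx <- tiny_two_state()
  refs <- make_reference_distograms(fx$ens$crystals[[1]], k = 3,
                                    blur_sigma = 0.5, seed = 12)
  path <- tempfile(fileext = ".rds")
  save_references(refs, path)
  r2 <- load_references(path)
  expect_length(r2, 3L)
  expect_equal(r2[[2]]$probs, refs[[2]]$probs)
  expect_equal(r2[[1]]$bin_edges, refs[[1]]$bin_edges)
})
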