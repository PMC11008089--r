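# Dense residual encoder/decoder networks and the Adam optimizer.
#
# Both networks are residual MLPs: a linear layer into a trunk of width
# `block_features`, `n_resnet_blocks` residual blocks (two linear layers with
# a leaky-ReLU between, added back to the trunk), and linear output heads
# (mu/logvar for the encoder, the flattened feature tensor for the decoder).
# Leaky-ReLU slope 0.2 throughout. Log-variances are clamped to [-12, 12].

.LRELU_SLOPE <- 0.2
.LV_CLAMP <- 12

nn_init_block <- function(h, scale, rng_sd = sqrt(2 / h)) {
  list(W1 = matrix(stats::rnorm(h * h, sd = rng_sd), h, h),
       b1 = numeric(h),
       W2 = matrix(stats::rnorm(h * h, sd = rng_sd * scale), h, h),
       b2 = numeric(h))
}

# Encoder: D -> h -> blocks -> (mu, logvar), each latent-dim wide.
nn_init_encoder <- function(D, h, n_blocks, latent) {
  list(W_in = matrix(stats::rnorm(D * h, sd = sqrt(2 / D)), D, h),
       b_in = numeric(h),
       blocks = lapply(seq_len(n_blocks), function(i) nn_init_block(h, 0.1)),
       W_mu = matrix(stats::rnorm(h * latent, sd = sqrt(1 / h)), h, latent),
       b_mu = numeric(latent),
       W_lv = matrix(stats::rnorm(h * latent, sd = sqrt(1 / h)), h, latent),
       b_lv = rep(-6, latent))   # start with small posterior noise
}

# Decoder: latent -> h -> blocks -> D.
nn_init_decoder <- function(D, h, n_blocks, latent) {
  list(W_in = matrix(stats::rnorm(latent * h, sd = sqrt(2 / latent)), latent, h),
       b_in = numeric(h),
       blocks = lapply(seq_len(n_blocks), function(i) nn_init_block(h, 0.1)),
       W_out = matrix(stats::rnorm(h * D, sd = sqrt(1 / h)), h, D),
       b_out = numeric(D))
}

# ---- structural helpers over nested parameter lists ----

param_map <- function(p, f) {
  if (is.list(p)) lapply(p, param_map, f = f) else f(p)
}

param_map2 <- function(p, q, f) {
  if (is.list(p)) Map(param_map2, p, q, MoreArgs = list(f = f)) else f(p, q)
}

wrap_params <- function(p, trainable = TRUE) {
  param_map(p, function(x) if (trainable) ad_param(x) else ad_const(x))
}

extract_grads <- function(pw) {
  param_map(pw, function(node) {
    g <- node$grad
    if (is.null(g)) g <- ad_value(node) * 0
    g
  })
}

params_equal <- function(a, b) {
  fa <- unlist(a, use.names = FALSE); fb <- unlist(b, use.names = FALSE)
  length(fa) == length(fb) && identical(fa, fb)
}

# ---- forward passes ----

act_ad <- function(x, activation) {
  if (activation == "tanh") ad_tanh(x) else ad_lrelu(x, .LRELU_SLOPE)
}

trunk_forward_ad <- function(pw, x, activation = "lrelu") {
  h <- act_ad(ad_add_bias(ad_matmul(x, pw$W_in), pw$b_in), activation)
  for (blk in pw$blocks) {
    t1 <- act_ad(ad_add_bias(ad_matmul(h, blk$W1), blk$b1), activation)
    h <- ad_add(h, ad_add_bias(ad_matmul(t1, blk$W2), blk$b2))
  }
  h
}

enc_forward_ad <- function(pw, x, activation = "lrelu") {
  h <- trunk_forward_ad(pw, x, activation)
  list(mu = ad_add_bias(ad_matmul(h, pw$W_mu), pw$b_mu),
       lv = ad_clamp(ad_add_bias(ad_matmul(h, pw$W_lv), pw$b_lv),
                     -.LV_CLAMP, .LV_CLAMP))
}

dec_forward_ad <- function(pw, z, activation = "lrelu") {
  h <- trunk_forward_ad(pw, z, activation)
  ad_add_bias(ad_matmul(h, pw$W_out), pw$b_out)
}

lrelu_plain <- function(x) x * (.LRELU_SLOPE + (1 - .LRELU_SLOPE) * (x > 0))

act_plain <- function(x, activation) {
  if (activation == "tanh") tanh(x) else lrelu_plain(x)
}

trunk_forward_plain <- function(p, x, activation = "lrelu") {
  h <- act_plain(sweep(x %*% p$W_in, 2, p$b_in, "+"), activation)
  for (blk in p$blocks) {
    t1 <- act_plain(sweep(h %*% blk$W1, 2, blk$b1, "+"), activation)
    h <- h + sweep(t1 %*% blk$W2, 2, blk$b2, "+")
  }
  h
}

enc_forward_plain <- function(p, x, activation = "lrelu") {
  h <- trunk_forward_plain(p, x, activation)
  list(mu = sweep(h %*% p$W_mu, 2, p$b_mu, "+"),
       lv = pmin(pmax(sweep(h %*% p$W_lv, 2, p$b_lv, "+"), -.LV_CLAMP), .LV_CLAMP))
}

dec_forward_plain <- function(p, z, activation = "lrelu") {
  h <- trunk_forward_plain(p, z, activation)
  sweep(h %*% p$W_out, 2, p$b_out, "+")
}

# ---- Adam ----

adam_new <- function(params) {
  list(m = param_map(params, function(x) x * 0),
       v = param_map(params, function(x) x * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      weight_decay = 0, eps = 1e-8) {
  state$t <- state$t + 1L
  if (weight_decay > 0)
    grads <- param_map2(grads, params, function(g, p) g + weight_decay * p)
  state$m <- param_map2(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- param_map2(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g ^ 2)
  bc1 <- 1 - beta1 ^ state$t
  bc2 <- 1 - beta2 ^ state$t
  upd <- param_map2(state$m, state$v, function(m, v)
    (m / bc1) / (sqrt(v / bc2) + eps))
  params <- param_map2(params, upd, function(p, u) p - lr * u)
  list(params = params, state = state)
}
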