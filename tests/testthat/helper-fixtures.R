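# Shared fixtures, memoized so expensive objects are built once per session.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Random but plausible backbone: an ideal helix with a mild random kink,
# used for fuzz/property tests.
random_backbone <- function(L = 12, seed = 1) {
  set.seed(seed)
  s <- make_toy_crystal(L, hinge_angle = stats::runif(1, -45, 45))
  disp <- matrix(stats::rnorm(L * 3, sd = 0.05), L, 3)
  backbone_structure(s$sequence, s$n + disp, s$ca + disp, s$c + disp,
                     s$cb + disp)
}

# Small two-state ensemble plus a briefly trained model; reused by the
# sivae/sampler/pipeline tests.
tiny_two_state <- function() {
  memo("tiny_two_state", function() {
    spec <- toy_ensemble_spec(n_residues = 24, n_crystals = 2,
                              hinge_angles = c(-25, 25),
                              snapshots_per_crystal = 30, seed = 3)
    ens <- make_toy_ensemble(spec)
    maps <- lapply(c(ens$snapshots[[1]], ens$snapshots[[2]]),
                   coords_to_features)
    cfg <- sivae_config(latent_dim = 16, block_features = 32,
                        n_resnet_blocks = 2, batch_size = 16, epochs = 25,
                        seed = 7, lr = 2e-3)
    model <- sivae_train(cfg, maps)
    list(ens = ens, maps = maps, model = model, cfg = cfg)
  })
}

# Independent dihedral oracle: rotate the frame so the central bond points
# along +z, then measure the 2D angle between the projected outer bonds.
# A different computational path from the package's atan2 cross-product form.
dihedral_oracle <- function(p1, p2, p3, p4) {
  b <- p3 - p2
  bz <- b / sqrt(sum(b * b))
  ref <- if (abs(bz[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  ex <- ref - sum(ref * bz) * bz
  ex <- ex / sqrt(sum(ex * ex))
  ey <- c(bz[2] * ex[3] - bz[3] * ex[2],
          bz[3] * ex[1] - bz[1] * ex[3],
          bz[1] * ex[2] - bz[2] * ex[1])
  proj <- function(v) c(sum(v * ex), sum(v * ey))
  u <- proj(p1 - p2)
  w <- proj(p4 - p3)
  a <- atan2(u[1] * w[2] - u[2] * w[1], sum(u * w))
  if (a <= -pi + 1e-15) a <- pi
  a
}

# Independent internal-to-Cartesian oracle: solves for the fourth point by
# multi-start numerical optimization of the three internal-coordinate
# residuals (bond, planar angle, torsion), with no frame construction.
nerf_oracle <- function(a, b, c, bond, theta, chi, seed = 1) {
  ang_diff <- function(x, y) atan2(sin(x - y), cos(x - y))
  obj <- function(d) {
    r1 <- sqrt(sum((d - c)^2)) - bond
    r2 <- planar_angle(b, c, d) - theta
    r3 <- ang_diff(dihedral_oracle(a, b, c, d), chi)
    r1^2 + r2^2 + r3^2
  }
  set.seed(seed)
  best <- NULL; bestv <- Inf
  for (k in 1:12) {
    start <- c + bond * stats::rnorm(3)
    o <- stats::optim(start, obj, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-16))
    if (o$value < bestv) { bestv <- o$value; best <- o$par }
  }
  stopifnot(bestv < 1e-14)
  best
}

random_rotation <- function(seed) {
  set.seed(seed)
  qr_r <- qr(matrix(stats::rnorm(9), 3, 3))
  R <- qr.Q(qr_r)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}
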