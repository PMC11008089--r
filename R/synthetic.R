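# synthetic_data: toy conformational ensembles with the statistical structure
# the method assumes -- a set of distinct "crystal" conformations >= 1 A CA
# RMSD apart, per-crystal clouds of MD-like snapshots (smooth low-frequency
# deformations, not i.i.d. noise), and smoothed reference distograms standing
# in for an uncertain structure predictor centered on the truth.

# Ideal alpha-helix internal coordinates.
.HELIX <- list(b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329,
               a_c_n_ca = 121.7 * pi / 180, a_n_ca_c = 111.2 * pi / 180,
               a_ca_c_n = 116.2 * pi / 180,
               phi = -57 * pi / 180, psi = -47 * pi / 180, omg = pi)

#' Build a two-segment hinge-helix toy crystal
#'
#' Constructs an ideal alpha-helical backbone of \code{n_residues} residues,
#' then rotates the C-terminal half rigidly by \code{hinge_angle} degrees
#' about an axis through the hinge CA, perpendicular to the local chain
#' direction. Different hinge angles give distinct, interpretable
#' "conformational states" with tunable pairwise RMSD. CB atoms are built by
#' ideal geometry.
#'
#' @param n_residues chain length (>= 3).
#' @param hinge_angle hinge rotation in degrees.
#' @param seed unused (the construction is deterministic); kept for a uniform
#'   generator interface.
#' @return a \code{\link{backbone_structure}}.
#' @export
make_toy_crystal <- function(n_residues = 60, hinge_angle = 0, seed = 0) {
  stopifnot(n_residues >= 3)
  h <- .HELIX
  N <- CA <- C <- matrix(NA_real_, n_residues, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(h$b_n_ca, 0, 0)
  C[1, ] <- CA[1, ] + h$b_ca_c *
    c(cos(pi - h$a_n_ca_c), sin(pi - h$a_n_ca_c), 0)
  for (i in seq_len(n_residues - 1)) {
    N[i + 1, ] <- nerf_place(N[i, ], CA[i, ], C[i, ], h$b_c_n, h$a_ca_c_n, h$psi)
    CA[i + 1, ] <- nerf_place(CA[i, ], C[i, ], N[i + 1, ], h$b_n_ca, h$a_c_n_ca, h$omg)
    C[i + 1, ] <- nerf_place(C[i, ], N[i + 1, ], CA[i + 1, ], h$b_ca_c, h$a_n_ca_c, h$phi)
  }
  hinge <- max(2, min(n_residues - 1, floor(n_residues / 2)))
  if (abs(hinge_angle) > 1e-12) {
    pivot <- CA[hinge, ]
    chain_dir <- CA[min(hinge + 2, n_residues), ] - CA[max(hinge - 2, 1), ]
    axis <- vcross(chain_dir, c(0, 0, 1))
    if (vnorm(axis) < 1e-8) axis <- vcross(chain_dir, c(0, 1, 0))
    R <- rotation_about_axis(axis, hinge_angle * pi / 180)
    mob <- seq(hinge + 1, n_residues)
    rot <- function(x) sweep(sweep(x, 2, pivot) %*% t(R), 2, -pivot)
    N[mob, ] <- rot(N[mob, , drop = FALSE])
    CA[mob, ] <- rot(CA[mob, , drop = FALSE])
    C[mob, ] <- rot(C[mob, , drop = FALSE])
  }
  backbone_structure(paste(rep("A", n_residues), collapse = ""), N, CA, C,
                     cb = NULL, chain_id = "A")
}

#' CA-trace RMSD between two backbone structures
#'
#' Proper-rotation Kabsch RMSD over CA atoms.
#'
#' @param a,b \code{backbone_structure} objects of equal length.
#' @return RMSD in Angstrom.
#' @export
ca_rmsd <- function(a, b) kabsch_rmsd(a$ca, b$ca)

#' Generate an MD-like snapshot cloud around a crystal
#'
#' Each snapshot is the crystal plus a smooth, correlated deformation with
#' two components: (1) optionally, a fluctuation along the structure's own
#' softest collective mode, supplied through \code{soft_mode} (for the
#' hinge-helix toys this is a small hinge-angle change, which is what short
#' MD of a hinged protein predominantly samples), and (2) a superposition of
#' \code{n_modes} low-frequency sinusoidal modes along the chain with random
#' amplitudes and phases. The two components are scaled so the expected
#' per-residue displacement magnitude is \code{sigma} Angstrom in total,
#' split by \code{soft_fraction}. The same displacement is applied to all
#' four atoms of a residue, so perturbations are correlated along the chain
#' (the fluctuation character of short MD, not white noise). Snapshots are
#' partitioned into \code{n_traj} contiguous pseudo-trajectories.
#'
#' @param crystal a \code{backbone_structure}.
#' @param sigma per-residue displacement scale in Angstrom (>= 0).
#' @param count total number of snapshots.
#' @param n_traj number of pseudo-trajectory labels.
#' @param seed RNG seed.
#' @param n_modes number of sinusoidal modes (default 5).
#' @param soft_mode optional function \code{(t) -> backbone_structure}
#'   returning the crystal deformed along its softest collective coordinate
#'   by amount \code{t} (dimensionless; t = 1 should displace atoms by
#'   roughly 1 Angstrom RMS). \code{NULL} disables the component.
#' @param soft_fraction fraction of the displacement variance carried by the
#'   soft mode when one is supplied (default 0.5).
#' @return list of \code{backbone_structure}s; each carries attributes
#'   \code{traj} (trajectory label) and \code{frame}.
#' @export
make_snapshot_cloud <- function(crystal, sigma = 0.3, count = 200, n_traj = 5,
                                seed = 1, n_modes = 5, soft_mode = NULL,
                                soft_fraction = 0.5) {
  stopifnot(sigma >= 0, count >= 0, soft_fraction >= 0, soft_fraction <= 1)
  set.seed(seed)
  L <- crystal$L
  pos <- (seq_len(L) - 0.5) / L
  basis <- vapply(seq_len(n_modes), function(m) sin(pi * m * pos), numeric(L))
  traj_of <- rep(seq_len(n_traj), each = ceiling(count / max(1, n_traj)))[seq_len(count)]
  out <- vector("list", count)
  fs <- if (is.null(soft_mode)) 0 else soft_fraction
  # sinusoidal component: E[disp_coord^2] = n_modes * E[sin^2] * a_sd^2,
  # scaled so its E|disp|^2 = (1 - fs) * sigma^2
  a_sd <- if (sigma > 0) sigma * sqrt((1 - fs) / (3 * n_modes * mean(basis ^ 2))) else 0
  sm_sd <- sigma * sqrt(fs)
  for (k in seq_len(count)) {
    base <- crystal
    if (!is.null(soft_mode) && sm_sd > 0)
      base <- soft_mode(stats::rnorm(1, sd = sm_sd))
    amp <- matrix(stats::rnorm(n_modes * 3, sd = a_sd), n_modes, 3)
    ph <- stats::runif(n_modes, 0, 2 * pi)
    bk <- vapply(seq_len(n_modes),
                 function(m) sin(pi * m * pos + ph[m]), numeric(L))
    disp <- bk %*% amp                       # L x 3 smooth displacement field
    s <- backbone_structure(base$sequence,
                            base$n + disp, base$ca + disp,
                            base$c + disp, base$cb + disp,
                            chain_id = base$chain_id, resno = base$resno)
    attr(s, "traj") <- traj_of[k]
    attr(s, "frame") <- k
    out[[k]] <- s
  }
  out
}

#' Snapshot count implied by a sampling schedule
#'
#' Number of snapshots obtained by saving a frame every \code{interval_ps}
#' picoseconds over \code{duration_ns} nanoseconds in each of \code{n_traj}
#' independent trajectories.
#'
#' @param duration_ns trajectory length in nanoseconds.
#' @param interval_ps saving interval in picoseconds; must divide the
#'   duration exactly.
#' @param n_traj number of independent trajectories.
#' @return integer snapshot count.
#' @export
snapshot_count <- function(duration_ns, interval_ps, n_traj) {
  total_ps <- duration_ns * 1000
  if (total_ps %% interval_ps != 0)
    stop("interval_ps must divide the trajectory duration", call. = FALSE)
  as.integer(total_ps / interval_ps) * as.integer(n_traj)
}

#' Toy ensemble specification
#'
#' Defaults are the benchmark's study conditions: 60 residues, 6 crystals,
#' 200 snapshots per crystal in 5 pseudo-trajectories, 0.3 Angstrom snapshot
#' scale, crystals pairwise at least 1 Angstrom CA RMSD apart.
#'
#' @param n_residues chain length.
#' @param n_crystals number of crystal conformations.
#' @param hinge_angles degrees, one per crystal; default evenly spaced on
#'   [-30, 30], which puts adjacent crystals just above the 1 Angstrom
#'   separation rule -- the scale on which distinct crystal forms of the
#'   motivating system differ.
#' @param snapshot_noise_sigma snapshot displacement scale (Angstrom).
#' @param snapshots_per_crystal snapshots per crystal.
#' @param trajectories_per_crystal pseudo-trajectories per crystal.
#' @param min_crystal_separation minimum pairwise CA RMSD (Angstrom).
#' @param seed RNG seed.
#' @return a \code{toy_ensemble_spec} list.
#' @export
toy_ensemble_spec <- function(n_residues = 60, n_crystals = 6,
                              hinge_angles = NULL,
                              snapshot_noise_sigma = 0.3,
                              snapshots_per_crystal = 200,
                              trajectories_per_crystal = 5,
                              min_crystal_separation = 1.0, seed = 1) {
  if (is.null(hinge_angles))
    hinge_angles <- seq(-30, 30, length.out = n_crystals)
  stopifnot(length(hinge_angles) == n_crystals)
  structure(list(n_residues = n_residues, n_crystals = n_crystals,
                 hinge_angles = hinge_angles,
                 snapshot_noise_sigma = snapshot_noise_sigma,
                 snapshots_per_crystal = snapshots_per_crystal,
                 trajectories_per_crystal = trajectories_per_crystal,
                 min_crystal_separation = min_crystal_separation, seed = seed),
            class = "toy_ensemble_spec")
}

#' Generate a toy conformational ensemble
#'
#' Builds the crystals from the hinge angles (widening the angle spread, if
#' necessary, until all pairs are at least \code{min_crystal_separation}
#' CA RMSD apart) and a snapshot cloud for each crystal.
#'
#' @param spec a \code{\link{toy_ensemble_spec}}.
#' @return a \code{toy_ensemble}: list with \code{crystals} (named list),
#'   \code{snapshots} (named list of snapshot lists, keyed by crystal id),
#'   and \code{spec}.
#' @export
make_toy_ensemble <- function(spec = toy_ensemble_spec()) {
  stopifnot(inherits(spec, "toy_ensemble_spec"))
  angles <- spec$hinge_angles
  for (attempt in 1:20) {
    crystals <- lapply(angles, function(a)
      make_toy_crystal(spec$n_residues, a, seed = spec$seed))
    ok <- TRUE
    for (i in seq_len(spec$n_crystals - 1))
      for (j in seq(i + 1, spec$n_crystals))
        if (ca_rmsd(crystals[[i]], crystals[[j]]) < spec$min_crystal_separation)
          ok <- FALSE
    if (ok) break
    angles <- angles * 1.25   # widen the spread and retry
  }
  if (!ok) stop("could not separate crystals by min_crystal_separation",
                call. = FALSE)
  ids <- sprintf("crystal_%d", seq_len(spec$n_crystals))
  names(crystals) <- ids
  # displacement per degree of hinge rotation, for unit-scaling the soft mode
  probe <- ca_rmsd(make_toy_crystal(spec$n_residues, 10),
                   make_toy_crystal(spec$n_residues, 0)) / 10
  snapshots <- lapply(seq_len(spec$n_crystals), function(k) {
    ang <- angles[k]
    soft <- function(t) make_toy_crystal(spec$n_residues, ang + t / probe)
    make_snapshot_cloud(crystals[[k]], sigma = spec$snapshot_noise_sigma,
                        count = spec$snapshots_per_crystal,
                        n_traj = spec$trajectories_per_crystal,
                        seed = spec$seed + k, soft_mode = soft)
  })
  names(snapshots) <- ids
  structure(list(crystals = crystals, snapshots = snapshots, spec = spec,
                 hinge_angles = angles),
            class = "toy_ensemble")
}

#' Holdout split with the 1-Angstrom exclusion rule
#'
#' Excludes from training the target crystal, every crystal within
#' \code{exclusion_rmsd} CA RMSD of the target, and all snapshots derived
#' from excluded crystals. The split is verified by recomputing all pairwise
#' CA RMSDs.
#'
#' @param ens a \code{toy_ensemble}.
#' @param target_id crystal id of the held-out target.
#' @param exclusion_rmsd exclusion radius in Angstrom (default 1.0).
#' @return a \code{holdout_split}: list with \code{target}, \code{train_crystals}
#'   (ids), \code{train_snapshots} (ids), and \code{excluded} (ids).
#' @export
make_holdout <- function(ens, target_id, exclusion_rmsd = 1.0) {
  stopifnot(inherits(ens, "toy_ensemble"))
  if (!target_id %in% names(ens$crystals))
    stop("unknown target id: ", target_id, call. = FALSE)
  target <- ens$crystals[[target_id]]
  ids <- names(ens$crystals)
  keep <- vapply(ids, function(id) {
    if (id == target_id) return(FALSE)
    ca_rmsd(ens$crystals[[id]], target) >= exclusion_rmsd
  }, logical(1))
  if (!any(keep))
    stop("all crystals excluded by the holdout rule; empty training set",
         call. = FALSE)
  structure(list(target = target_id,
                 train_crystals = ids[keep],
                 train_snapshots = ids[keep],
                 excluded = ids[!keep & ids != target_id],
                 exclusion_rmsd = exclusion_rmsd),
            class = "holdout_split")
}

#' Synthetic reference distograms around a target structure
#'
#' Emulates an uncertain structure predictor centered on the truth: builds
#' \code{k} distograms by soft (RBF) binning of the target's CB-CB distances
#' with jittered blur widths.
#'
#' @param target a \code{backbone_structure}.
#' @param k number of reference distograms (default 5).
#' @param blur_sigma base blur width in Angstrom.
#' @param seed RNG seed (jitters the blur width per reference).
#' @param bin_edges distance bin edges (default \code{\link{default_bin_edges}}).
#' @return list of \code{k} \code{distogram} objects.
#' @export
make_reference_distograms <- function(target, k = 5, blur_sigma = 0.5,
                                      seed = 1, bin_edges = default_bin_edges()) {
  stopifnot(k >= 1)
  set.seed(seed)
  d <- cb_distance_matrix(target)
  jit <- stats::runif(k, 0.75, 1.25)
  lapply(seq_len(k), function(i)
    soft_distogram(d, bin_edges = bin_edges, sigma = blur_sigma * jit[i]))
}

# CB-CB pairwise distance matrix of a structure (no cutoff).
cb_distance_matrix <- function(s) {
  as.matrix(stats::dist(s$cb))
}
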