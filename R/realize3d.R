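# realize3d: distance-geometry realization of decoded feature maps and the
# structural evaluation metrics. This module is the desk-scale stand-in for
# an external structure-prediction network; realize_adapter() defines the
# seam through which such an engine can be dropped in.
#
# The realization runs in two stages. Stage 1 embeds the L CB atoms from
# the masked dist channel alone: shortest-path metric completion of the
# unknown entries, classical MDS, then gradient refinement on the observed
# distances only. Stage 2 places each CA atom independently by least-squares
# trilateration against the CB cloud, using the ideal 1.522 A CA-CB bond and
# the CA(i)-CB(j) distances implied by the phi planar angles (law of
# cosines). The global mirror ambiguity (distances never fix chirality) is
# resolved last, by correlating omega dihedrals computed from the realized
# CA/CB atoms with the feature map's omega channel and reflecting if they
# anticorrelate.

#' Realization configuration
#'
#' @param refine_iters gradient-refinement iterations (default 200).
#' @param refine_lr Adam step size on coordinates.
#' @param residual_tol residual (RMS error on observed distances, Angstrom)
#'   below which the realization is flagged converged.
#' @param max_neg_eig_mass maximum tolerated negative-eigenvalue mass in the
#'   MDS Gram spectrum before the input is declared non-embeddable.
#' @param mask_margin distances within this margin below the cutoff are
#'   treated as unobserved (Angstrom, default 1). Decoded maps regress
#'   truly-distant pairs toward the sentinel value, so the last Angstrom
#'   below the cutoff carries no reliable geometry.
#' @return a \code{realize_config}.
#' @export
realize_config <- function(refine_iters = 200, refine_lr = 0.05,
                           residual_tol = 0.2, max_neg_eig_mass = 0.5,
                           mask_margin = 1.0) {
  structure(as.list(environment()), class = "realize_config")
}

# CA(i)-CB(j) distance via the law of cosines on the phi angle.
ca_cb_cross_dist <- function(d, phi) {
  sqrt(pmax(0, .CB_BOND ^ 2 + d ^ 2 - 2 * .CB_BOND * d * cos(phi)))
}

#' Realize 3D coordinates from a template feature map
#'
#' Distance-geometry pipeline. The CB trace is embedded from the masked dist
#' channel (shortest-path metric completion of unknown entries, classical
#' MDS, Adam refinement on the observed distances only); each CA atom is
#' then placed by least-squares trilateration against the CB cloud using the
#' ideal CA-CB bond and the CA(i)-CB(j) distances implied by the phi angles;
#' finally the embedding is reflected if omega dihedrals computed from the
#' realized atoms anticorrelate with the feature map's omega channel. N and
#' C atoms of the returned structure are ideal-geometry placeholders along
#' the CA trace (evaluation uses CA/CB).
#'
#' @param f a \code{template_features}.
#' @param cfg a \code{\link{realize_config}}.
#' @return a \code{realization_result}: list with \code{structure}
#'   (\code{backbone_structure}), \code{residual} (Angstrom RMS on observed
#'   distances), \code{converged}, \code{reflected}.
#' @export
realize <- function(f, cfg = realize_config()) {
  stopifnot(inherits(f, "template_features"))
  L <- f$L
  mask <- f$mask & (f$dist < f$cutoff - cfg$mask_margin)
  diag(mask) <- TRUE
  # ---- stage 1: CB embedding from the dist channel ----
  D <- f$dist
  D[!mask] <- NA_real_
  diag(D) <- 0
  known <- !is.na(D)
  full <- D
  if (any(!known)) {
    ek <- which(known & upper.tri(known), arr.ind = TRUE)
    g <- igraph::graph_from_data_frame(
      data.frame(from = ek[, 1], to = ek[, 2], weight = D[ek]),
      directed = FALSE, vertices = data.frame(name = seq_len(L)))
    sp <- igraph::distances(g)
    ord <- as.integer(igraph::V(g)$name)
    sp <- sp[order(ord), order(ord)]
    if (any(!is.finite(sp)))
      return(realization_failure(f, "distance graph is disconnected"))
    full[!known] <- sp[!known]
  }
  G <- -0.5 * (full ^ 2 -
                 outer(rowMeans(full ^ 2), rep(1, L)) -
                 outer(rep(1, L), colMeans(full ^ 2)) +
                 mean(full ^ 2))
  eg <- eigen((G + t(G)) / 2, symmetric = TRUE)
  neg_mass <- sum(abs(pmin(eg$values, 0))) / sum(abs(eg$values))
  if (neg_mass > cfg$max_neg_eig_mass)
    return(realization_failure(f, "input distances are not embeddable"))
  ev <- pmax(eg$values[1:3], 0)
  cb <- eg$vectors[, 1:3, drop = FALSE] %*% diag(sqrt(ev), 3)
  cb <- refine_embedding(cb, D, known, cfg)
  resid <- embedding_residual(cb, D, known)
  # ---- stage 2: CA placement by per-residue trilateration ----
  ca <- place_ca_atoms(cb, f, mask)
  # ---- stage 3: chirality from the omega channel ----
  obs <- which(mask & upper.tri(mask), arr.ind = TRUE)
  X <- rbind(cb, ca)
  reflected <- FALSE
  if (nrow(obs) > 0) {
    score <- omega_agreement(X, obs, f$omega, L)
    Xr <- X %*% diag(c(1, 1, -1))
    if (omega_agreement(Xr, obs, f$omega, L) > score) {
      X <- Xr
      reflected <- TRUE
    }
  }
  cb <- X[seq_len(L), , drop = FALSE]
  ca <- X[L + seq_len(L), , drop = FALSE]
  s <- placeholder_backbone(f$sequence, ca, cb)
  structure(list(structure = s, residual = resid,
                 converged = resid <= cfg$residual_tol,
                 reflected = reflected, neg_eig_mass = neg_mass),
            class = "realization_result")
}

# Least-squares trilateration of each CA against the realized CB cloud:
# |CA(i) - CB(i)| = 1.522 and |CA(i) - CB(j)| from the phi angle by the law
# of cosines. A few damped Gauss-Newton iterations per residue; the solution
# is generically unique because the reference points are non-coplanar.
place_ca_atoms <- function(cb, f, mask, iters = 25) {
  L <- nrow(cb)
  centroid <- colMeans(cb)
  ca <- matrix(NA_real_, L, 3)
  for (i in seq_len(L)) {
    js <- which(mask[i, ] & seq_len(L) != i)
    pts <- rbind(cb[i, , drop = FALSE], cb[js, , drop = FALSE])
    tgt <- c(.CB_BOND, ca_cb_cross_dist(f$dist[i, js], f$phi[i, js]))
    out <- cb[i, ] - centroid
    nrm <- vnorm(out)
    dir0 <- if (nrm > 1e-6) out / nrm else c(1, 0, 0)
    x <- cb[i, ] + .CB_BOND * dir0
    if (length(js) < 3) { ca[i, ] <- x; next }
    for (it in seq_len(iters)) {
      dv <- sweep(-pts, 2, x, "+")         # rows: x - p_j
      dn <- sqrt(rowSums(dv ^ 2))
      dn[dn < 1e-9] <- 1e-9
      r <- dn - tgt
      J <- dv / dn
      A <- crossprod(J) + diag(1e-6, 3)
      step <- tryCatch(solve(A, crossprod(J, r)), error = function(e) NULL)
      if (is.null(step)) break
      x <- x - as.numeric(step)
      if (sqrt(sum(step ^ 2)) < 1e-10) break
    }
    ca[i, ] <- x
  }
  ca
}

realization_failure <- function(f, why) {
  warning("realization failed: ", why, call. = FALSE)
  structure(list(structure = NULL, residual = Inf, converged = FALSE,
                 reflected = FALSE, reason = why),
            class = "realization_result")
}

#' @export
print.realization_result <- function(x, ...) {
  cat(sprintf("<realization_result> residual %.4f A, converged: %s\n",
              x$residual, x$converged))
  invisible(x)
}

embedding_residual <- function(X, D, known) {
  up <- known & upper.tri(known)
  idx <- which(up, arr.ind = TRUE)
  dd <- sqrt(rowSums((X[idx[, 1], , drop = FALSE] - X[idx[, 2], , drop = FALSE]) ^ 2))
  sqrt(mean((dd - D[idx]) ^ 2))
}

refine_embedding <- function(X, D, known, cfg) {
  M <- nrow(X)
  W <- known
  diag(W) <- FALSE
  Dt <- D
  Dt[!W] <- 0
  m <- v <- X * 0
  for (it in seq_len(cfg$refine_iters)) {
    dx <- outer(X[, 1], X[, 1], "-")
    dy <- outer(X[, 2], X[, 2], "-")
    dz <- outer(X[, 3], X[, 3], "-")
    dd <- sqrt(dx ^ 2 + dy ^ 2 + dz ^ 2)
    dd[dd < 1e-9] <- 1e-9
    err <- (dd - Dt) * W            # per-pair signed error
    cf <- err / dd
    G <- cbind(rowSums(cf * dx), rowSums(cf * dy), rowSums(cf * dz)) *
      (4 / sum(W))
    m <- 0.9 * m + 0.1 * G
    v <- 0.999 * v + 0.001 * G ^ 2
    mh <- m / (1 - 0.9 ^ it); vh <- v / (1 - 0.999 ^ it)
    X <- X - cfg$refine_lr * mh / (sqrt(vh) + 1e-8)
  }
  X
}

# Mean cosine agreement between omega dihedrals computed from an embedding
# (CB rows 1..L, CA rows L+1..2L) and the feature map's omega channel, on a
# subsample of observed pairs.
omega_agreement <- function(X, obs, omega_chan, L, max_pairs = 500) {
  sep <- abs(obs[, 1] - obs[, 2])
  use <- which(sep >= 2)
  if (length(use) == 0) return(0)
  if (length(use) > max_pairs)
    use <- use[round(seq(1, length(use), length.out = max_pairs))]
  i <- obs[use, 1]; j <- obs[use, 2]
  om <- dihedral_rows(X[L + i, , drop = FALSE], X[i, , drop = FALSE],
                      X[j, , drop = FALSE], X[L + j, , drop = FALSE])
  mean(cos(om - omega_chan[cbind(i, j)]))
}

# Placeholder N/C atoms along the CA trace so realized structures satisfy
# the backbone container's shape contract; evaluation uses CA/CB only.
placeholder_backbone <- function(sequence, ca, cb) {
  L <- nrow(ca)
  unit_to <- function(i, j) {
    u <- ca[j, ] - ca[i, ]
    n <- vnorm(u)
    if (n < 1e-9) c(1, 0, 0) else u / n
  }
  N <- C <- matrix(NA_real_, L, 3)
  for (i in seq_len(L)) {
    prev <- if (i > 1) unit_to(i, i - 1) else -unit_to(i, min(i + 1, L))
    nxt <- if (i < L) unit_to(i, i + 1) else -unit_to(i, max(i - 1, 1))
    N[i, ] <- ca[i, ] + 1.46 * prev
    C[i, ] <- ca[i, ] + 1.52 * nxt
  }
  suppressWarnings(backbone_structure(sequence, N, ca, C, cb))
}

#' Adapter seam for an external 3D-generation engine
#'
#' \code{realize_adapter} returns a function \code{(feature_map) ->
#' realization_result}. The default engine is the package's
#' distance-geometry \code{\link{realize}}; a wrapper around an external
#' structure-prediction network with the same signature can be supplied
#' instead and the rest of the pipeline is unchanged.
#'
#' @param engine a function \code{(template_features, cfg) -> realization_result};
#'   default \code{\link{realize}}.
#' @param cfg configuration forwarded to the engine.
#' @return a single-argument realization function.
#' @export
realize_adapter <- function(engine = realize, cfg = realize_config()) {
  force(engine); force(cfg)
  function(f) engine(f, cfg)
}

#' Binding-pocket residues near a ligand
#'
#' Residues whose CB atom (a side-chain proxy at backbone-only resolution)
#' lies within \code{cutoff} of any ligand atom.
#'
#' @param s a \code{backbone_structure}.
#' @param ligand_atoms m x 3 matrix of ligand heavy-atom coordinates.
#' @param cutoff distance cutoff in Angstrom (default 5).
#' @return a \code{pocket_definition}: list with \code{residue_indices} and
#'   \code{cutoff}.
#' @export
pocket_residues <- function(s, ligand_atoms, cutoff = 5) {
  stopifnot(inherits(s, "backbone_structure"))
  ligand_atoms <- rbind(ligand_atoms)
  if (nrow(ligand_atoms) == 0) stop("empty ligand", call. = FALSE)
  d2 <- outer(rowSums(s$cb ^ 2), rep(1, nrow(ligand_atoms))) +
    outer(rep(1, s$L), rowSums(ligand_atoms ^ 2)) -
    2 * s$cb %*% t(ligand_atoms)
  mind <- sqrt(pmax(0, apply(d2, 1, min)))
  idx <- which(mind <= cutoff)
  if (length(idx) == 0)
    warning("no residues within ", cutoff, " Angstrom of the ligand; empty pocket",
            call. = FALSE)
  structure(list(residue_indices = idx, cutoff = cutoff),
            class = "pocket_definition")
}

#' Pocket-restricted CA RMSD
#'
#' Kabsch RMSD over the pocket residues' CA atoms, with the superposition
#' computed on the pocket atoms themselves.
#'
#' @param a,b \code{backbone_structure}s of equal length.
#' @param pocket a \code{pocket_definition} valid for both.
#' @return RMSD in Angstrom.
#' @export
pocket_rmsd <- function(a, b, pocket) {
  stopifnot(inherits(pocket, "pocket_definition"))
  idx <- pocket$residue_indices
  if (length(idx) < 3) stop("pocket has fewer than 3 residues", call. = FALSE)
  if (any(idx < 1 | idx > a$L | idx > b$L))
    stop("pocket indices out of range", call. = FALSE)
  kabsch_rmsd(a$ca[idx, , drop = FALSE], b$ca[idx, , drop = FALSE])
}

#' Closest ensemble member to a target
#'
#' @param ensemble nonempty list of \code{backbone_structure}s.
#' @param target a \code{backbone_structure}.
#' @param metric "ca" (full CA RMSD) or "pocket".
#' @param pocket required when \code{metric = "pocket"}.
#' @return list: \code{index}, \code{rmsd}, and the vector of all
#'   \code{rmsds}.
#' @export
closest_in_ensemble <- function(ensemble, target, metric = c("ca", "pocket"),
                                pocket = NULL) {
  metric <- match.arg(metric)
  if (length(ensemble) == 0) stop("empty ensemble", call. = FALSE)
  vals <- vapply(ensemble, function(s) {
    if (metric == "ca") ca_rmsd(s, target) else pocket_rmsd(s, target, pocket)
  }, numeric(1))
  i <- which.min(vals)
  list(index = i, rmsd = vals[i], rmsds = vals)
}
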