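# featurize: BackboneStructure <-> 6D template feature maps.
#
# Angle conventions (trRosetta/RoseTTAFold):
#   omega[i,j] = dihedral CA(i)-CB(i)-CB(j)-CA(j)   (symmetric)
#   theta[i,j] = dihedral N(i)-CA(i)-CB(i)-CB(j)    (asymmetric)
#   phi[i,j]   = planar angle CA(i)-CB(i)-CB(j)     (asymmetric, [0, pi])
# Dihedrals live in (-pi, pi]. Distances/angles are stored raw (Angstrom,
# radians), never binned. Pairs beyond the cutoff carry sentinel values
# (dist = cutoff, angles = 0) with mask = FALSE; the mask channel rides along.

# Ideal virtual-CB internal coordinates (frozen convention).
.CB_BOND <- 1.522       # CA-CB bond, Angstrom
.CB_ANGLE <- 110.4 * pi / 180   # N-CA-CB
.CB_TORSION <- -122.5 * pi / 180  # C-N-CA-CB

#' Construct a backbone structure
#'
#' @param sequence one-letter amino-acid string of length L.
#' @param n,ca,c,cb L x 3 coordinate matrices (Angstrom). \code{cb} may be
#'   \code{NULL}, in which case every CB is built virtually from N/CA/C.
#' @param chain_id chain identifier (metadata).
#' @param resno optional author residue numbering (metadata).
#' @return an object of class \code{backbone_structure}.
#' @export
backbone_structure <- function(sequence, n, ca, c, cb = NULL, chain_id = "A",
                               resno = NULL) {
  n <- as.matrix(n); ca <- as.matrix(ca); c <- as.matrix(c)
  L <- nchar(sequence)
  if (L < 1) stop("empty sequence", call. = FALSE)
  for (m in list(n, ca, c)) {
    if (nrow(m) != L || ncol(m) != 3 || anyNA(m))
      stop("coordinate arrays must be complete L x 3 matrices", call. = FALSE)
  }
  if (is.null(cb)) {
    cb <- t(vapply(seq_len(L), function(i) virtual_cb(n[i, ], ca[i, ], c[i, ]),
                   numeric(3)))
  } else {
    cb <- as.matrix(cb)
    if (nrow(cb) != L || ncol(cb) != 3 || anyNA(cb))
      stop("coordinate arrays must be complete L x 3 matrices", call. = FALSE)
  }
  if (is.null(resno)) resno <- seq_len(L)
  s <- structure(list(sequence = sequence, L = L, n = n, ca = ca, c = c,
                      cb = cb, chain_id = chain_id, resno = resno),
                 class = "backbone_structure")
  if (L >= 2) {
    dd <- sqrt(rowSums((ca[-1, , drop = FALSE] - ca[-L, , drop = FALSE]) ^ 2))
    if (any(dd <= 2.0 | dd >= 4.5))
      warning("consecutive CA-CA distances outside (2.0, 4.5) Angstrom; ",
              "structure may not be physically plausible", call. = FALSE)
  }
  s
}

#' @export
print.backbone_structure <- function(x, ...) {
  cat(sprintf("<backbone_structure> chain %s, %d residues\n", x$chain_id, x$L))
  invisible(x)
}

#' Ideal virtual C-beta position
#'
#' Places CB from the backbone N/CA/C atoms using fixed internal coordinates:
#' bond CA-CB 1.522 Angstrom, angle N-CA-CB 110.4 degrees, dihedral
#' C-N-CA-CB -122.5 degrees. Used for glycine (which has no CB) and to
#' replace corrupt file CB atoms.
#'
#' @param n,ca,c length-3 numeric vectors (Angstrom).
#' @return length-3 numeric vector: the CB position.
#' @export
virtual_cb <- function(n, ca, c) {
  nerf_place(c, n, ca, .CB_BOND, .CB_ANGLE, .CB_TORSION)
}

#' Convert a backbone structure to 6D template features
#'
#' Computes, for every residue pair, the CB-CB distance and the omega/theta
#' dihedrals and phi planar angle, plus a validity mask which is TRUE iff the
#' CB-CB distance is at most \code{cutoff} (inclusive boundary). Pairs beyond
#' the cutoff carry sentinel values: distance set to \code{cutoff}, all three
#' angles 0. The diagonal has distance 0, mask TRUE and angles 0.
#'
#' @param s a \code{backbone_structure}.
#' @param cutoff pair validity cutoff in Angstrom (default 20).
#' @return an object of class \code{template_features} with fields
#'   \code{L, sequence, dist, omega, theta, phi, mask, cutoff}.
#' @export
coords_to_features <- function(s, cutoff = 20) {
  stopifnot(inherits(s, "backbone_structure"))
  L <- s$L
  if (L < 3) stop("structure too short to featurize (need L >= 3)", call. = FALSE)
  idx <- expand.grid(i = seq_len(L), j = seq_len(L))
  i <- idx$i; j <- idx$j
  CBi <- s$cb[i, , drop = FALSE]; CBj <- s$cb[j, , drop = FALSE]
  CAi <- s$ca[i, , drop = FALSE]; CAj <- s$ca[j, , drop = FALSE]
  Ni <- s$n[i, , drop = FALSE]
  d <- sqrt(rdot(CBi - CBj, CBi - CBj))
  off <- i != j
  omega <- theta <- phi <- numeric(L * L)
  omega[off] <- dihedral_rows(CAi[off, , drop = FALSE], CBi[off, , drop = FALSE],
                              CBj[off, , drop = FALSE], CAj[off, , drop = FALSE])
  theta[off] <- dihedral_rows(Ni[off, , drop = FALSE], CAi[off, , drop = FALSE],
                              CBi[off, , drop = FALSE], CBj[off, , drop = FALSE])
  phi[off] <- planar_rows(CAi[off, , drop = FALSE], CBi[off, , drop = FALSE],
                          CBj[off, , drop = FALSE])
  dist <- matrix(d, L, L)
  mask <- dist <= cutoff
  diag(mask) <- TRUE
  omega <- matrix(omega, L, L); theta <- matrix(theta, L, L); phi <- matrix(phi, L, L)
  # sentinel for invalid pairs
  dist[!mask] <- cutoff
  omega[!mask] <- 0; theta[!mask] <- 0; phi[!mask] <- 0
  template_features(L = L, sequence = s$sequence, dist = dist, omega = omega,
                    theta = theta, phi = phi, mask = mask, cutoff = cutoff)
}

#' Template feature map constructor
#'
#' Low-level constructor; checks shapes and (loosely) ranges. Prefer
#' \code{\link{coords_to_features}}.
#'
#' @param L residue count.
#' @param sequence one-letter sequence string (length L).
#' @param dist,omega,theta,phi L x L numeric matrices (Angstrom / radians).
#' @param mask L x L logical matrix.
#' @param cutoff validity cutoff in Angstrom.
#' @return object of class \code{template_features}.
#' @export
template_features <- function(L, sequence, dist, omega, theta, phi, mask,
                              cutoff = 20) {
  for (m in list(dist, omega, theta, phi, mask))
    if (!all(dim(m) == c(L, L))) stop("feature channel has wrong shape", call. = FALSE)
  structure(list(L = L, sequence = sequence, dist = dist, omega = omega,
                 theta = theta, phi = phi, mask = mask, cutoff = cutoff),
            class = "template_features")
}

#' @export
print.template_features <- function(x, ...) {
  cat(sprintf("<template_features> L=%d, cutoff=%.1f A, %.1f%% pairs valid\n",
              x$L, x$cutoff, 100 * mean(x$mask)))
  invisible(x)
}

#' Extract the CB-CB distance channel
#'
#' Returns the raw distance matrix of a feature map; pairs outside the mask
#' carry the sentinel value (the cutoff).
#'
#' @param f a \code{template_features} object.
#' @return L x L numeric matrix (Angstrom).
#' @export
features_to_distance_matrix <- function(f) {
  stopifnot(inherits(f, "template_features"))
  f$dist
}

#' Serialize / load a template feature map
#'
#' Feature maps are stored as a single RDS container holding the five
#' channels (dist/omega/theta/phi/mask), the sequence string and the cutoff.
#'
#' @param f a \code{template_features} object.
#' @param path file path.
#' @return \code{save_features} returns \code{path} invisibly;
#'   \code{load_features} returns the feature map.
#' @export
save_features <- function(f, path) {
  stopifnot(inherits(f, "template_features"))
  saveRDS(unclass(f), path)
  invisible(path)
}

#' @rdname save_features
#' @export
load_features <- function(path) {
  x <- readRDS(path)
  template_features(x$L, x$sequence, x$dist, x$omega, x$theta, x$phi, x$mask,
                    x$cutoff)
}
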