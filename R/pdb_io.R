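# PDB input/output, via bio3d. Only backbone N/CA/C/CB atoms are retained;
# HETATM records are ignored except by read_ligand_pdb().

#' Read a backbone structure from a PDB file
#'
#' Retains one chain and the N/CA/C/CB atoms of its ATOM records. Residues
#' missing any of N, CA or C are dropped with a warning. The CB atom is taken
#' from the file when present and geometrically sane (|CB-CA| within 0.3
#' Angstrom of the ideal 1.522); otherwise (glycine, corrupt atoms) a virtual
#' CB is constructed from N/CA/C.
#'
#' @param path PDB file path.
#' @param chain chain identifier (default "A").
#' @return a \code{\link{backbone_structure}}.
#' @export
read_pdb <- function(path, chain = "A") {
  if (!file.exists(path)) stop("PDB file not found: ", path, call. = FALSE)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM" & at$chain == chain, , drop = FALSE]
  if (nrow(at) == 0) stop("chain '", chain, "' not found or empty", call. = FALSE)
  # first altloc only
  at <- at[at$alt %in% c("", " ", NA, "A"), , drop = FALSE]
  key <- paste(at$resno, at$insert %||% "", sep = "_")
  res_keys <- unique(key)
  rows_n <- rows_ca <- rows_c <- rows_cb <- rep(NA_integer_, length(res_keys))
  for (k in seq_along(res_keys)) {
    rr <- which(key == res_keys[k])
    el <- at$elety[rr]
    rows_n[k] <- rr[match("N", el)]
    rows_ca[k] <- rr[match("CA", el)]
    rows_c[k] <- rr[match("C", el)]
    rows_cb[k] <- rr[match("CB", el)]
  }
  ok <- !is.na(rows_n) & !is.na(rows_ca) & !is.na(rows_c)
  if (any(!ok))
    warning(sum(!ok), " residue(s) dropped: missing N/CA/C backbone atoms",
            call. = FALSE)
  if (!any(ok)) stop("no complete residues after filtering", call. = FALSE)
  rows_n <- rows_n[ok]; rows_ca <- rows_ca[ok]; rows_c <- rows_c[ok]
  rows_cb <- rows_cb[ok]
  xyz <- function(rows) unname(as.matrix(at[rows, c("x", "y", "z")]))
  n <- xyz(rows_n); ca <- xyz(rows_ca); c3 <- xyz(rows_c)
  L <- nrow(ca)
  cb <- matrix(NA_real_, L, 3)
  has_cb <- !is.na(rows_cb)
  cb[has_cb, ] <- unname(as.matrix(at[rows_cb[has_cb], c("x", "y", "z")]))
  for (i in seq_len(L)) {
    bad <- !has_cb[i] ||
      abs(vnorm(cb[i, ] - ca[i, ]) - .CB_BOND) > 0.3
    if (bad) cb[i, ] <- virtual_cb(n[i, ], ca[i, ], c3[i, ])
  }
  res3 <- at$resid[rows_ca]
  seq1 <- bio3d::aa321(res3)
  seq1[is.na(seq1) | seq1 == ""] <- "X"
  backbone_structure(paste(seq1, collapse = ""), n, ca, c3, cb,
                     chain_id = chain, resno = at$resno[rows_ca])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a backbone structure to a PDB file
#'
#' Emits ATOM records for the N, CA, C and CB atoms of every residue.
#'
#' @param s a \code{backbone_structure}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_backbone_pdb <- function(s, path) {
  stopifnot(inherits(s, "backbone_structure"))
  L <- s$L
  aa3 <- bio3d::aa123(strsplit(s$sequence, "")[[1]])
  aa3[is.na(aa3)] <- "ALA"
  xyz <- matrix(NA_real_, 4 * L, 3)
  xyz[seq(1, 4 * L, 4), ] <- s$n
  xyz[seq(2, 4 * L, 4), ] <- s$ca
  xyz[seq(3, 4 * L, 4), ] <- s$c
  xyz[seq(4, 4 * L, 4), ] <- s$cb
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(xyz)),
                   resno = rep(s$resno, each = 4),
                   resid = rep(aa3, each = 4),
                   elety = rep(c("N", "CA", "C", "CB"), L),
                   chain = rep(s$chain_id, 4 * L),
                   eleno = seq_len(4 * L))
  invisible(path)
}

#' Read ligand heavy-atom coordinates from PDB HETATM records
#'
#' @param path PDB file path.
#' @param resid optional HETATM residue name filter (e.g. a ligand code).
#' @return m x 3 matrix of ligand atom coordinates (Angstrom).
#' @export
read_ligand_pdb <- function(path, resid = NULL) {
  if (!file.exists(path)) stop("PDB file not found: ", path, call. = FALSE)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom[pdb$atom$type == "HETATM", , drop = FALSE]
  if (!is.null(resid)) at <- at[at$resid %in% resid, , drop = FALSE]
  at <- at[!at$resid %in% c("HOH", "WAT"), , drop = FALSE]
  if (nrow(at) == 0) stop("no ligand HETATM records found", call. = FALSE)
  unname(as.matrix(at[, c("x", "y", "z")]))
}
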