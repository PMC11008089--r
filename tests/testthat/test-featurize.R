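# A 3-residue hand-written PDB fixture (ideal-ish alanine coordinates).
pdb_fixture_lines <- c(
  "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
  "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
  "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C",
  "ATOM      4  CB  ALA A   1       1.988  -0.773  -1.199  1.00  0.00           C",
  "ATOM      5  N   ALA A   2       3.332   1.536   0.000  1.00  0.00           N",
  "ATOM      6  CA  ALA A   2       4.042   2.803   0.110  1.00  0.00           C",
  "ATOM      7  C   ALA A   2       5.520   2.600   0.390  1.00  0.00           C",
  "ATOM      8  CB  ALA A   2       3.880   3.650  -1.150  1.00  0.00           C",
  "ATOM      9  N   GLY A   3       6.250   3.690   0.420  1.00  0.00           N",
  "ATOM     10  CA  GLY A   3       7.680   3.680   0.680  1.00  0.00           C",
  "ATOM     11  C   GLY A   3       8.420   4.890   0.160  1.00  0.00           C",
  "END")

write_pdb_fixture <- function(lines = pdb_fixture_lines) {
  path <- tempfile(fileext = ".pdb")
  writeLines(lines, path)
  path
}

test_that("read_pdb returns the fixture coordinates verbatim", {
  s <- read_pdb(write_pdb_fixture(), chain = "A")
  expect_s3_class(s, "backbone_structure")
  expect_equal(s$L, 3L)
  expect_equal(s$sequence, "AAG")
  expect_equal(s$ca[1, ], c(1.458, 0, 0))
  expect_equal(s$n[2, ], c(3.332, 1.536, 0))
  expect_equal(s$cb[1, ], c(1.988, -0.773, -1.199))
})

test_that("read_pdb drops residues missing backbone atoms, with a warning", {
  lines <- pdb_fixture_lines[-6]            # remove CA of residue 2
  w <- testthat::capture_warnings(s <- read_pdb(write_pdb_fixture(lines),
                                                chain = "A"))
  expect_true(any(grepl("dropped", w)))
  expect_equal(s$L, 2L)
  expect_equal(s$sequence, "AG")
})

test_that("glycine without CB gets a virtual CB matching the ideal construction", {
  s <- read_pdb(write_pdb_fixture(), chain = "A")
  # residue 3 is GLY with no CB in the file
  expect_false(anyNA(s$cb[3, ]))
  oracle <- nerf_oracle(s$c[3, ], s$n[3, ], s$ca[3, ],
                        1.522, 110.4 * pi / 180, -122.5 * pi / 180)
  expect_equal(s$cb[3, ], oracle, tolerance = 1e-6)
})

test_that("read_pdb error conditions are distinct", {
  expect_error(read_pdb(tempfile(fileext = ".pdb")), "not found")
  expect_error(read_pdb(write_pdb_fixture(), chain = "Q"), "chain")
})

test_that("virtual_cb honors its internal-coordinate contract", {
  s <- make_toy_crystal(6, 12)
  cb <- virtual_cb(s$n[2, ], s$ca[2, ], s$c[2, ])
  expect_equal(vnorm(cb - s$ca[2, ]), 1.522, tolerance = 1e-10)
  # equivariance under rigid motion
  R <- random_rotation(5); tr <- c(4, -2, 9)
  move <- function(x) as.numeric(R %*% x + tr)
  cb2 <- virtual_cb(move(s$n[2, ]), move(s$ca[2, ]), move(s$c[2, ]))
  expect_equal(cb2, move(cb), tolerance = 1e-9)
  # NeRF brute-force oracle
  oracle <- nerf_oracle(s$c[2, ], s$n[2, ], s$ca[2, ],
                        1.522, 110.4 * pi / 180, -122.5 * pi / 180)
  expect_equal(cb, oracle, tolerance = 1e-6)
  expect_error(virtual_cb(c(0, 0, 0), c(1, 0, 0), c(0.5, 0, 0)),
               "collinear|degenerate")
})

test_that("coords_to_features satisfies the feature-map invariants", {
  for (seed in 1:4) {
    s <- random_backbone(L = 14, seed = seed)
    f <- coords_to_features(s)
    expect_equal(f$dist, t(f$dist))
    expect_equal(diag(f$dist), rep(0, f$L))
    expect_equal(f$omega, t(f$omega), tolerance = 1e-12)
    expect_equal(f$mask, t(f$mask))
    expect_true(all(f$mask == (f$dist <= f$cutoff) | !f$mask))
    expect_true(all(diag(f$mask)))
    expect_true(all(f$omega > -pi & f$omega <= pi))
    expect_true(all(f$theta > -pi & f$theta <= pi))
    expect_true(all(f$phi >= 0 & f$phi <= pi))
    # sentinel contract on masked-out pairs
    expect_true(all(f$dist[!f$mask] == f$cutoff))
    expect_true(all(f$omega[!f$mask] == 0))
  }
})

test_that("the 20 Angstrom boundary is inclusive", {
  # duplicate a 3-residue fragment, translated so CB_1-CB_4 is exactly 20.0
  base <- make_toy_crystal(3, 0)
  tr <- c(20, 0, 0)
  shift <- function(m) sweep(m, 2, tr, "+")
  s2 <- suppressWarnings(backbone_structure(
    paste0(base$sequence, base$sequence),
    rbind(base$n, shift(base$n)), rbind(base$ca, shift(base$ca)),
    rbind(base$c, shift(base$c)), rbind(base$cb, shift(base$cb))))
  f <- coords_to_features(s2)
  expect_equal(f$dist[1, 4], 20)
  expect_true(f$mask[1, 4])
})

test_that("orientation angles agree with the brute-force oracle", {
  s <- random_backbone(L = 4, seed = 9)
  f <- coords_to_features(s)
  for (i in 1:4) for (j in 1:4) {
    if (i == j || !f$mask[i, j]) next
    expect_equal(f$omega[i, j],
                 dihedral_oracle(s$ca[i, ], s$cb[i, ], s$cb[j, ], s$ca[j, ]),
                 tolerance = 1e-9)
    expect_equal(f$theta[i, j],
                 dihedral_oracle(s$n[i, ], s$ca[i, ], s$cb[i, ], s$cb[j, ]),
                 tolerance = 1e-9)
    u <- s$ca[i, ] - s$cb[i, ]; v <- s$cb[j, ] - s$cb[i, ]
    expect_equal(f$phi[i, j],
                 acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))),
                 tolerance = 1e-9)
  }
})

test_that("features_to_distance_matrix returns CB distances and sentinels", {
  s <- random_backbone(L = 10, seed = 2)
  f <- coords_to_features(s)
  d <- features_to_distance_matrix(f)
  direct <- as.matrix(dist(s$cb))
  expect_equal(d[f$mask], direct[f$mask], tolerance = 1e-9)
  expect_true(all(d[!f$mask] == f$cutoff))
})

test_that("too-short structures are rejected", {
  s <- make_toy_crystal(3, 0)
  two <- backbone_structure(substr(s$sequence, 1, 2), s$n[1:2, ], s$ca[1:2, ],
                            s$c[1:2, ], s$cb[1:2, ])
  expect_error(coords_to_features(two), "short")
})

test_that("features are invariant under rigid motion and flag mirrors", {
  s <- random_backbone(L = 10, seed = 21)
  f <- coords_to_features(s)
  R <- random_rotation(22); tr <- c(5, 6, -7)
  move <- function(m) sweep(m %*% t(R), 2, tr, "+")
  s_mov <- backbone_structure(s$sequence, move(s$n), move(s$ca), move(s$c),
                              move(s$cb))
  f_mov <- coords_to_features(s_mov)
  for (ch in c("dist", "omega", "theta", "phi"))
    expect_equal(f_mov[[ch]], f[[ch]], tolerance = 1e-6)
  # mirror image: distances unchanged, dihedrals flip sign somewhere
  mir <- function(m) m %*% diag(c(1, 1, -1))
  s_mir <- backbone_structure(s$sequence, mir(s$n), mir(s$ca), mir(s$c),
                              mir(s$cb))
  f_mir <- coords_to_features(s_mir)
  expect_equal(f_mir$dist, f$dist, tolerance = 1e-9)
  off <- which(f$mask & abs(f$omega) > 0.1, arr.ind = TRUE)
  expect_gt(nrow(off), 0)
  expect_equal(f_mir$omega[off], -f$omega[off], tolerance = 1e-9)
})

test_that("feature maps round-trip through disk serialization", {
  f <- coords_to_features(random_backbone(L = 8, seed = 4))
  path <- tempfile(fileext = ".rds")
  save_features(f, path)
  g <- load_features(path)
  expect_equal(unclass(g), unclass(f))
})

test_that("backbone PDB writing round-trips through read_pdb", {
  s <- make_toy_crystal(8, 15)
  path <- tempfile(fileext = ".pdb")
  write_backbone_pdb(s, path)
  s2 <- read_pdb(path, chain = "A")
  expect_equal(s2$L, s$L)
  expect_equal(s2$ca, s$ca, tolerance = 1e-3, ignore_attr = TRUE)
  expect_equal(s2$cb, s$cb, tolerance = 0.35, ignore_attr = TRUE)  # CB re-idealized on read
})
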