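test_that("a hand-written PDB parses with exact coordinates", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00  0.00           C",
    "ATOM      3  C   ALA A   1      10.674   5.272  -4.262  1.00  0.00           C",
    "END"), path)
  st <- read_structure(path)
  expect_equal(nrow(st$atoms), 3)
  expect_equal(st$atoms$x, c(11.104, 11.639, 10.674))
  expect_equal(st$atoms$element, c("N", "C", "C"))
  expect_equal(st$n_models, 1)
})

test_that("multi-model files become trajectory frames", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "MODEL        1",
    "ATOM      1  CA  GLY A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  GLY A   2       3.000   4.000   0.000  1.00  0.00           C",
    "ENDMDL",
    "MODEL        2",
    "ATOM      1  CA  GLY A   1       1.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  GLY A   2       4.000   4.000   0.000  1.00  0.00           C",
    "ENDMDL",
    "END"), path)
  st <- read_structure(path)
  expect_equal(st$n_models, 2)
  expect_equal(structure_coords(st, 2)[1, 1], 1.0)
})

test_that("alternate locations resolve to the highest occupancy", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AGLY A   1       0.000   0.000   0.000  0.40  0.00           C",
    "ATOM      2  CA BGLY A   1       2.000   0.000   0.000  0.60  0.00           C",
    "END"), path)
  st <- read_structure(path)
  expect_equal(nrow(st$atoms), 1)
  expect_equal(st$atoms$x, 2.0)
})

test_that("unparseable coordinates fail with the offending line number", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  GLY A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  GLY A   2       xx.000   4.000   0.000  1.00  0.00           C"),
    path)
  expect_error(read_structure(path), "line 2")
})

test_that("the toy calyx round-trips through PDB at coordinate precision", {
  st <- make_toy_calyx(cavity_radius = 3, cavity_depth = 6)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure(st, path)
  back <- read_structure(path)
  expect_equal(nrow(back$atoms), nrow(st$atoms))
  expect_equal(back$atoms$x, st$atoms$x, tolerance = 1e-3)
  expect_equal(back$atoms$y, st$atoms$y, tolerance = 1e-3)
  expect_equal(back$atoms$z, st$atoms$z, tolerance = 1e-3)
  expect_equal(back$atoms$resno, st$atoms$resno)
})

test_that("unknown elements get the default radius with a warning", {
  atoms <- data.frame(serial = 1, name = "XX", element = "XQ", resid = "UNK",
                      resno = 1, chain = "A", x = 0, y = 0, z = 0)
  expect_warning(st <- new_structure(atoms), "default radius")
  expect_equal(st$atoms$radius, 1.7)
})

test_that("CA distances match hand geometry and flag missing atoms", {
  xyz <- rbind(c(0, 0, 0), c(3, 4, 0))
  st <- coords_structure(xyz)
  expect_equal(ca_distance(st, 1, 2), 5)
  expect_equal(ca_distance(st, 1, 1), 0)
  st2 <- coords_structure(xyz, name = "CB")
  expect_error(ca_distance(st2, 1, 2), "no CA")
})

test_that("superposition is exact for rigid motions and rejects mirror images", {
  set.seed(31)
  P <- matrix(rnorm(300), ncol = 3)
  R <- random_rotation(2)
  Q <- P %*% t(R) + matrix(c(1, -2, 3), 100, 3, byrow = TRUE)
  r <- superpose_rmsd(P, Q)
  expect_lt(as.numeric(r), 1e-6)
  # mirror image: improper rotations are forbidden, RMSD stays large
  M <- P; M[, 1] <- -M[, 1]
  expect_gt(as.numeric(superpose_rmsd(P, M)), 0.5)
  expect_error(superpose_rmsd(P[1:2, ], Q[1:2, ]), "3 atoms")
  expect_warning(superpose_rmsd(cbind(1:5, 0, 0), cbind(1:5, 0, 0)),
                 "collinear")
})

test_that("single displaced atom gives the closed-form RMSD and matches bio3d", {
  set.seed(7)
  P <- matrix(rnorm(300), ncol = 3)
  Q <- P
  Q[5, ] <- Q[5, ] + c(1, 0, 0)
  r <- as.numeric(superpose_rmsd(P, Q))
  # optimal translation spreads a single 1 A displacement over n atoms:
  # rmsd = d sqrt(n - 1) / n, approximately d/sqrt(n) = 0.1
  expect_equal(r, 0.1, tolerance = 0.05)
  # bio3d::rmsd rounds its result to three decimals
  ref <- bio3d::rmsd(as.vector(t(P)), as.vector(t(Q)), fit = TRUE)
  expect_equal(r, ref, tolerance = 5e-3)
})

test_that("windowed RMSF is zero for static trajectories and d for a square-wave atom", {
  n <- 100
  set.seed(13)
  base <- matrix(rnorm(3 * n, sd = 5), ncol = 3)
  frames <- 8
  xyz <- t(vapply(seq_len(frames), function(m) {
    co <- base
    co[1, 1] <- co[1, 1] + ifelse(m %% 2 == 0, 0.5, -0.5)
    as.vector(t(co))
  }, numeric(3 * n)))
  atoms <- data.frame(serial = seq_len(n), name = "CA", element = "C",
                      resid = "GLY", resno = seq_len(n), chain = "A",
                      x = base[, 1], y = base[, 2], z = base[, 3])
  st <- new_structure(atoms, xyz = xyz)
  out <- windowed_rmsf(st, n_windows = 2)
  expect_equal(out$rmsf_mean[1], 0.5, tolerance = 0.02)
  expect_true(all(out$rmsf_mean[-1] < 0.02))
  # static trajectory: exactly zero everywhere, SE zero for one window
  stat <- new_structure(atoms, xyz = xyz[c(1, 1, 1), ])
  out2 <- windowed_rmsf(stat, n_windows = 1)
  expect_true(all(out2$rmsf_mean < 1e-10))
  expect_true(all(out2$rmsf_se == 0))
  expect_error(windowed_rmsf(stat, n_windows = 10), "windows")
})

test_that("hydrogen-bond occupancy follows the distance/angle criteria", {
  mk_frame <- function(acc_x) c(0, 0, 0, 1, 0, 0, acc_x, 0, 0)
  atoms <- data.frame(serial = 1:3, name = c("N", "H", "O"),
                      element = c("N", "H", "O"), resid = "GLY",
                      resno = c(1, 1, 2), chain = "A",
                      x = c(0, 1, 2.8), y = 0, z = 0)
  # 10 frames: bond present (2.8 A, 180 deg) in 9, broken (5 A) in 1
  xyz <- t(vapply(1:10, function(m) mk_frame(if (m == 10) 5 else 2.8),
                  numeric(9)))
  st <- new_structure(atoms, xyz = xyz)
  out <- hbond_occupancy(st, donors = 1, acceptors = 3,
                         hydrogens = list(2))
  expect_equal(out$occupancy_pct, 90)
  # all-frames bond and never-bonded pair
  st_on <- new_structure(atoms, xyz = xyz[1:9, , drop = FALSE])
  expect_equal(hbond_occupancy(st_on, 1, 3, list(2))$occupancy_pct, 100)
  far <- atoms; far$x[3] <- 4.2
  st_far <- new_structure(far)
  expect_equal(hbond_occupancy(st_far, 1, 3, list(2))$occupancy_pct, 0)
  # bent geometry fails the angle criterion even at short distance
  bent <- atoms; bent$x[2] <- 0; bent$y[2] <- 1
  st_bent <- new_structure(bent)
  expect_equal(hbond_occupancy(st_bent, 1, 3, list(2))$occupancy_pct, 0)
  # distance-only fallback without hydrogens
  expect_equal(hbond_occupancy(st_bent, 1, 3)$occupancy_pct, 100)
  expect_error(hbond_occupancy(st, integer(0), 3), "empty")
})
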