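test_that("designed residue force means are recovered within 2%", {
  fx <- make_pairforce_fixture(c(R98 = 120, W100 = 90, L84 = 10),
                               n_frames = 1e4, seed = 8)
  prof <- aggregate_residue_profile(fx$records, fx$ligand_atoms,
                                    fx$atom_residues)
  got <- setNames(prof$mean_force_pN, prof$residue)[names(fx$designed_means)]
  expect_equal(unname(got), unname(fx$designed_means), tolerance = 0.02)
})

test_that("a single unit pair force converts to 1.66054 pN", {
  rec <- data.frame(frame = 1, atom_i = 1, atom_j = 10,
                    fx = 1, fy = 0, fz = 0)
  prof <- aggregate_residue_profile(rec, ligand_atoms = 1,
                                    atom_residues = c("10" = "R98"))
  expect_equal(prof$mean_force_pN, 1.66054)
})

test_that("zero-noise single-frame fixtures are recovered exactly", {
  fx <- make_pairforce_fixture(c(A = 50, B = 20), n_frames = 1,
                               noise_sd = 0, seed = 3)
  prof <- aggregate_residue_profile(fx$records, fx$ligand_atoms,
                                    fx$atom_residues)
  got <- setNames(prof$mean_force_pN, prof$residue)
  expect_equal(got[["A"]], 50, tolerance = 1e-10)
  expect_equal(got[["B"]], 20, tolerance = 1e-10)
})

test_that("aggregation is antisymmetric, permutation invariant and linear", {
  fx <- make_pairforce_fixture(c(A = 80, B = 30), n_frames = 50, seed = 12)
  prof <- aggregate_residue_profile(fx$records, fx$ligand_atoms,
                                    fx$atom_residues)
  # swapping i/j with negated forces is the same physical record set
  swapped <- fx$records
  swapped[, c("atom_i", "atom_j")] <- swapped[, c("atom_j", "atom_i")]
  swapped[, c("fx", "fy", "fz")] <- -swapped[, c("fx", "fy", "fz")]
  prof_sw <- aggregate_residue_profile(swapped, fx$ligand_atoms,
                                       fx$atom_residues)
  expect_identical(prof$mean_force_pN, prof_sw$mean_force_pN)
  # record order is irrelevant
  perm <- fx$records[sample.int(nrow(fx$records)), ]
  prof_pm <- aggregate_residue_profile(perm, fx$ligand_atoms,
                                       fx$atom_residues)
  expect_identical(prof$mean_force_pN, prof_pm$mean_force_pN)
  # linearity in the forces
  scaled <- fx$records
  scaled[, c("fx", "fy", "fz")] <- 3 * scaled[, c("fx", "fy", "fz")]
  prof_sc <- aggregate_residue_profile(scaled, fx$ligand_atoms,
                                       fx$atom_residues)
  expect_equal(prof_sc$mean_force_pN, 3 * prof$mean_force_pN,
               tolerance = 1e-12)
})

test_that("unmapped atoms are reported by id", {
  rec <- data.frame(frame = 1, atom_i = 1, atom_j = 99,
                    fx = 1, fy = 0, fz = 0)
  expect_error(aggregate_residue_profile(rec, 1, c("10" = "R98")), "99")
})

test_that("key-residue selection uses a strict threshold and descending order", {
  fx <- make_pairforce_fixture(c(R98 = 120, W100 = 90, L84 = 10),
                               n_frames = 1, noise_sd = 0, seed = 1)
  prof <- aggregate_residue_profile(fx$records, fx$ligand_atoms,
                                    fx$atom_residues)
  expect_equal(select_key_residues(prof, 70), c("R98", "W100"))
  expect_equal(select_key_residues(prof, 40), c("R98", "W100"))
  # strictly greater: a residue exactly at the threshold is excluded
  expect_equal(select_key_residues(prof, 120), character(0))
  expect_equal(select_key_residues(prof, 5), c("R98", "W100", "L84"))
  zero <- prof; zero$mean_force_pN <- 0
  expect_equal(select_key_residues(zero, 0), character(0))
})

test_that("profile differencing flags markedly increased residues", {
  mk <- function(means, src) {
    fx <- make_pairforce_fixture(means, n_frames = 1, noise_sd = 0, seed = 2)
    aggregate_residue_profile(fx$records, fx$ligand_atoms, fx$atom_residues,
                              source = src)
  }
  pull <- mk(c(T62 = 60, R98 = 45), "pulling")
  eq <- mk(c(T62 = 10, R98 = 40), "equilibrium")
  out <- diff_profiles(pull, eq, abs_floor = 40, ratio = 2)
  expect_equal(out$residue, "T62")
  # identical profiles flag nothing
  expect_equal(nrow(diff_profiles(pull, pull, 40, 2)), 0L)
  # zero equilibrium force counts as infinite ratio
  pull2 <- mk(c(NEW = 50), "pulling")
  eq2 <- mk(c(OTHER = 50), "equilibrium")
  out2 <- diff_profiles(pull2, eq2, 40, 2)
  expect_equal(out2$residue, "NEW")
  expect_true(is.infinite(out2$ratio))
})

test_that("pairwise force records round-trip as TSV including the scalar superset", {
  fx <- make_pairforce_fixture(c(A = 40), n_frames = 5, seed = 6)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pairforce_tsv(fx$records, path)
  back <- read_pairforce_tsv(path)
  expect_equal(back$fx, fx$records$fx, tolerance = 1e-7)
  # scalar signed force column is accepted and expanded
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write.table(data.frame(frame = 1:2, atom_i = 1, atom_j = 10, f = c(1, -1)),
              p2, sep = "\t", row.names = FALSE, quote = FALSE)
  sc <- read_pairforce_tsv(p2)
  expect_equal(sc$fx, c(1, -1))
  expect_equal(sc$fy, c(0, 0))
})
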