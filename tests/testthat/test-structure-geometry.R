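# small in-source PDB exercising altloc, HETATM and insertion codes
fixture_pdb_lines <- c(
  "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
  "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
  "ATOM      3  O   ALA A   1       2.100   1.100   0.000  1.00  0.00           O",
  "ATOM      4  CA AVAL A   2       2.000   2.000   0.000  0.60  0.00           C",
  "ATOM      5  CA BVAL A   2       2.200   2.200   0.000  0.40  0.00           C",
  "ATOM      6  CA  GLY A   2A      3.000   3.000   1.000  1.00  0.00           C",
  "ATOM      7  CA  SER B   1       0.000   5.000   0.000  1.00  0.00           C",
  "ATOM      8  N   SER B   1       0.500   5.500   0.500  1.00  0.00           N",
  "ATOM      9  CA  THR B   2       1.500   6.000   0.000  1.00  0.00           C",
  "HETATM   10  O   HOH A 100       9.000   9.000   9.000  1.00  0.00           O",
  "END")

test_that("PDB reading keeps one Calpha per residue and drops HETATM", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(fixture_pdb_lines, f)
  s <- read_ca_structure(f)
  expect_equal(nrow(s$ca), 5L)               # altloc B dropped, HETATM ignored
  expect_equal(sum(s$ca$chain == "A"), 3L)
  expect_equal(s$ca$x[s$ca$resno == 2 & s$ca$chain == "A" &
                        s$ca$insert == ""], 2.0)    # altloc A kept
  expect_true(any(s$ca$insert == "A"))              # insertion code preserved
  sB <- read_ca_structure(f, chains = "B")
  expect_equal(nrow(sB$ca), 2L)
  # full atoms retained for contact analysis
  expect_true(all(c("N", "O") %in% s$atoms$elesy))
})

test_that("written assemblies read back identically", {
  s <- gen_ring_assembly(5, radius = 25)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_ca_pdb(s, f)
  s2 <- read_ca_structure(f)
  expect_equal(ca_coords(s2), ca_coords(s), tolerance = 1e-3,
               ignore_attr = TRUE)
  expect_equal(s2$ca$chain, s$ca$chain)
})

test_that("Kabsch superposition recovers exact rigid transforms", {
  s <- gen_ring_assembly(6, radius = 30)
  rig <- random_rigid(seed = 8)
  s2 <- s; s2$ca[c("x", "y", "z")] <- apply_rigid(ca_coords(s), rig)
  sup <- kabsch_superpose(s, s2)
  expect_lt(sup$rmsd, 1e-10)
  expect_equal(det(sup$rotation), 1, tolerance = 1e-12)
  expect_equal(crossprod(sup$rotation), diag(3), tolerance = 1e-12,
               ignore_attr = TRUE)
  moved <- apply_transform(s, sup)
  expect_equal(ca_coords(moved), ca_coords(s2), tolerance = 1e-9,
               ignore_attr = TRUE)
  # identity case
  expect_lt(kabsch_superpose(s, s)$rmsd, 1e-12)
})

test_that("Kabsch RMSD matches a brute-force rotation-search oracle", {
  mobile <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  target <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 2))
  rmsd <- kabsch_superpose(mobile, target)$rmsd
  oracle <- random_rotation_rmsd(mobile, target)
  expect_equal(rmsd, oracle, tolerance = 1e-6)
  expect_lte(rmsd, oracle + 1e-9)   # never worse than the search
})

test_that("RMSD is invariant under rigid transforms of both structures", {
  set.seed(31)
  A <- matrix(rnorm(30), ncol = 3)
  B <- A + matrix(rnorm(30, sd = 0.3), ncol = 3)
  base <- kabsch_superpose(A, B)$rmsd
  for (s in 1:5) {
    rig1 <- random_rigid(seed = 100 + s); rig2 <- random_rigid(seed = 200 + s)
    expect_equal(kabsch_superpose(apply_rigid(A, rig1),
                                  apply_rigid(B, rig2))$rmsd,
                 base, tolerance = 1e-9)
  }
  expect_error(kabsch_superpose(A[1:2, ], B[1:2, ]), "3")
})

test_that("displacement field applies the arrow drawing conventions", {
  s <- gen_ring_assembly(4, radius = 20)
  expect_equal(attr(displacement_field(s, s), "n_shown"), 0L)

  shifted <- s; shifted$ca$x <- shifted$ca$x + 3
  d <- displacement_field(s, shifted)
  expect_equal(attr(d, "n_shown"), nrow(s$ca))
  expect_equal(unique(d$dx), 6)             # 3 A shift, scale factor 2
  expect_equal(unique(round(d$length, 10)), 3)

  # mixed shifts: the >= 2 A threshold is inclusive
  mixed <- s
  sh <- rep(c(1, 2, 5), length.out = nrow(s$ca))
  mixed$ca$z <- mixed$ca$z + sh
  dm <- displacement_field(s, mixed)
  expect_equal(attr(dm, "n_shown"), sum(sh >= 2))
  expect_equal(sort(unique(round(dm$length, 10))), c(2, 5))

  # with scale 1 and no threshold, adding the field reconstructs b
  d1 <- displacement_field(s, mixed, scale = 1, min_len = 0)
  rebuilt <- ca_coords(s) + as.matrix(d1[c("dx", "dy", "dz")])
  expect_equal(rebuilt, ca_coords(mixed), ignore_attr = TRUE)

  other <- s; other$ca$chain <- "Z"
  expect_error(displacement_field(s, other), "keys")
})

test_that("ring geometry inverts constructed rings and spirals", {
  hexa <- gen_ring_assembly(6, radius = 50)
  g <- ring_geometry(subunit_centroids(hexa, LETTERS[1:6]))
  expect_equal(g$rotation_deg, 60, tolerance = 1e-6)
  expect_lt(abs(g$rise), 1e-9)
  expect_equal(g$handedness, "closed")
  expect_equal(g$radius, 50, tolerance = 1e-6)
  # rotations around a closed ring sum to 360 degrees
  expect_equal(g$rotation_deg * 6, 360, tolerance = 1e-6)

  # hexagonal screw: 6 subunits per turn, pitch 60 A
  p61 <- gen_ring_assembly(12, radius = 50, twist_deg = 60, rise = 10,
                           handedness = "right")
  gp <- ring_geometry(subunit_centroids(p61, LETTERS[1:12]))
  expect_equal(gp$rotation_deg, 60, tolerance = 1e-6)
  expect_equal(gp$rise, 10, tolerance = 1e-6)
  expect_equal(gp$handedness, "right")

  mir <- gen_ring_assembly(12, radius = 50, twist_deg = 60, rise = 10,
                           handedness = "left")
  gm <- ring_geometry(subunit_centroids(mir, LETTERS[1:12]))
  expect_equal(gm$rotation_deg, 60, tolerance = 1e-6)
  expect_equal(gm$handedness, "left")

  line <- cbind(1:5, 1:5, 1:5)
  expect_error(ring_geometry(line), "collinear")
  expect_error(gen_ring_assembly(2), "at least 3")
})

test_that("polar contacts count cross-interface N/O pairs within cutoff", {
  mk_atoms <- function(offset) {
    data.frame(chain = c("A", "A", "B", "B"),
               resno = c(1, 2, 1, 2), insert = "",
               resid = "SER",
               x = c(0, 0, 3.0 + offset, 3.6 + offset),
               y = 0, z = c(0, 8, 0, 8),
               elety = c("OG", "OG", "N", "N"),
               elesy = c("O", "O", "N", "N"),
               stringsAsFactors = FALSE)
  }
  ca <- data.frame(chain = c("A", "B"), resno = 1, insert = "",
                   resid = "SER", x = c(0, 3), y = 0, z = 0,
                   stringsAsFactors = FALSE)
  intact <- ca_structure(ca, atoms = mk_atoms(0))
  pc <- polar_contacts(intact, "A", "B")
  expect_equal(attr(pc, "n_contacts"), 1L)   # 3.0 A yes, 3.6 A no
  expect_equal(pc$dist, 3.0)

  # cracked interface: all pairs moved +1.5 A -> contacts strictly decrease
  cracked <- ca_structure(ca, atoms = mk_atoms(1.5))
  expect_lt(attr(polar_contacts(cracked, "A", "B"), "n_contacts"),
            attr(pc, "n_contacts"))

  ca_only <- gen_ring_assembly(4, radius = 20)
  expect_error(polar_contacts(ca_only, "A", "B"), "atoms unavailable")
})
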