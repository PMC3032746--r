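test_that("synthetic shapes have the documented topology", {
  s <- makeSyntheticMolecule("single_atom", radius = 1.9)
  expect_equal(nrow(atoms(s)), 1L)
  expect_equal(nrow(bonds(s)), 0L)
  hex <- makeSyntheticMolecule("linear_alkane", n = 6)
  expect_equal(nrow(atoms(hex)), 6L)
  expect_equal(nrow(bonds(hex)), 5L)
  # bond length is preserved by the zigzag geometry
  at <- atoms(hex)
  d12 <- sqrt(sum((at[1, c("x", "y", "z")] - at[2, c("x", "y", "z")])^2))
  expect_equal(d12, 1.54, tolerance = 1e-10)
  ring <- makeSyntheticMolecule("ring", n = 6)
  expect_true(all(bonds(ring)$in_ring))
  dim <- makeSyntheticMolecule("dimer", separation = 5)
  expect_equal(atoms(dim)$x, c(0, 5))
})

test_that("rotatable-bond counting follows the medicinal-chemistry rules", {
  expect_equal(rotatableBondCount(makeSyntheticMolecule("linear_alkane",
                                                        n = 2)), 0L)
  expect_equal(rotatableBondCount(makeSyntheticMolecule("linear_alkane",
                                                        n = 4)), 1L)
  # pentane/hexane: interior C-C bonds only
  expect_equal(rotatableBondCount(makeSyntheticMolecule("linear_alkane",
                                                        n = 5)), 2L)
  expect_equal(rotatableBondCount(makeSyntheticMolecule("linear_alkane",
                                                        n = 6)), 3L)
  expect_equal(rotatableBondCount(makeSyntheticMolecule("ring", n = 6)), 0L)
})

test_that("amide C-N bonds are excluded unless requested", {
  m <- amideMolecule()
  expect_equal(rotatableBondCount(m), 0L)
  expect_equal(rotatableBondCount(m, includeAmides = TRUE), 1L)
})

test_that("hydrogens neither count as bonds nor toward heavy degree", {
  # propane with explicit hydrogens on the middle carbon: still 0 rotatable
  m <- Molecule(
    data.frame(element = c("C", "C", "C", "H", "H"),
               x = c(0, 1.5, 3.0, 1.5, 1.5),
               y = c(0, 0, 0, 1.0, -1.0), z = 0),
    data.frame(a = c(1L, 2L, 2L, 2L), b = c(2L, 3L, 4L, 5L), order = 1L))
  expect_equal(rotatableBondCount(m), 0L)
})

test_that("the count is invariant under atom reordering and rigid motion", {
  base <- makeSyntheticMolecule("linear_alkane", n = 7)
  n0 <- rotatableBondCount(base)
  perm <- withr::with_seed(3, sample(nrow(atoms(base))))
  inv <- order(perm)
  at <- atoms(base)[perm, ]
  bd <- bonds(base)
  bd$a <- inv[bd$a]; bd$b <- inv[bd$b]
  swap <- bd$a > bd$b
  tmp <- bd$a[swap]; bd$a[swap] <- bd$b[swap]; bd$b[swap] <- tmp
  expect_equal(rotatableBondCount(Molecule(at, bd)), n0)
  # rigid rotation + translation
  th <- 0.83
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  at2 <- atoms(base)
  xyz <- as.matrix(at2[, c("x", "y", "z")]) %*% R
  at2$x <- xyz[, 1] + 5; at2$y <- xyz[, 2] - 2; at2$z <- xyz[, 3] + 1
  m2 <- Molecule(at2, bonds(base))
  expect_equal(rotatableBondCount(m2), n0)
  # SASA uses a space-fixed point set, so rigid motion agrees only to the
  # point-set resolution, not exactly
  expect_equal(shrakeRupleySasa(m2)$total, shrakeRupleySasa(base)$total,
               tolerance = 0.01)
})

test_that("Molecule validity rejects malformed tables", {
  at <- data.frame(element = c("C", "C"), x = c(0, 1.5), y = 0, z = 0)
  expect_error(Molecule(at, data.frame(a = 1L, b = 1L, order = 1L)),
               "self-bond")
  expect_error(Molecule(at, data.frame(a = c(1L, 2L), b = c(2L, 1L),
                                       order = 1L)), "duplicate")
  expect_error(Molecule(at, data.frame(a = 1L, b = 3L, order = 1L)),
               "non-existent")
  at$radius <- c(1.7, -1)
  expect_error(Molecule(at), "strictly positive")
})

test_that("ring perception flags exactly the cycle bonds", {
  # cyclohexane with a methyl substituent: 6 ring bonds + 1 chain bond
  ring <- makeSyntheticMolecule("ring", n = 6)
  at <- rbind(atoms(ring),
              data.frame(element = "C", x = 4, y = 0, z = 0, radius = 1.7))
  bd <- bonds(ring)[, c("a", "b", "order")]
  bd <- rbind(bd, data.frame(a = 1L, b = 7L, order = 1L))
  flags <- perceiveRings(7L, bd)
  expect_equal(flags, c(rep(TRUE, 6), FALSE))
})

test_that("V2000 connection tables read back with correct topology", {
  mol_txt <- c(
    "butane", "  fmoscore", "",
    "  4  3  0  0  0  0  0  0  0  0999 V2000",
    "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    1.5400    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    2.3000    1.3000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    3.8400    1.3000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "  1  2  1  0  0  0  0",
    "  2  3  1  0  0  0  0",
    "  3  4  1  0  0  0  0",
    "M  END")
  m <- readMolFile(mol_txt)
  expect_equal(nrow(atoms(m)), 4L)
  expect_equal(atoms(m)$element, rep("C", 4))
  expect_equal(atoms(m)$radius, rep(1.70, 4))
  expect_equal(rotatableBondCount(m), 1L)
  expect_error(readMolFile(mol_txt[1:6]), "truncated")
})

test_that("PDB HETATM records read with distance-based bond perception", {
  pdb <- c(
    "HETATM    1  C1  ETO A   1       0.000   0.000   0.000  1.00  0.00           C",
    "HETATM    2  C2  ETO A   1       1.540   0.000   0.000  1.00  0.00           C",
    "HETATM    3  O1  ETO A   1       2.250   1.200   0.000  1.00  0.00           O")
  m <- readPdbMolecule(pdb)
  expect_equal(atoms(m)$element, c("C", "C", "O"))
  bd <- bonds(m)
  expect_equal(nrow(bd), 2L)   # C1-C2 and C2-O1, not C1-O1
  expect_setequal(paste(bd$a, bd$b), c("1 2", "2 3"))
  expect_error(readPdbMolecule("REMARK nothing"), "no coordinate records")
})
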