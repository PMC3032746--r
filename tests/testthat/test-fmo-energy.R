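twoBody <- function(e1, e2, e12, pie = 0) {
  FmoSystem(
    data.frame(index = 1:2, label = c("A", "B"), energy = c(e1, e2)),
    data.frame(i = 1L, j = 2L, dimer_energy = e12, pie = pie))
}

test_that("total energy reduces correctly in the degenerate cases", {
  one <- FmoSystem(data.frame(index = 1L, label = "A", energy = -10.0))
  expect_equal(totalEnergy(one), -10.0)
  expect_equal(totalEnergy(twoBody(-1, -2, -3.5)), -3.5)
})

test_that("total energy matches a brute-force term-by-term oracle", {
  for (seed in 1:5) {
    gen <- makeSyntheticFmoLog(5, seed = seed)
    expect_equal(totalEnergy(gen$system), refTotalEnergy(gen$system),
                 tolerance = 1e-12)
  }
})

test_that("total energy reduces to the monomer sum in the non-interacting limit", {
  gen <- makeSyntheticFmoLog(6, seed = 2)
  fr <- fmoFragments(gen$system)
  pr <- fmoPairs(gen$system)
  pr$dimer_energy <- fr$energy[pr$i] + fr$energy[pr$j]
  sys <- FmoSystem(fr, pr)
  expect_equal(totalEnergy(sys), sum(fr$energy), tolerance = 1e-10)
})

test_that("a missing dimer energy is an error naming the pair", {
  sys <- twoBody(-1, -2, NA_real_)
  expect_error(totalEnergy(sys), "\\(1,2\\)")
})

test_that("pieSum handles empty, small and generated systems", {
  lone <- FmoSystem(data.frame(index = 1L, label = "A", energy = -1))
  expect_equal(pieSum(lone, 1), 0)
  sys <- FmoSystem(
    data.frame(index = 1:3, label = c("A", "B", "L"), energy = -(1:3)),
    data.frame(i = c(1L, 2L), j = c(3L, 3L), pie = c(-2.5, -1.5)))
  expect_equal(pieSum(sys, 3), -4.0)
  expect_equal(pieSum(sys, 1), -2.5)
  gen <- makeSyntheticFmoLog(20, ligandIndex = 20, seed = 1)
  gt <- sum(with(fmoPairs(gen$system), pie[i == 20 | j == 20]))
  expect_equal(pieSum(gen$system, 20), gt)
  expect_error(pieSum(sys, 9), "invalid fragment index")
})

test_that("summing pieSum over all fragments double-counts every pair", {
  gen <- makeSyntheticFmoLog(9, seed = 4)
  total <- sum(vapply(1:9, function(f) pieSum(gen$system, f), numeric(1)))
  expect_equal(total, 2 * sum(fmoPairs(gen$system)$pie), tolerance = 1e-10)
})

test_that("supermolecule enthalpy applies the Hartree conversion", {
  expect_equal(supermoleculeEnthalpy(-3.5, -1.0, -2.0), -313.75475)
  expect_equal(supermoleculeEnthalpy(-3.0, -1.0, -2.0), 0)
  withr::with_seed(10, {
    for (k in 1:5) {
      v <- rnorm(3)
      expect_equal(supermoleculeEnthalpy(v[1], v[2], v[3]),
                   (v[1] - v[2] - v[3]) * 627.5095, tolerance = 1e-12)
    }
  })
})

test_that("the IFIE map is symmetric, zero-diagonal and consistent with pieSum", {
  empty <- FmoSystem(data.frame(index = 1:3, label = c("A", "B", "C"),
                                energy = -(1:3)))
  expect_equal(ifieMap(empty)$matrix, matrix(0, 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C"))))
  sys <- FmoSystem(
    data.frame(index = 1:3, label = c("A", "B", "L"), energy = -(1:3)),
    data.frame(i = c(1L, 2L), j = c(3L, 3L), pie = c(-2.5, -1.5)),
    ligandIndex = 3L)
  m <- ifieMap(sys)
  expect_equal(m$matrix["A", "L"], -2.5)
  expect_equal(m$matrix["B", "L"], -1.5)
  expect_equal(m$matrix["A", "B"], 0)
  gen <- makeSyntheticFmoLog(12, ligandIndex = 5, seed = 6)
  mg <- ifieMap(gen$system)
  expect_equal(mg$matrix, t(mg$matrix))
  expect_true(all(diag(mg$matrix) == 0))
  expect_equal(sum(mg$matrix[5, ]), pieSum(gen$system, 5),
               tolerance = 1e-10)
  # ranking is ascending (most stabilising partner first)
  expect_false(is.unsorted(mg$ranking$pie))
})

test_that("IFIE map and ranking export to CSV", {
  gen <- makeSyntheticFmoLog(4, ligandIndex = 4, seed = 2)
  mf <- tempfile(fileext = ".csv"); rf <- tempfile(fileext = ".csv")
  writeIfieMap(gen$system, mf, rf)
  m <- as.matrix(read.csv(mf, row.names = 1))
  expect_equal(unname(m), unname(ifieMap(gen$system)$matrix),
               tolerance = 1e-6)
  rk <- read.csv(rf)
  expect_equal(nrow(rk), 3L)
})
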