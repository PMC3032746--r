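# Independent oracles used across the suite. Each deliberately re-derives
# the quantity by the most naive route available so it shares no code with
# the implementation it checks.

# SASA by dense random sampling on each expanded sphere.
refSasaBruteForce <- function(mol, probe = 1.4, nPerAtom = 100000L,
                              seed = 99L) {
  at <- atoms(mol)
  xyz <- as.matrix(at[, c("x", "y", "z")])
  R <- at$radius + probe
  n <- nrow(at)
  withr::with_seed(seed, {
    total <- 0
    per <- numeric(n)
    for (i in seq_len(n)) {
      v <- matrix(rnorm(3 * nPerAtom), ncol = 3)
      v <- v / sqrt(rowSums(v^2))
      pts <- sweep(v * R[i], 2, xyz[i, ], "+")
      exposed <- rep(TRUE, nPerAtom)
      for (j in seq_len(n)[-i]) {
        d2 <- (pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 +
              (pts[, 3] - xyz[j, 3])^2
        exposed <- exposed & d2 >= R[j]^2
      }
      per[i] <- mean(exposed) * 4 * pi * R[i]^2
    }
    list(perAtom = per, total = sum(per))
  })
}

# Two-body FMO total energy by explicit term-by-term loops.
refTotalEnergy <- function(system) {
  fr <- fmoFragments(system)
  pr <- fmoPairs(system)
  e <- 0
  for (k in seq_len(nrow(fr))) e <- e + fr$energy[k]
  for (k in seq_len(nrow(pr)))
    e <- e + (pr$dimer_energy[k] - fr$energy[pr$i[k]] - fr$energy[pr$j[k]])
  e
}

# A random well-conditioned regression problem.
randomRegression <- function(n, p, sigma = 0.5, seed = 1L) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("x", seq_len(p))))
    beta <- rnorm(p)
    y <- drop(X %*% beta) + rnorm(n, 0, sigma)
    list(X = X, y = y, beta = beta, sigma = sigma)
  })
}

# A small amide-containing chain: C1-C2(=O3)-N4-C5.
amideMolecule <- function() {
  Molecule(
    data.frame(element = c("C", "C", "O", "N", "C"),
               x = c(0, 1.5, 1.9, 2.3, 3.8),
               y = c(0, 0, 1.2, -1.1, -1.1),
               z = 0),
    data.frame(a = c(1L, 2L, 2L, 4L),
               b = c(2L, 3L, 4L, 5L),
               order = c(1L, 2L, 1L, 1L)))
}
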