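# Shared fixtures, built in code.

# Boltzmann constant used throughout the tests (kJ/(mol K)).
kBoltz <- 0.0083145

# Four residues at the corners of a 5 Angstrom square (z = 0), the
# hand-enumerable geometry for the selection-rule tests: with
# min_seq_sep 3 only the pair (1, 4) is sequence-eligible, and its
# distance is 0.5 nm.
squareModel <- function(plddt = rep(95, 4)) {
  xyz <- rbind(c(0, 0, 0), c(0.5, 0, 0), c(0.5, 0.5, 0), c(0, 0.5, 0))
  proteinModel(xyz, plddt = plddt)
}

squarePae <- function(pae14 = 1.0, other = 8) {
  v <- matrix(other, 4, 4)
  diag(v) <- 0
  v[1, 4] <- v[4, 1] <- pae14
  paeMatrix(v)
}

# A deterministic non-symmetric PAE matrix.
asymPae <- function(n = 5, seed = 3) {
  set.seed(seed)
  v <- matrix(runif(n * n, 0.5, 10), n)
  diag(v) <- 0
  paeMatrix(v)
}

# Small random ensemble around a random reference structure.
randomEnsemble <- function(f = 50, n = 5, spread = 0.05, seed = 42) {
  set.seed(seed)
  ref <- matrix(rnorm(n * 3), n)
  coords <- array(NA_real_, c(f, n, 3))
  for (k in seq_len(f))
    coords[k, , ] <- ref + matrix(rnorm(n * 3, sd = spread), n)
  ensemble(coords)
}

# Random rigid rotation matrix.
randomRotation <- function(seed = 1) {
  set.seed(seed)
  qr.Q(qr(matrix(rnorm(9), 3)))
}

# Apply a rigid motion to every frame of an ensemble.
transformEnsemble <- function(ens, rot, shift = c(1, -2, 0.5)) {
  x <- caCoords(ens)
  for (k in seq_len(dim(x)[1]))
    x[k, , ] <- x[k, , ] %*% t(rot) + matrix(shift, dim(x)[2], 3,
                                             byrow = TRUE)
  ensemble(x, weights = frameWeights(ens))
}

# Write a minimal C-alpha PDB with given B-factors; returns the path.
writeTinyPdb <- function(b, path = tempfile(fileext = ".pdb"),
                         dropCaOf = integer(0)) {
  n <- length(b)
  lines <- character(0)
  atom <- 1L
  for (i in seq_len(n)) {
    x <- i * 3.8
    if (!(i %in% dropCaOf)) {
      lines <- c(lines, sprintf(
        "ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
        atom, i, x, 0, 0, 1, b[i]))
      atom <- atom + 1L
    }
    lines <- c(lines, sprintf(
      "ATOM  %5d  CB  ALA A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
      atom, i, x, 1.5, 0, 1, b[i]))
    atom <- atom + 1L
  }
  writeLines(c(lines, "END"), path)
  path
}
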