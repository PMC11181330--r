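#' @include utils.R
NULL

#' Read a coordinate ensemble from a multi-model PDB
#'
#' Reads every MODEL of a multi-model PDB (C-alpha atoms only, in file
#' order) into an [Ensemble-class] in nm.
#'
#' @param path multi-model PDB file.
#' @return an [Ensemble-class] with uniform frame weights.
#' @export
readEnsemble <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  sel <- bio3d::atom.select(pdb, elety = "CA", verbose = FALSE)
  xyz <- pdb$xyz[, sel$xyz, drop = FALSE]
  f <- nrow(xyz)
  n <- ncol(xyz) / 3L
  coords <- array(NA_real_, c(f, n, 3))
  for (k in seq_len(f))
    coords[k, , ] <- matrix(xyz[k, ], ncol = 3, byrow = TRUE) / .ANG_PER_NM
  ensemble(coords)
}

## Frame-wise distances for one residue pair, in nm.
.pairSeries <- function(coords, i, j) {
  d <- coords[, i, , drop = FALSE] - coords[, j, , drop = FALSE]
  sqrt(rowSums(matrix(d, nrow = dim(coords)[1])^2))
}

## Weighted population moments of the full pairwise-distance set, in
## nm. Two passes over the frames (mean first, then central second
## moment) keep the variance numerically clean near zero.
.distanceMoments <- function(ens) {
  x <- ens@coords
  w <- ens@weights
  f <- dim(x)[1]; n <- dim(x)[2]
  m1 <- matrix(0, n, n)
  for (k in seq_len(f))
    m1 <- m1 + w[k] * pairDistances(x[k, , , drop = TRUE])
  v <- matrix(0, n, n)
  for (k in seq_len(f)) {
    dc <- pairDistances(x[k, , , drop = TRUE]) - m1
    v <- v + w[k] * dc * dc
  }
  list(mean = m1, sd = sqrt(v))
}

#' Distance-fluctuation matrix (sigma_d)
#'
#' Entry (i, j) is the weighted population standard deviation
#' (1/sum(w) normalization) of the frame-wise C-alpha i - C-alpha j
#' distance across the ensemble, reported in Angstrom. Being built
#' from internal distances it requires no structural alignment, which
#' makes it robust for multidomain proteins where superposition is
#' ambiguous.
#'
#' @param ens an [Ensemble-class] (at least 2 frames for a nonzero
#'   result).
#' @return symmetric, zero-diagonal N x N matrix in Angstrom.
#' @export
distanceStdMatrix <- function(ens) {
  stopifnot(is(ens, "Ensemble"))
  .distanceMoments(ens)$sd * .ANG_PER_NM
}

#' Mean C-alpha distance matrix
#'
#' Weighted trajectory-mean pairwise distances, the ranking used to
#' pick each residue's nearest neighbours in [residueFlexibility()].
#'
#' @param ens an [Ensemble-class].
#' @return N x N matrix in Angstrom.
#' @export
meanDistanceMatrix <- function(ens) {
  stopifnot(is(ens, "Ensemble"))
  .distanceMoments(ens)$mean * .ANG_PER_NM
}

#' Per-residue flexibility profile (sigma_d,n)
#'
#' For each residue, the mean of its sigma_d entries over the n
#' nearest nonbonded partners, nearest by trajectory-mean distance.
#' "Nonbonded" excludes the residue itself and its sequence neighbours
#' (|i - j| <= 1), whose distances are fixed by bonded geometry. Ties
#' in mean distance are broken toward the smaller residue index.
#' n = 20 is the default operating point: correlation with confidence
#' scores is flat over roughly n = 10-70.
#'
#' @param sigma N x N sigma_d matrix in Angstrom
#'   ([distanceStdMatrix()]).
#' @param meanDist N x N mean-distance matrix in Angstrom
#'   ([meanDistanceMatrix()]).
#' @param n number of neighbours to average over (default 20).
#' @param chain optional per-residue chain ids; the |i - j| <= 1
#'   exclusion applies within a chain only.
#' @return numeric vector of length N, in Angstrom.
#' @export
residueFlexibility <- function(sigma, meanDist, n = 20, chain = NULL) {
  nres <- nrow(sigma)
  stopifnot(ncol(sigma) == nres, all(dim(meanDist) == dim(sigma)), n >= 1)
  if (is.null(chain)) chain <- rep("A", nres)
  out <- numeric(nres)
  for (i in seq_len(nres)) {
    excl <- i
    nb <- which(chain == chain[i] & abs(seq_len(nres) - i) <= 1L)
    eligible <- setdiff(seq_len(nres), union(excl, nb))
    if (length(eligible) < n)
      stop(sprintf("residue %d has only %d eligible partners (n = %d)",
                   i, length(eligible), n))
    ord <- eligible[order(meanDist[i, eligible], eligible)]
    out[i] <- mean(sigma[i, ord[seq_len(n)]])
  }
  out
}

#' Per-frame radius of gyration
#'
#' Unweighted C-alpha radius of gyration of each frame: the root mean
#' squared distance to the frame centroid.
#'
#' @param ens an [Ensemble-class].
#' @return numeric vector of length F, in Angstrom.
#' @export
radiusOfGyration <- function(ens) {
  stopifnot(is(ens, "Ensemble"))
  x <- ens@coords
  vapply(seq_len(dim(x)[1]), function(f) {
    xyz <- x[f, , , drop = TRUE]
    c0 <- colMeans(xyz)
    sqrt(mean(rowSums(sweep(xyz, 2, c0)^2)))
  }, numeric(1)) * .ANG_PER_NM
}

#' Root-mean-square fluctuation per residue
#'
#' RMSF(i) = sqrt(weighted mean over frames of the squared
#' displacement from the mean position). With `align = TRUE` (default)
#' each frame is first rigid-superposed onto the ensemble mean
#' structure (one refinement iteration), the standard treatment before
#' comparing with crystallographic B-factors. Unlike sigma_d,n, RMSF
#' depends on that alignment and is less meaningful for flexible
#' multidomain systems.
#'
#' @param ens an [Ensemble-class] with at least 2 frames.
#' @param align superpose frames onto the ensemble mean first?
#' @return numeric vector of length N, in Angstrom.
#' @export
rmsf <- function(ens, align = TRUE) {
  stopifnot(is(ens, "Ensemble"))
  if (nFrames(ens) < 2L) stop("RMSF needs at least 2 frames")
  w <- ens@weights
  if (align) {
    al <- alignToMean(ens)
    x <- al$coords; m <- al$mean
  } else {
    x <- ens@coords; m <- meanStructureOf(x, w)
  }
  n <- dim(x)[2]
  sq <- sapply(seq_len(dim(x)[1]), function(f)
    rowSums((x[f, , , drop = TRUE] - m)^2))
  sqrt(as.vector(sq %*% w)) * .ANG_PER_NM
}

#' Convert RMSF to a crystallographic B-factor
#'
#' B = (8 pi^2 / 3) RMSF^2, the isotropic harmonic relation used when
#' comparing simulated fluctuations against experimental B-factors.
#'
#' @param rmsfAng RMSF value(s) in Angstrom.
#' @return B-factor(s) in Angstrom^2.
#' @export
bfactorFromRmsf <- function(rmsfAng) (8 * pi^2 / 3) * rmsfAng^2
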