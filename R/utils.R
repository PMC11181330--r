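#' @include AllClasses.R
NULL

## Run code with a locally seeded RNG, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

## All pairwise Euclidean distances of an N x 3 coordinate matrix.
pairDistances <- function(xyz) {
  d <- as.matrix(stats::dist(xyz))
  dimnames(d) <- NULL
  d
}

#' Construct a ProteinModel
#'
#' @param coords N x 3 matrix of C-alpha positions in nm.
#' @param plddt per-residue confidence, 0-100 (default 100).
#' @param chain chain id per residue (default "A").
#' @param resno author residue numbers (default 1..N).
#' @return a [ProteinModel-class].
#' @export
proteinModel <- function(coords, plddt = rep(100, nrow(coords)),
                         chain = rep("A", nrow(coords)),
                         resno = seq_len(nrow(coords))) {
  coords <- as.matrix(coords)
  dimnames(coords) <- NULL
  new("ProteinModel", chain = as.character(chain),
      resno = as.integer(resno), coords = coords,
      plddt = as.numeric(plddt))
}

#' Construct a PaeMatrix
#'
#' @param values square numeric matrix in Angstrom.
#' @param maxPae cap in Angstrom (default 31.75, AlphaFold's cap).
#' @return a [PaeMatrix-class].
#' @export
paeMatrix <- function(values, maxPae = 31.75) {
  values <- as.matrix(values)
  dimnames(values) <- NULL
  new("PaeMatrix", values = values, maxPae = as.numeric(maxPae))
}

#' Construct an Ensemble
#'
#' @param coords F x N x 3 array in nm, or an N x 3 matrix for a
#'   single frame.
#' @param weights optional per-frame weights; default uniform.
#' @return an [Ensemble-class].
#' @export
ensemble <- function(coords, weights = NULL) {
  if (is.matrix(coords)) coords <- array(coords, c(1L, dim(coords)))
  f <- dim(coords)[1]
  if (is.null(weights)) weights <- rep(1 / f, f)
  else {
    if (any(weights < 0) || sum(weights) <= 0)
      stop("frame weights must be non-negative with positive sum")
    weights <- weights / sum(weights)
  }
  new("Ensemble", coords = coords, weights = as.numeric(weights))
}

#' Construct a BuildParams
#'
#' Defaults are the published AF-ENM operating point; see
#' [BuildParams-class].
#'
#' @param cutoffNm cutoff radius in nm (default 0.9).
#' @param plddtMin strict pLDDT gate (default 90).
#' @param minSeqSep minimum within-chain separation (default 3).
#' @param kMin strict force-constant gate in kJ/(mol nm^2) (default 75).
#' @param temperatureK temperature in K (default 310).
#' @param genericK generic force constant (default 500).
#' @param mode "standard", "af_const" or "af_scaled" (default).
#' @return a [BuildParams-class].
#' @export
buildParams <- function(cutoffNm = 0.9, plddtMin = 90, minSeqSep = 3,
                        kMin = 75, temperatureK = 310, genericK = 500,
                        mode = c("af_scaled", "af_const", "standard")) {
  mode <- match.arg(mode)
  new("BuildParams", cutoffNm = as.numeric(cutoffNm),
      plddtMin = as.numeric(plddtMin), minSeqSep = as.integer(minSeqSep),
      kMin = as.numeric(kMin), temperatureK = as.numeric(temperatureK),
      genericK = as.numeric(genericK), mode = mode)
}

## Optimal rigid superposition of `mobile` (N x 3) onto `fixed`,
## delegated to bio3d's least-squares rotation. Used for RMSF, PCA and
## projection alignment.
superpose <- function(mobile, fixed) {
  fit <- bio3d::rot.lsq(xx = as.vector(t(mobile)),
                        yy = as.vector(t(fixed)))
  matrix(fit, ncol = 3, byrow = TRUE)
}

## Align every frame of an F x N x 3 array onto a reference N x 3
## structure; returns the aligned array.
alignFrames <- function(coords, ref) {
  out <- coords
  for (f in seq_len(dim(coords)[1]))
    out[f, , ] <- superpose(coords[f, , , drop = TRUE], ref)
  out
}

## Weighted mean structure of an aligned F x N x 3 array.
meanStructureOf <- function(coords, weights) {
  apply(coords, c(2, 3), function(v) sum(v * weights))
}

## Iteratively align an ensemble to its own mean: mean of raw frames,
## align, recompute mean, align once more (one refinement pass).
alignToMean <- function(ens) {
  x <- ens@coords
  w <- ens@weights
  m <- meanStructureOf(x, w)
  x <- alignFrames(x, m)
  m <- meanStructureOf(x, w)
  x <- alignFrames(x, m)
  list(coords = x, mean = meanStructureOf(x, w))
}
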