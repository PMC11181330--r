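#' @include utils.R
NULL

#' Fit the top-2 principal modes of a reference ensemble
#'
#' Frames are rigid-superposed onto the ensemble mean (one refinement
#' iteration), the 3N x 3N coordinate covariance is formed with frame
#' weights, and its two highest-variance eigenvectors are returned.
#' Sign convention: each component's largest-magnitude loading is made
#' positive, so the basis is deterministic.
#'
#' @param ref an [Ensemble-class] with at least 3 frames.
#' @return a [PcaBasis-class].
#' @export
fitPca <- function(ref) {
  stopifnot(is(ref, "Ensemble"))
  if (nFrames(ref) < 3L) stop("PCA needs at least 3 frames")
  al <- alignToMean(ref)
  f <- dim(al$coords)[1]
  x <- t(vapply(seq_len(f), function(k) as.vector(t(al$coords[k, , ])),
                numeric(3L * dim(al$coords)[2])))
  mu <- as.vector(t(al$mean))
  xc <- sweep(x, 2, mu) * sqrt(ref@weights)
  cov <- crossprod(xc)                 # weighted population covariance
  eig <- eigen(cov, symmetric = TRUE)
  comp <- eig$vectors[, 1:2, drop = FALSE]
  for (k in 1:2) {
    s <- sign(comp[which.max(abs(comp[, k])), k])
    if (s < 0) comp[, k] <- -comp[, k]
  }
  new("PcaBasis", meanStructure = al$mean, components = comp,
      explainedVariance = eig$values[1:2])
}

#' Project an ensemble onto a PCA basis
#'
#' Each frame is rigid-superposed onto the basis mean structure and
#' its centered, flattened coordinates are dotted with the two
#' components. Coarse-grained backbone beads are matched to the basis
#' C-alpha sites by residue index; pass `indexMap` (candidate residue
#' index for each basis residue) when the correspondence is not the
#' identity.
#'
#' @param ens an [Ensemble-class].
#' @param basis a [PcaBasis-class].
#' @param indexMap optional integer vector, length = basis residues.
#' @return F x 2 matrix of scores in nm ("projected cloud").
#' @export
projectEnsemble <- function(ens, basis, indexMap = NULL) {
  stopifnot(is(ens, "Ensemble"), is(basis, "PcaBasis"))
  nb <- nrow(basis@meanStructure)
  if (is.null(indexMap)) {
    if (nResidues(ens) != nb)
      stop(sprintf("ensemble has %d residues but basis expects %d",
                   nResidues(ens), nb))
    indexMap <- seq_len(nb)
  }
  if (length(indexMap) != nb || any(indexMap < 1) ||
      any(indexMap > nResidues(ens)))
    stop("indexMap must give one valid ensemble index per basis residue")
  mu <- as.vector(t(basis@meanStructure))
  f <- nFrames(ens)
  out <- matrix(NA_real_, f, 2, dimnames = list(NULL, c("PC1", "PC2")))
  for (k in seq_len(f)) {
    xyz <- ens@coords[k, indexMap, , drop = TRUE]
    fit <- superpose(xyz, basis@meanStructure)
    out[k, ] <- (as.vector(t(fit)) - mu) %*% basis@components
  }
  out
}

## Weighted mean and covariance of a 2D cloud.
.cloudMoments <- function(p, weights = NULL, ridge = 1e-10) {
  f <- nrow(p)
  w <- if (is.null(weights)) rep(1 / f, f) else weights / sum(weights)
  mu <- colSums(p * w)
  pc <- sweep(p, 2, mu)
  sig <- crossprod(pc * sqrt(w)) + diag(ridge, 2)
  list(mu = mu, sigma = sig)
}

#' Gaussian Kullback-Leibler divergence between projected clouds
#'
#' Fits a 2D Gaussian to each cloud by moment matching and returns the
#' closed-form divergence
#' KL(p||q) = 1/2 (tr(Sq^-1 Sp) + (mq - mp)' Sq^-1 (mq - mp) - 2 +
#' ln(det Sq / det Sp)). A lower value means the candidate occupies
#' the reference's conformational subspace more faithfully. KL is
#' asymmetric; the conventional report here is
#' KL(candidate || reference).
#'
#' @param p the first ("candidate") F x 2 cloud from
#'   [projectEnsemble()] (at least 3 points).
#' @param q the second ("reference") cloud.
#' @param ridge diagonal regularization added to each fitted
#'   covariance (default 1e-10 nm^2).
#' @return KL divergence in nats.
#' @export
klGaussian <- function(p, q, ridge = 1e-10) {
  p <- as.matrix(p); q <- as.matrix(q)
  stopifnot(ncol(p) == 2L, ncol(q) == 2L)
  if (nrow(p) < 3L || nrow(q) < 3L) stop("need at least 3 points per cloud")
  mp <- .cloudMoments(p, ridge = ridge)
  mq <- .cloudMoments(q, ridge = ridge)
  dq <- det(mq$sigma); dp <- det(mp$sigma)
  if (dq <= 0 || dp <= 0) stop("singular covariance after ridge")
  qi <- solve(mq$sigma)
  dm <- mq$mu - mp$mu
  as.numeric(0.5 * (sum(diag(qi %*% mp$sigma)) + t(dm) %*% qi %*% dm -
                      2 + log(dq / dp)))
}

#' Compare a candidate ensemble against a reference
#'
#' Convenience wrapper: fits the PCA basis on the reference, projects
#' both ensembles, and returns the Gaussian KL divergence in both
#' directions together with the clouds.
#'
#' @param candidate,reference [Ensemble-class] objects.
#' @param indexMap optional candidate-to-basis residue map (see
#'   [projectEnsemble()]).
#' @return list with `kl` (candidate || reference), `klReverse`,
#'   `basis`, `candidateCloud`, `referenceCloud`.
#' @export
compareEnsembles <- function(candidate, reference, indexMap = NULL) {
  basis <- fitPca(reference)
  refCloud <- projectEnsemble(reference, basis)
  candCloud <- projectEnsemble(candidate, basis, indexMap = indexMap)
  list(kl = klGaussian(candCloud, refCloud),
       klReverse = klGaussian(refCloud, candCloud),
       basis = basis, candidateCloud = candCloud,
       referenceCloud = refCloud)
}
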