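#' @import methods
NULL

## Boltzmann constant in kJ/(mol*K); Angstrom <-> nm conversion used
## throughout (coordinates are stored in nm, fluctuation metrics are
## reported in Angstrom to match the conventional thresholds).
.kB <- 0.0083145
.ANG_PER_NM <- 10

#' ProteinModel: one C-alpha per residue with AlphaFold confidence
#'
#' Holds the coarse, residue-level view of a predicted structure:
#' ordered chain/residue identifiers, C-alpha coordinates in nm, and the
#' per-residue pLDDT confidence (0-100 scale, stored by AlphaFold in the
#' B-factor column). Residue order is the file's record order and is the
#' canonical 1-based index used by every matrix in the package (PAE,
#' sigma_d, elastic bonds).
#'
#' @slot chain character vector, chain identifier per residue.
#' @slot resno integer vector, author residue numbers (labels only).
#' @slot coords numeric N x 3 matrix of C-alpha positions in nm.
#' @slot plddt numeric vector of per-residue pLDDT values in [0, 100].
#'
#' @exportClass ProteinModel
setClass("ProteinModel",
  representation(chain = "character", resno = "integer",
                 coords = "matrix", plddt = "numeric"))

setValidity("ProteinModel", function(object) {
  n <- nrow(object@coords)
  msg <- character()
  if (is.null(n) || n < 2L)
    msg <- c(msg, "a ProteinModel needs at least 2 residues")
  if (!is.numeric(object@coords) || ncol(object@coords) != 3L)
    msg <- c(msg, "coords must be an N x 3 numeric matrix")
  if (length(object@plddt) != n || length(object@chain) != n ||
      length(object@resno) != n)
    msg <- c(msg, "chain, resno, plddt and coords must agree in length")
  if (any(!is.finite(object@coords)))
    msg <- c(msg, "coords must be finite")
  if (any(object@plddt < 0 | object@plddt > 100, na.rm = TRUE))
    msg <- c(msg, "pLDDT values must lie in [0, 100]")
  if (length(msg)) msg else TRUE
})

#' PaeMatrix: predicted aligned error in Angstrom
#'
#' Square N x N matrix of AlphaFold's predicted aligned error: entry
#' (i, j) estimates the positional error (Angstrom) of residue i when
#' the prediction is aligned on residue j. AlphaFold caps the score,
#' by default at 31.75 Angstrom. The raw matrix is generally
#' non-symmetric; see [symmetrizePae()].
#'
#' @slot values numeric N x N matrix in Angstrom.
#' @slot maxPae scalar cap in Angstrom (default 31.75).
#'
#' @exportClass PaeMatrix
setClass("PaeMatrix",
  representation(values = "matrix", maxPae = "numeric"))

setValidity("PaeMatrix", function(object) {
  v <- object@values
  msg <- character()
  if (!is.numeric(v) || nrow(v) != ncol(v))
    msg <- c(msg, "PAE matrix must be square and numeric")
  if (any(v < 0, na.rm = TRUE))
    msg <- c(msg, "PAE entries must be non-negative")
  if (length(object@maxPae) != 1L || object@maxPae <= 0)
    msg <- c(msg, "maxPae must be a positive scalar")
  if (any(v > object@maxPae + 1e-9, na.rm = TRUE))
    msg <- c(msg, "PAE entries exceed the stated cap")
  if (length(msg)) msg else TRUE
})

#' BuildParams: parameter set of the AF-ENM construction
#'
#' Bundles every tunable of the elastic-network construction. Defaults
#' are the published operating point of the method: 0.9 nm cutoff,
#' strict pLDDT > 90 residue gate, sequence separation >= 3 (bonded and
#' angle terms of the simulation force field cover closer pairs),
#' strict k > 75 kJ/(mol nm^2) bond gate (equivalent to symmetrized
#' PAE < 1.85 Angstrom at 310 K), and a generic 500 kJ/(mol nm^2)
#' constant where PAE scaling is off.
#'
#' @slot cutoffNm distance cutoff r_c in nm.
#' @slot plddtMin pLDDT gate (strict >) for both residues of a bond.
#' @slot minSeqSep minimum |i - j| within a chain.
#' @slot kMin force-constant gate (strict >) in kJ/(mol nm^2),
#'   applied in mode "af_scaled" and as the membership test in
#'   "af_const".
#' @slot temperatureK temperature in K used in k = kB*T/PAE^2.
#' @slot genericK constant force constant in kJ/(mol nm^2).
#' @slot mode one of "standard", "af_const", "af_scaled".
#'
#' @exportClass BuildParams
setClass("BuildParams",
  representation(cutoffNm = "numeric", plddtMin = "numeric",
                 minSeqSep = "integer", kMin = "numeric",
                 temperatureK = "numeric", genericK = "numeric",
                 mode = "character"),
  prototype(cutoffNm = 0.9, plddtMin = 90, minSeqSep = 3L, kMin = 75,
            temperatureK = 310, genericK = 500, mode = "af_scaled"))

setValidity("BuildParams", function(object) {
  msg <- character()
  num <- c(cutoffNm = object@cutoffNm, plddtMin = object@plddtMin,
           minSeqSep = object@minSeqSep, kMin = object@kMin,
           temperatureK = object@temperatureK, genericK = object@genericK)
  if (any(lengths(list(object@cutoffNm, object@plddtMin, object@minSeqSep,
                       object@kMin, object@temperatureK, object@genericK,
                       object@mode)) != 1L))
    msg <- c(msg, "all BuildParams fields must be scalars")
  else if (any(!is.finite(num)) || any(num[c("cutoffNm", "temperatureK",
                                             "genericK")] <= 0))
    msg <- c(msg, "cutoffNm, temperatureK and genericK must be positive")
  if (!object@mode %in% c("standard", "af_const", "af_scaled"))
    msg <- c(msg, "mode must be standard, af_const or af_scaled")
  if (length(msg)) msg else TRUE
})

#' ElasticNetwork: a set of harmonic C-alpha bonds
#'
#' The elastic network V = sum over bonds of 1/2 k (r - r0)^2 as a
#' bond table: 1-based residue indices i < j, reference distance r0 in
#' nm, and force constant k in kJ/(mol nm^2), together with the
#' [BuildParams-class] that produced it.
#'
#' @slot bonds data.frame with columns i, j, r0, k, sorted by (i, j).
#' @slot params the [BuildParams-class] used for construction.
#' @slot nResidues number of residues in the underlying model.
#'
#' @exportClass ElasticNetwork
setClass("ElasticNetwork",
  representation(bonds = "data.frame", params = "BuildParams",
                 nResidues = "integer"))

setValidity("ElasticNetwork", function(object) {
  b <- object@bonds
  msg <- character()
  if (!all(c("i", "j", "r0", "k") %in% names(b)))
    msg <- c(msg, "bonds must have columns i, j, r0, k")
  else if (nrow(b)) {
    if (any(b$i >= b$j)) msg <- c(msg, "bonds must satisfy i < j")
    if (any(b$j > object@nResidues) || any(b$i < 1L))
      msg <- c(msg, "bond indices must lie in 1..nResidues")
    if (any(b$r0 <= 0) || any(b$k <= 0))
      msg <- c(msg, "r0 and k must be positive")
    if (anyDuplicated(b[c("i", "j")]))
      msg <- c(msg, "duplicate (i, j) bond")
  }
  if (length(msg)) msg else TRUE
})

#' Ensemble: frames x residues x 3 coordinate stack
#'
#' A conformational ensemble of F frames over the same N C-alpha sites,
#' in nm, with optional per-frame weights (normalized to sum to 1).
#' This is the substrate of all fluctuation metrics.
#'
#' @slot coords numeric array F x N x 3 in nm.
#' @slot weights numeric vector of F non-negative frame weights.
#'
#' @exportClass Ensemble
setClass("Ensemble",
  representation(coords = "array", weights = "numeric"))

setValidity("Ensemble", function(object) {
  d <- dim(object@coords)
  msg <- character()
  if (length(d) != 3L || d[3] != 3L)
    msg <- c(msg, "coords must be an F x N x 3 array")
  else {
    if (d[1] < 1L) msg <- c(msg, "need at least one frame")
    if (d[2] < 2L) msg <- c(msg, "need at least two residues")
    if (length(object@weights) != d[1])
      msg <- c(msg, "one weight per frame required")
    if (any(object@weights < 0)) msg <- c(msg, "weights must be >= 0")
    if (abs(sum(object@weights) - 1) > 1e-8)
      msg <- c(msg, "weights must sum to 1")
  }
  if (length(msg)) msg else TRUE
})

#' PcaBasis: top-2 principal modes of a reference ensemble
#'
#' Mean structure plus the two highest-variance orthonormal modes of
#' the 3N C-alpha coordinate covariance, used to project candidate
#' ensembles into a common 2D space.
#'
#' @slot meanStructure numeric N x 3 matrix (nm).
#' @slot components numeric 3N x 2 matrix, orthonormal columns.
#' @slot explainedVariance numeric length-2, decreasing (nm^2).
#'
#' @exportClass PcaBasis
setClass("PcaBasis",
  representation(meanStructure = "matrix", components = "matrix",
                 explainedVariance = "numeric"))

setValidity("PcaBasis", function(object) {
  msg <- character()
  n3 <- 3L * nrow(object@meanStructure)
  if (!identical(dim(object@components), c(n3, 2L)))
    msg <- c(msg, "components must be a 3N x 2 matrix")
  else {
    g <- crossprod(object@components)
    if (max(abs(g - diag(2))) > 1e-8)
      msg <- c(msg, "components must be orthonormal")
  }
  if (length(object@explainedVariance) != 2L ||
      diff(object@explainedVariance) > 1e-12)
    msg <- c(msg, "explainedVariance must be length 2, non-increasing")
  if (length(msg)) msg else TRUE
})

#' ToySystem: a synthetic benchmark system with known ground truth
#'
#' Bundles a toy chain, its synthetic confidence scores, and the ground
#' truth they were generated from: the per-pair distance-fluctuation
#' standard deviations (Angstrom), the per-residue flexibility class,
#' and the generating elastic network ("truth network") whose harmonic
#' ensemble realizes those fluctuations.
#'
#' @slot model the [ProteinModel-class] (pLDDT filled from the
#'   flexibility classes).
#' @slot pae the physical-channel [PaeMatrix-class]: ground-truth
#'   distance sigma for the designated confident contacts, large values
#'   elsewhere.
#' @slot truth list with elements `sigmaPair` (N x N Angstrom),
#'   `sigmaDn` (per-residue flexibility truth, Angstrom), `flexClass`
#'   (character, "rigid"/"flexible"), `scaffold` (data.frame i, j,
#'   sigma of the confident-contact scaffold), `network` (the
#'   generating [ElasticNetwork-class]) and `seed`.
#'
#' @exportClass ToySystem
setClass("ToySystem",
  representation(model = "ProteinModel", pae = "PaeMatrix",
                 truth = "list"))

setValidity("ToySystem", function(object) {
  n <- nResidues(object@model)
  msg <- character()
  if (nrow(object@pae@values) != n)
    msg <- c(msg, "PAE dimension must match the model")
  need <- c("sigmaPair", "sigmaDn", "flexClass", "scaffold", "network",
            "seed")
  if (!all(need %in% names(object@truth)))
    msg <- c(msg, paste("truth must contain:", paste(need, collapse = ", ")))
  if (length(msg)) msg else TRUE
})
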