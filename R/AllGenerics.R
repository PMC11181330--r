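#' @include AllClasses.R
NULL

#' Number of residues
#'
#' @param x a ProteinModel, PaeMatrix, ElasticNetwork, Ensemble or
#'   ToySystem.
#' @return integer residue count.
#' @export
setGeneric("nResidues", function(x) standardGeneric("nResidues"))

#' C-alpha coordinates in nm
#'
#' @param x an object carrying coordinates.
#' @return N x 3 numeric matrix (ProteinModel) or F x N x 3 array
#'   (Ensemble), in nm.
#' @export
setGeneric("caCoords", function(x) standardGeneric("caCoords"))

#' Per-residue pLDDT values
#'
#' @param x a ProteinModel or ToySystem.
#' @return numeric vector on the 0-100 scale.
#' @export
setGeneric("plddt", function(x) standardGeneric("plddt"))

#' PAE values in Angstrom
#'
#' @param x a PaeMatrix or ToySystem.
#' @return numeric N x N matrix.
#' @export
setGeneric("paeValues", function(x) standardGeneric("paeValues"))

#' Bond table of an elastic network
#'
#' @param x an ElasticNetwork.
#' @return data.frame with columns i, j, r0 (nm), k (kJ/(mol nm^2)).
#' @export
setGeneric("bonds", function(x) standardGeneric("bonds"))

#' Number of frames in an ensemble
#'
#' @param x an Ensemble.
#' @return integer frame count.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Symmetrize a PAE matrix
#'
#' AlphaFold's PAE is generally non-symmetric; the elastic-network
#' construction uses the average of the (i, j) and (j, i) entries.
#'
#' @param pae a [PaeMatrix-class] (or plain square matrix).
#' @return a symmetric [PaeMatrix-class] (or matrix).
#' @export
setGeneric("symmetrizePae", function(pae) standardGeneric("symmetrizePae"))
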