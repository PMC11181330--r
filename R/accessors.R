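#' @include AllGenerics.R
NULL

#' @rdname nResidues
#' @export
setMethod("nResidues", "ProteinModel", function(x) nrow(x@coords))

#' @rdname nResidues
#' @export
setMethod("nResidues", "PaeMatrix", function(x) nrow(x@values))

#' @rdname nResidues
#' @export
setMethod("nResidues", "ElasticNetwork", function(x) x@nResidues)

#' @rdname nResidues
#' @export
setMethod("nResidues", "Ensemble", function(x) dim(x@coords)[2])

#' @rdname nResidues
#' @export
setMethod("nResidues", "ToySystem", function(x) nResidues(x@model))

#' @rdname caCoords
#' @export
setMethod("caCoords", "ProteinModel", function(x) x@coords)

#' @rdname caCoords
#' @export
setMethod("caCoords", "Ensemble", function(x) x@coords)

#' @rdname plddt
#' @export
setMethod("plddt", "ProteinModel", function(x) x@plddt)

#' @rdname plddt
#' @export
setMethod("plddt", "ToySystem", function(x) x@model@plddt)

#' @rdname paeValues
#' @export
setMethod("paeValues", "PaeMatrix", function(x) x@values)

#' @rdname paeValues
#' @export
setMethod("paeValues", "ToySystem", function(x) x@pae@values)

#' @rdname bonds
#' @export
setMethod("bonds", "ElasticNetwork", function(x) x@bonds)

#' @rdname nFrames
#' @export
setMethod("nFrames", "Ensemble", function(x) dim(x@coords)[1])

#' Chain identifiers of a ProteinModel
#'
#' @param model a [ProteinModel-class].
#' @return character vector of per-residue chain ids.
#' @export
chainIds <- function(model) {
  stopifnot(is(model, "ProteinModel"))
  model@chain
}

#' Construction parameters of an ElasticNetwork
#'
#' @param network an [ElasticNetwork-class].
#' @return the [BuildParams-class] it was built with.
#' @export
buildParamsOf <- function(network) {
  stopifnot(is(network, "ElasticNetwork"))
  network@params
}

#' Frame weights of an Ensemble
#'
#' @param ens an [Ensemble-class].
#' @return numeric vector of weights summing to 1.
#' @export
frameWeights <- function(ens) {
  stopifnot(is(ens, "Ensemble"))
  ens@weights
}

#' Ground truth of a ToySystem
#'
#' @param toy a [ToySystem-class].
#' @return list with sigmaPair, flexClass, scaffold, network, seed.
#' @export
toyTruth <- function(toy) {
  stopifnot(is(toy, "ToySystem"))
  toy@truth
}

setMethod("show", "ProteinModel", function(object) {
  n <- nResidues(object)
  cat(sprintf("ProteinModel: %d residues, %d chain(s)\n",
              n, length(unique(object@chain))))
  cat(sprintf("  pLDDT: min %.1f / median %.1f / max %.1f  (%.0f%% > 90)\n",
              min(object@plddt), stats::median(object@plddt),
              max(object@plddt), 100 * mean(object@plddt > 90)))
  invisible(object)
})

setMethod("show", "PaeMatrix", function(object) {
  v <- object@values
  off <- v[row(v) != col(v)]
  cat(sprintf("PaeMatrix: %d x %d (cap %.2f A)\n", nrow(v), ncol(v),
              object@maxPae))
  if (length(off))
    cat(sprintf("  off-diagonal: min %.2f / median %.2f / max %.2f A; asymmetry %.3g A\n",
                min(off), stats::median(off), max(off),
                max(abs(v - t(v)))))
  invisible(object)
})

setMethod("show", "ElasticNetwork", function(object) {
  b <- object@bonds
  cat(sprintf("ElasticNetwork: %d bonds over %d residues (mode %s)\n",
              nrow(b), object@nResidues, object@params@mode))
  if (nrow(b))
    cat(sprintf("  r0: %.3f-%.3f nm; k: %.1f-%.1f kJ/(mol nm^2)\n",
                min(b$r0), max(b$r0), min(b$k), max(b$k)))
  invisible(object)
})

setMethod("show", "Ensemble", function(object) {
  cat(sprintf("Ensemble: %d frames x %d residues%s\n",
              nFrames(object), nResidues(object),
              if (length(unique(object@weights)) > 1L)
                " (non-uniform weights)" else ""))
  invisible(object)
})

setMethod("show", "BuildParams", function(object) {
  cat(sprintf(paste0("BuildParams(mode = %s): cutoff %.2f nm, pLDDT > %g, ",
                     "|i-j| >= %d, k > %g kJ/(mol nm^2), T = %g K, ",
                     "generic k = %g\n"),
              object@mode, object@cutoffNm, object@plddtMin,
              object@minSeqSep, object@kMin, object@temperatureK,
              object@genericK))
  invisible(object)
})

setMethod("show", "ToySystem", function(object) {
  cls <- object@truth$flexClass
  cat(sprintf("ToySystem: %d residues (%d rigid, %d flexible), seed %s\n",
              nResidues(object), sum(cls == "rigid"),
              sum(cls == "flexible"), format(object@truth$seed)))
  invisible(object)
})

setMethod("show", "PcaBasis", function(object) {
  cat(sprintf("PcaBasis: %d residues; explained variance %.4g / %.4g nm^2\n",
              nrow(object@meanStructure), object@explainedVariance[1],
              object@explainedVariance[2]))
  invisible(object)
})
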