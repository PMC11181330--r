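#' @include afio.R
NULL

#' PAE-derived force constant
#'
#' Models the C-alpha pair-distance distribution as a Gaussian whose
#' standard deviation is the (symmetrized) predicted aligned error.
#' Inverting the corresponding free-energy well
#' dG(r) = -kB*T*ln P(r) into a harmonic potential gives
#'
#'   k = kB * T / PAE^2
#'
#' with PAE in nm and kB = 0.0083145 kJ/(mol K). At T = 310 K a PAE of
#' 1.85 Angstrom maps to about 75 kJ/(mol nm^2) — the bond-inclusion
#' threshold of the AF-ENM.
#'
#' @param paeAng PAE value(s) in Angstrom, > 0.
#' @param temperatureK temperature in K (default 310).
#' @return force constant(s) in kJ/(mol nm^2).
#' @examples
#' forceConstant(1.85, 310)   # ~75.31
#' @export
forceConstant <- function(paeAng, temperatureK = 310) {
  if (any(paeAng <= 0)) stop("PAE must be positive (zero-variance bond)")
  .kB * temperatureK / (paeAng / .ANG_PER_NM)^2
}

#' PAE equivalent of a force constant
#'
#' Exact inverse of [forceConstant()]: the PAE (Angstrom) whose
#' Gaussian distance distribution yields the given harmonic stiffness.
#'
#' @param k force constant(s) in kJ/(mol nm^2), > 0.
#' @param temperatureK temperature in K (default 310).
#' @return PAE value(s) in Angstrom.
#' @examples
#' paeFromForceConstant(75, 310)   # ~1.854
#' @export
paeFromForceConstant <- function(k, temperatureK = 310) {
  if (any(k <= 0)) stop("force constant must be positive")
  sqrt(.kB * temperatureK / k) * .ANG_PER_NM
}

## Candidate pairs (i < j) within cutoff that satisfy the sequence
## separation rule (inter-chain pairs are exempt from it).
.eligiblePairs <- function(model, cutoffNm, minSeqSep) {
  d <- pairDistances(caCoords(model))
  n <- nResidues(model)
  idx <- which(upper.tri(d) & d <= cutoffNm, arr.ind = TRUE)
  if (!nrow(idx))
    return(data.frame(i = integer(), j = integer(), r0 = numeric()))
  i <- idx[, 1]; j <- idx[, 2]
  ch <- chainIds(model)
  keep <- ch[i] != ch[j] | abs(i - j) >= minSeqSep
  data.frame(i = i[keep], j = j[keep], r0 = d[cbind(i, j)][keep])
}

.newNetwork <- function(pairs, params, n) {
  pairs <- pairs[order(pairs$i, pairs$j), , drop = FALSE]
  rownames(pairs) <- NULL
  new("ElasticNetwork", bonds = pairs, params = params,
      nResidues = as.integer(n))
}

#' Build a standard (generic-k) elastic network
#'
#' The conventional construction used with coarse-grained MARTINI
#' models: every C-alpha pair within the cutoff and past the sequence
#' separation gets a harmonic bond with one shared force constant
#' (default 500 kJ/(mol nm^2)); confidence scores play no role.
#'
#' @param model a [ProteinModel-class].
#' @param cutoffNm cutoff radius in nm (default 0.9).
#' @param genericK shared force constant (default 500).
#' @param minSeqSep minimum within-chain |i - j| (default 3).
#' @return an [ElasticNetwork-class] with r0 = observed distances.
#' @export
buildStandardEnm <- function(model, cutoffNm = 0.9, genericK = 500,
                             minSeqSep = 3) {
  params <- buildParams(cutoffNm = cutoffNm, genericK = genericK,
                        minSeqSep = minSeqSep, mode = "standard")
  pairs <- .eligiblePairs(model, cutoffNm, as.integer(minSeqSep))
  pairs$k <- rep(genericK, nrow(pairs))
  .newNetwork(pairs, params, nResidues(model))
}

#' Build an AlphaFold-optimized elastic network (AF-ENM)
#'
#' Selection rules: a pair (i, j) is bonded iff both residues have
#' pLDDT strictly above `plddtMin`, their C-alpha distance is within
#' the cutoff, they are on different chains or separated by at least
#' `minSeqSep` residues, and — using the symmetrized PAE — the derived
#' force constant k = kB*T/PAE^2 is strictly above `kMin`. The k-gate
#' is exactly equivalent to PAE < paeFromForceConstant(kMin, T)
#' (1.85 Angstrom at the defaults). Mode "af_scaled" keeps the
#' PAE-derived k per bond; "af_const" applies the same membership test
#' but assigns the generic constant; "standard" ignores the scores
#' entirely (see [buildStandardEnm()]).
#'
#' @param model a [ProteinModel-class].
#' @param pae a [PaeMatrix-class] matching the model (symmetrized
#'   internally if it is not already).
#' @param params a [BuildParams-class]; see [buildParams()].
#' @return an [ElasticNetwork-class], bonds sorted by (i, j).
#' @export
buildAfEnm <- function(model, pae, params = buildParams()) {
  checkPaePairing(model, pae)
  validObject(params)
  if (params@mode == "standard")
    return(buildStandardEnm(model, cutoffNm = params@cutoffNm,
                            genericK = params@genericK,
                            minSeqSep = params@minSeqSep))
  sym <- symmetrizePae(pae)@values
  pairs <- .eligiblePairs(model, params@cutoffNm, params@minSeqSep)
  pl <- plddt(model)
  keep <- pl[pairs$i] > params@plddtMin & pl[pairs$j] > params@plddtMin
  pairs <- pairs[keep, , drop = FALSE]
  pv <- sym[cbind(pairs$i, pairs$j)]
  if (any(pv <= 0))
    stop("symmetrized PAE is zero for pair(s) ",
         paste(sprintf("(%d,%d)", pairs$i[pv <= 0], pairs$j[pv <= 0]),
               collapse = ", "))
  kv <- forceConstant(pv, params@temperatureK)
  pairs <- pairs[kv > params@kMin, , drop = FALSE]
  kv <- kv[kv > params@kMin]
  pairs$k <- if (params@mode == "af_scaled") kv
             else rep(params@genericK, nrow(pairs))
  .newNetwork(pairs, params, nResidues(model))
}
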