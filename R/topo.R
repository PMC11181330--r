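#' @include enm.R
NULL

#' Write an elastic network as a GROMACS topology include
#'
#' Emits a `[ bonds ]` section with one `ai aj funct r0 k` line per
#' bond (r0 in nm, k in kJ/(mol nm^2)), optionally wrapped in an
#' `#ifdef` guard, in deterministic (i, j) order. The default bond
#' function type 6 is the usual elastic-network convention in MARTINI
#' topologies: a harmonic bond that generates no exclusions, so the
#' rubber bands do not delete nonbonded interactions; type 1 is
#' selectable. One backbone bead per residue is assumed; pass
#' `indexMap` for non-trivial coarse-grained mappings.
#'
#' @param network an [ElasticNetwork-class].
#' @param path output file path.
#' @param functType integer bond function type (default 6).
#' @param offset atom index offset added to 1-based residue indices
#'   minus one; default 1 keeps 1-based GROMACS numbering.
#' @param ifdefGuard optional preprocessor tag (e.g. "RUBBER_BANDS").
#' @param indexMap optional integer vector mapping residue index ->
#'   bead/atom index (overrides `offset`).
#' @param precisionR0,precisionK decimal places for r0 and k
#'   (defaults 5 and 2).
#' @return the path, invisibly.
#' @export
writeItp <- function(network, path, functType = 6L, offset = 1L,
                     ifdefGuard = NULL, indexMap = NULL,
                     precisionR0 = 5L, precisionK = 2L) {
  stopifnot(is(network, "ElasticNetwork"))
  if (offset < 0L) stop("offset must be >= 0")
  if (precisionR0 < 1L || precisionK < 1L) stop("precision must be >= 1")
  b <- bonds(network)
  toIdx <- function(r)
    if (is.null(indexMap)) r - 1L + as.integer(offset)
    else as.integer(indexMap[r])
  lines <- c("; elastic network bonds generated by afenm",
             sprintf("; mode=%s cutoff=%g nm plddt_min=%g k_min=%g T=%g K",
                     network@params@mode, network@params@cutoffNm,
                     network@params@plddtMin, network@params@kMin,
                     network@params@temperatureK))
  if (!is.null(ifdefGuard)) lines <- c(lines, paste0("#ifdef ", ifdefGuard))
  lines <- c(lines, "[ bonds ]", "; ai aj funct r0(nm) k(kJ/mol/nm^2)")
  if (nrow(b))
    lines <- c(lines, sprintf(
      paste0("%d %d %d %.", precisionR0, "f %.", precisionK, "f"),
      toIdx(b$i), toIdx(b$j), as.integer(functType), b$r0, b$k))
  if (!is.null(ifdefGuard)) lines <- c(lines, "#endif")
  tryCatch(writeLines(lines, path),
           error = function(e) stop("cannot write ", path, ": ",
                                    conditionMessage(e)))
  invisible(path)
}

#' Read a `[ bonds ]` section back from an ITP file
#'
#' Round-trip companion of [writeItp()]; values carry the printed
#' precision only.
#'
#' @param path ITP file path.
#' @param offset the atom index offset used at write time (default 1).
#' @param nResidues residue count of the underlying model; default is
#'   inferred from the largest index.
#' @return an [ElasticNetwork-class] (default construction parameters).
#' @export
readItp <- function(path, offset = 1L, nResidues = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[!grepl("^[;#]", lines) & nzchar(lines)]
  start <- which(lines == "[ bonds ]")
  if (!length(start)) stop("no [ bonds ] section in ", path)
  body <- lines[-seq_len(start[1])]
  nextSec <- grep("^\\[", body)
  if (length(nextSec)) body <- body[seq_len(nextSec[1] - 1L)]
  if (!length(body)) {
    b <- data.frame(i = integer(), j = integer(), r0 = numeric(),
                    k = numeric())
  } else {
    f <- do.call(rbind, lapply(strsplit(body, "\\s+"), as.numeric))
    b <- data.frame(i = as.integer(f[, 1]) - as.integer(offset) + 1L,
                    j = as.integer(f[, 2]) - as.integer(offset) + 1L,
                    r0 = f[, 4], k = f[, 5])
  }
  if (is.null(nResidues)) nResidues <- max(b$j, 2L)
  .newNetwork(b, buildParams(), nResidues)
}

#' Write a lossless bond table (CSV or JSON)
#'
#' Full-precision dump of the bond list plus the construction
#' parameters; the JSON form round-trips exactly through
#' [readBondTable()].
#'
#' @param network an [ElasticNetwork-class].
#' @param path output path.
#' @param format "csv" or "json".
#' @return the path, invisibly.
#' @export
writeBondTable <- function(network, path, format = c("json", "csv")) {
  stopifnot(is(network, "ElasticNetwork"))
  format <- match.arg(format)
  b <- bonds(network)
  p <- network@params
  if (format == "csv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf(
      "# mode=%s cutoff_nm=%.17g plddt_min=%.17g min_seq_sep=%d k_min=%.17g temperature_K=%.17g generic_k=%.17g n_residues=%d",
      p@mode, p@cutoffNm, p@plddtMin, p@minSeqSep, p@kMin,
      p@temperatureK, p@genericK, network@nResidues), con)
    utils::write.csv(b, con, row.names = FALSE)
  } else {
    obj <- list(params = list(mode = p@mode, cutoff_nm = p@cutoffNm,
                              plddt_min = p@plddtMin,
                              min_seq_sep = p@minSeqSep, k_min = p@kMin,
                              temperature_K = p@temperatureK,
                              generic_k = p@genericK),
                n_residues = network@nResidues,
                bonds = as.list(b))
    ## 17 significant digits make the double round-trip exact
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  }
  invisible(path)
}

#' Read a bond table written by [writeBondTable()]
#'
#' @param path path to a JSON or CSV bond table.
#' @return an [ElasticNetwork-class] with its original parameters.
#' @export
readBondTable <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::fromJSON(path)
    p <- obj$params
    params <- buildParams(cutoffNm = p$cutoff_nm, plddtMin = p$plddt_min,
                          minSeqSep = p$min_seq_sep, kMin = p$k_min,
                          temperatureK = p$temperature_K,
                          genericK = p$generic_k, mode = p$mode)
    b <- obj$bonds
    b <- data.frame(i = as.integer(unlist(b$i)),
                    j = as.integer(unlist(b$j)),
                    r0 = as.numeric(unlist(b$r0)),
                    k = as.numeric(unlist(b$k)))
    .newNetwork(b, params, obj$n_residues)
  } else if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    header <- readLines(path, n = 1L)
    kv <- regmatches(header, gregexpr("[a-z_A-Z]+=[^ ]+", header))[[1]]
    kv <- stats::setNames(sub(".*=", "", kv), sub("=.*", "", kv))
    params <- buildParams(cutoffNm = as.numeric(kv["cutoff_nm"]),
                          plddtMin = as.numeric(kv["plddt_min"]),
                          minSeqSep = as.integer(kv["min_seq_sep"]),
                          kMin = as.numeric(kv["k_min"]),
                          temperatureK = as.numeric(kv["temperature_K"]),
                          genericK = as.numeric(kv["generic_k"]),
                          mode = kv[["mode"]])
    b <- utils::read.csv(path, skip = 1L)
    .newNetwork(b, params, as.integer(kv["n_residues"]))
  } else stop("unknown bond-table format: ", path)
}
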