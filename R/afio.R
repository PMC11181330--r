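#' @include utils.R
NULL

#' Read an AlphaFold structure into a ProteinModel
#'
#' Parses a PDB or mmCIF file (via bio3d), keeps exactly one C-alpha
#' per residue in file record order, and takes the per-residue pLDDT
#' from the B-factor column — the AlphaFold-DB convention. Some
#' pipelines (e.g. ColabFold with `--amber`) write pLDDT on a 0-1
#' scale; if every B-factor is <= 1 the values are multiplied by 100
#' and a warning is issued.
#'
#' Multi-chain files are concatenated in file order into one index
#' space; chain ids are retained so the sequence-separation rule of the
#' network construction never couples residues of different chains.
#' For altloc duplicates the first record wins; insertion-coded
#' residues are kept in file order.
#'
#' @param path file path.
#' @param format "pdb", "mmcif" or "auto" (default: by extension,
#'   falling back to pdb).
#' @return a [ProteinModel-class] with coordinates in nm.
#' @examples
#' pdb <- system.file("extdata", "toy_plddt.pdb", package = "afenm")
#' readStructure(pdb)
#' @export
readStructure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto")
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE))
      "mmcif" else "pdb"
  pdb <- if (format == "mmcif") bio3d::read.cif(path)
         else bio3d::read.pdb(path)
  atoms <- pdb$atom
  if (!nrow(atoms)) stop("empty structure: ", path)
  ## residue identity in file order (chain, resno, insert)
  rid <- paste(atoms$chain, atoms$resno,
               ifelse(is.na(atoms$insert), "", atoms$insert))
  ridf <- factor(rid, levels = unique(rid))
  isCa <- atoms$elety == "CA" & !grepl("^H", atoms$resid)
  missing <- levels(ridf)[!(levels(ridf) %in% unique(rid[isCa]))]
  ## drop pure hetero/solvent groups (no CA and not amino acid-like)
  aaLevels <- levels(ridf)[levels(ridf) %in%
                             unique(rid[atoms$type == "ATOM"])]
  missing <- intersect(missing, aaLevels)
  if (length(missing))
    stop("residue(s) without a C-alpha record: ",
         paste(trimws(missing), collapse = ", "))
  caIdx <- which(isCa)
  caIdx <- caIdx[!duplicated(ridf[caIdx])]      # first altloc wins
  caIdx <- caIdx[ridf[caIdx] %in% aaLevels]
  if (length(caIdx) < 2L)
    stop("structure has fewer than 2 C-alpha residues")
  b <- atoms$b[caIdx]
  if (any(is.na(b))) stop("missing B-factor (pLDDT) values")
  if (all(b <= 1.0)) {
    warning("all B-factors <= 1: interpreting as fractional pLDDT, ",
            "rescaling by 100")
    b <- b * 100
  }
  coords <- cbind(atoms$x, atoms$y, atoms$z)[caIdx, , drop = FALSE] / .ANG_PER_NM
  proteinModel(coords = coords, plddt = b,
               chain = as.character(atoms$chain[caIdx]),
               resno = atoms$resno[caIdx])
}

#' Read an AlphaFold PAE matrix from JSON
#'
#' Understands both common dialects: the AlphaFold-DB form
#' `{"predicted_aligned_error": [[...], ...]}` (2D array, possibly
#' wrapped in a one-element list) and the legacy flattened form with
#' parallel `residue1`/`residue2`/`distance` arrays covering all N^2
#' ordered pairs. `max_predicted_aligned_error` is honoured when
#' present, else the standard 31.75 Angstrom cap is assumed.
#'
#' @param path path to the JSON file.
#' @return a [PaeMatrix-class] in Angstrom (row k of the matrix
#'   corresponds to residue k in file order of the paired structure).
#' @export
readPae <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  ## unwrap the one-element-list envelope used by legacy files
  if (is.data.frame(obj)) {
    if (nrow(obj) != 1L) stop("unrecognized PAE JSON dialect: ", path)
    obj <- lapply(obj, function(col) if (is.list(col)) col[[1]] else col)
  }
  if (is.list(obj) && is.null(names(obj)) && length(obj) == 1L)
    obj <- obj[[1]]
  maxPae <- 31.75
  for (nm in c("max_predicted_aligned_error", "max_pae"))
    if (!is.null(obj[[nm]])) maxPae <- as.numeric(obj[[nm]])[1]
  paeField <- NULL
  for (nm in c("predicted_aligned_error", "pae"))
    if (!is.null(obj[[nm]])) paeField <- obj[[nm]]
  if (!is.null(paeField)) {
    if (is.list(paeField)) {
      lens <- lengths(paeField)
      if (length(unique(lens)) != 1L || lens[1] != length(paeField))
        stop("PAE matrix not square")
      paeField <- do.call(rbind, paeField)
    }
    m <- as.matrix(paeField)
    storage.mode(m) <- "double"
    if (nrow(m) != ncol(m)) stop("PAE matrix not square")
  } else if (all(c("residue1", "residue2", "distance") %in% names(obj))) {
    r1 <- as.integer(obj$residue1)
    r2 <- as.integer(obj$residue2)
    d <- as.numeric(obj$distance)
    n <- max(r1, r2)
    if (length(d) != n * n ||
        anyDuplicated(cbind(r1, r2)) ||
        min(r1, r2) != 1L)
      stop("incomplete or inconsistent PAE triple list")
    m <- matrix(NA_real_, n, n)
    m[cbind(r1, r2)] <- d
    if (any(is.na(m))) stop("incomplete or inconsistent PAE triple list")
  } else {
    stop("unrecognized PAE JSON dialect: ", path)
  }
  if (any(m < 0)) stop("negative PAE entries")
  paeMatrix(m, maxPae = max(maxPae, max(m)))
}

#' @rdname symmetrizePae
#' @export
setMethod("symmetrizePae", "PaeMatrix", function(pae) {
  paeMatrix((pae@values + t(pae@values)) / 2, maxPae = pae@maxPae)
})

#' @rdname symmetrizePae
#' @export
setMethod("symmetrizePae", "matrix", function(pae) {
  if (nrow(pae) != ncol(pae)) stop("PAE matrix not square")
  (pae + t(pae)) / 2
})

#' Check that a structure and a PAE matrix belong together
#'
#' @param model a [ProteinModel-class].
#' @param pae a [PaeMatrix-class].
#' @return invisibly TRUE; errors if the residue counts differ.
#' @export
checkPaePairing <- function(model, pae) {
  n <- nResidues(model)
  m <- nResidues(pae)
  if (n != m)
    stop(sprintf("structure has %d residues but PAE matrix is %d x %d",
                 n, m, m))
  invisible(TRUE)
}
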