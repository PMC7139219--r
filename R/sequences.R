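## Lipobox detection and maturation-state sequences.

.AA1 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

## The conserved lipobox: [LVI][ASTVI][GAS][C], cysteine at the +1 position
## relative to the signal-peptide cleavage site.
.LIPOBOX_REGEX <- "[LVI][ASTVI][GAS]C"

.checkResidues <- function(residues, id = "sequence") {
  if (!is.character(residues) || length(residues) != 1L || nchar(residues) < 1L)
    stop("residues must be a single non-empty string", call. = FALSE)
  chars <- strsplit(residues, "")[[1]]
  bad <- which(!chars %in% .AA1)
  if (length(bad))
    stop(sprintf("%s contains invalid residue '%s' at position %d",
                 id, chars[bad[1]], bad[1]), call. = FALSE)
  invisible(chars)
}

#' Scan a protein sequence for lipobox motifs
#'
#' Finds every 4-residue window matching the conserved lipobox pattern
#' \code{[LVI][ASTVI][GAS][C]}, whose cysteine is the residue that receives
#' the lipid modification. All matches, including overlapping ones, are
#' reported in order of position; the caller chooses among multiple matches
#' (see \code{\link{selectLipoboxMatch}}).
#'
#' @param residues one-letter amino-acid string (standard 20 codes only;
#'   nonstandard letters such as X or U are rejected with the offending
#'   position)
#' @param id sequence identifier used in messages and reports
#' @return data.frame with one row per match: id, cys_position (1-based
#'   position of the conserved cysteine), motif (the 4-residue window),
#'   sp_length (residues N-terminal of the cysteine)
#' @examples
#' scanLipobox("MKATKLVLGAVILGSTLLAGC", id = "Lpp")
#' @export
scanLipobox <- function(residues, id = "seq") {
  .checkResidues(residues, id)
  m <- gregexpr(paste0("(?=(", .LIPOBOX_REGEX, "))"), residues, perl = TRUE)[[1]]
  starts <- as.integer(m)
  if (length(starts) == 1L && starts == -1L) starts <- integer(0)
  cys <- starts + 3L
  data.frame(
    id = rep(id, length(starts)),
    cys_position = cys,
    motif = if (length(starts)) substring(residues, starts, cys)
            else character(0),
    sp_length = cys - 1L,
    stringsAsFactors = FALSE)
}

#' Select one lipobox match among several
#'
#' Default rule: prefer the match whose signal peptide length (residues
#' before the cysteine) lies in the physiological 15-40 band; otherwise the
#' first match.
#'
#' @param matches data.frame as returned by \code{\link{scanLipobox}}
#' @param spRange acceptable signal-peptide length range
#' @return single-row data.frame
#' @export
selectLipoboxMatch <- function(matches, spRange = c(15L, 40L)) {
  if (nrow(matches) == 0L) stop("no lipobox matches to select from",
                                call. = FALSE)
  ok <- which(matches$sp_length >= spRange[1] & matches$sp_length <= spRange[2])
  matches[if (length(ok)) ok[1] else 1L, , drop = FALSE]
}

#' Derive the residue content of a maturation state
#'
#' SP and SP_DI retain the full precursor including the signal peptide; DI
#' and TRI start at the lipobox cysteine (the signal peptidase has cleaved
#' the signal peptide); UNTETHERED is a user-designated core-domain range
#' with no tether or lipid.
#'
#' @param residues full precursor sequence (one-letter)
#' @param match a single lipobox match row from \code{\link{scanLipobox}}
#' @param state one of "SP", "SP_DI", "DI", "TRI", "UNTETHERED"
#' @param coreRange integer length-2 residue range (required for UNTETHERED)
#' @return one-letter string of the state's residues
#' @export
deriveStateSequence <- function(residues, match, state,
                                coreRange = NULL) {
  .checkResidues(residues)
  state <- match.arg(state, .MATURATION_STATES)
  cys <- match$cys_position[1]
  if (is.na(cys) || cys < 1L || cys > nchar(residues) ||
      substring(residues, cys, cys) != "C")
    stop("match inconsistent with sequence: no cysteine at position ", cys,
         call. = FALSE)
  switch(state,
         SP = ,
         SP_DI = residues,
         DI = ,
         TRI = substring(residues, cys),
         UNTETHERED = {
           if (is.null(coreRange) || length(coreRange) != 2L)
             stop("UNTETHERED requires a coreRange of two residue positions",
                  call. = FALSE)
           if (coreRange[1] < 1L || coreRange[2] > nchar(residues) ||
               coreRange[1] > coreRange[2])
             stop("coreRange outside the sequence", call. = FALSE)
           substring(residues, coreRange[1], coreRange[2])
         })
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA file
#' @return named character vector of one-letter sequences
#' @export
readProteinFasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  out <- as.character(set)
  names(out) <- sub("\\s.*$", "", names(set))
  out
}

#' Write protein sequences to FASTA
#'
#' @param sequences named character vector
#' @param path output file
#' @export
writeProteinFasta <- function(sequences, path) {
  set <- Biostrings::AAStringSet(sequences)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Scan a FASTA file for lipobox motifs and write a TSV report
#'
#' @param fasta input FASTA of protein sequences
#' @param out optional path of the TSV report (id, cys_position, motif,
#'   sp_length); when NULL, no file is written
#' @return data.frame of all matches over all records
#' @export
scanLipoboxFasta <- function(fasta, out = NULL) {
  seqs <- readProteinFasta(fasta)
  res <- do.call(rbind, lapply(names(seqs), function(id)
    scanLipobox(seqs[[id]], id = id)))
  if (is.null(res)) res <- scanLipobox("C", id = "x")[0, ]
  if (!is.null(out))
    utils::write.table(res, out, sep = "\t", quote = FALSE, row.names = FALSE)
  res
}
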