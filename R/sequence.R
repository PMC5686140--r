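# Protein sequence container and FASTA input/output.

#' Construct a validated protein sequence
#'
#' A \code{protein_sequence} is the substrate of all sequence-level
#' descriptors: an identifier plus an ordered string over the 20 standard
#' one-letter amino-acid codes.
#'
#' @param residues Character scalar, the amino-acid sequence (case
#'   insensitive). Only the 20 standard codes are accepted.
#' @param id Free-text identifier.
#' @return An object of class \code{protein_sequence} with fields \code{id},
#'   \code{residues} (uppercase string) and \code{n} (residue count).
#' @examples
#' ps <- protein_sequence("MEEEKHHHLF", id = "demo")
#' ps$n
#' @export
protein_sequence <- function(residues, id = "seq") {
  if (length(residues) != 1L || !is.character(residues) || is.na(residues))
    stop("`residues` must be a single character string")
  residues <- toupper(residues)
  if (nchar(residues) == 0L)
    stop("empty sequence is not a valid protein sequence")
  chars <- strsplit(residues, "")[[1]]
  bad <- which(!chars %in% AA_STANDARD)
  if (length(bad))
    stop(sprintf(
      "non-standard residue letter(s) %s at position(s) %s",
      paste(unique(chars[bad]), collapse = ","),
      paste(utils::head(bad, 10L), collapse = ",")))
  structure(
    list(id = as.character(id), residues = residues, n = length(chars)),
    class = "protein_sequence")
}

#' @export
print.protein_sequence <- function(x, ...) {
  cat(sprintf("<protein_sequence> %s (%d aa)\n", x$id, x$n))
  cat(strtrim(x$residues, 60),
      if (x$n > 60) "..." else "", "\n", sep = "")
  invisible(x)
}

# Residues as a character vector.
seq_chars <- function(seq) strsplit(seq$residues, "")[[1]]

as_protein_sequence <- function(x, id = "seq") {
  if (inherits(x, "protein_sequence")) x else protein_sequence(x, id = id)
}

#' Read protein sequences from a FASTA file
#'
#' Records are uppercased and validated against the 20 standard amino-acid
#' codes; non-standard letters are rejected with their positions. With
#' \code{translate = TRUE} the file is read as nucleotide CDS records and
#' translated with the standard genetic code (reading frame 1, one trailing
#' stop codon allowed).
#'
#' @param path Path to a FASTA file (single- or multi-record).
#' @param translate Logical; treat records as coding DNA and translate.
#' @return A list of [protein_sequence()] objects.
#' @export
read_fasta <- function(path, translate = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (translate) {
    dna <- Biostrings::readDNAStringSet(path)
    aa <- Biostrings::translate(dna, if.fuzzy.codon = "error")
    strs <- as.character(aa)
    strs <- sub("\\*$", "", strs)   # trailing stop
    if (any(grepl("\\*", strs)))
      stop("internal stop codon in CDS record(s): ",
           paste(names(strs)[grepl("\\*", strs)], collapse = ", "))
  } else {
    aa <- Biostrings::readAAStringSet(path)
    strs <- as.character(aa)
  }
  ids <- sub("\\s.*$", "", names(strs))
  out <- vector("list", length(strs))
  for (i in seq_along(strs)) {
    out[[i]] <- tryCatch(
      protein_sequence(strs[[i]], id = ids[[i]]),
      error = function(e) stop(sprintf("record '%s': %s", ids[[i]],
                                       conditionMessage(e)), call. = FALSE))
  }
  out
}

#' Write protein sequences to a FASTA file
#'
#' @param seqs A [protein_sequence()] or list of them.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return Invisibly, \code{path}.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  if (inherits(seqs, "protein_sequence")) seqs <- list(seqs)
  con <- file(path, "w")
  on.exit(close(con))
  for (s in seqs) {
    writeLines(paste0(">", s$id), con)
    starts <- seq(1L, s$n, by = width)
    writeLines(substring(s$residues, starts,
                         pmin(starts + width - 1L, s$n)), con)
  }
  invisible(path)
}
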