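#' Read protein sequences from a FASTA file
#'
#' Thin wrapper around [Biostrings::readAAStringSet()] that returns a tibble
#' and enforces the package's sequence contract: record order is preserved,
#' sequences are upper-cased, a single terminal `*` stop symbol is stripped,
#' duplicate identifiers are an error, and any character outside the 20
#' standard amino acids plus `X` is an error reported with its position.
#'
#' @param path Path to a FASTA file of protein sequences.
#' @return A tibble with columns `protein_id` and `sequence`.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1", "MNASQK"), fa)
#' read_fasta(fa)
read_fasta <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("FASTA file not found: ", path))
  }
  # read as raw strings so that illegal characters survive for validation
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) {
    abort(paste0("FASTA file is empty: ", path))
  }
  # FASTA headers may carry descriptions after whitespace; the id is the first word
  ids <- sub("\\s.*$", "", names(seqs))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    abort(paste0("Duplicate FASTA id(s): ", paste(unique(dup), collapse = ", ")))
  }
  sequence <- toupper(as.character(seqs))
  sequence <- sub("\\*$", "", sequence)
  names(sequence) <- NULL
  ok <- paste(c(AA20, "X"), collapse = "")
  bad <- regexpr(paste0("[^", ok, "]"), sequence)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    abort(sprintf(
      "Illegal residue '%s' at position %d of sequence '%s'",
      substr(sequence[i], bad[i], bad[i]), bad[i], ids[i]
    ))
  }
  tibble(protein_id = ids, sequence = sequence)
}

#' Write protein sequences to a FASTA file
#'
#' Inverse of [read_fasta()]: `read_fasta(write_fasta(x, path))` reproduces
#' `x` for canonical records (upper-case sequences, no stop symbol).
#'
#' @param sequences A data frame with columns `protein_id` and `sequence`.
#' @param path Output file path.
#' @param width Line width for wrapping sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path, width = 60L) {
  stopifnot(all(c("protein_id", "sequence") %in% names(sequences)))
  xs <- Biostrings::AAStringSet(sequences$sequence)
  names(xs) <- sequences$protein_id
  Biostrings::writeXStringSet(xs, filepath = path, width = width)
  invisible(path)
}
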