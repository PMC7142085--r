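# Ortholog alignments and conservation measures: per-column Shannon entropy
# (bits) and region mean entropies. Alignments carry a designated reference
# (human) row and a map from ungapped reference positions to alignment
# columns.

#' Construct an ortholog alignment object
#'
#' @param taxa Character vector of taxon ids.
#' @param sequences Character vector of aligned sequences (equal lengths,
#'   `-` for gaps), parallel to `taxa`.
#' @param reference_taxon Taxon id of the reference (human) row.
#' @return An `ortholog_msa` object: list with `taxa`, `mat` (taxa x columns
#'   character matrix), `reference_taxon`, `ref_map` (integer vector mapping
#'   ungapped reference position to alignment column).
#' @export
ortholog_msa <- function(taxa, sequences, reference_taxon) {
  stopifnot(length(taxa) == length(sequences), length(taxa) >= 2L)
  widths <- nchar(sequences)
  if (length(unique(widths)) != 1L) {
    abort("Alignment rows have unequal lengths")
  }
  if (!reference_taxon %in% taxa) {
    abort(paste0("Reference taxon '", reference_taxon, "' not present in the alignment"))
  }
  if (anyDuplicated(taxa)) abort("Duplicate taxon ids in the alignment")
  mat <- do.call(rbind, strsplit(toupper(sequences), "", fixed = TRUE))
  rownames(mat) <- taxa
  ref_map <- which(mat[reference_taxon, ] != "-")
  out <- list(taxa = taxa, mat = mat, reference_taxon = reference_taxon,
              ref_map = as.integer(ref_map))
  class(out) <- "ortholog_msa"
  out
}

#' @export
print.ortholog_msa <- function(x, ...) {
  cat(sprintf("Ortholog alignment: %d taxa x %d columns (reference: %s, %d ungapped positions)\n",
              length(x$taxa), ncol(x$mat), x$reference_taxon, length(x$ref_map)))
  invisible(x)
}

#' Read an ortholog multiple alignment from aligned FASTA
#'
#' @param path Aligned FASTA file (equal-length rows, `-` gaps).
#' @param reference_taxon Id of the reference (human) row; must be present.
#' @return An `ortholog_msa` object (see [ortholog_msa()]).
#' @export
read_msa <- function(path, reference_taxon) {
  if (!file.exists(path)) abort(paste0("Alignment file not found: ", path))
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0L) abort(paste0("Alignment file is empty: ", path))
  ids <- sub("\\s.*$", "", names(seqs))
  w <- Biostrings::width(seqs)
  if (length(unique(w)) != 1L) {
    abort(paste0("Alignment rows have unequal lengths in ", path))
  }
  ortholog_msa(ids, as.character(seqs), reference_taxon)
}

#' Check that an alignment annotates a given record
#'
#' The reference row with gaps removed must equal the record's sequence.
#'
#' @param alignment An `ortholog_msa`.
#' @param records A `glyco_records` tibble.
#' @param protein_id Record to check against.
#' @return `TRUE` invisibly, or an error naming the protein.
#' @export
link_alignment <- function(alignment, records, protein_id) {
  i <- match(protein_id, records$protein_id)
  if (is.na(i)) abort(paste0("Unknown protein id: ", protein_id))
  ref <- paste(alignment$mat[alignment$reference_taxon, alignment$ref_map],
               collapse = "")
  if (!identical(ref, records$sequence[i])) {
    abort(paste0("Alignment reference row does not match the sequence of protein '",
                 protein_id, "'"))
  }
  invisible(TRUE)
}

#' Shannon entropy of alignment columns
#'
#' `H = -sum_i p_i log2 p_i` over the symbol frequencies of a column, in
#' bits. Under `gap_as_symbol` (default) the gap is a 21st symbol; under
#' `skip_gapped_rows` gapped rows are dropped from the column (an all-gap
#' column yields `NA`).
#'
#' @param alignment An `ortholog_msa`.
#' @param columns Integer vector of alignment columns (default: all).
#' @param gap_policy `"gap_as_symbol"` or `"skip_gapped_rows"`.
#' @return Numeric vector of entropies (bits), one per column.
#' @export
column_entropy <- function(alignment, columns = seq_len(ncol(alignment$mat)),
                           gap_policy = c("gap_as_symbol", "skip_gapped_rows")) {
  gap_policy <- match.arg(gap_policy)
  if (any(columns < 1L | columns > ncol(alignment$mat))) {
    abort("Alignment column index out of bounds")
  }
  vapply(columns, function(j) {
    col <- alignment$mat[, j]
    if (gap_policy == "skip_gapped_rows") {
      col <- col[col != "-"]
      if (length(col) == 0L) return(NA_real_)
    }
    p <- tabulate(match(col, unique(col))) / length(col)
    -sum(p * log2(p))
  }, numeric(1))
}

#' Mean column entropy over a set of reference positions
#'
#' Maps ungapped reference positions through the alignment's `ref_map` and
#' averages the column entropies (NA-aware).
#'
#' @param alignment An `ortholog_msa`.
#' @param reference_positions 1-based ungapped positions on the reference row.
#' @inheritParams column_entropy
#' @return Mean entropy in bits (scalar).
#' @export
region_mean_entropy <- function(alignment, reference_positions,
                                gap_policy = c("gap_as_symbol", "skip_gapped_rows")) {
  gap_policy <- match.arg(gap_policy)
  if (length(reference_positions) == 0L) {
    abort("Empty reference position set")
  }
  if (any(reference_positions < 1L |
            reference_positions > length(alignment$ref_map))) {
    abort("Reference position outside the ungapped reference sequence")
  }
  cols <- alignment$ref_map[reference_positions]
  mean(column_entropy(alignment, cols, gap_policy), na.rm = TRUE)
}

#' Write an ortholog alignment as aligned FASTA
#'
#' @param alignment An `ortholog_msa`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_msa <- function(alignment, path) {
  seqs <- apply(alignment$mat, 1L, paste, collapse = "")
  write_fasta(tibble(protein_id = alignment$taxa, sequence = seqs), path)
}
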