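# Glycoprotein records: one row per protein with list-columns for glycosite
# positions and disorder intervals. All coordinates are 1-based; intervals are
# inclusive, sorted and pairwise disjoint after assembly.

#' Assemble validated glycoprotein records
#'
#' Merges sequences with glycosite and disorder annotations into one validated
#' record per protein. Overlapping or adjacent disorder intervals are merged
#' (with a warning); a glycosite falling on a residue other than asparagine, or
#' out of bounds, or an annotation naming a protein missing from the sequence
#' set, is an error.
#'
#' @param sequences Tibble with `protein_id`, `sequence` (from [read_fasta()]).
#' @param glycosites Tibble with `protein_id`, `position` (1-based), or a list
#'   as returned by [read_annotation_tables()] (in which case `disorder` is
#'   taken from it too).
#' @param disorder Tibble with `protein_id`, `start`, `end` (1-based
#'   inclusive). Ignored when `glycosites` is an annotation-table list.
#' @return A `glyco_records` tibble with columns `protein_id`, `sequence`,
#'   `length`, `glycosites` (list of sorted integer vectors), `disorder`
#'   (list of tibbles with `start`, `end`), `n_glycosites`,
#'   `disordered_fraction`.
#' @export
#' @examples
#' seqs <- tibble::tibble(protein_id = "p1", sequence = "ANASQ")
#' gly <- tibble::tibble(protein_id = "p1", position = 2L)
#' dis <- tibble::tibble(protein_id = "p1", start = 4L, end = 5L)
#' assemble_records(seqs, gly, dis)
assemble_records <- function(sequences, glycosites, disorder = NULL) {
  if (is.list(glycosites) && !is.data.frame(glycosites) &&
      all(c("glycosites", "disorder") %in% names(glycosites))) {
    disorder <- glycosites$disorder
    glycosites <- glycosites$glycosites
  }
  if (is.null(disorder)) {
    disorder <- tibble(protein_id = character(), start = integer(), end = integer())
  }
  stopifnot(all(c("protein_id", "sequence") %in% names(sequences)))

  missing_ids <- setdiff(
    unique(c(glycosites$protein_id, disorder$protein_id)),
    sequences$protein_id
  )
  if (length(missing_ids) > 0L) {
    abort(paste0(
      "Annotation rows reference protein(s) absent from the sequence set: ",
      paste(missing_ids, collapse = ", ")
    ))
  }

  gly_by_id <- split(glycosites$position, glycosites$protein_id)
  dis_by_id <- split(disorder[c("start", "end")], disorder$protein_id)

  n <- nrow(sequences)
  gly_col <- vector("list", n)
  dis_col <- vector("list", n)
  dis_frac <- numeric(n)
  merged_any <- character(0)

  for (i in seq_len(n)) {
    id <- sequences$protein_id[i]
    seq_i <- sequences$sequence[i]
    len <- nchar(seq_i)

    pos <- sort(unique(as.integer(gly_by_id[[id]] %||% integer(0))))
    if (length(pos) > 0L) {
      oob <- pos[pos < 1L | pos > len]
      if (length(oob) > 0L) {
        abort(sprintf("Glycosite position %d out of bounds for protein '%s' (length %d)",
                      oob[1L], id, len))
      }
      res <- substring(seq_i, pos, pos)
      non_n <- which(res != "N")
      if (length(non_n) > 0L) {
        abort(sprintf(
          "Glycosite at position %d of protein '%s' is '%s', not asparagine",
          pos[non_n[1L]], id, res[non_n[1L]]
        ))
      }
    }

    div <- dis_by_id[[id]]
    if (!is.null(div) && nrow(div) > 0L) {
      if (any(div$end > len)) {
        abort(sprintf("Disorder interval [%d,%d] out of bounds for protein '%s' (length %d)",
                      div$start[which(div$end > len)[1L]],
                      div$end[which(div$end > len)[1L]], id, len))
      }
      o <- order(div$start)
      s <- div$start[o]
      e <- div$end[o]
      if (length(s) > 1L && any(s[-1L] <= e[-length(e)] + 1L)) {
        # overlapping or adjacent: merge via IRanges
        red <- IRanges::reduce(IRanges::IRanges(start = s, end = e))
        merged_any <- c(merged_any, id)
        s <- IRanges::start(red)
        e <- IRanges::end(red)
      }
      div <- tibble::new_tibble(list(start = as.integer(s), end = as.integer(e)))
    } else {
      div <- tibble::new_tibble(list(start = integer(0), end = integer(0)))
    }

    gly_col[[i]] <- pos
    dis_col[[i]] <- div
    dis_frac[i] <- if (nrow(div) > 0L) sum(div$end - div$start + 1L) / len else 0
  }

  if (length(merged_any) > 0L) {
    warn(paste0(
      "Merged overlapping/adjacent disorder intervals for: ",
      paste(unique(merged_any), collapse = ", ")
    ))
  }

  out <- tibble(
    protein_id = sequences$protein_id,
    sequence = sequences$sequence,
    length = nchar(sequences$sequence),
    glycosites = gly_col,
    disorder = dis_col,
    n_glycosites = lengths(gly_col),
    disordered_fraction = dis_frac
  )
  class(out) <- c("glyco_records", class(out))
  out
}

# Per-residue locale labels for one protein: character vector of
# "ORDERED"/"DISORDERED", length = sequence length.
locale_labels <- function(length, disorder) {
  lab <- rep("ORDERED", length)
  if (nrow(disorder) > 0L) {
    idx <- unlist(Map(seq.int, disorder$start, disorder$end), use.names = FALSE)
    lab[idx] <- "DISORDERED"
  }
  lab
}

#' Locale of residue positions
#'
#' Returns the ordered/disordered class of one or more residue positions,
#' derived from a record's disorder intervals.
#'
#' @param records A `glyco_records` tibble.
#' @param protein_id Protein identifier (scalar, or vector recycled against
#'   `position`).
#' @param position 1-based residue position(s).
#' @return Character vector of `"ORDERED"` / `"DISORDERED"`.
#' @export
locale_of <- function(records, protein_id, position) {
  n <- max(length(protein_id), length(position))
  protein_id <- rep_len(protein_id, n)
  position <- rep_len(as.integer(position), n)
  idx <- match(protein_id, records$protein_id)
  if (anyNA(idx)) {
    abort(paste0("Unknown protein id: ", protein_id[which(is.na(idx))[1L]]))
  }
  out <- character(n)
  for (k in seq_len(n)) {
    i <- idx[k]
    p <- position[k]
    if (p < 1L || p > records$length[i]) {
      abort(sprintf("Position %d out of bounds for protein '%s' (length %d)",
                    p, protein_id[k], records$length[i]))
    }
    d <- records$disorder[[i]]
    out[k] <- if (nrow(d) > 0L && any(p >= d$start & p <= d$end)) "DISORDERED" else "ORDERED"
  }
  out
}

#' Summarize a record set for QC
#'
#' Counts per protein and cohort-wide: glycosites by locale, glycosites not
#' sitting at a sequon asparagine, and glycosites too close to a terminus for
#' an 11-residue neighborhood.
#'
#' @param records A `glyco_records` tibble.
#' @param flank Neighborhood half-width used for the terminal-skip count.
#' @return A one-row tibble of cohort counts.
#' @export
qc_summary <- function(records, flank = 5L) {
  seqn <- scan_sequons(records)
  gly <- glycosite_table(records)
  if (nrow(gly) == 0L) {
    return(tibble(
      n_proteins = nrow(records), n_glycosites = 0L, n_ordered = 0L,
      n_disordered = 0L, n_non_sequon = 0L, n_terminal_skipped = 0L
    ))
  }
  key <- paste(seqn$protein_id, seqn$n_position)
  gkey <- paste(gly$protein_id, gly$position)
  len <- records$length[match(gly$protein_id, records$protein_id)]
  tibble(
    n_proteins = nrow(records),
    n_glycosites = nrow(gly),
    n_ordered = sum(gly$locale == "ORDERED"),
    n_disordered = sum(gly$locale == "DISORDERED"),
    n_non_sequon = sum(!gkey %in% key),
    n_terminal_skipped = sum(gly$position <= flank | gly$position > len - flank)
  )
}

# Long-format glycosite table: one row per (protein, glycosite) with locale.
glycosite_table <- function(records) {
  rows <- purrr::map2(records$protein_id, seq_len(nrow(records)), function(id, i) {
    pos <- records$glycosites[[i]]
    if (length(pos) == 0L) return(NULL)
    tibble(protein_id = id, position = pos,
           locale = locale_of(records, id, pos))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble(protein_id = character(), position = integer(), locale = character())
  }
  out
}
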