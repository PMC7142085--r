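# N-linked glycosylation sequon: N followed by any residue except proline,
# followed by serine or threonine -- written N(X-P)S/T. Overlapping matches
# are all reported.

# Sequon positions within one sequence string; returns a tibble of
# n_position (1-based), x_residue, third_residue.
find_sequons <- function(sequence) {
  len <- nchar(sequence)
  if (len < 3L) {
    return(tibble(n_position = integer(0), x_residue = character(0),
                  third_residue = character(0)))
  }
  ch <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  i <- seq_len(len - 2L)
  hit <- ch[i] == "N" & ch[i + 1L] != "P" & ch[i + 2L] %in% c("S", "T")
  pos <- i[hit]
  tibble(n_position = pos, x_residue = ch[pos + 1L], third_residue = ch[pos + 2L])
}

#' Scan records for N(X-P)S/T sequons
#'
#' Finds every sequon in every record, including overlapping ones, and labels
#' each with the locale of its asparagine, whether the asparagine is an
#' annotated glycosite, and whether the 3-residue motif spans an
#' ordered/disordered boundary.
#'
#' @param records A `glyco_records` tibble (or any tibble with `protein_id`
#'   and `sequence`; locale and glycosite columns are then trivial).
#' @return A tibble with one row per sequon: `protein_id`, `n_position`
#'   (1-based position of the asparagine), `x_residue`, `third_residue`,
#'   `locale` (of the asparagine), `is_glycosite`, `spans_boundary`.
#' @export
#' @examples
#' recs <- assemble_records(
#'   tibble::tibble(protein_id = "p1", sequence = "ANGSA"),
#'   tibble::tibble(protein_id = character(), position = integer())
#' )
#' scan_sequons(recs)
scan_sequons <- function(records) {
  has_ann <- all(c("glycosites", "disorder") %in% names(records))
  rows <- purrr::map(seq_len(nrow(records)), function(i) {
    hits <- find_sequons(records$sequence[i])
    if (nrow(hits) == 0L) return(NULL)
    id <- records$protein_id[i]
    if (has_ann) {
      lab <- locale_labels(nchar(records$sequence[i]), records$disorder[[i]])
      loc <- lab[hits$n_position]
      spans <- lab[hits$n_position] != lab[hits$n_position + 1L] |
        lab[hits$n_position + 1L] != lab[hits$n_position + 2L]
      isg <- hits$n_position %in% records$glycosites[[i]]
    } else {
      loc <- rep("ORDERED", nrow(hits))
      spans <- rep(FALSE, nrow(hits))
      isg <- rep(FALSE, nrow(hits))
    }
    dplyr::mutate(hits, protein_id = id, locale = loc,
                  is_glycosite = isg, spans_boundary = spans)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    return(tibble(
      protein_id = character(0), n_position = integer(0),
      x_residue = character(0), third_residue = character(0),
      locale = character(0), is_glycosite = logical(0),
      spans_boundary = logical(0)
    ))
  }
  dplyr::select(out, "protein_id", "n_position", "x_residue", "third_residue",
                "locale", "is_glycosite", "spans_boundary")
}

#' Default residue property classes for the sequon X position
#'
#' The class table used by [classify_x()]: acidic \{D, E\}; basic \{K, R, H\};
#' hydrophobic = positive Kyte-Doolittle hydropathy; bulky = upper half of the
#' Zimmerman bulkiness scale; small \{G, A, S, C, T, P, N, D\}; hydrophilic =
#' complement of hydrophobic. Classes may overlap. Pass an edited copy to
#' [classify_x()] / [x_class_profile()] to swap conventions.
#'
#' @return Named list of character vectors, one per class.
#' @export
default_x_classes <- function() {
  scales <- builtin_scales()
  kd <- scales$hydrophobicity
  bulk <- scales$bulkiness
  hydrophobic <- names(kd$values)[kd$values > 0]
  bulky <- names(sort(bulk$values, decreasing = TRUE))[1:10]
  list(
    acidic = c("D", "E"),
    basic = c("K", "R", "H"),
    hydrophobic = hydrophobic,
    bulky = bulky,
    small = c("G", "A", "S", "C", "T", "P", "N", "D"),
    hydrophilic = setdiff(AA20, hydrophobic)
  )
}

#' Property classes of a sequon X residue
#'
#' @param residue Character vector of single amino-acid letters.
#' @param classes Class table; see [default_x_classes()].
#' @return A list (one element per input residue) of class-label character
#'   vectors; empty (with a warning) for non-standard residues such as `X`.
#' @export
classify_x <- function(residue, classes = default_x_classes()) {
  out <- lapply(residue, function(r) {
    if (!r %in% AA20) {
      warn(paste0("Non-standard residue '", r, "' has no property classes"))
      return(character(0))
    }
    names(classes)[vapply(classes, function(cl) r %in% cl, logical(1))]
  })
  if (length(out) == 1L) out[[1L]] else out
}

#' Per-region class profile of sequon X residues
#'
#' For each locale (ordered/disordered), the proportion of sequons whose X
#' residue belongs to each property class. Classes overlap, so proportions
#' need not sum to 1.
#'
#' @param records A `glyco_records` tibble.
#' @param classes Class table; see [default_x_classes()].
#' @return A tibble with columns `locale`, `class`, `n_sequons`, `proportion`.
#'   A locale with zero sequons yields `NA` proportions.
#' @export
x_class_profile <- function(records, classes = default_x_classes()) {
  seqn <- scan_sequons(records)
  if (nrow(seqn) == 0L) abort("No sequons found in the record set")
  purrr::map_dfr(LOCALE_LEVELS, function(loc) {
    xs <- seqn$x_residue[seqn$locale == loc]
    if (length(xs) == 0L) {
      inform(paste0("No sequons in ", loc, " regions; profile is NA"))
      return(tibble(locale = loc, class = names(classes),
                    n_sequons = 0L, proportion = NA_real_))
    }
    prop <- vapply(classes, function(cl) mean(xs %in% cl), numeric(1))
    tibble(locale = loc, class = names(classes),
           n_sequons = length(xs), proportion = unname(prop))
  })
}

#' Fraction of asparagines participating in a sequon, per region
#'
#' For one record and one locale, the fraction of asparagine residues in that
#' locale that are the N of some sequon.
#'
#' @param records A `glyco_records` tibble.
#' @param region `"ORDERED"` or `"DISORDERED"`.
#' @return A tibble with `protein_id`, `region`, `n_asn`, `n_in_sequon`,
#'   `fraction` (`NA` when the region contains no asparagine).
#' @export
sequon_asn_fraction <- function(records, region = c("ORDERED", "DISORDERED")) {
  region <- match.arg(region)
  purrr::map_dfr(seq_len(nrow(records)), function(i) {
    seq_i <- records$sequence[i]
    lab <- locale_labels(nchar(seq_i), records$disorder[[i]])
    ch <- strsplit(seq_i, "", fixed = TRUE)[[1L]]
    asn <- which(ch == "N" & lab == region)
    hits <- find_sequons(seq_i)$n_position
    tibble(
      protein_id = records$protein_id[i],
      region = region,
      n_asn = length(asn),
      n_in_sequon = sum(asn %in% hits),
      fraction = if (length(asn) == 0L) NA_real_ else sum(asn %in% hits) / length(asn)
    )
  })
}
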