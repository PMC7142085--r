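# Annotation tables use UniProt-style 1-based coordinates; disorder intervals
# are 1-based inclusive. '#'-prefixed lines are comments.

read_tsv_checked <- function(path, col_names, col_types) {
  if (!file.exists(path)) {
    abort(paste0("Annotation table not found: ", path))
  }
  x <- readr::read_tsv(path, comment = "#", col_types = readr::cols(.default = readr::col_character()),
                       progress = FALSE)
  if (!identical(names(x), col_names)) {
    abort(sprintf(
      "Expected header '%s' in %s, found '%s'",
      paste(col_names, collapse = "\\t"), path, paste(names(x), collapse = "\\t")
    ))
  }
  for (j in which(col_types == "i")) {
    raw <- x[[j]]
    val <- suppressWarnings(as.integer(raw))
    bad <- which(is.na(val) & !is.na(raw))
    if (length(bad) > 0L) {
      abort(sprintf(
        "Non-integer value '%s' in column '%s' of %s (data line %d)",
        raw[bad[1L]], col_names[j], path, bad[1L]
      ))
    }
    x[[j]] <- val
  }
  x
}

#' Read a glycosite annotation table
#'
#' @param path TSV file with header `protein_id<TAB>position`; positions are
#'   1-based. Lines starting with `#` are ignored.
#' @return A tibble with columns `protein_id` (character) and `position`
#'   (integer, 1-based).
#' @export
read_glycosite_table <- function(path) {
  x <- read_tsv_checked(path, c("protein_id", "position"), c("c", "i"))
  if (nrow(x) > 0L && any(x$position < 1L)) {
    abort(sprintf("Glycosite positions must be >= 1 (%s)", path))
  }
  x
}

#' Read a disorder-interval annotation table
#'
#' @param path TSV file with header `protein_id<TAB>start<TAB>end`; intervals
#'   are 1-based inclusive. An empty table (header only) is valid and means
#'   all proteins are fully ordered.
#' @return A tibble with columns `protein_id`, `start`, `end` (integers,
#'   1-based inclusive).
#' @export
read_disorder_table <- function(path) {
  x <- read_tsv_checked(path, c("protein_id", "start", "end"), c("c", "i", "i"))
  if (nrow(x) > 0L) {
    if (any(x$start < 1L)) abort(sprintf("Disorder interval starts must be >= 1 (%s)", path))
    bad <- which(x$start > x$end)
    if (length(bad) > 0L) {
      abort(sprintf(
        "Disorder interval with start > end for protein '%s' (%d > %d) in %s",
        x$protein_id[bad[1L]], x$start[bad[1L]], x$end[bad[1L]], path
      ))
    }
  }
  x
}

#' Read both annotation tables at once
#'
#' @param glyco_path Path to the glycosite TSV (see [read_glycosite_table()]).
#' @param disorder_path Path to the disorder TSV (see [read_disorder_table()]).
#' @return A list with elements `glycosites` and `disorder`.
#' @export
read_annotation_tables <- function(glyco_path, disorder_path) {
  list(
    glycosites = read_glycosite_table(glyco_path),
    disorder = read_disorder_table(disorder_path)
  )
}

#' Write a tibble as a TSV with header
#'
#' All pipeline stage outputs use this writer (UTF-8, tab-separated, header
#' row, no quoting).
#'
#' @param x A data frame. List-columns are not supported.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}
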