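# 11-residue windows: glycosite-centered neighborhoods and glycosite-free
# ordered/disordered control windows. Window length is configurable but must
# be odd; the neighborhood center is the glycosylated asparagine.

#' Extract glycosite-centered neighborhood windows
#'
#' One window per glycosite lying at least `flank` residues from each
#' terminus; glycosites closer to a terminus are skipped (and reported via a
#' message) so all windows are directly comparable.
#'
#' @param records A `glyco_records` tibble.
#' @param window_length Odd window length (default 11, i.e. 5 residues each
#'   side of the asparagine).
#' @return A tibble with `protein_id`, `kind` (`"NEIGHBORHOOD"`), `start`
#'   (1-based), `residues`, `center_locale`, `locale_purity` (fraction of
#'   window residues sharing `center_locale`).
#' @export
extract_neighborhoods <- function(records, window_length = 11L) {
  stopifnot(window_length %% 2L == 1L, window_length >= 3L)
  flank <- (window_length - 1L) %/% 2L
  skipped <- 0L
  rows <- purrr::map(seq_len(nrow(records)), function(i) {
    pos <- records$glycosites[[i]]
    if (length(pos) == 0L) return(NULL)
    len <- records$length[i]
    keep <- pos > flank & pos <= len - flank
    skipped <<- skipped + sum(!keep)
    pos <- pos[keep]
    if (length(pos) == 0L) return(NULL)
    lab <- locale_labels(len, records$disorder[[i]])
    s <- pos - flank
    purity <- vapply(seq_along(pos), function(k) {
      mean(lab[s[k]:(s[k] + window_length - 1L)] == lab[pos[k]])
    }, numeric(1))
    tibble::new_tibble(list(
      protein_id = rep(records$protein_id[i], length(pos)),
      kind = rep("NEIGHBORHOOD", length(pos)),
      start = s,
      residues = substring(records$sequence[i], s, s + window_length - 1L),
      center_locale = lab[pos],
      locale_purity = purity
    ))
  })
  if (skipped > 0L) {
    inform(paste0(skipped, " glycosite(s) skipped: too close to a terminus for a ",
                  window_length, "-residue neighborhood"))
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble(protein_id = character(0), kind = character(0), start = integer(0),
                  residues = character(0), center_locale = character(0),
                  locale_purity = numeric(0))
  }
  out
}

# All eligible 1-based start positions of a control window of class `locale`
# for one record row: every residue in the window has that locale, the window
# contains no glycosite, and it does not intersect any glycosite neighborhood
# span [g - flank, g + flank].
eligible_control_starts <- function(sequence_length, disorder, glycosites, locale,
                                    window_length = 11L) {
  flank <- (window_length - 1L) %/% 2L
  if (sequence_length < window_length) return(integer(0))
  lab <- locale_labels(sequence_length, disorder)
  blocked <- rep(FALSE, sequence_length)
  for (g in glycosites) {
    blocked[max(1L, g - flank):min(sequence_length, g + flank)] <- TRUE
  }
  ok <- (lab == locale) & !blocked
  # window starts whose full span is eligible, via a running sum of ok flags
  cs <- cumsum(ok)
  starts <- seq_len(sequence_length - window_length + 1L)
  span_ok <- (cs[starts + window_length - 1L] -
                c(0L, cs)[starts]) == window_length
  starts[span_ok]
}

#' Sample ordered/disordered control windows
#'
#' For each protein and each locale class, samples uniformly (given the seed)
#' among all glycosite-free, locale-pure windows that do not overlap any
#' glycosite neighborhood. Proteins with no eligible window for a class get an
#' `NA` row for that class.
#'
#' @param records A `glyco_records` tibble.
#' @param seed Integer seed making the sampling reproducible; `NULL` uses the
#'   current RNG state.
#' @param window_length Odd window length (default 11).
#' @param controls_per_protein Number of control windows per class per protein
#'   (default 1, sampled without replacement up to availability).
#' @return A tibble with `protein_id`, `kind` (`"ORDERED_CONTROL"` /
#'   `"DISORDERED_CONTROL"`), `start`, `residues`, `center_locale`,
#'   `locale_purity` (1 by construction); `start`/`residues` are `NA` when no
#'   eligible window exists.
#' @export
sample_control_windows <- function(records, seed = NULL, window_length = 11L,
                                   controls_per_protein = 1L) {
  stopifnot(window_length %% 2L == 1L, controls_per_protein >= 1L)
  with_seed(seed, {
    rows <- purrr::map(seq_len(nrow(records)), function(i) {
      per_class <- lapply(c("ORDERED", "DISORDERED"), function(locale) {
        kind <- if (locale == "ORDERED") "ORDERED_CONTROL" else "DISORDERED_CONTROL"
        starts <- eligible_control_starts(
          records$length[i], records$disorder[[i]], records$glycosites[[i]],
          locale, window_length
        )
        if (length(starts) == 0L) {
          return(list(kind = kind, start = NA_integer_, residues = NA_character_,
                      locale = locale, purity = NA_real_))
        }
        k <- min(controls_per_protein, length(starts))
        s <- if (length(starts) == 1L) starts else sample(starts, k)
        list(kind = rep(kind, k), start = s,
             residues = substring(records$sequence[i], s, s + window_length - 1L),
             locale = rep(locale, k), purity = rep(1, k))
      })
      n_i <- sum(lengths(lapply(per_class, `[[`, "start")))
      tibble::new_tibble(list(
        protein_id = rep(records$protein_id[i], n_i),
        kind = unlist(lapply(per_class, `[[`, "kind"), use.names = FALSE),
        start = unlist(lapply(per_class, `[[`, "start"), use.names = FALSE),
        residues = unlist(lapply(per_class, `[[`, "residues"), use.names = FALSE),
        center_locale = unlist(lapply(per_class, `[[`, "locale"), use.names = FALSE),
        locale_purity = unlist(lapply(per_class, `[[`, "purity"), use.names = FALSE)
      ))
    })
    dplyr::bind_rows(rows)
  })
}
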