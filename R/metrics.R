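# Per-protein paired locale metrics: glycosite locale fractions, residue
# percentages and sequon densities in ordered vs disordered regions. Each
# metric yields one (ordered, disordered) pair per protein for the matched
# Wilcoxon test.

#' Per-protein glycosite locale fractions
#'
#' Fraction of a protein's glycosites whose locale is ordered; the
#' disordered fraction is its complement. Proteins without glycosites get
#' `NA`.
#'
#' @param records A `glyco_records` tibble.
#' @return A tibble with `protein_id`, `n_glycosites`, `ordered_fraction`,
#'   `disordered_fraction`.
#' @export
glycosite_locale_fractions <- function(records) {
  f <- vapply(seq_len(nrow(records)), function(i) {
    pos <- records$glycosites[[i]]
    if (length(pos) == 0L) return(NA_real_)
    d <- records$disorder[[i]]
    if (nrow(d) == 0L) return(1)
    dis <- vapply(pos, function(p) any(p >= d$start & p <= d$end), logical(1))
    mean(!dis)
  }, numeric(1))
  tibble(protein_id = records$protein_id, n_glycosites = records$n_glycosites,
         ordered_fraction = f, disordered_fraction = 1 - f)
}

# Total residue count of a locale class in one record row.
region_length <- function(records, i, region) {
  sum(locale_labels(records$length[i], records$disorder[[i]]) == region)
}

#' Percentage of a residue set within a region
#'
#' Per protein, `100 * (# region residues in residue_set) / (region length)`;
#' `NA` when the protein has no residues of that locale.
#'
#' @param records A `glyco_records` tibble.
#' @param residue_set Character vector of amino-acid letters, e.g. `"N"` or
#'   `c("S", "T")`.
#' @param region `"ORDERED"` or `"DISORDERED"`.
#' @return A tibble with `protein_id`, `region`, `region_length`, `percent`.
#' @export
metric_residue_percent <- function(records, residue_set,
                                   region = c("ORDERED", "DISORDERED")) {
  region <- match.arg(region)
  purrr::map_dfr(seq_len(nrow(records)), function(i) {
    lab <- locale_labels(records$length[i], records$disorder[[i]])
    ch <- chars(records$sequence[i])
    in_region <- lab == region
    len <- sum(in_region)
    tibble(
      protein_id = records$protein_id[i], region = region, region_length = len,
      percent = if (len == 0L) NA_real_ else 100 * sum(ch[in_region] %in% residue_set) / len
    )
  })
}

#' Sequon density within a region
#'
#' Per protein, sequons per 100 residues of a locale class: `100 * (# sequons
#' whose asparagine has the region's locale) / (region length)`; `NA` when
#' the region is shorter than 3 residues.
#'
#' @inheritParams metric_residue_percent
#' @return A tibble with `protein_id`, `region`, `region_length`,
#'   `density_per_100`.
#' @export
metric_sequon_density <- function(records, region = c("ORDERED", "DISORDERED")) {
  region <- match.arg(region)
  seqn <- scan_sequons(records)
  counts <- table(seqn$protein_id[seqn$locale == region])
  purrr::map_dfr(seq_len(nrow(records)), function(i) {
    id <- records$protein_id[i]
    len <- region_length(records, i, region)
    k <- if (id %in% names(counts)) as.integer(counts[[id]]) else 0L
    tibble(
      protein_id = id, region = region, region_length = len,
      density_per_100 = if (len < 3L) NA_real_ else 100 * k / len
    )
  })
}

#' Paired per-protein locale metric table
#'
#' Builds the full paired metric table used for the matched Wilcoxon tests:
#' for each protein, ordered vs disordered values of glycosite occurrence,
#' Asn/Ser/Thr percentages, sequon density and sequon-participating Asn
#' fraction.
#'
#' @param records A `glyco_records` tibble.
#' @return A tibble with `protein_id`, `metric`, `value_ordered`,
#'   `value_disordered` (long over metrics). Metrics: `glycosite_fraction`,
#'   `asn_percent`, `ser_percent`, `thr_percent`, `sequon_density`,
#'   `sequon_asn_fraction`.
#' @export
locale_metric_table <- function(records) {
  frac <- glycosite_locale_fractions(records)
  pair_from <- function(metric, ord, dis, value_col) {
    tibble(protein_id = ord$protein_id, metric = metric,
           value_ordered = ord[[value_col]], value_disordered = dis[[value_col]])
  }
  dplyr::bind_rows(
    tibble(protein_id = frac$protein_id, metric = "glycosite_fraction",
           value_ordered = frac$ordered_fraction,
           value_disordered = frac$disordered_fraction),
    pair_from("asn_percent",
              metric_residue_percent(records, "N", "ORDERED"),
              metric_residue_percent(records, "N", "DISORDERED"), "percent"),
    pair_from("ser_percent",
              metric_residue_percent(records, "S", "ORDERED"),
              metric_residue_percent(records, "S", "DISORDERED"), "percent"),
    pair_from("thr_percent",
              metric_residue_percent(records, "T", "ORDERED"),
              metric_residue_percent(records, "T", "DISORDERED"), "percent"),
    pair_from("sequon_density",
              metric_sequon_density(records, "ORDERED"),
              metric_sequon_density(records, "DISORDERED"), "density_per_100"),
    pair_from("sequon_asn_fraction",
              sequon_asn_fraction(records, "ORDERED"),
              sequon_asn_fraction(records, "DISORDERED"), "fraction")
  )
}

#' Test every paired metric with the Wilcoxon signed-rank test
#'
#' @param metric_table Output of [locale_metric_table()] (long format) or any
#'   tibble with `metric`, `value_ordered`, `value_disordered`.
#' @return A tibble with one row per metric: `metric`, `n_pairs`,
#'   `n_effective`, `statistic`, `p_value`, `method`.
#' @export
test_locale_metrics <- function(metric_table) {
  metric_table |>
    dplyr::group_by(.data$metric) |>
    dplyr::group_modify(function(df, key) {
      res <- suppressWarnings(
        wilcoxon_signed_rank(df$value_ordered, df$value_disordered)
      )
      dplyr::mutate(tidy(res), n_pairs = nrow(df), .before = 1L)
    }) |>
    dplyr::ungroup() |>
    dplyr::select("metric", "n_pairs", "n_effective", "statistic", "p_value", "method")
}

#' Mean, median and standard error of the mean per metric and region
#'
#' NA-aware descriptive summary of a paired metric table, mirroring a
#' mean/median/SEM table layout. SEM uses the sample standard deviation over
#' the non-NA count (`NA` for a single value).
#'
#' @param metric_table As for [test_locale_metrics()].
#' @return A tibble with `metric`, `region`, `n`, `mean`, `median`, `sem`.
#' @export
summarize_metric <- function(metric_table) {
  long <- tidyr::pivot_longer(
    metric_table, dplyr::all_of(c("value_ordered", "value_disordered")),
    names_to = "region", names_prefix = "value_", values_to = "value"
  )
  long$region <- toupper(long$region)
  long |>
    dplyr::group_by(.data$metric, .data$region) |>
    dplyr::summarize(
      n = sum(!is.na(.data$value)),
      mean = if (n == 0L) NA_real_ else mean(.data$value, na.rm = TRUE),
      median = if (n == 0L) NA_real_ else median(.data$value, na.rm = TRUE),
      sem = if (n < 2L) NA_real_ else sd(.data$value, na.rm = TRUE) / sqrt(n),
      .groups = "drop"
    )
}
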