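# Cohort-level simulation experiments shared by the property tests.

# Per-protein glycosite locale pairs -> matched Wilcoxon p-value.
cohort_locale_test <- function(n_proteins, bias, seed, length_range = c(150L, 300L)) {
  sim <- simulate_cohort(generator_params(
    n_proteins = n_proteins, seed = seed, p_glycosite_ordered = bias,
    length_range = length_range
  ))
  gf <- glycosite_locale_fractions(sim$records)
  res <- suppressWarnings(
    wilcoxon_signed_rank(gf$ordered_fraction, gf$disordered_fraction)
  )
  list(mean_ordered = mean(gf$ordered_fraction, na.rm = TRUE), p = res$p_value)
}

# One ortholog-entropy cohort: TRUE if the mean neighborhood entropy is below
# the mean disordered-control entropy.
entropy_cohort_sign <- function(seed, nb_rate, dis_rate, ord_rate = 0.05,
                                n_proteins = 100L) {
  p <- generator_params(n_proteins = n_proteins, seed = seed,
                        length_range = c(150L, 300L),
                        neighborhood_rate = nb_rate, ordered_rate = ord_rate,
                        disordered_rate = dis_rate)
  sim <- simulate_cohort(p)
  nbw <- extract_neighborhoods(sim$records)
  nb_by <- split(nbw$start, nbw$protein_id)
  cw <- sample_control_windows(sim$records, seed = seed + 1000L)
  dc <- cw[cw$kind == "DISORDERED_CONTROL", ]
  dc_by <- setNames(dc$start, dc$protein_id)
  seeds <- glycolocale:::split_seed(seed + 5000L, nrow(sim$records))
  e_nb <- e_dc <- numeric(0)
  for (i in seq_len(nrow(sim$records))) {
    id <- sim$records$protein_id[i]
    st <- nb_by[[id]]
    d <- dc_by[id]
    if (is.null(st) || length(st) == 0L || is.na(d)) next
    og <- gen_orthologs(sim$records, id, p, seed = seeds[i])
    nb_pos <- unique(unlist(lapply(st, function(x) x:(x + 10L))))
    e_nb <- c(e_nb, region_mean_entropy(og$alignment, nb_pos))
    e_dc <- c(e_dc, region_mean_entropy(og$alignment, d:(d + 10L)))
  }
  mean(e_nb) < mean(e_dc)
}
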