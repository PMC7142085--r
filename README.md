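# glycolocale

Are N-linked glycosylation sites excluded from intrinsically disordered
regions? `glycolocale` is an R package for testing exactly that question on
annotated glycoprotein cohorts. It is aimed at protein bioinformaticians who
have, for each protein, a sequence, a set of experimentally established
N-glycosites, and predicted disorder intervals (from any disorder
meta-predictor — disorder prediction itself is out of scope), plus optionally
ortholog alignments for conservation analysis.

## What it computes

For a cohort of glycoproteins the package derives, per protein, the locale
(ordered/disordered) of every residue from the disorder intervals, and then:

* **Sequon analysis** — scans every N(X−P)S/T sequon (Asn followed by any
  residue except Pro, then Ser/Thr, overlaps included), classifies the X
  residue by property class (acidic, basic, hydrophobic, bulky, small,
  hydrophilic), and computes the fraction of asparagines participating in a
  sequon per locale.
* **Paired locale metrics** — per-protein pairs (ordered vs disordered) of
  glycosite occurrence, Asn/Ser/Thr percentages, and sequon density, tested
  with the Wilcoxon matched-pairs signed-rank test (exact null distribution
  for small tie-free samples, tie- and continuity-corrected normal
  approximation otherwise).
* **Composition enrichment** — 11-residue glycosite-centered neighborhoods
  and glycosite-free ordered/disordered control windows are pooled and
  compared as residue pools. For each amino acid *a* the fractional
  difference *D(a) = (C_q(a) − C_b(a)) / C_b(a)* is tested with a
  multinomial bootstrap (default 10,000 iterations), a two-sided z-test on
  *D*/SE, and Bonferroni correction; the same machinery scores
  composition-weighted residue property scales (hydropathy, bulkiness,
  flexibility, disorder propensity, ...).
* **Conservation** — per-column Shannon entropy (bits) of ortholog multiple
  alignments, mean entropy per region (neighborhoods, controls, full
  length), and the classic integer evolutionary-trace rank of each position
  given a species tree, again compared across regions with paired Wilcoxon
  tests.
* **Synthetic cohorts** — a generator producing glycoproteins with
  alternating ordered/disordered segments of distinct composition, sequon-
  embedded glycosites planted with a controllable ordered-locale bias, and
  gapless ortholog alignments evolved at region-specific substitution rates
  on a fixed (human, chimp, mouse, chicken) topology. Every analysis stage
  is testable against this known ground truth without downloading anything.

## Worked example

```r
library(glycolocale)

# a 50-protein synthetic cohort with the default 0.8 ordered-glycosite bias
sim  <- simulate_cohort(generator_params(n_proteins = 50, seed = 7))
frac <- glycosite_locale_fractions(sim$records)
wilcoxon_signed_rank(frac$ordered_fraction, frac$disordered_fraction)
#> Wilcoxon matched-pairs signed-rank test
#>   n_effective = 45 (dropped: 0 NA pair(s), 5 zero difference(s))
#>   W = 1018, p = 5.9456e-09  [normal_approx]
mean(frac$ordered_fraction, na.rm = TRUE)
#> [1] 0.839
```

The per-protein fraction of glycosites in ordered regions averages 0.84 and
the matched-pairs test rejects equal occurrence emphatically — the cohort
was built with an 0.8 ordered bias, so both numbers are as expected.

```r
neigh    <- extract_neighborhoods(sim$records)
controls <- sample_control_windows(sim$records, seed = 8)
dc  <- subset(controls, kind == "DISORDERED_CONTROL" & !is.na(start))
enr <- bootstrap_enrichment(neigh$residues, dc$residues,
                            iterations = 10000, seed = 9)
head(dplyr::arrange(as.data.frame(enr), d), 4)
#>   aa c_query c_background      d     se  p_value significant direction
#> 1  P  0.0319       0.1200 -0.734 0.0491 1.40e-50        TRUE  depleted
#> 2  K  0.0326       0.0800 -0.593 0.0868 8.21e-12        TRUE  depleted
#> 3  E  0.0369       0.0873 -0.578 0.0827 2.81e-12        TRUE  depleted
#> 4  Q  0.0393       0.0782 -0.497 0.1001 6.78e-07        TRUE  depleted
```

Glycosite neighborhoods are strongly depleted of proline and of charged
residues relative to disordered control windows — the disorder-associated
residues the generator enriches in disordered segments. `autoplot(enr)`
draws the enrichment profile; `run_pipeline()` executes every stage
end-to-end into a directory of TSVs, and `exec/glycolocale` exposes the same
stages as shell subcommands.

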