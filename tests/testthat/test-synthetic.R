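test_that("default compositions are valid distributions with the right biases", {
  comps <- default_compositions()
  expect_equal(sum(comps$ordered), 1, tolerance = 1e-9)
  expect_equal(sum(comps$disordered), 1, tolerance = 1e-9)
  for (aa in c("P", "E", "S", "R", "Q", "N", "M")) {
    expect_gt(comps$disordered[[aa]], comps$ordered[[aa]])
  }
  for (aa in c("W", "F", "Y", "I", "L", "V", "C")) {
    expect_gt(comps$ordered[[aa]], comps$disordered[[aa]])
  }
  # expected disorder-propensity score higher under the disordered composition
  sc <- builtin_scales()$disorder_propensity$values
  aa20 <- names(comps$ordered)
  expect_gt(sum(comps$disordered[aa20] * sc[aa20]),
            sum(comps$ordered[aa20] * sc[aa20]))
})

test_that("simulated cohorts validate, are deterministic and honor the truth", {
  p <- generator_params(n_proteins = 10, seed = 42)
  a <- simulate_cohort(p)
  b <- simulate_cohort(p)
  expect_equal(a, b)

  # truth locales agree with locale_of on the assembled records
  truth_loc <- locale_of(a$records, a$truth$protein_id, a$truth$position)
  expect_equal(truth_loc, a$truth$locale)
  # every planted site is a glycosite and a canonical sequon
  s <- scan_sequons(a$records)
  expect_true(all(paste(a$truth$protein_id, a$truth$position) %in%
                    paste(s$protein_id, s$n_position)))
  expect_true(all(a$truth$x_residue != "P"))
  expect_true(all(a$truth$third_residue %in% c("S", "T")))
  # planted sites stay clear of the termini
  len <- a$records$length[match(a$truth$protein_id, a$records$protein_id)]
  expect_true(all(a$truth$position >= 6 & a$truth$position <= len - 5))
})

test_that("an all-ordered bias plants every glycosite in ordered segments", {
  sim <- simulate_cohort(generator_params(n_proteins = 10, seed = 2,
                                          p_glycosite_ordered = 1.0))
  expect_true(all(sim$truth$locale == "ORDERED"))
  sim0 <- simulate_cohort(generator_params(n_proteins = 10, seed = 2,
                                           p_glycosite_ordered = 0.0))
  expect_true(all(sim0$truth$locale == "DISORDERED"))
})

test_that("realized disordered fraction tracks the target", {
  sim <- simulate_cohort(generator_params(n_proteins = 60, seed = 8,
                                          disordered_fraction = 0.35))
  expect_lt(abs(mean(sim$records$disordered_fraction) - 0.35), 0.05)
  sim2 <- simulate_cohort(generator_params(n_proteins = 60, seed = 9,
                                           disordered_fraction = 0.5))
  expect_lt(abs(mean(sim2$records$disordered_fraction) - 0.5), 0.05)
})

test_that("realized segment composition matches the generator composition", {
  # chi-square goodness of fit of ordered-segment residues (glycosite
  # neighborhoods masked out, since planting rewrites residues there)
  sim <- simulate_cohort(generator_params(n_proteins = 120, seed = 77))
  comps <- default_compositions()
  res_all <- character(0)
  for (i in seq_len(nrow(sim$records))) {
    lab <- locale_of(sim$records, sim$records$protein_id[i],
                     seq_len(sim$records$length[i]))
    ch <- strsplit(sim$records$sequence[i], "")[[1]]
    mask <- rep(FALSE, length(ch))
    for (g in sim$records$glycosites[[i]]) {
      mask[max(1, g - 5):min(length(ch), g + 5)] <- TRUE
    }
    res_all <- c(res_all, ch[lab == "ORDERED" & !mask])
  }
  counts <- table(factor(res_all, levels = names(comps$ordered)))
  pval <- suppressWarnings(chisq.test(counts, p = comps$ordered)$p.value)
  expect_gt(pval, 0.01)
})

test_that("empty cohorts and infeasible placements are handled", {
  expect_warning(sim <- simulate_cohort(generator_params(n_proteins = 0)), "empty")
  expect_equal(nrow(sim$records), 0L)
  dir <- withr::local_tempdir()
  out <- suppressWarnings(gen_cohort(generator_params(n_proteins = 0), dir))
  expect_true(file.exists(out$glycosites))

  # a fully ordered architecture cannot host a forced-disordered glycosite
  p_bad <- generator_params(n_proteins = 1, seed = 3, p_glycosite_ordered = 0,
                            disordered_fraction = 0.001,
                            length_range = c(40L, 50L),
                            ordered_segment_range = c(40L, 50L))
  expect_error(simulate_cohort(p_bad), "attempts")
})

test_that("ortholog generation respects rates, topology and determinism", {
  p <- generator_params(n_proteins = 3, seed = 12)
  sim <- simulate_cohort(p)
  id <- sim$records$protein_id[1]

  # zero rates: identical rows, zero entropy everywhere
  p0 <- generator_params(n_proteins = 3, seed = 12, neighborhood_rate = 0,
                         ordered_rate = 0, disordered_rate = 0)
  og0 <- gen_orthologs(sim$records, id, p0, seed = 1)
  expect_equal(length(unique(apply(og0$alignment$mat, 1, paste, collapse = ""))), 1L)
  expect_true(all(column_entropy(og0$alignment) == 0))

  og <- gen_orthologs(sim$records, id, p, seed = 7)
  og2 <- gen_orthologs(sim$records, id, p, seed = 7)
  expect_equal(og$alignment$mat, og2$alignment$mat)
  # gapless: ref_map is the identity
  expect_equal(og$alignment$ref_map, seq_len(sim$records$length[1]))
  expect_setequal(og$tree$tip.label, c("human", "chimp", "mouse", "chicken"))
  expect_true(ape::is.rooted(og$tree))
  # human row is the record itself
  expect_equal(paste(og$alignment$mat["human", ], collapse = ""),
               sim$records$sequence[1])

  # substitution density ranks with the branch scaling
  diffs <- vapply(c("chimp", "mouse", "chicken"), function(t) {
    mean(og$alignment$mat[t, ] != og$alignment$mat["human", ])
  }, numeric(1))
  expect_lt(diffs[["chimp"]], diffs[["chicken"]])
})

test_that("cohort manifest records parameters and seed", {
  dir <- withr::local_tempdir()
  out <- gen_cohort(generator_params(n_proteins = 3, seed = 5), dir)
  manifest <- jsonlite::read_json(out$manifest)
  expect_equal(manifest$seed, 5L)
  expect_equal(manifest$n_proteins, 3L)
  expect_equal(manifest$p_glycosite_ordered, 0.8)
})
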