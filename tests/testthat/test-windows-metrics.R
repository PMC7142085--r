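test_that("neighborhood extraction centers glycosites and skips termini", {
  seq20 <- paste0("AAAAAAAAA", "NGS", "AAAAAAAA")  # N at position 10
  r <- make_records("p1", seq20,
                    gly = tibble::tibble(protein_id = "p1", position = 10L))
  w <- extract_neighborhoods(r)
  expect_equal(w$start, 5L)
  expect_equal(nchar(w$residues), 11L)
  expect_equal(substr(w$residues, 6, 6), "N")

  # terminal glycosite skipped with a message
  r2 <- make_records("p2", "AANGSAAAAAAA",
                     gly = tibble::tibble(protein_id = "p2", position = 3L))
  expect_message(w2 <- extract_neighborhoods(r2), "skipped")
  expect_equal(nrow(w2), 0L)

  # two nearby glycosites give two overlapping windows
  seq30 <- paste0(strrep("A", 9), "NGSNGS", strrep("A", 15))
  r3 <- make_records("p3", seq30,
                     gly = tibble::tibble(protein_id = c("p3", "p3"),
                                          position = c(10L, 13L)))
  w3 <- extract_neighborhoods(r3)
  expect_equal(w3$start, c(5L, 8L))
})

test_that("neighborhood purity and center locale reflect the intervals", {
  r <- make_records("p1", paste0(strrep("A", 7), "NGS", strrep("A", 10)),
                    gly = tibble::tibble(protein_id = "p1", position = 8L),
                    dis = tibble::tibble(protein_id = "p1", start = 10L, end = 20L))
  w <- extract_neighborhoods(r)
  expect_equal(w$center_locale, "ORDERED")
  # window spans 3..13; positions 10..13 are disordered -> purity 7/11
  expect_equal(w$locale_purity, 7 / 11)
})

test_that("control sampling matches the brute-force eligibility oracle", {
  set.seed(13)
  for (rep in 1:20) {
    len <- sample(30:80, 1)
    n_dis <- sample(0:2, 1)
    ds <- sort(sample(seq_len(len - 12), n_dis))
    dis <- if (n_dis > 0) {
      tibble::tibble(start = ds, end = pmin(len, ds + sample(5:14, n_dis, TRUE)))
    } else {
      tibble::tibble(start = integer(0), end = integer(0))
    }
    gly <- sample(setdiff(seq(6, len - 5), 0), sample(0:2, 1))
    for (locale in c("ORDERED", "DISORDERED")) {
      got <- glycolocale:::eligible_control_starts(len, dis, gly, locale, 11L)
      want <- oracle_eligible_starts(len, as.data.frame(dis), gly, locale, 11)
      expect_equal(got, as.integer(want))
    }
  }
})

test_that("control sampling is seed-deterministic and respects eligibility", {
  sim <- simulate_cohort(generator_params(n_proteins = 12, seed = 21))
  a <- sample_control_windows(sim$records, seed = 4)
  b <- sample_control_windows(sim$records, seed = 4)
  expect_equal(a, b)
  cc <- sample_control_windows(sim$records, seed = 5)
  expect_false(identical(a$start, cc$start))

  nb <- extract_neighborhoods(sim$records)
  ok <- !is.na(a$start)
  for (i in which(ok)) {
    span <- a$start[i]:(a$start[i] + 10L)
    lab <- locale_of(sim$records, a$protein_id[i], span)
    expect_true(all(lab == a$center_locale[i]))
    # never intersects a neighborhood of the same protein
    nb_i <- nb[nb$protein_id == a$protein_id[i], ]
    if (nrow(nb_i) > 0) {
      for (s in nb_i$start) expect_length(intersect(span, s:(s + 10L)), 0)
    }
  }
})

test_that("a protein whose longest disordered run is under 11 gets NA control", {
  r <- make_records("p1", strrep("A", 40),
                    dis = tibble::tibble(protein_id = "p1", start = 5L, end = 14L))
  w <- sample_control_windows(r, seed = 1)
  expect_true(is.na(w$start[w$kind == "DISORDERED_CONTROL"]))
  expect_false(is.na(w$start[w$kind == "ORDERED_CONTROL"]))
})

test_that("glycosite locale fractions are complementary and correct", {
  r <- make_records("p1", paste0(strrep("A", 5), "NGSQQNGSQQNGS", strrep("A", 12)),
                    gly = tibble::tibble(protein_id = rep("p1", 3),
                                         position = c(6L, 11L, 16L)),
                    dis = tibble::tibble(protein_id = "p1", start = 14L, end = 20L))
  f <- glycosite_locale_fractions(r)
  expect_equal(f$ordered_fraction, 2 / 3)
  expect_equal(f$ordered_fraction + f$disordered_fraction, 1)
  # no glycosites -> NA
  f0 <- glycosite_locale_fractions(make_records("q", "AAAA"))
  expect_true(is.na(f0$ordered_fraction))
})

test_that("residue percentages and sequon density match hand counts", {
  r <- make_records("p1", "NNSAQQQQDD",
                    dis = tibble::tibble(protein_id = "p1", start = 5L, end = 10L))
  expect_equal(metric_residue_percent(r, "N", "ORDERED")$percent, 50)
  expect_equal(metric_residue_percent(r, c("S", "T"), "ORDERED")$percent, 25)
  expect_equal(metric_residue_percent(r, "N", "DISORDERED")$percent, 0)

  # fully ordered 100-mer with exactly 2 sequons
  seq100 <- paste0("NGS", strrep("A", 44), "NAT", strrep("A", 50))
  r2 <- make_records("p2", seq100)
  expect_equal(metric_sequon_density(r2, "ORDERED")$density_per_100, 2)
  d <- metric_sequon_density(r2, "DISORDERED")
  expect_true(is.na(d$density_per_100))  # zero-length region

  # fully disordered protein: ordered region empty -> NA percent
  r3 <- make_records("p3", "QQQQQQQQQQ",
                     dis = tibble::tibble(protein_id = "p3", start = 1L, end = 10L))
  expect_true(is.na(metric_residue_percent(r3, "N", "ORDERED")$percent))
})

test_that("metric summary returns NA-aware mean, median and SEM", {
  tab <- tibble::tibble(protein_id = c("a", "b", "c"), metric = "m",
                        value_ordered = c(1, 2, 3), value_disordered = c(1, NA, 3))
  s <- summarize_metric(tab)
  so <- s[s$region == "ORDERED", ]
  expect_equal(so$mean, 2)
  expect_equal(so$median, 2)
  expect_equal(so$sem, sd(1:3) / sqrt(3))
  sd_ <- s[s$region == "DISORDERED", ]
  expect_equal(sd_$n, 2L)
  expect_equal(sd_$mean, 2)

  one <- summarize_metric(tibble::tibble(protein_id = "a", metric = "m",
                                         value_ordered = 5, value_disordered = NA))
  expect_true(is.na(one$sem[one$region == "ORDERED"]))
  expect_true(is.na(one$mean[one$region == "DISORDERED"]))
})
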