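test_that("residue pooling tabulates fractions and drops unknown residues", {
  prof <- pool_residues(c("AAAAAAAAAAA"))
  expect_equal(prof$fraction[prof$aa == "A"], 1)
  expect_equal(sum(prof$fraction), 1, tolerance = 1e-12)

  prof2 <- pool_residues(c(strrep("A", 11), strrep("C", 11)))
  expect_equal(attr(prof2, "total"), 22L)

  expect_message(prof3 <- pool_residues("AAXXA"), "non-standard")
  expect_equal(attr(prof3, "total"), 3L)
  expect_error(pool_residues(character(0)), "Empty")
})

test_that("fractional difference follows the (Cq - Cb)/Cb definition", {
  q <- glycolocale:::composition_profile(c(rep("P", 10), rep("A", 90)))
  b <- glycolocale:::composition_profile(c(rep("P", 8), rep("A", 92)))
  d <- fractional_difference(q, b)
  expect_equal(d$d[d$aa == "P"], (0.10 - 0.08) / 0.08)
  # identical profiles: all D zero
  d0 <- fractional_difference(q, q)
  expect_true(all(d0$d == 0))
  # background zero, query positive -> NA; both zero -> 0
  expect_true(is.na(d$d[d$aa == "W"] == 0) || d$d[d$aa == "W"] == 0)
  q2 <- glycolocale:::composition_profile(c("W", "A"))
  b2 <- glycolocale:::composition_profile(c("A", "A"))
  d2 <- fractional_difference(q2, b2)
  expect_true(is.na(d2$d[d2$aa == "W"]))
  expect_equal(d2$d[d2$aa == "C"], 0)
  # reconstruction identity: sum Cb (1 + D) = 1 where defined
  ok <- !is.na(d$d)
  expect_equal(sum(d$c_background[ok] * (1 + d$d[ok])), 1, tolerance = 1e-12)
})

test_that("identical pools are never significant; results are seed-stable", {
  pool <- sample(rep(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 30))
  e1 <- bootstrap_enrichment(pool, pool, iterations = 500, seed = 2)
  expect_true(all(e1$d == 0))
  expect_true(all(!e1$significant))
  expect_true(all(e1$p_value == 1))
  e2 <- bootstrap_enrichment(pool, pool, iterations = 500, seed = 2)
  expect_equal(e1, e2)
})

test_that("a planted composition shift is detected with the right sign", {
  set.seed(31)
  bg_comp <- c(P = 0.05, A = 0.35, G = 0.30, S = 0.30)
  q_comp <- c(P = 0.10, A = 0.325, G = 0.30, S = 0.275)
  bg <- sample(names(bg_comp), 2000, TRUE, bg_comp)
  qu <- sample(names(q_comp), 2000, TRUE, q_comp)
  e <- bootstrap_enrichment(qu, bg, iterations = 1000, seed = 3)
  p_row <- e[e$aa == "P", ]
  expect_true(p_row$significant)
  expect_equal(p_row$direction, "enriched")
  expect_gt(p_row$d, 0)
})

test_that("bootstrap p-values track permutation p-values on null data", {
  set.seed(17)
  comp <- setNames(rep(0.05, 20), strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
  boot_p <- perm_p <- matrix(NA_real_, nrow = 30, ncol = 20)
  for (r in 1:30) {
    qu <- sample(names(comp), 400, TRUE, comp)
    bg <- sample(names(comp), 400, TRUE, comp)
    boot_p[r, ] <- bootstrap_enrichment(qu, bg, iterations = 300, seed = r)$p_value
    perm_p[r, ] <- permutation_enrichment(qu, bg, n_perm = 300, seed = r)$p_value
  }
  rho <- cor(as.vector(boot_p), as.vector(perm_p), method = "spearman",
             use = "complete.obs")
  expect_gt(rho, 0.8)
})

test_that("built-in scales cover the cited properties with 20 entries each", {
  sc <- builtin_scales()
  needed <- c("aromaticity", "polarity", "charge", "hydrophobicity",
              "flexibility", "exposure", "beta_frequency", "coil_frequency",
              "disorder_propensity", "order_propensity", "bulkiness")
  expect_true(all(needed %in% names(sc)))
  for (s in sc) {
    expect_length(s$values, 20)
    expect_false(anyNA(s$values))
    expect_true(nzchar(s$provenance))
  }
  expect_equal(unname(sc$aromaticity$values[c("F", "A")]), c(1, 0))
  expect_lt(sc$charge$values[["D"]], 0)
  expect_gt(sc$charge$values[["K"]], 0)
  expect_equal(sc$order_propensity$values, -sc$disorder_propensity$values)
})

test_that("property enrichment has forced signs and honest nulls", {
  sc <- builtin_scales()
  pool_g <- rep("G", 500)
  pool_w <- rep("W", 500)
  e <- property_enrichment(pool_g, pool_w, scales = sc["bulkiness"],
                           iterations = 200, seed = 5)
  expect_equal(e$difference,
               unname(sc$bulkiness$values[["G"]] - sc$bulkiness$values[["W"]]))
  expect_equal(e$direction, "depleted")

  same <- property_enrichment(pool_g, pool_g, scales = sc["bulkiness"],
                              iterations = 200, seed = 5)
  expect_equal(same$difference, 0)
  expect_equal(same$direction, "ns")

  # disorder propensity separates the generator's two compositions
  comps <- default_compositions()
  qu <- sample(names(comps$disordered), 2000, TRUE, comps$disordered)
  bg <- sample(names(comps$ordered), 2000, TRUE, comps$ordered)
  pe <- property_enrichment(qu, bg, scales = sc["disorder_propensity"],
                            iterations = 500, seed = 6)
  expect_gt(pe$difference, 0)
})

test_that("three pairwise comparisons are directionally consistent", {
  # planted compositions: neighborhood-like pool intermediate in P between
  # ordered and disordered controls
  set.seed(23)
  comps <- default_compositions()
  nb <- sample(names(comps$ordered), 3000, TRUE, comps$ordered)
  oc <- sample(names(comps$ordered), 3000, TRUE, comps$ordered)
  dc <- sample(names(comps$disordered), 3000, TRUE, comps$disordered)
  e_nd <- bootstrap_enrichment(nb, dc, iterations = 500, seed = 1)
  e_od <- bootstrap_enrichment(oc, dc, iterations = 500, seed = 2)
  both <- dplyr::inner_join(
    dplyr::filter(e_nd, .data$significant),
    dplyr::filter(e_od, .data$significant),
    by = "aa", suffix = c("_nd", "_od")
  )
  # amino acids significant in both neighborhood-vs-disordered and
  # ordered-vs-disordered comparisons shift the same way
  expect_gt(nrow(both), 0)
  expect_true(all(sign(both$d_nd) == sign(both$d_od)))
})
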