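test_that("MSA construction validates rows and builds the reference map", {
  aln <- ortholog_msa(c("human", "mouse"), c("A-C", "AGC"), "human")
  expect_equal(aln$ref_map, c(1L, 3L))
  expect_error(ortholog_msa(c("a", "b"), c("AC", "ACG"), "a"), "unequal")
  expect_error(ortholog_msa(c("a", "b"), c("AC", "AG"), "zz"), "not present")

  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">human", "AC-D", ">mouse", "ACGD", ">fly", "AC-D"), fa)
  aln2 <- read_msa(fa, "human")
  expect_equal(length(aln2$taxa), 3L)
  expect_equal(aln2$ref_map, c(1L, 2L, 4L))
  expect_error(read_msa(fa, "chicken"), "not present")
})

test_that("link_alignment checks the ungapped reference against the record", {
  r <- make_records("p1", "ACD")
  aln <- ortholog_msa(c("human", "mouse"), c("AC-D", "ACGD"), "human")
  expect_true(link_alignment(aln, r, "p1"))
  aln_bad <- ortholog_msa(c("human", "mouse"), c("ACCD", "ACGD"), "human")
  expect_error(link_alignment(aln_bad, r, "p1"), "p1")
})

test_that("column entropy matches hand computations under both gap policies", {
  aln <- ortholog_msa(c("a", "b", "c", "d"),
                      c("AAAA", "AC-A", "AD-A", "AE-A"), "a")
  expect_equal(column_entropy(aln, 1L), 0)
  expect_equal(column_entropy(aln, 2L), 2)  # uniform over 4 symbols
  # column 3: {A, -, -, -} with gap as symbol: H({1,3}/4)
  expect_equal(column_entropy(aln, 3L),
               -(1 / 4 * log2(1 / 4) + 3 / 4 * log2(3 / 4)))
  expect_equal(column_entropy(aln, 3L, gap_policy = "skip_gapped_rows"), 0)
  # "AA-C" pattern: counts {2,1,1}/4 = 1.5 bits
  aln2 <- ortholog_msa(c("a", "b", "c", "d"), c("A", "A", "-", "C"), "a")
  expect_equal(column_entropy(aln2, 1L), 1.5)
  # all-gap column under skip policy is NA
  aln3 <- ortholog_msa(c("a", "b"), c("A-", "A-"), "a")
  expect_true(is.na(column_entropy(aln3, 2L, gap_policy = "skip_gapped_rows")))
})

test_that("entropy bounds and row-permutation invariance hold", {
  set.seed(5)
  sym <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "-")
  for (rep in 1:10) {
    n_rows <- sample(3:8, 1)
    mat <- replicate(n_rows, paste(sample(sym, 25, TRUE), collapse = ""))
    mat[1] <- gsub("-", "A", mat[1])  # reference must have ungapped positions
    aln <- ortholog_msa(paste0("t", 1:n_rows), mat, "t1")
    h <- column_entropy(aln)
    expect_true(all(h >= 0 & h <= log2(21) + 1e-12))
    h_skip <- column_entropy(aln, gap_policy = "skip_gapped_rows")
    expect_true(all(is.na(h_skip) | (h_skip >= 0 & h_skip <= log2(20) + 1e-12)))
    perm <- sample(n_rows)
    aln_p <- ortholog_msa(paste0("t", 1:n_rows)[perm], mat[perm], "t1")
    expect_equal(column_entropy(aln_p), h)
  }
})

test_that("region mean entropy maps reference positions through ref_map", {
  aln <- ortholog_msa(c("human", "m"), c("AC-DF", "AG-EF"), "human")
  # reference positions 1..4 map to columns 1,2,4,5
  expect_equal(region_mean_entropy(aln, 2L), 1)
  expect_equal(region_mean_entropy(aln, c(1L, 4L)), 0)
  expect_equal(region_mean_entropy(aln, 1:4), mean(c(0, 1, 1, 0)))
  expect_error(region_mean_entropy(aln, integer(0)), "Empty")
  expect_error(region_mean_entropy(aln, 9L), "outside")
  # identical orthologs: zero everywhere
  aln0 <- ortholog_msa(c("human", "m"), c("ACDF", "ACDF"), "human")
  expect_equal(region_mean_entropy(aln0, 1:4), 0)
})

test_that("ET ranks follow the partition-level definition on known trees", {
  tree <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  aln <- ortholog_msa(c("A", "B", "C", "D"),
                      c("LLWA", "LLWC", "VLWG", "VLWT"), "A")
  rk <- et_rank(aln, tree)
  expect_equal(rk$rank[2], 1L)  # invariant column
  expect_equal(rk$rank[1], 2L)  # A=B='L', C=D='V' resolves at level 2
  expect_equal(rk$rank[4], 4L)  # one residue per leaf
})

test_that("ET ranks equal the graph-components oracle on random 6-leaf trees", {
  skip_if_not_installed("igraph")
  set.seed(11)
  aas <- strsplit("ACDEFG", "")[[1]]
  for (rep in 1:15) {
    tree <- ape::rtree(6)
    cols <- replicate(12, setNames(sample(aas, 6, TRUE), tree$tip.label))
    seqs <- apply(cols, 1, paste, collapse = "")
    aln <- ortholog_msa(tree$tip.label, seqs, tree$tip.label[1])
    rk <- et_rank(aln, tree)
    for (j in 1:12) {
      expect_equal(rk$rank[j], oracle_et_rank(tree, cols[, j]),
                   info = paste("rep", rep, "col", j))
    }
  }
})

test_that("ET rank handles unrooted trees and mismatched taxa", {
  tree <- ape::unroot(ape::rtree(5))
  aln <- ortholog_msa(tree$tip.label, rep("AAA", 5), tree$tip.label[1])
  expect_warning(rk <- et_rank(aln, tree), "midpoint")
  expect_true(all(rk$rank == 1L))

  aln_bad <- ortholog_msa(c("x", "y", "z", "w", "v"), rep("AAA", 5), "x")
  expect_error(et_rank(aln_bad, ape::rtree(5)), "tip labels")
})

test_that("region rank comparison aggregates means and runs paired tests", {
  tree <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  mk <- function(seqs) ortholog_msa(c("A", "B", "C", "D"), seqs, "A")
  # protein 1: positions 1-2 invariant, 3-4 variable
  a1 <- mk(c("AAGT", "AACG", "AATC", "AAAA"))
  a2 <- mk(c("CCAT", "CCCG", "CCGC", "CCTA"))
  rk <- dplyr::bind_rows(
    dplyr::mutate(et_rank(a1, tree), protein_id = "p1"),
    dplyr::mutate(et_rank(a2, tree), protein_id = "p2")
  )
  regions <- tibble::tibble(
    protein_id = rep(c("p1", "p2"), each = 4),
    region = rep(rep(c("conserved", "variable"), each = 2), 2),
    position = rep(c(1L, 2L, 3L, 4L), 2)
  )
  cmp <- compare_region_ranks(rk, regions)
  expect_equal(nrow(cmp$means), 4L)
  m <- cmp$means
  expect_true(all(m$mean_rank[m$region == "conserved"] == 1))
  expect_true(all(m$mean_rank[m$region == "variable"] > 1))
  expect_equal(nrow(cmp$tests), 1L)
  expect_equal(cmp$tests$n_effective, 2L)
})
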