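# Integer evolutionary-trace ranking: internal tree nodes ordered by distance
# from the root define partition levels; the rank of an alignment column is
# the smallest level at which the column is invariant within every leaf
# group. Rank 1 = invariant across all rows; a column that is only invariant
# in singleton groups gets rank = number of leaves.

# Leaf group labels at every partition level. Returns a levels x leaves
# integer matrix; row k gives the group id of each leaf at level k
# (activating the k-1 shallowest internal nodes as split points).
partition_levels <- function(tree) {
  ntip <- length(tree$tip.label)
  depths <- ape::node.depth.edgelength(tree)
  internal <- (ntip + 1L):(ntip + tree$Nnode)
  # ties in depth broken by node number (ape traversal order), documented
  internal <- internal[order(depths[internal], internal)]
  parent <- integer(ntip + tree$Nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  root <- internal[1L]
  # root-to-leaf paths (node sequences), computed once
  paths <- lapply(seq_len(ntip), function(leaf) {
    p <- leaf
    node <- leaf
    while (node != root) {
      node <- parent[node]
      p <- c(p, node)
    }
    rev(p)  # root ... leaf
  })
  n_levels <- length(internal) + 1L
  out <- matrix(0L, nrow = n_levels, ncol = ntip)
  for (k in seq_len(n_levels)) {
    active <- internal[seq_len(k - 1L)]
    labels <- vapply(paths, function(p) {
      on_path <- p[p %in% c(active)]
      if (length(on_path) == 0L) return("root")
      # deepest activated node on the path, and the child followed below it
      na <- on_path[length(on_path)]
      child <- p[match(na, p) + 1L]
      paste(na, child)
    }, character(1))
    out[k, ] <- as.integer(factor(labels))
  }
  out
}

#' Integer evolutionary-trace ranks of alignment columns
#'
#' Implements the classic integer evolutionary trace given an alignment and a
#' phylogenetic tree of its taxa: internal nodes sorted by distance from the
#' root define partition levels; at each level the leaves fall into groups,
#' and the rank of a column is the smallest level at which the column's
#' residues are identical within every group (gaps count as a distinct
#' symbol). Invariant columns get rank 1; columns with a distinct residue per
#' leaf get rank = number of leaves. Ties in node depth are broken by node
#' number (deterministic).
#'
#' @param alignment An `ortholog_msa`; taxa must equal the tree's tip labels.
#' @param tree A rooted `phylo` object ([ape::read.tree()]); an unrooted tree
#'   is midpoint-rooted with a warning.
#' @return An `et_rank` tibble with `position` (ungapped reference position),
#'   `column` (alignment column) and `rank`.
#' @export
et_rank <- function(alignment, tree) {
  if (!inherits(tree, "phylo")) abort("`tree` must be an ape 'phylo' object")
  if (!setequal(tree$tip.label, alignment$taxa)) {
    abort("Tree tip labels do not match the alignment's taxa")
  }
  if (!ape::is.rooted(tree)) {
    warn("Tree is unrooted; midpoint-rooting it")
    tree <- midpoint_root(tree)
  }
  if (is.null(tree$edge.length)) {
    tree$edge.length <- rep(1, nrow(tree$edge))
  }
  groups <- partition_levels(tree)          # levels x leaves
  mat <- alignment$mat[tree$tip.label, , drop = FALSE]
  n_levels <- nrow(groups)
  nc <- ncol(mat)
  ranks <- rep(length(tree$tip.label), nc)
  unranked <- rep(TRUE, nc)
  for (k in seq_len(n_levels)) {
    ok <- rep(TRUE, nc)
    for (grp in unique(groups[k, ])) {
      rows <- which(groups[k, ] == grp)
      if (length(rows) < 2L) next
      ref <- mat[rows[1L], ]
      for (r in rows[-1L]) ok <- ok & (mat[r, ] == ref)
    }
    hit <- unranked & ok
    ranks[hit] <- k
    unranked[hit] <- FALSE
    if (!any(unranked)) break
  }
  out <- tibble(
    position = seq_along(alignment$ref_map),
    column = alignment$ref_map,
    rank = ranks[alignment$ref_map]
  )
  class(out) <- c("et_rank", class(out))
  out
}

# Midpoint rooting without an extra hard dependency: root on the midpoint of
# the longest tip-to-tip path.
midpoint_root <- function(tree) {
  d <- ape::cophenetic.phylo(tree)
  ij <- which(d == max(d), arr.ind = TRUE)[1L, ]
  ape::root(tree, outgroup = rownames(d)[ij[1L]], resolve.root = TRUE)
}

#' Per-region mean evolutionary-trace ranks with paired tests
#'
#' Given per-protein rank tables and region position sets, computes the mean
#' rank per protein and region and tests each region pair across proteins
#' with the Wilcoxon matched-pairs signed-rank test.
#'
#' @param rank_tables A tibble with `protein_id`, `position`, `rank`
#'   (stacked [et_rank()] outputs), or a named list of `et_rank` tibbles.
#' @param regions A tibble with `protein_id`, `region`, `position` (long: one
#'   row per region residue).
#' @return A list with `means` (tibble `protein_id`, `region`, `mean_rank`,
#'   `n_positions`) and `tests` (tibble `region_a`, `region_b`,
#'   `n_effective`, `statistic`, `p_value`, `method`).
#' @export
compare_region_ranks <- function(rank_tables, regions) {
  if (!is.data.frame(rank_tables)) {
    rank_tables <- dplyr::bind_rows(rank_tables, .id = "protein_id")
  }
  means <- regions |>
    dplyr::inner_join(rank_tables, by = c("protein_id", "position")) |>
    dplyr::group_by(.data$protein_id, .data$region) |>
    dplyr::summarize(mean_rank = mean(.data$rank), n_positions = dplyr::n(),
                     .groups = "drop")
  tests <- pairwise_region_tests(means, "mean_rank")
  list(means = means, tests = tests)
}

# Paired Wilcoxon over every pair of regions in a per-protein means table.
pairwise_region_tests <- function(means, value_col) {
  wide <- tidyr::pivot_wider(
    means[c("protein_id", "region", value_col)],
    names_from = "region", values_from = dplyr::all_of(value_col)
  )
  region_names <- setdiff(names(wide), "protein_id")
  if (length(region_names) < 2L) {
    return(tibble(region_a = character(0), region_b = character(0),
                  n_effective = integer(0), statistic = numeric(0),
                  p_value = numeric(0), method = character(0)))
  }
  pairs <- utils::combn(region_names, 2L, simplify = FALSE)
  purrr::map_dfr(pairs, function(pr) {
    res <- suppressWarnings(wilcoxon_signed_rank(wide[[pr[1L]]], wide[[pr[2L]]]))
    tibble(region_a = pr[1L], region_b = pr[2L],
           n_effective = res$n_effective, statistic = res$statistic,
           p_value = res$p_value, method = res$method)
  })
}
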