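# Independent oracles used to cross-check the package's implementations.
# These are deliberately naive (loops, exhaustive enumeration) and share no
# code with the functions they verify.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Naive sequon scan: explicit position loop over the sequence.
oracle_scan_sequons <- function(sequence) {
  ch <- strsplit(sequence, "")[[1]]
  hits <- integer(0)
  n <- length(ch)
  if (n >= 3) {
    for (i in 1:(n - 2)) {
      if (ch[i] == "N" && ch[i + 1] != "P" && (ch[i + 2] == "S" || ch[i + 2] == "T")) {
        hits <- c(hits, i)
      }
    }
  }
  hits
}

# Exact two-sided signed-rank p-value by full enumeration of the 2^n sign
# assignments (requires tie-free non-zero differences).
oracle_wilcoxon_exact <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  stopifnot(n >= 1, n <= 15, !anyDuplicated(abs(d)))
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  p_low <- mean(w_all <= w_obs)
  p_high <- mean(w_all >= w_obs)
  min(1, 2 * min(p_low, p_high))
}

# Naive interval merge: sort then sweep, merging overlapping or adjacent
# 1-based inclusive intervals.
oracle_merge_intervals <- function(start, end) {
  o <- order(start)
  start <- start[o]
  end <- end[o]
  ms <- start[1]
  me <- end[1]
  out <- NULL
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me + 1) {
      me <- max(me, end[i])
    } else {
      out <- rbind(out, c(ms, me))
      ms <- start[i]
      me <- end[i]
    }
  }
  out <- rbind(out, c(ms, me))
  data.frame(start = out[, 1], end = out[, 2])
}

# Naive eligible control-window starts: check every start position directly.
oracle_eligible_starts <- function(sequence_length, disorder, glycosites, locale,
                                   window_length = 11) {
  lab <- rep("ORDERED", sequence_length)
  if (nrow(disorder) > 0) {
    for (i in seq_len(nrow(disorder))) {
      lab[disorder$start[i]:disorder$end[i]] <- "DISORDERED"
    }
  }
  flank <- (window_length - 1) / 2
  ok <- integer(0)
  for (s in seq_len(max(0, sequence_length - window_length + 1))) {
    span <- s:(s + window_length - 1)
    if (any(lab[span] != locale)) next
    clash <- FALSE
    for (g in glycosites) {
      if (any(abs(span - g) <= flank) || g %in% span) clash <- TRUE
    }
    if (clash) next
    ok <- c(ok, s)
  }
  ok
}

# Evolutionary-trace groups via graph components: delete the k-1 shallowest
# internal nodes from the tree graph and take the leaf sets of the remaining
# connected components. Rank = smallest level at which every group is
# column-invariant.
oracle_et_rank <- function(tree, column_by_taxon) {
  ntip <- length(tree$tip.label)
  depths <- ape::node.depth.edgelength(tree)
  internal <- (ntip + 1):(ntip + tree$Nnode)
  internal <- internal[order(depths[internal], internal)]
  g <- igraph::graph_from_edgelist(apply(tree$edge, 2, as.character),
                                   directed = FALSE)
  for (k in seq_len(length(internal) + 1)) {
    active <- as.character(internal[seq_len(k - 1)])
    gk <- igraph::delete_vertices(g, intersect(active, igraph::V(g)$name))
    comp <- igraph::components(gk)$membership
    leaf_names <- as.character(seq_len(ntip))
    present <- intersect(leaf_names, names(comp))
    groups <- split(present, comp[present])
    # deleted-node leaves (leaf adjacent to a removed vertex) stay as their
    # own component automatically
    invariant <- all(vapply(groups, function(leaves) {
      taxa <- tree$tip.label[as.integer(leaves)]
      length(unique(column_by_taxon[taxa])) == 1
    }, logical(1)))
    if (invariant) return(k)
  }
  ntip
}

# Shared fixture: build records from parallel vectors without file I/O.
make_records <- function(ids, seqs, gly = NULL, dis = NULL) {
  sequences <- tibble::tibble(protein_id = ids, sequence = seqs)
  if (is.null(gly)) {
    gly <- tibble::tibble(protein_id = character(0), position = integer(0))
  }
  if (is.null(dis)) {
    dis <- tibble::tibble(protein_id = character(0), start = integer(0),
                          end = integer(0))
  }
  assemble_records(sequences, gly, dis)
}
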