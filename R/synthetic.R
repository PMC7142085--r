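# Synthetic glycoprotein cohorts with known ground truth: alternating
# ordered/disordered segments with distinct residue compositions, sequon-
# embedded glycosites planted with a controllable ordered-locale bias, and
# gapless ortholog alignments evolved at region-specific substitution rates
# on a fixed 4-taxon amniote topology.

#' Default ordered/disordered residue compositions
#'
#' Starting from a uniform composition, the disordered composition up-weights
#' the disorder-associated residues P, E, S, R, Q, N, M plus the charged
#' K and D, and down-weights the aromatic/aliphatic order-promoting residues;
#' the ordered composition does the reverse. Multipliers are in the source
#' and deliberately simple; both vectors are normalized to sum to 1.
#'
#' @return A list with `ordered` and `disordered`: named numeric 20-vectors
#'   summing to 1.
#' @export
default_compositions <- function() {
  up_dis <- c(P = 2.5, E = 2.2, S = 2.0, R = 1.8, Q = 1.8, N = 1.6, M = 1.3,
              K = 1.8, D = 1.5, G = 1.3)
  down_dis <- c(W = 0.30, F = 0.40, Y = 0.40, I = 0.50, L = 0.60, V = 0.60, C = 0.30)
  up_ord <- c(W = 1.6, F = 1.7, Y = 1.5, I = 1.8, L = 1.8, V = 1.8, C = 1.4)
  down_ord <- c(P = 0.50, E = 0.70, S = 0.90, R = 0.80, Q = 0.80, K = 0.80)
  base <- setNames(rep(1, 20L), AA20)
  dis <- base
  dis[names(up_dis)] <- up_dis
  dis[names(down_dis)] <- down_dis
  ord <- base
  ord[names(up_ord)] <- up_ord
  ord[names(down_ord)] <- down_ord
  list(ordered = ord / sum(ord), disordered = dis / sum(dis))
}

#' Generator parameters for synthetic cohorts
#'
#' @param n_proteins Number of proteins in the cohort.
#' @param length_range Protein length drawn uniformly from this range.
#' @param disordered_fraction Target fraction of disordered residues per
#'   protein (controls the relative disordered segment length).
#' @param ordered_segment_range Ordered segment lengths drawn uniformly from
#'   this range; disordered segment lengths are the same draw scaled by
#'   `disordered_fraction / (1 - disordered_fraction)`.
#' @param glycosite_count_range Glycosites per protein, uniform integer range.
#' @param p_glycosite_ordered Probability that a planted glycosite lies in an
#'   ordered segment.
#' @param compositions List with `ordered` and `disordered` 20-vectors (see
#'   [default_compositions()]).
#' @param neighborhood_rate,ordered_rate,disordered_rate Ortholog
#'   substitution rates (substitutions per site per unit branch length) for
#'   glycosite-neighborhood, other ordered, and disordered positions.
#' @param branch_scaling Named numeric: relative divergence of each
#'   non-reference taxon from the reference.
#' @param seed Cohort seed; all randomness derives from it via per-protein
#'   subseeds.
#' @return A `generator_params` list.
#' @export
generator_params <- function(n_proteins = 100L,
                             length_range = c(300L, 600L),
                             disordered_fraction = 0.35,
                             ordered_segment_range = c(30L, 80L),
                             glycosite_count_range = c(1L, 5L),
                             p_glycosite_ordered = 0.8,
                             compositions = default_compositions(),
                             neighborhood_rate = 0.02,
                             ordered_rate = 0.05,
                             disordered_rate = 0.2,
                             branch_scaling = c(chimp = 0.5, mouse = 1.5, chicken = 3.0),
                             seed = 1L) {
  stopifnot(
    n_proteins >= 0L,
    length_range[1L] >= 30L, length_range[2L] >= length_range[1L],
    disordered_fraction > 0, disordered_fraction < 1,
    p_glycosite_ordered >= 0, p_glycosite_ordered <= 1,
    abs(sum(compositions$ordered) - 1) < 1e-9,
    abs(sum(compositions$disordered) - 1) < 1e-9,
    all(c(neighborhood_rate, ordered_rate, disordered_rate) >= 0)
  )
  out <- list(
    n_proteins = as.integer(n_proteins), length_range = as.integer(length_range),
    disordered_fraction = disordered_fraction,
    ordered_segment_range = as.integer(ordered_segment_range),
    glycosite_count_range = as.integer(glycosite_count_range),
    p_glycosite_ordered = p_glycosite_ordered, compositions = compositions,
    neighborhood_rate = neighborhood_rate, ordered_rate = ordered_rate,
    disordered_rate = disordered_rate, branch_scaling = branch_scaling,
    seed = as.integer(seed)
  )
  class(out) <- "generator_params"
  out
}

sample_composition <- function(n, comp) {
  sample(AA20, n, replace = TRUE, prob = comp)
}

# One protein: segment architecture, residues, planted sequon glycosites.
# Assumes the RNG is already positioned (per-protein subseed).
gen_protein_impl <- function(params, id, max_attempts = 10L) {
  r <- params$disordered_fraction / (1 - params$disordered_fraction)
  for (attempt in seq_len(max_attempts)) {
    len <- sample(params$length_range[1L]:params$length_range[2L], 1L)
    # alternating segments until the target length is covered
    cls <- sample(c("ORDERED", "DISORDERED"), 1L)
    seg_class <- character(0)
    seg_len <- integer(0)
    total <- 0L
    while (total < len) {
      base <- sample(params$ordered_segment_range[1L]:params$ordered_segment_range[2L], 1L)
      l <- if (cls == "ORDERED") base else max(1L, as.integer(round(base * r)))
      l <- min(l, len - total)
      seg_class <- c(seg_class, cls)
      seg_len <- c(seg_len, l)
      total <- total + l
      cls <- if (cls == "ORDERED") "DISORDERED" else "ORDERED"
    }
    seg_end <- cumsum(seg_len)
    seg_start <- seg_end - seg_len + 1L
    residues <- character(len)
    for (s in seq_along(seg_len)) {
      comp <- params$compositions[[tolower(seg_class[s])]]
      residues[seg_start[s]:seg_end[s]] <- sample_composition(seg_len[s], comp)
    }

    n_gly <- sample(params$glycosite_count_range[1L]:params$glycosite_count_range[2L], 1L)
    want_ordered <- runif(n_gly) < params$p_glycosite_ordered
    placed <- integer(0)
    placed_seg <- integer(0)
    ok <- TRUE
    for (g in seq_len(n_gly)) {
      cls_g <- if (want_ordered[g]) "ORDERED" else "DISORDERED"
      # candidate N positions: inside a segment of the drawn class, with the
      # whole tripeptide in-segment, >= 6 and <= len-5 (full 11-mer interior),
      # and >= 11 residues from every already-planted site
      cand <- integer(0)
      for (s in which(seg_class == cls_g)) {
        lo <- max(seg_start[s], 6L)
        hi <- min(seg_end[s] - 2L, len - 5L)
        if (hi >= lo) cand <- c(cand, lo:hi)
      }
      if (length(placed) > 0L && length(cand) > 0L) {
        keep <- vapply(cand, function(p) all(abs(p - placed) >= 11L), logical(1))
        cand <- cand[keep]
      }
      if (length(cand) == 0L) {
        ok <- FALSE
        break
      }
      p <- if (length(cand) == 1L) cand else sample(cand, 1L)
      placed <- c(placed, p)
      placed_seg <- c(placed_seg, which(seg_start <= p & seg_end >= p))
    }
    if (!ok) next

    # rewrite each planted site to an N-X-S/T sequon (X != P, drawn from the
    # segment composition)
    for (k in seq_along(placed)) {
      p <- placed[k]
      comp <- params$compositions[[tolower(seg_class[placed_seg[k]])]]
      x <- sample_composition(1L, comp)
      while (x == "P") x <- sample_composition(1L, comp)
      residues[p] <- "N"
      residues[p + 1L] <- x
      residues[p + 2L] <- sample(c("S", "T"), 1L)
    }

    dis_idx <- seg_class == "DISORDERED"
    disorder <- tibble::new_tibble(list(start = seg_start[dis_idx],
                                        end = seg_end[dis_idx]))
    placed_order <- order(placed)
    return(list(
      protein_id = id,
      sequence = paste(residues, collapse = ""),
      glycosites = sort(placed),
      disorder = disorder,
      truth = tibble::new_tibble(list(
        protein_id = rep(id, length(placed)),
        position = placed[placed_order],
        locale = seg_class[placed_seg][placed_order],
        x_residue = residues[placed[placed_order] + 1L],
        third_residue = residues[placed[placed_order] + 2L]
      ))
    ))
  }
  abort(sprintf(
    "Could not place glycosites for protein '%s' after %d attempts (check p_glycosite_ordered against the segment architecture)",
    id, max_attempts
  ))
}

#' Simulate a glycoprotein cohort in memory
#'
#' Generates `n_proteins` records with alternating ordered/disordered
#' segments, composition-biased residues and sequon-embedded glycosites
#' planted in ordered segments with probability `p_glycosite_ordered`. All
#' randomness derives from `params$seed` through per-protein subseeds, so any
#' protein is reproducible in isolation.
#'
#' @param params A `generator_params` list.
#' @return A list with `records` (a validated `glyco_records` tibble) and
#'   `truth` (tibble `protein_id`, `position`, `locale`, `x_residue`,
#'   `third_residue` of every planted glycosite).
#' @export
simulate_cohort <- function(params = generator_params()) {
  n <- params$n_proteins
  if (n == 0L) {
    warn("Simulating an empty cohort (n_proteins = 0)")
    empty <- assemble_records(
      tibble(protein_id = character(0), sequence = character(0)),
      tibble(protein_id = character(0), position = integer(0)),
      tibble(protein_id = character(0), start = integer(0), end = integer(0))
    )
    return(list(records = empty,
                truth = tibble(protein_id = character(0), position = integer(0),
                               locale = character(0), x_residue = character(0),
                               third_residue = character(0))))
  }
  subseeds <- split_seed(params$seed, n)
  ids <- sprintf("syn%04d", seq_len(n))
  prots <- purrr::map(seq_len(n), function(i) {
    with_seed(subseeds[i], gen_protein_impl(params, ids[i]))
  })
  sequences <- tibble(protein_id = ids,
                      sequence = purrr::map_chr(prots, "sequence"))
  gly_list <- lapply(prots, `[[`, "glycosites")
  glyco <- tibble(
    protein_id = rep(ids, lengths(gly_list)),
    position = unlist(gly_list, use.names = FALSE) %||% integer(0)
  )
  dis_list <- lapply(prots, `[[`, "disorder")
  disorder <- tibble(
    protein_id = rep(ids, vapply(dis_list, nrow, integer(1))),
    start = unlist(lapply(dis_list, `[[`, "start"), use.names = FALSE) %||% integer(0),
    end = unlist(lapply(dis_list, `[[`, "end"), use.names = FALSE) %||% integer(0)
  )
  records <- assemble_records(sequences, glyco, disorder)
  list(records = records, truth = purrr::map_dfr(prots, "truth"))
}

#' Write a synthetic cohort to disk
#'
#' Emits exactly the formats the annotation reader consumes — a FASTA of
#' sequences, a glycosite TSV and a disorder TSV — plus the truth table and a
#' JSON run manifest recording the generator parameters and seed.
#'
#' @param params A `generator_params` list.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the written file paths plus the
#'   in-memory `records` and `truth`.
#' @export
gen_cohort <- function(params = generator_params(), dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sim <- simulate_cohort(params)
  paths <- list(
    fasta = file.path(dir, "sequences.fasta"),
    glycosites = file.path(dir, "glycosites.tsv"),
    disorder = file.path(dir, "disorder.tsv"),
    truth = file.path(dir, "truth.tsv"),
    manifest = file.path(dir, "params.json")
  )
  if (nrow(sim$records) > 0L) {
    write_fasta(sim$records[c("protein_id", "sequence")], paths$fasta)
  } else {
    writeLines(character(0), paths$fasta)
  }
  write_table(tibble(protein_id = sim$truth$protein_id,
                     position = sim$truth$position), paths$glycosites)
  dis <- purrr::map_dfr(seq_len(nrow(sim$records)), function(i) {
    d <- sim$records$disorder[[i]]
    if (nrow(d) == 0L) return(NULL)
    dplyr::mutate(d, protein_id = sim$records$protein_id[i], .before = 1L)
  })
  if (is.null(dis) || nrow(dis) == 0L) {
    dis <- tibble(protein_id = character(0), start = integer(0), end = integer(0))
  }
  write_table(dis, paths$disorder)
  write_table(sim$truth, paths$truth)
  manifest <- params
  manifest$compositions <- lapply(params$compositions, function(x) as.list(round(x, 6)))
  jsonlite::write_json(unclass(manifest), paths$manifest, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, list(records = sim$records, truth = sim$truth)))
}

# Fixed amniote topology for synthetic orthologs; branch lengths mirror the
# relative divergences in `branch_scaling`.
synthetic_tree <- function(branch_scaling = c(chimp = 0.5, mouse = 1.5, chicken = 3.0)) {
  b <- branch_scaling
  # ultrametric: tip-to-tip distance between human and taxon t equals b[t]
  txt <- sprintf(
    "(((human:%g,chimp:%g):%g,mouse:%g):%g,chicken:%g);",
    b[["chimp"]] / 2, b[["chimp"]] / 2,
    (b[["mouse"]] - b[["chimp"]]) / 2, b[["mouse"]] / 2,
    (b[["chicken"]] - b[["mouse"]]) / 2, b[["chicken"]] / 2
  )
  ape::read.tree(text = txt)
}

#' Simulate an ortholog alignment for one record
#'
#' Derives chimp, mouse and chicken rows from the reference sequence by
#' independent per-site substitutions: the substitution probability at a site
#' is `branch_scaling[taxon] * rate`, where the rate is the neighborhood rate
#' inside planted glycosite neighborhoods (glycosite +/- `flank`), the
#' ordered rate in other ordered positions and the disordered rate in
#' disordered positions. Substituted residues are redrawn from the segment
#' composition excluding the current residue. No indels are introduced, so
#' the alignment is gapless and `ref_map` is the identity.
#'
#' @param records A `glyco_records` tibble.
#' @param protein_id Which record to evolve.
#' @param params A `generator_params` list (rates, branch scaling,
#'   compositions).
#' @param seed Optional seed for this alignment.
#' @param flank Neighborhood half-width (default 5).
#' @return A list with `alignment` (an `ortholog_msa`, reference taxon
#'   `"human"`) and `tree` (rooted `phylo` with the fixed topology).
#' @export
gen_orthologs <- function(records, protein_id, params = generator_params(),
                          seed = NULL, flank = 5L) {
  i <- match(protein_id, records$protein_id)
  if (is.na(i)) abort(paste0("Unknown protein id: ", protein_id))
  seq_i <- chars(records$sequence[i])
  len <- length(seq_i)
  lab <- locale_labels(len, records$disorder[[i]])
  rate <- ifelse(lab == "DISORDERED", params$disordered_rate, params$ordered_rate)
  for (g in records$glycosites[[i]]) {
    span <- max(1L, g - flank):min(len, g + flank)
    rate[span] <- params$neighborhood_rate
  }
  comp_o <- params$compositions$ordered
  comp_d <- params$compositions$disordered
  with_seed(seed, {
    rows <- lapply(names(params$branch_scaling), function(taxon) {
      p_sub <- pmin(1, rate * params$branch_scaling[[taxon]])
      hit <- which(runif(len) < p_sub)
      out <- seq_i
      for (j in hit) {
        comp <- if (lab[j] == "DISORDERED") comp_d else comp_o
        repeat {
          new <- sample_composition(1L, comp)
          if (new != out[j]) break
        }
        out[j] <- new
      }
      paste(out, collapse = "")
    })
    aln <- ortholog_msa(
      taxa = c("human", names(params$branch_scaling)),
      sequences = c(records$sequence[i], unlist(rows)),
      reference_taxon = "human"
    )
    list(alignment = aln, tree = synthetic_tree(params$branch_scaling))
  })
}
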