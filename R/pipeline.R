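# File-based pipeline orchestration: each stage reads and writes TSVs under
# the configured output directory, so stages are independently runnable and
# resumable. A thin command-line dispatcher over these functions ships in
# exec/glycolocale.

CONFIG_KEYS <- c("mode", "simulate", "inputs", "outdir", "seed", "window_length",
                 "controls_per_protein", "iterations", "alpha", "correction",
                 "gap_policy", "conservation", "log_level")
SIMULATE_KEYS <- c("n_proteins", "length_range", "disordered_fraction",
                   "ordered_segment_range", "glycosite_count_range",
                   "p_glycosite_ordered", "neighborhood_rate", "ordered_rate",
                   "disordered_rate")
INPUT_KEYS <- c("fasta", "glycosites", "disorder", "msa_dir", "tree")

#' Read and validate a pipeline run configuration
#'
#' @param config A YAML file path or a named list. Recognised keys: `mode`
#'   (`"simulate"` or `"files"`), `simulate` (generator parameter overrides),
#'   `inputs` (`fasta`, `glycosites`, `disorder`, `msa_dir`, `tree`),
#'   `outdir`, `seed`, `window_length`, `controls_per_protein`, `iterations`,
#'   `alpha`, `correction`, `gap_policy`, `conservation`, `log_level`.
#'   Unknown keys are an error.
#' @param seed,outdir Optional overrides applied after reading.
#' @return A validated `run_config` list with defaults filled in.
#' @export
read_run_config <- function(config, seed = NULL, outdir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), CONFIG_KEYS)
  if (length(unknown) > 0L) {
    abort(paste0("Unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  if (!is.null(config$simulate)) {
    unknown <- setdiff(names(config$simulate), SIMULATE_KEYS)
    if (length(unknown) > 0L) {
      abort(paste0("Unknown config key(s): ", paste0("simulate.", unknown, collapse = ", ")))
    }
  }
  if (!is.null(config$inputs)) {
    unknown <- setdiff(names(config$inputs), INPUT_KEYS)
    if (length(unknown) > 0L) {
      abort(paste0("Unknown config key(s): ", paste0("inputs.", unknown, collapse = ", ")))
    }
  }
  defaults <- list(mode = "simulate", simulate = list(), inputs = NULL,
                   outdir = "glycolocale_run", seed = 1L, window_length = 11L,
                   controls_per_protein = 1L, iterations = 10000L, alpha = 0.05,
                   correction = "bonferroni", gap_policy = "gap_as_symbol",
                   conservation = TRUE, log_level = "info")
  out <- utils::modifyList(defaults, config)
  if (!is.null(seed)) out$seed <- as.integer(seed)
  if (!is.null(outdir)) out$outdir <- outdir
  if (!out$mode %in% c("simulate", "files")) {
    abort("config key 'mode' must be 'simulate' or 'files'")
  }
  if (out$mode == "files" && is.null(out$inputs)) {
    abort("mode 'files' requires an 'inputs' block")
  }
  class(out) <- "run_config"
  out
}

cohort_params <- function(config) {
  do.call(generator_params, c(config$simulate, list(seed = config$seed)))
}

input_paths <- function(config) {
  if (config$mode == "simulate") {
    d <- file.path(config$outdir, "input")
    list(fasta = file.path(d, "sequences.fasta"),
         glycosites = file.path(d, "glycosites.tsv"),
         disorder = file.path(d, "disorder.tsv"),
         msa_dir = file.path(d, "msas"),
         tree = file.path(d, "tree.nwk"))
  } else {
    config$inputs
  }
}

load_records <- function(config) {
  paths <- input_paths(config)
  for (p in c(paths$fasta, paths$glycosites, paths$disorder)) {
    if (!file.exists(p)) {
      abort(paste0("Missing pipeline input '", p,
                   "'; run the simulate stage first or point 'inputs' at existing files"))
    }
  }
  assemble_records(read_fasta(paths$fasta),
                   read_annotation_tables(paths$glycosites, paths$disorder))
}

#' Pipeline stage: simulate a cohort
#'
#' Writes a synthetic cohort (sequences, annotations, truth, manifest) under
#' `<outdir>/input`, plus per-protein ortholog alignments and the species
#' tree when conservation is enabled.
#'
#' @param config A `run_config` (see [read_run_config()]).
#' @return Invisibly, the list of written paths.
#' @export
run_simulate <- function(config) {
  config <- read_run_config(config)
  params <- cohort_params(config)
  indir <- file.path(config$outdir, "input")
  out <- gen_cohort(params, indir)
  if (isTRUE(config$conservation) && nrow(out$records) > 0L) {
    msa_dir <- file.path(indir, "msas")
    if (!dir.exists(msa_dir)) dir.create(msa_dir, recursive = TRUE)
    seeds <- split_seed(params$seed + 1L, nrow(out$records))
    for (i in seq_len(nrow(out$records))) {
      sim <- gen_orthologs(out$records, out$records$protein_id[i], params,
                           seed = seeds[i])
      write_msa(sim$alignment,
                file.path(msa_dir, paste0(out$records$protein_id[i], ".fasta")))
      if (i == 1L) {
        ape::write.tree(sim$tree, file.path(indir, "tree.nwk"))
      }
    }
  }
  invisible(out)
}

#' Pipeline stage: annotate
#'
#' Assembles records from the input files and writes the QC summary, the
#' sequon table and the window table (neighborhoods plus seeded control
#' windows).
#'
#' @param config A `run_config`.
#' @return Invisibly, a list with `records`, `sequons`, `windows`, `qc`.
#' @export
run_annotate <- function(config) {
  config <- read_run_config(config)
  records <- load_records(config)
  if (sum(records$n_glycosites) == 0L) {
    abort("No glycosites in the input annotation; nothing to annotate")
  }
  sequons <- scan_sequons(records)
  windows <- dplyr::bind_rows(
    extract_neighborhoods(records, config$window_length),
    sample_control_windows(records, seed = config$seed + 101L,
                           window_length = config$window_length,
                           controls_per_protein = config$controls_per_protein)
  )
  qc <- qc_summary(records, flank = (config$window_length - 1L) %/% 2L)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  out_seq <- dplyr::mutate(sequons,
                           x_classes = purrr::map_chr(.data$x_residue, function(x) {
                             paste(suppressWarnings(classify_x(x)), collapse = ";")
                           }))
  write_table(out_seq, file.path(config$outdir, "sequons.tsv"))
  write_table(windows, file.path(config$outdir, "windows.tsv"))
  write_table(qc, file.path(config$outdir, "records_qc.tsv"))
  invisible(list(records = records, sequons = sequons, windows = windows, qc = qc))
}

#' Pipeline stage: paired locale metrics
#'
#' Computes the per-protein paired metric table, the Wilcoxon matched-pairs
#' tests, and the mean/median/SEM summary, writing all three as TSVs.
#'
#' @param config A `run_config`.
#' @return Invisibly, a list with `metrics`, `tests`, `summary`.
#' @export
run_metrics <- function(config) {
  config <- read_run_config(config)
  records <- load_records(config)
  metrics <- locale_metric_table(records)
  tests <- test_locale_metrics(metrics)
  summary <- summarize_metric(metrics)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  write_table(metrics, file.path(config$outdir, "metrics.tsv"))
  write_table(tests, file.path(config$outdir, "wilcoxon_tests.tsv"))
  write_table(summary, file.path(config$outdir, "metric_summary.tsv"))
  invisible(list(metrics = metrics, tests = tests, summary = summary))
}

ENRICH_COMPARISONS <- list(
  neighborhood_vs_disordered_control = c("NEIGHBORHOOD", "DISORDERED_CONTROL"),
  neighborhood_vs_ordered_control = c("NEIGHBORHOOD", "ORDERED_CONTROL"),
  ordered_vs_disordered_control = c("ORDERED_CONTROL", "DISORDERED_CONTROL")
)

#' Pipeline stage: composition and property enrichment
#'
#' Runs the three pairwise pool comparisons (neighborhoods vs disordered
#' controls, neighborhoods vs ordered controls, ordered vs disordered
#' controls), each as an amino-acid table and a property table.
#'
#' @param config A `run_config`.
#' @return Invisibly, a named list of comparison results.
#' @export
run_enrich <- function(config) {
  config <- read_run_config(config)
  win_path <- file.path(config$outdir, "windows.tsv")
  if (!file.exists(win_path)) {
    abort(paste0("Missing '", win_path, "'; run the annotate stage first"))
  }
  windows <- readr::read_tsv(win_path, show_col_types = FALSE, progress = FALSE)
  seeds <- split_seed(config$seed + 202L, 2L * length(ENRICH_COMPARISONS))
  out <- list()
  k <- 0L
  for (nm in names(ENRICH_COMPARISONS)) {
    kinds <- ENRICH_COMPARISONS[[nm]]
    qw <- windows$residues[windows$kind == kinds[1L] & !is.na(windows$residues)]
    bw <- windows$residues[windows$kind == kinds[2L] & !is.na(windows$residues)]
    if (length(qw) == 0L || length(bw) == 0L) {
      warn(paste0("Empty pool for comparison '", nm, "'; skipped"))
      next
    }
    k <- k + 1L
    aa <- bootstrap_enrichment(qw, bw, iterations = config$iterations,
                               alpha = config$alpha, seed = seeds[2L * k - 1L],
                               correction = config$correction)
    prop <- property_enrichment(qw, bw, iterations = config$iterations,
                                alpha = config$alpha, seed = seeds[2L * k],
                                correction = config$correction)
    write_table(aa, file.path(config$outdir, paste0("enrichment_", nm, "_aa.tsv")))
    write_table(prop, file.path(config$outdir, paste0("enrichment_", nm, "_properties.tsv")))
    out[[nm]] <- list(aa = aa, properties = prop)
  }
  invisible(out)
}

# Region position sets (long format) from a windows table: every residue of
# each window, labelled by the window family.
window_regions <- function(windows) {
  kinds <- c(NEIGHBORHOOD = "neighborhood", ORDERED_CONTROL = "ordered_control",
             DISORDERED_CONTROL = "disordered_control")
  win <- windows[!is.na(windows$start), ]
  purrr::map_dfr(seq_len(nrow(win)), function(i) {
    w <- nchar(win$residues[i])
    tibble(protein_id = win$protein_id[i], region = kinds[[win$kind[i]]],
           position = win$start[i]:(win$start[i] + w - 1L))
  }) |> dplyr::distinct()
}

#' Pipeline stage: conservation
#'
#' For each protein with an ortholog alignment, computes the mean column
#' entropy of its glycosite neighborhoods, control windows and full length,
#' plus evolutionary-trace mean ranks when a tree is available; pairs are
#' tested across proteins with the Wilcoxon signed-rank test.
#'
#' @param config A `run_config`.
#' @return Invisibly, a list with `entropy`, `entropy_tests`, `et_means`,
#'   `et_tests` (the ET elements are `NULL` without a tree).
#' @export
run_conserve <- function(config) {
  config <- read_run_config(config)
  paths <- input_paths(config)
  win_path <- file.path(config$outdir, "windows.tsv")
  if (!file.exists(win_path)) {
    abort(paste0("Missing '", win_path, "'; run the annotate stage first"))
  }
  if (is.null(paths$msa_dir) || !dir.exists(paths$msa_dir)) {
    abort("No MSA directory available; enable conservation in simulate mode or provide inputs$msa_dir")
  }
  records <- load_records(config)
  windows <- readr::read_tsv(win_path, show_col_types = FALSE, progress = FALSE)
  regions <- window_regions(windows)
  tree <- NULL
  if (!is.null(paths$tree) && file.exists(paths$tree)) {
    tree <- ape::read.tree(paths$tree)
  } else {
    inform("No tree available; evolutionary-trace ranking skipped")
  }

  ent_rows <- list()
  rank_rows <- list()
  for (i in seq_len(nrow(records))) {
    id <- records$protein_id[i]
    msa_path <- file.path(paths$msa_dir, paste0(id, ".fasta"))
    if (!file.exists(msa_path)) next
    aln <- read_msa(msa_path, "human")
    link_alignment(aln, records, id)
    reg_i <- regions[regions$protein_id == id, ]
    fam <- split(reg_i$position, reg_i$region)
    fam$full_length <- seq_len(records$length[i])
    ent_rows[[id]] <- purrr::imap_dfr(fam, function(pos, region) {
      tibble(protein_id = id, region = region,
             mean_entropy = region_mean_entropy(aln, pos, config$gap_policy),
             n_positions = length(pos))
    })
    if (!is.null(tree)) {
      rk <- et_rank(aln, tree)
      rank_rows[[id]] <- dplyr::mutate(rk, protein_id = id, .before = 1L)
    }
  }
  if (length(ent_rows) == 0L) abort("No alignments matched the record set")
  entropy <- dplyr::bind_rows(ent_rows)
  entropy_tests <- pairwise_region_tests(
    dplyr::filter(entropy, .data$region != "full_length"), "mean_entropy"
  )
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  write_table(entropy, file.path(config$outdir, "entropy.tsv"))
  write_table(entropy_tests, file.path(config$outdir, "entropy_tests.tsv"))

  et_means <- et_tests <- NULL
  if (!is.null(tree)) {
    ranks <- dplyr::bind_rows(rank_rows)
    write_table(ranks, file.path(config$outdir, "et_ranks.tsv"))
    cmp <- compare_region_ranks(ranks, regions)
    et_means <- cmp$means
    et_tests <- cmp$tests
    write_table(et_means, file.path(config$outdir, "et_means.tsv"))
    write_table(et_tests, file.path(config$outdir, "et_tests.tsv"))
  }
  invisible(list(entropy = entropy, entropy_tests = entropy_tests,
                 et_means = et_means, et_tests = et_tests))
}

#' Pipeline stage: consolidated report
#'
#' Collects every test table the completed stages produced into one
#' machine-readable summary TSV plus a JSON run manifest (package version,
#' seed, config hash).
#'
#' @param config A `run_config`.
#' @return Invisibly, a list with `report` and `manifest`.
#' @export
run_report <- function(config) {
  config <- read_run_config(config)
  rows <- list()
  f <- file.path(config$outdir, "wilcoxon_tests.tsv")
  if (file.exists(f)) {
    x <- readr::read_tsv(f, show_col_types = FALSE, progress = FALSE)
    rows$metrics <- tibble(family = "locale_metric", test = x$metric,
                           n = x$n_effective, statistic = x$statistic,
                           p_value = x$p_value, method = x$method)
  }
  for (nm in names(ENRICH_COMPARISONS)) {
    for (tab in c("aa", "properties")) {
      f <- file.path(config$outdir, paste0("enrichment_", nm, "_", tab, ".tsv"))
      if (!file.exists(f)) next
      x <- readr::read_tsv(f, show_col_types = FALSE, progress = FALSE)
      key <- if (tab == "aa") x$aa else x$scale
      est <- if (tab == "aa") x$d else x$difference
      rows[[paste(nm, tab)]] <- tibble(
        family = paste0("enrichment_", tab), test = paste(nm, key),
        n = sum(!is.na(est)), statistic = est, p_value = x$p_value,
        method = "bootstrap_z"
      )
    }
  }
  for (f0 in c("entropy_tests", "et_tests")) {
    f <- file.path(config$outdir, paste0(f0, ".tsv"))
    if (!file.exists(f)) next
    x <- readr::read_tsv(f, show_col_types = FALSE, progress = FALSE)
    if (nrow(x) == 0L) next
    rows[[f0]] <- tibble(family = f0, test = paste(x$region_a, "vs", x$region_b),
                         n = x$n_effective, statistic = x$statistic,
                         p_value = x$p_value, method = x$method)
  }
  report <- dplyr::bind_rows(rows)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  write_table(report, file.path(config$outdir, "report.tsv"))
  manifest <- list(
    package = "glycolocale",
    version = as.character(utils::packageVersion("glycolocale")),
    seed = config$seed,
    config_hash = rlang::hash(unclass(config)),
    n_tests = nrow(report)
  )
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(list(report = report, manifest = manifest))
}

#' Run the full pipeline
#'
#' Simulate (in simulate mode), annotate, metrics, enrichment, conservation
#' (when enabled) and report, in order, under one output directory.
#'
#' @param config A YAML path or config list (see [read_run_config()]).
#' @param seed,outdir Optional overrides.
#' @return Invisibly, the report list from [run_report()].
#' @export
run_pipeline <- function(config = list(), seed = NULL, outdir = NULL) {
  config <- read_run_config(config, seed = seed, outdir = outdir)
  if (config$mode == "simulate") run_simulate(config)
  run_annotate(config)
  run_metrics(config)
  run_enrich(config)
  if (isTRUE(config$conservation)) run_conserve(config)
  run_report(config)
}
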