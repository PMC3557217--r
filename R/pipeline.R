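# End-to-end orchestration: configuration validation and the run_all()
# driver that chains simulate/load -> pair -> codon-align -> purge ->
# analyze and emits a consolidated, fully deterministic report.

.config_defaults <- function() {
  list(
    # data source: either four input paths, or the simulation below
    fasta_a = NA_character_, fasta_b = NA_character_,
    orthology_a = NA_character_, orthology_b = NA_character_,
    seed = 1L, n_pairs = 200L, codon_length = 150L,
    p_syn = 0.3, p_nonsyn = 0.02, delta_at3 = 0.15,
    p_indel = 0.01, n_decoys = 10L, p_misassign = 0.05,
    preset = "uniform",
    # pairing filters
    min_identity = 80, max_evalue = 1e-9, min_score = 50,
    # codon-usage analysis
    ellipse_scale = 1.5, wca_pooled = FALSE,
    # output
    outdir = NA_character_
  )
}

#' Validate and normalize a pipeline configuration
#'
#' Fills defaults, rejects unknown keys, and range-checks every threshold.
#' All violations are reported together, each naming the offending key.
#'
#' @param config Named list of configuration overrides (may be empty).
#' @return The normalized configuration list (class `pipeline_config`).
#' @export
validate_config <- function(config = list()) {
  defaults <- .config_defaults()
  unknown <- setdiff(names(config), names(defaults))
  errors <- character()
  if (length(unknown)) {
    errors <- c(errors, paste0("unknown key(s): ",
                               paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(defaults, config[setdiff(names(config), unknown)])
  chk <- function(ok, msg) if (!isTRUE(ok)) errors <<- c(errors, msg)
  chk(cfg$min_identity >= 0 && cfg$min_identity <= 100,
      "min_identity: must be in [0, 100]")
  chk(cfg$max_evalue > 0, "max_evalue: must be positive")
  chk(cfg$min_score >= 0, "min_score: must be non-negative")
  chk(cfg$ellipse_scale > 0, "ellipse_scale: must be positive")
  for (key in c("p_syn", "p_nonsyn", "p_indel", "p_misassign")) {
    chk(cfg[[key]] >= 0 && cfg[[key]] <= 1,
        paste0(key, ": must be in [0, 1]"))
  }
  chk(abs(cfg$delta_at3) <= 1, "delta_at3: must be in [-1, 1]")
  chk(cfg$n_pairs >= 0, "n_pairs: must be non-negative")
  chk(cfg$codon_length >= 10, "codon_length: must be at least 10")
  chk(cfg$preset %in% c("uniform", "E2D_excess", "S_gain"),
      "preset: must be one of uniform, E2D_excess, S_gain")
  if (length(errors)) {
    abort(paste0("invalid configuration:\n  ",
                 paste(errors, collapse = "\n  ")))
  }
  structure(cfg, class = "pipeline_config")
}

.config_sim_params <- function(cfg) {
  sim_params(
    n_pairs = cfg$n_pairs, codon_length = cfg$codon_length,
    p_syn = cfg$p_syn, p_nonsyn = cfg$p_nonsyn, delta_at3 = cfg$delta_at3,
    pref_a = pref_matrix_preset(cfg$preset),
    pref_b = uniform_pref_matrix(),
    p_indel = cfg$p_indel, n_decoys = cfg$n_decoys,
    p_misassign = cfg$p_misassign, seed = cfg$seed
  )
}

#' Run the complete comparative analysis
#'
#' Chains every stage: obtain sequences and orthology tables (from the
#' configured input paths, or from the synthetic generator), align and pair
#' translated segments per orthology group, apply the identity/e-value
#' filter and the stop/ambiguity purge, back-translate to codon alignments,
#' and compute all headline statistics (replacement imbalance and net usage,
#' ERK Wilcoxon, GC3 ledger, codon shift table with Fisher contingency, WCA,
#' GC summaries). The run is deterministic given the configuration.
#'
#' @param config Configuration list or `pipeline_config`; see
#'   [validate_config()].
#' @return A `run_report` list: `config`, `config_hash`, `version`,
#'   `counters` (the filter funnel), `column_summary`, `results` (all
#'   statistics), and the intermediate tables (`pairs`, `columns`). If
#'   `config$outdir` is set, artifacts (TSV/JSON) are also written there.
#' @export
run_all <- function(config = list()) {
  cfg <- if (inherits(config, "pipeline_config")) config
         else validate_config(config)

  external <- !is.na(cfg$fasta_a)
  if (external) {
    seqs <- bind_rows(
      read_fasta(cfg$fasta_a, species = "A"),
      read_fasta(cfg$fasta_b, species = "B")
    )
    orth_a <- read_orthology(cfg$orthology_a)
    orth_b <- read_orthology(cfg$orthology_b)
    truth <- NULL
  } else {
    ds <- simulate_dataset(.config_sim_params(cfg))
    seqs <- ds$sequences
    orth_a <- ds$orthology_a
    orth_b <- ds$orthology_b
    truth <- ds$truth
  }

  alns <- align_ortholog_candidates(seqs, orth_a, orth_b)
  best <- select_best_pairs(alns)
  filtered <- withCallingHandlers(
    filter_pairs(best, min_identity = cfg$min_identity,
                 max_evalue = cfg$max_evalue, min_score = cfg$min_score),
    orthocodon_evalue_skip = function(c) invokeRestart("muffleMessage")
  )
  cols_all <- backtranslate_pairs(filtered, seqs)
  retained <- purge_invalid(filtered, cols_all)
  cols <- cols_all |> filter(.data$pair_id %in% retained$pair_id)

  counters <- list(
    sequences_in = nrow(seqs),
    groups_seen = unname(attr(best, "counters")["groups_seen"]),
    candidate_alignments = nrow(alns),
    best_pairs = nrow(best),
    pairs_after_identity_filter = nrow(filtered),
    pairs_purged = unname(attr(retained, "n_removed")),
    pairs_retained = nrow(retained)
  )

  col_summary <- classify_columns(cols)
  C <- count_replacements(cols)
  D <- imbalance(C)
  nets <- net_usage(D)
  erk <- if (any(cols$class == "nonsynonymous")) {
    erk_test(cols)
  } else {
    # a fully conserved pair set carries no ERK information
    structure(list(records = tibble(), statistic = NA_real_,
                   p_value = NA_real_, n_effective = 0L,
                   method = "not computed (no exchanged positions)"),
              class = "erk_test")
  }
  ledger <- gc3_ledger(cols)
  shifts <- codon_shift_table(cols)
  contingency <- shift_contingency(shifts)
  usage <- codon_usage_counts(cols, pooled = cfg$wca_pooled)
  wca_res <- wca(usage$counts, usage$species,
                 ellipse_scale = cfg$ellipse_scale)
  gc <- mean_gc(cols)

  report <- structure(list(
    config = unclass(cfg),
    config_hash = rlang::hash(unclass(cfg)),
    version = as.character(utils::packageVersion("orthocodon")),
    counters = counters,
    column_summary = col_summary,
    results = list(
      replacement_counts = C,
      imbalance = D,
      net_usage = nets,
      erk = erk,
      ledger = ledger,
      shift_table = shifts,
      shift_contingency = contingency,
      wca = wca_res,
      mean_gc = gc,
      mean_identity = mean(retained$percent_identity)
    ),
    pairs = retained,
    columns = cols,
    truth = truth
  ), class = "run_report")

  if (!is.na(cfg$outdir)) write_report(report, cfg$outdir)
  report
}

#' Write run-report artifacts to a directory
#'
#' Persists every intermediate and result table as TSV, the headline
#' statistics as JSON, and the report summary as JSON (no timestamps, so
#' identical runs produce byte-identical artifacts).
#'
#' @param report A `run_report`.
#' @param outdir Output directory (created if missing).
#' @return Invisibly, the vector of written paths.
#' @export
write_report <- function(report, outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  p <- function(f) file.path(outdir, f)
  readr::write_tsv(report$pairs |> select(-dplyr::any_of(c("aligned_a",
                                                           "aligned_b"))),
                   p("pairs.tsv"))
  readr::write_tsv(report$columns, p("codon_columns.tsv"))
  readr::write_tsv(report$column_summary, p("column_summary.tsv"))
  C <- report$results$replacement_counts
  readr::write_tsv(as_tibble(as.data.frame.matrix(unclass(C)),
                             rownames = "aa"), p("replacement_counts.tsv"))
  readr::write_tsv(as_tibble(as.data.frame.matrix(
    unclass(report$results$imbalance)), rownames = "aa"),
    p("imbalance.tsv"))
  readr::write_tsv(report$results$net_usage, p("net_usage.tsv"))
  readr::write_tsv(report$results$erk$records, p("erk_records.tsv"))
  readr::write_tsv(report$results$shift_table, p("codon_shifts.tsv"))
  readr::write_tsv(report$results$wca$row_coords, p("wca_rows.tsv"))
  readr::write_tsv(report$results$wca$col_coords, p("wca_codons.tsv"))
  readr::write_tsv(report$results$mean_gc, p("mean_gc.tsv"))
  summary <- list(
    config = report$config, config_hash = report$config_hash,
    version = report$version, counters = report$counters,
    statistics = report_statistics(report)
  )
  summary$config$pref_a <- NULL
  jsonlite::write_json(summary, p("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(p("report.json")))
}

#' Headline statistics of a run report as a flat named list
#'
#' @param report A `run_report`.
#' @return Named list of scalar statistics.
#' @export
report_statistics <- function(report) {
  r <- report$results
  nets <- setNames(r$net_usage$net, r$net_usage$aa)
  list(
    pairs_retained = report$counters$pairs_retained,
    mean_identity_percent = r$mean_identity,
    aligned_residue_pairs = sum(report$column_summary$aligned),
    synonymous_nt12_conserved = r$ledger$n_synonymous_nt12_conserved,
    net_gc3_loss_a = r$ledger$net_gc3_loss_a,
    fisher_p_shift_contingency = r$shift_contingency$p_value,
    wilcoxon_p_erk = r$erk$p_value,
    mean_gc_percent_a = r$mean_gc$mean_gc_percent[1],
    mean_gc_percent_b = r$mean_gc$mean_gc_percent[2],
    net_E = unname(nets["E"]), net_D = unname(nets["D"]),
    net_S = unname(nets["S"]),
    wca_axis1_inertia_fraction =
      r$wca$eigenvalues[1] / sum(r$wca$eigenvalues)
  )
}

#' @export
print.run_report <- function(x, ...) {
  cat("orthocodon run report (config ", substr(x$config_hash, 1, 8), ")\n",
      sep = "")
  cat("filter funnel:\n")
  for (nm in names(x$counters)) {
    cat(sprintf("  %-28s %d\n", nm, x$counters[[nm]]))
  }
  s <- report_statistics(x)
  cat("headline statistics:\n")
  cat(sprintf("  mean identity:            %.2f%%\n",
              s$mean_identity_percent))
  cat(sprintf("  aligned residue pairs:    %d\n", s$aligned_residue_pairs))
  cat(sprintf("  net GC3 loss (species A): %d over %d synonymous pairs\n",
              s$net_gc3_loss_a, s$synonymous_nt12_conserved))
  cat(sprintf("  Fisher p (AT3/GC3 shift): %.3g\n",
              s$fisher_p_shift_contingency))
  cat(sprintf("  Wilcoxon p (ERK):         %.3g\n", s$wilcoxon_p_erk))
  cat(sprintf("  mean GC:  A %.3f%%  B %.3f%%\n",
              s$mean_gc_percent_a, s$mean_gc_percent_b))
  invisible(x)
}
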