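# Synthetic ortholog-pair generator.
#
# Emulates what the comparative analysis assumes about its input: pairs of
# orthologous coding sequences diverged from a common ancestor, with a
# lineage-specific A/T preference at synonymous third positions, configurable
# non-synonymous replacement preferences, occasional whole-codon indels,
# decoy sequences without partners, and noisy orthology assignments. Because
# divergence is simulated per codon, the true alignment and the true injected
# signatures are known exactly, which is what makes every downstream
# statistic testable without external data.

#' Uniform amino-acid replacement preference matrix
#'
#' Row-stochastic 20x20 matrix with zero diagonal: a non-synonymous event
#' replaces the current amino acid by any of the other 19 with equal
#' probability.
#'
#' @return 20x20 numeric matrix with amino-acid dimnames.
#' @export
uniform_pref_matrix <- function() {
  m <- matrix(1, 20, 20, dimnames = list(AA_LETTERS, AA_LETTERS))
  diag(m) <- 0
  m / rowSums(m)
}

#' Named replacement-preference presets
#'
#' `"uniform"` is [uniform_pref_matrix()]. `"E2D_excess"` models directional
#' selection against glutamic acid: replacements leaving E strongly favor
#' the conservative E -> D exchange (weight x`2 * boost`) and replacements
#' creating new E are disfavored (into-E weights x`1/boost`). Both pieces
#' are needed: because the per-codon replacement rate is fixed and the
#' matrix rows are stochastic with a zero diagonal, retargeting E-source
#' events alone conserves species-level E usage, so a net E deficit can
#' only come from suppressed E gains. `"S_gain"` boosts every replacement
#' *into* serine (weight x`boost`), emulating a global serine surplus.
#' Presets describe lineage A only; lineage B keeps uniform preferences, so
#' the injected signature is asymmetric between the species, as a real
#' adaptive signal would be.
#'
#' @param name Preset name.
#' @param boost Weight multiplier for the boosted cells.
#' @return 20x20 row-stochastic matrix.
#' @export
pref_matrix_preset <- function(name = c("uniform", "E2D_excess", "S_gain"),
                               boost = 10) {
  name <- match.arg(name)
  m <- matrix(1, 20, 20, dimnames = list(AA_LETTERS, AA_LETTERS))
  diag(m) <- 0
  if (name == "E2D_excess") {
    m["E", "D"] <- 2 * boost
    m[setdiff(AA_LETTERS, "E"), "E"] <- 1 / boost
  }
  if (name == "S_gain") m[, "S"] <- m[, "S"] * boost
  diag(m) <- 0
  m / rowSums(m)
}

.check_pref <- function(m, what) {
  if (!is.matrix(m) || !all(dim(m) == c(20, 20))) {
    abort(paste0(what, " must be a 20x20 matrix"))
  }
  if (any(abs(rowSums(m) - 1) > 1e-9)) {
    abort(paste0(what, " rows must sum to 1"))
  }
  if (any(diag(m) != 0)) abort(paste0(what, " must have a zero diagonal"))
  if (any(m < 0)) abort(paste0(what, " must be non-negative"))
  invisible(m)
}

#' Simulation parameters
#'
#' Bundles and validates all generator settings. Defaults describe the study
#' conditions the analysis is calibrated for: 200 ortholog pairs of
#' 150-codon ancestors, a per-codon synonymous substitution probability of
#' 0.3 and non-synonymous probability of 0.02 per lineage (yielding a
#' translated identity near 96%), a lineage-A third-position A/T preference
#' `delta_at3` of 0.15, rare whole-codon indels, 10 decoy sequences and a 5%
#' orthology misassignment rate.
#'
#' @param n_pairs Number of ortholog pairs.
#' @param codon_length Codons per ancestor (minimum 10).
#' @param p_syn Per-codon probability of a synonymous resampling event per
#'   lineage.
#' @param p_nonsyn Per-codon probability of a non-synonymous replacement
#'   event per lineage.
#' @param delta_at3 Third-position A/T preference in `[-1, 1]`: during a
#'   synonymous event, lineage A resamples codons with weights proportional
#'   to `1 + delta_at3` for A/T-ending codons (lineage B uses
#'   `1 - delta_at3`), so positive values push lineage A towards AT3.
#' @param pref_a,pref_b Row-stochastic 20x20 replacement-preference matrices
#'   (target given source) for lineages A and B.
#' @param p_indel Per-codon probability of a whole-codon indel (deletion or
#'   insertion with equal probability); reading frame is always preserved.
#' @param n_decoys Unpaired decoy sequences appended per species.
#' @param p_misassign Probability that an orthology-table row points to a
#'   wrong group.
#' @param seed Root seed; per-pair child seeds are derived from it by
#'   counter, so results do not depend on generation order.
#' @param aa_freq Amino-acid frequencies for ancestor composition.
#' @return A validated list of class `sim_params`.
#' @export
sim_params <- function(n_pairs = 200L, codon_length = 150L,
                       p_syn = 0.3, p_nonsyn = 0.02, delta_at3 = 0.15,
                       pref_a = uniform_pref_matrix(),
                       pref_b = uniform_pref_matrix(),
                       p_indel = 0.01, n_decoys = 10L, p_misassign = 0.05,
                       seed = 1L, aa_freq = VERTEBRATE_AA_FREQ) {
  probs <- c(p_syn = p_syn, p_nonsyn = p_nonsyn, p_indel = p_indel,
             p_misassign = p_misassign)
  if (any(probs < 0 | probs > 1)) {
    abort("all probabilities must be in [0, 1]")
  }
  if (p_syn + p_nonsyn + p_indel > 1) {
    abort("p_syn + p_nonsyn + p_indel must not exceed 1")
  }
  if (abs(delta_at3) > 1) abort("delta_at3 must be in [-1, 1]")
  if (n_pairs < 0 || n_decoys < 0) abort("counts must be non-negative")
  .check_pref(pref_a, "pref_a")
  .check_pref(pref_b, "pref_b")
  stopifnot(length(aa_freq) == 20, all(aa_freq > 0))
  aa_freq <- aa_freq / sum(aa_freq)
  structure(list(
    n_pairs = as.integer(n_pairs), codon_length = as.integer(codon_length),
    p_syn = p_syn, p_nonsyn = p_nonsyn, delta_at3 = delta_at3,
    pref_a = pref_a, pref_b = pref_b, p_indel = p_indel,
    n_decoys = as.integer(n_decoys), p_misassign = p_misassign,
    seed = as.integer(seed), aa_freq = aa_freq
  ), class = "sim_params")
}

# Child seeds derived once from the root seed; index k is the counter.
.child_seeds <- function(params, n) {
  old <- .Random.seed_save()
  set.seed(params$seed)
  s <- sample.int(2147483646L, n)
  .Random.seed_restore(old)
  s
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# Draw n stop-free codons from the ancestor composition: amino acid from
# aa_freq, codon uniform within its synonymous family.
.random_codons <- function(n, aa_freq) {
  env <- .codon_table()
  aa <- sample(AA_LETTERS, n, replace = TRUE, prob = aa_freq[AA_LETTERS])
  .uniform_family_codons(aa, env)
}

# Vectorized uniform codon draw within each amino acid's family.
.uniform_family_codons <- function(aa, env = .codon_table()) {
  out <- character(length(aa))
  for (a in unique(aa)) {
    idx <- which(aa == a)
    fam <- env$families[[a]]
    out[idx] <- fam[sample.int(length(fam), length(idx), replace = TRUE)]
  }
  out
}

#' Generate ancestral coding sequences
#'
#' @param params A [sim_params()] object.
#' @return Tibble of coding sequences (`id`, `species = "ancestor"`,
#'   `nucleotides`, `frame_offset`), stop-free by construction.
#' @export
generate_ancestors <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  if (params$codon_length < 10) {
    abort("codon_length must be at least 10 (too short to align)")
  }
  if (params$n_pairs == 0) {
    return(tibble(id = character(), species = character(),
                  nucleotides = character(), frame_offset = integer()))
  }
  seeds <- .child_seeds(params, params$n_pairs)
  rows <- purrr::map(seq_len(params$n_pairs), function(k) {
    set.seed(seeds[k])
    codons <- .random_codons(params$codon_length, params$aa_freq)
    tibble(id = sprintf("anc%05d", k), species = "ancestor",
           nucleotides = paste(codons, collapse = ""), frame_offset = 0L)
  })
  bind_rows(rows)
}

# Synonymous resampling weights for each sense codon's family, per lineage
# sign; returns a list keyed by amino acid of weight vectors over family
# codons.
.syn_weights <- function(delta_at3, sign) {
  env <- .codon_table()
  lapply(env$families, function(f) {
    w <- 1 + sign * delta_at3 * as.numeric(env$at3[f])
    if (sum(w) <= 0) w <- rep(1, length(w)) # degenerate family, fall back
    w
  })
}

# Core divergence of a codon vector along one lineage. Returns the derived
# codons plus an ancestor-position map (NA for insertions) and event counts.
.diverge_codons <- function(codons, params, lineage) {
  env <- .codon_table()
  n <- length(codons)
  s <- if (lineage == "A") 1 else -1
  u <- stats::runif(n)
  ev <- rep("none", n)
  ev[u < params$p_syn] <- "syn"
  ev[u >= params$p_syn & u < params$p_syn + params$p_nonsyn] <- "nonsyn"
  ev[u >= params$p_syn + params$p_nonsyn &
       u < params$p_syn + params$p_nonsyn + params$p_indel] <- "indel"
  out <- codons
  aa <- .translate_codons(codons)

  syn_idx <- which(ev == "syn")
  n_syn_changed <- 0L
  if (length(syn_idx)) {
    wts <- .syn_weights(params$delta_at3, s)
    for (a in unique(aa[syn_idx])) {
      idx <- syn_idx[aa[syn_idx] == a]
      fam <- env$families[[a]]
      if (length(fam) == 1L) next
      out[idx] <- fam[sample.int(length(fam), length(idx), replace = TRUE,
                                 prob = wts[[a]])]
    }
    n_syn_changed <- sum(out[syn_idx] != codons[syn_idx])
  }

  nonsyn_idx <- which(ev == "nonsyn")
  if (length(nonsyn_idx)) {
    pref <- if (lineage == "A") params$pref_a else params$pref_b
    for (a in unique(aa[nonsyn_idx])) {
      idx <- nonsyn_idx[aa[nonsyn_idx] == a]
      targets <- sample(AA_LETTERS, length(idx), replace = TRUE,
                        prob = pref[a, ])
      out[idx] <- .uniform_family_codons(targets, env)
    }
  }

  # Whole-codon indels: deletion drops the codon, insertion adds a random
  # stop-free codon after it. Frame is preserved either way.
  map <- seq_len(n)
  indel_idx <- which(ev == "indel")
  n_del <- 0L; n_ins <- 0L
  if (length(indel_idx)) {
    del <- stats::runif(length(indel_idx)) < 0.5
    del_pos <- indel_idx[del]
    ins_pos <- indel_idx[!del]
    n_del <- length(del_pos); n_ins <- length(ins_pos)
    times <- rep(1L, n)
    times[del_pos] <- 0L
    times[ins_pos] <- 2L
    src <- rep(seq_len(n), times)
    out <- out[src]
    map <- src
    is_ins_copy <- duplicated(src) # second occurrence = inserted codon
    if (any(is_ins_copy)) {
      out[is_ins_copy] <- .random_codons(sum(is_ins_copy), params$aa_freq)
      map[is_ins_copy] <- NA_integer_
    }
  }

  list(
    codons = out, map = map, n_syn = n_syn_changed,
    n_nonsyn = length(nonsyn_idx), n_del = n_del, n_ins = n_ins
  )
}

#' Diverge an ancestor along one lineage
#'
#' Applies the per-codon divergence model: with probability `p_syn` a codon
#' is resampled within its synonymous family (third-position A/T codons
#' upweighted by `1 + delta_at3` in lineage A, downweighted in lineage B);
#' otherwise with probability `p_nonsyn` the amino acid is replaced according
#' to the lineage's preference matrix and a codon drawn uniformly in the
#' target family; otherwise with probability `p_indel` a whole codon is
#' deleted or inserted. Events are mutually exclusive per codon.
#'
#' @param ancestor One-row sequence tibble (stop-free coding sequence).
#' @param params A [sim_params()] object.
#' @param lineage `"A"` or `"B"`.
#' @return One-row sequence tibble for the derived lineage.
#' @export
diverge <- function(ancestor, params, lineage = c("A", "B")) {
  lineage <- match.arg(lineage)
  ancestor <- .as_sequence_tbl(ancestor)
  stopifnot(nrow(ancestor) == 1)
  codons <- split_codons(ancestor$nucleotides, ancestor$frame_offset)
  if (any(.translate_codons(codons) == "*")) {
    abort("ancestor must be stop-free")
  }
  d <- .diverge_codons(codons, params, lineage)
  tibble(id = paste0(lineage, "_", ancestor$id), species = lineage,
         nucleotides = paste(d$codons, collapse = ""), frame_offset = 0L)
}

# True per-codon alignment of one simulated pair, from the ancestor-position
# maps of the two lineages. An insertion always directly follows its source
# codon, which anchors it between ancestor positions.
.pair_alignment <- function(da, db, n_anc) {
  pos_a <- match(seq_len(n_anc), da$map) # derived index of each anc position
  pos_b <- match(seq_len(n_anc), db$map)
  a_has <- !is.na(pos_a)
  b_has <- !is.na(pos_b)
  main <- which(a_has | b_has)
  key <- 3 * main
  cod_a <- ifelse(a_has[main], da$codons[pos_a[main]], "---")
  cod_b <- ifelse(b_has[main], db$codons[pos_b[main]], "---")
  ins_a <- which(is.na(da$map))
  if (length(ins_a)) {
    key <- c(key, 3 * da$map[ins_a - 1L] + 1)
    cod_a <- c(cod_a, da$codons[ins_a])
    cod_b <- c(cod_b, rep("---", length(ins_a)))
  }
  ins_b <- which(is.na(db$map))
  if (length(ins_b)) {
    key <- c(key, 3 * db$map[ins_b - 1L] + 2)
    cod_a <- c(cod_a, rep("---", length(ins_b)))
    cod_b <- c(cod_b, db$codons[ins_b])
  }
  o <- order(key)
  list(codon_a = cod_a[o], codon_b = cod_b[o])
}

#' Simulate classified codon columns directly
#'
#' Generates ortholog pairs and returns the per-column classified codon
#' table implied by the *true* alignment known to the generator (no aligner
#' involved). This is the fast path used for replicate-based calibration;
#' the full pipeline ([run_all()]) instead rediscovers the alignment from the
#' sequences.
#'
#' @param params A [sim_params()] object.
#' @return List with `columns` (classified codon-column tibble, see
#'   [classify_codon_columns()]) and `truth` (per-pair realized identity and
#'   event counts).
#' @export
simulate_pair_columns <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  if (params$codon_length < 10) abort("codon_length must be at least 10")
  n <- params$n_pairs
  seeds <- .child_seeds(params, 3L * max(n, 1L))
  cols_list <- vector("list", n)
  truth_list <- vector("list", n)
  for (k in seq_len(n)) {
    set.seed(seeds[k])
    anc <- .random_codons(params$codon_length, params$aa_freq)
    set.seed(seeds[n + k])
    da <- .diverge_codons(anc, params, "A")
    set.seed(seeds[2L * n + k])
    db <- .diverge_codons(anc, params, "B")
    aln <- .pair_alignment(da, db, params$codon_length)
    cols_list[[k]] <- aln
    truth_list[[k]] <- c(da$n_syn, db$n_syn, da$n_nonsyn, db$n_nonsyn,
                         da$n_del + da$n_ins, db$n_del + db$n_ins)
  }
  lens <- vapply(cols_list, function(x) length(x$codon_a), 0L)
  pair_ids <- sprintf("pair%05d", seq_len(n))
  columns <- classify_codon_columns(tibble(
    pair_id = rep(pair_ids, lens),
    group_id = rep(sprintf("OG%05d", seq_len(n)), lens),
    column = unlist(lapply(lens, seq_len)),
    codon_a = unlist(lapply(cols_list, `[[`, "codon_a")),
    codon_b = unlist(lapply(cols_list, `[[`, "codon_b"))
  ))
  tm <- do.call(rbind, truth_list)
  truth <- tibble(
    pair_id = pair_ids, ancestor_id = sprintf("anc%05d", seq_len(n)),
    n_syn_a = tm[, 1], n_syn_b = tm[, 2],
    n_nonsyn_a = tm[, 3], n_nonsyn_b = tm[, 4],
    n_indel_a = tm[, 5], n_indel_b = tm[, 6]
  )
  ident <- columns |>
    filter(.data$class != "indel") |>
    group_by(.data$pair_id) |>
    summarise(identity = 100 * mean(.data$class %in%
                                      c("identical", "synonymous")),
              .groups = "drop")
  truth <- left_join(truth, ident, by = "pair_id")
  list(columns = columns, truth = truth)
}

#' Simulate a complete dataset
#'
#' Generates ancestors, diverges each along lineages A and B, appends decoy
#' sequences without partners, and builds (optionally corrupted) orthology
#' assignment tables. Everything needed for parameter-recovery tests is
#' recorded in `truth`.
#'
#' @param params A [sim_params()] object.
#' @return List with `sequences` (tibble over both species and decoys),
#'   `orthology_a`, `orthology_b` (tibbles `seq_id`, `group_id`, `bitscore`,
#'   `evalue`) and `truth` (list: `params`, per-pair table, misassignment
#'   counts).
#' @export
simulate_dataset <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  if (params$codon_length < 10) abort("codon_length must be at least 10")
  n <- params$n_pairs
  seeds <- .child_seeds(params, 3L * max(n, 1L) + 2L * params$n_decoys + 1L)
  seq_rows <- list()
  truth_rows <- list()
  for (k in seq_len(n)) {
    set.seed(seeds[k])
    anc <- .random_codons(params$codon_length, params$aa_freq)
    set.seed(seeds[n + k])
    da <- .diverge_codons(anc, params, "A")
    set.seed(seeds[2L * n + k])
    db <- .diverge_codons(anc, params, "B")
    gid <- sprintf("OG%05d", k)
    seq_rows[[length(seq_rows) + 1L]] <- tibble(
      id = c(sprintf("A_%05d", k), sprintf("B_%05d", k)),
      species = c("A", "B"),
      nucleotides = c(paste(da$codons, collapse = ""),
                      paste(db$codons, collapse = "")),
      frame_offset = 0L, group_id = gid
    )
    aa_a <- .translate_codons(da$codons[!is.na(da$map)])
    aa_b <- .translate_codons(db$codons[!is.na(db$map)])
    shared <- intersect(da$map[!is.na(da$map)], db$map[!is.na(db$map)])
    ident <- mean(aa_a[match(shared, da$map[!is.na(da$map)])] ==
                    aa_b[match(shared, db$map[!is.na(db$map)])]) * 100
    truth_rows[[k]] <- tibble(
      group_id = gid, ancestor_id = sprintf("anc%05d", k),
      identity = ident,
      n_nonsyn_a = da$n_nonsyn, n_nonsyn_b = db$n_nonsyn,
      n_indel_a = da$n_del + da$n_ins, n_indel_b = db$n_del + db$n_ins
    )
  }
  # decoys: realistic stop-free sequences with partner-less orthology groups
  for (d in seq_len(params$n_decoys)) {
    set.seed(seeds[3L * max(n, 1L) + d])
    seq_rows[[length(seq_rows) + 1L]] <- tibble(
      id = sprintf("A_decoy%03d", d), species = "A",
      nucleotides = paste(.random_codons(params$codon_length, params$aa_freq),
                          collapse = ""),
      frame_offset = 0L, group_id = sprintf("DECOYA%03d", d)
    )
    set.seed(seeds[3L * max(n, 1L) + params$n_decoys + d])
    seq_rows[[length(seq_rows) + 1L]] <- tibble(
      id = sprintf("B_decoy%03d", d), species = "B",
      nucleotides = paste(.random_codons(params$codon_length, params$aa_freq),
                          collapse = ""),
      frame_offset = 0L, group_id = sprintf("DECOYB%03d", d)
    )
  }
  sequences <- bind_rows(seq_rows)

  # orthology tables, with a p_misassign fraction of corrupted group ids
  set.seed(seeds[length(seeds)])
  all_groups <- unique(sequences$group_id)
  make_orth <- function(sp) {
    rows <- sequences |> filter(.data$species == sp)
    corrupt <- stats::runif(nrow(rows)) < params$p_misassign
    gid <- rows$group_id
    for (i in which(corrupt)) {
      gid[i] <- sample(setdiff(all_groups, rows$group_id[i]), 1L)
    }
    list(tbl = tibble(
      seq_id = rows$id, group_id = gid,
      bitscore = round(stats::runif(nrow(rows), 100, 400), 1),
      evalue = 10^stats::runif(nrow(rows), -80, -20)
    ), n_corrupted = sum(corrupt))
  }
  oa <- make_orth("A")
  ob <- make_orth("B")

  list(
    sequences = sequences |> select(-"group_id"),
    orthology_a = oa$tbl, orthology_b = ob$tbl,
    truth = list(
      params = params, per_pair = bind_rows(truth_rows),
      n_misassigned_a = oa$n_corrupted, n_misassigned_b = ob$n_corrupted
    )
  )
}

#' Write a simulated dataset to disk
#'
#' Emits one FASTA per species, one orthology TSV per species, and a truth
#' JSON recording all generator parameters and per-pair realized quantities.
#'
#' @param dataset Result of [simulate_dataset()].
#' @param outdir Writable output directory (created if missing).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_dataset <- function(dataset, outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  paths <- c(
    fasta_a = file.path(outdir, "species_A.fasta"),
    fasta_b = file.path(outdir, "species_B.fasta"),
    orthology_a = file.path(outdir, "orthology_A.tsv"),
    orthology_b = file.path(outdir, "orthology_B.tsv"),
    truth = file.path(outdir, "truth.json")
  )
  seqs <- dataset$sequences
  write_fasta(seqs[seqs$species == "A", ], paths[["fasta_a"]])
  write_fasta(seqs[seqs$species == "B", ], paths[["fasta_b"]])
  write_orthology(dataset$orthology_a, paths[["orthology_a"]])
  write_orthology(dataset$orthology_b, paths[["orthology_b"]])
  truth <- dataset$truth
  truth$params <- unclass(truth$params)
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
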