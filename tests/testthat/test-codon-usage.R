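# GC3/AT3 ledger, codon shift panels, Fisher exact test, WCA, GC summaries.

test_that("the GC3 ledger counts only synonymous nt12-conserved columns", {
  cols <- build_cols(c("GCT", "GCT", "CTG", "GAA"),
                     c("GCC", "GCA", "TTG", "GAT"))
  led <- gc3_ledger(cols)
  # (GCT,GCC): A third = T (AT3), B third = C (GC3) -> gc3_to_at3
  # (GCT,GCA): both AT3 -> no shift; (CTG,TTG): nt1 differs -> excluded
  # (GAA,GAT): nonsynonymous -> excluded
  expect_equal(led$gc3_to_at3, 1)
  expect_equal(led$at3_to_gc3, 0)
  expect_equal(led$net_gc3_loss_a, 1)
  expect_equal(led$n_synonymous_nt12_conserved, 2)
  expect_equal(led$n_aligned_residue_pairs, 4)
  g <- glance(led)
  expect_equal(g$net_gc3_loss_a, 1)
})

test_that("ledger equals the naive rescan oracle and species-swap negates
           the net loss", {
  p <- sim_params(n_pairs = 60, codon_length = 80, p_indel = 0.02, seed = 51)
  cols <- simulate_pair_columns(p)$columns
  led <- gc3_ledger(cols)
  o <- oracle_rescan(cols)
  expect_equal(led$n_aligned_residue_pairs, o$n_aligned)
  expect_equal(led$n_synonymous_nt12_conserved, o$n_syn12)
  expect_equal(led$gc3_to_at3, o$gc3_to_at3)
  expect_equal(led$at3_to_gc3, o$at3_to_gc3)
  expect_equal(cols$class, o$classes)

  swapped <- cols |>
    dplyr::mutate(tmp = codon_a, codon_a = codon_b, codon_b = tmp,
                  tmp2 = aa_a, aa_a = aa_b, aa_b = tmp2,
                  tmp3 = nt3_a, nt3_a = nt3_b, nt3_b = tmp3)
  expect_equal(gc3_ledger(swapped)$net_gc3_loss_a, -led$net_gc3_loss_a)
})

test_that("shift table frequencies are normalized over 59 codons and the
           worked alanine example holds", {
  cols <- build_cols(
    c(rep("GCT", 60), rep("GCC", 40)),
    c(rep("GCT", 40), rep("GCC", 20), rep("GCC", 40))
  )
  st <- codon_shift_table(cols)
  expect_equal(nrow(st), 59)
  expect_false(any(c("ATG", "TGG", "TAA", "TAG", "TGA") %in% st$codon))
  expect_equal(sum(st$freq_a), 1, tolerance = 1e-12)
  expect_equal(sum(st$freq_b), 1, tolerance = 1e-12)
  expect_equal(st$shift[st$codon == "GCT"], 0.2)
  expect_equal(st$panel[st$codon == "GCT"], "positive")
  expect_true(st$at3[st$codon == "GCT"])
  expect_equal(st$shift[st$codon == "GCC"], -0.2)
  expect_false(st$at3[st$codon == "GCC"])
  expect_equal(sum(st$shift), 0, tolerance = 1e-12)
})

test_that("identical usage gives all-zero shifts; random tables sum to zero", {
  cols <- build_cols(c("GCT", "AAA", "CGT"), c("GCT", "AAA", "CGT"))
  st <- codon_shift_table(cols)
  expect_true(all(st$shift == 0))
  p <- sim_params(n_pairs = 30, codon_length = 60, seed = 41)
  st2 <- codon_shift_table(simulate_pair_columns(p)$columns)
  expect_equal(sum(st2$shift), 0, tolerance = 1e-12)
})

test_that("Fisher two-sided p follows the point-probability convention", {
  expect_equal(fisher_exact_2x2(matrix(c(3, 0, 0, 3), 2)), 0.1,
               tolerance = 1e-9)
  expect_equal(fisher_exact_2x2(matrix(c(1, 0, 0, 1), 2)), 1.0,
               tolerance = 1e-9)
  expect_error(fisher_exact_2x2(matrix(c(-1, 0, 0, 1), 2)), "negative")
})

test_that("Fisher p matches hypergeometric enumeration for 200 random
           tables with margins <= 20", {
  set.seed(71)
  for (i in 1:200) {
    tab <- matrix(sample(0:10, 4, replace = TRUE), 2)
    expect_equal(fisher_exact_2x2(tab), oracle_fisher_p(tab),
                 tolerance = 1e-7,
                 info = paste(tab, collapse = ","))
  }
})

test_that("the shift contingency table partitions nonzero-shift codons by
           third base and direction", {
  p <- sim_params(n_pairs = 40, codon_length = 100, seed = 81)
  st <- codon_shift_table(simulate_pair_columns(p)$columns)
  ct <- shift_contingency(st)
  expect_equal(sum(ct$table) + ct$n_zero_shift, 59)
  expect_equal(unname(ct$table["AT3", "positive"]),
               sum(st$at3 & st$shift > 0))
  expect_gte(ct$p_value, 0)
  expect_lte(ct$p_value, 1)
})

test_that("per-species mean GC over segments matches direct recomputation", {
  cols <- dplyr::bind_rows(
    build_cols(c("GGG", "CCC"), c("GGG", "CCC"), "p1"),
    build_cols(c("ATA", "TAT"), c("ATA", "TAT"), "p2")
  )
  gc <- mean_gc(cols)
  expect_equal(gc$mean_gc_percent, c(50, 50))
  p <- sim_params(n_pairs = 20, codon_length = 50, p_indel = 0.02, seed = 91)
  cols2 <- simulate_pair_columns(p)$columns
  gc2 <- mean_gc(cols2)
  # oracle: recompute from raw per-pair strings
  segs <- split(cols2[cols2$codon_a != "---" & cols2$codon_b != "---", ],
                cols2$pair_id[cols2$codon_a != "---" & cols2$codon_b != "---"])
  ora <- mean(vapply(segs, function(s) {
    x <- paste(s$codon_a, collapse = "")
    100 * sum(strsplit(x, "")[[1]] %in% c("G", "C")) / nchar(x)
  }, 0.0))
  expect_equal(gc2$mean_gc_percent[1], ora)
})

# --- WCA ------------------------------------------------------------------

# Two-block codon count table differing only in third-base composition
# within each synonymous family.
make_two_cluster_counts <- function(n_per_block = 12, depth = 300,
                                    delta = 0.6, seed = 1) {
  set.seed(seed)
  code <- Biostrings::GENETIC_CODE
  universe <- setdiff(names(code)[code != "*"], c("ATG", "TGG"))
  fams <- split(universe, code[universe])
  rows <- lapply(seq_len(2 * n_per_block), function(r) {
    s <- if (r <= n_per_block) 1 else -1
    counts <- setNames(numeric(length(universe)), universe)
    for (fam in fams) {
      at3 <- substr(fam, 3, 3) %in% c("A", "T")
      w <- 1 + s * delta * at3
      counts[fam] <- as.numeric(rmultinom(1, depth, w / sum(w)))
    }
    counts
  })
  counts <- do.call(rbind, rows)
  rownames(counts) <- sprintf("seg%02d", seq_len(nrow(counts)))
  list(counts = counts,
       species = rep(c("A", "B"), each = n_per_block))
}

test_that("WCA axis 1 tracks the third-base composition of a two-cluster
           table and separates the species ellipses along axis 1", {
  tc <- make_two_cluster_counts()
  res <- wca(tc$counts, tc$species)
  cc <- res$col_coords
  # perfect rank separation of AT3 vs GC3 codons on axis 1 ...
  expect_gt(min(cc$axis1[cc$at3]), max(cc$axis1[!cc$at3]))
  # ... which pins tie-corrected Spearman at its theoretical maximum for a
  # binary indicator, sqrt(3 * n1 * n0 / (n^2 - 1))
  rho <- cor(cc$axis1, as.numeric(cc$at3), method = "spearman")
  n1 <- sum(cc$at3); n0 <- sum(!cc$at3); n <- n1 + n0
  expect_equal(abs(rho), sqrt(3 * n1 * n0 / (n^2 - 1)), tolerance = 1e-6)
  # sign convention: AT3 codons positive on axis 1
  expect_gt(mean(cc$axis1[cc$at3]), 0)
  ell <- res$ellipses
  sep1 <- abs(diff(ell$mean_axis1))
  sep2 <- abs(diff(ell$mean_axis2))
  expect_gt(sep1, 5 * sep2)
  # block A is the AT3-rich one, so it sits on the positive side
  expect_gt(ell$mean_axis1[ell$species == "A"],
            ell$mean_axis1[ell$species == "B"])
})

test_that("WCA row coordinates are weighted-centered and eigenvalues are
           non-negative, non-increasing", {
  p <- sim_params(n_pairs = 25, codon_length = 80, seed = 15)
  usage <- codon_usage_counts(simulate_pair_columns(p)$columns)
  res <- wca(usage$counts, usage$species)
  for (ax in c("axis1", "axis2")) {
    expect_equal(sum(res$row_weights * res$row_coords[[ax]]), 0,
                 tolerance = 1e-9)
  }
  ev <- res$eigenvalues
  expect_true(all(ev >= 0))
  expect_true(all(diff(ev) <= 1e-12))
})

test_that("a degenerate table with identical row profiles errors", {
  counts <- matrix(rep(c(GCT = 5, GCC = 5, GCA = 5, GCG = 5), each = 6),
                   nrow = 6)
  colnames(counts) <- c("GCT", "GCC", "GCA", "GCG")
  expect_error(wca(counts), "degenerate")
})

test_that("pooled usage counts collapse to one row per species", {
  p <- sim_params(n_pairs = 15, codon_length = 60, seed = 25)
  cols <- simulate_pair_columns(p)$columns
  pooled <- codon_usage_counts(cols, pooled = TRUE)
  expect_equal(nrow(pooled$counts), 2)
  per_seg <- codon_usage_counts(cols)
  expect_equal(sum(pooled$counts), sum(per_seg$counts))
})

test_that("wca tidiers expose coordinates and inertia", {
  tc <- make_two_cluster_counts(seed = 2)
  res <- wca(tc$counts, tc$species)
  expect_equal(nrow(tidy(res, "columns")), 59)
  expect_equal(nrow(tidy(res, "rows")), 24)
  g <- glance(res)
  expect_equal(sum(g$inertia_fraction), 1)
})
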