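# Ortholog pairing: best-pair selection, threshold filters, purging.

make_pairs <- function(...) {
  tibble::tibble(...)
}

test_that("select_best_pairs keeps the exhaustive per-group maximum with
           the stated tie-breaks", {
  alns <- make_pairs(
    group_id = c("g1", "g1", "g2", "g2"),
    id_a = c("a1", "a2", "a3", "a4"), id_b = c("b1", "b2", "b3", "b4"),
    score = c(50, 40, 60, 60),
    percent_identity = c(90, 95, 85, 90),
    evalue = NA_real_
  )
  best <- select_best_pairs(alns)
  expect_equal(nrow(best), 2)
  expect_equal(best$id_a[best$group_id == "g1"], "a1") # higher score wins
  expect_equal(best$id_a[best$group_id == "g2"], "a4") # tie -> higher identity

  # brute-force oracle over random groups
  set.seed(3)
  for (rep in 1:20) {
    rnd <- make_pairs(
      group_id = sample(c("g1", "g2", "g3"), 9, replace = TRUE),
      id_a = sprintf("a%02d", 1:9), id_b = sprintf("b%02d", 1:9),
      score = sample(1:100, 9), percent_identity = runif(9, 50, 100),
      evalue = NA_real_
    )
    best <- select_best_pairs(rnd)
    for (g in unique(rnd$group_id)) {
      sub <- rnd[rnd$group_id == g, ]
      expect_equal(best$score[best$group_id == g], max(sub$score))
    }
  }
})

test_that("equal scores and identities fall back to lexicographic ids", {
  alns <- make_pairs(
    group_id = "g", id_a = c("a2", "a1"), id_b = c("b2", "b1"),
    score = 50, percent_identity = 90, evalue = NA_real_
  )
  expect_equal(select_best_pairs(alns)$id_a, "a1")
})

test_that("filter_pairs enforces identity and e-value thresholds with an
           inclusive identity boundary", {
  pairs <- make_pairs(
    pair_id = sprintf("p%d", 1:4),
    percent_identity = c(96, 79.9, 80.0, 95),
    evalue = c(1e-30, 1e-30, 1e-30, 1e-5),
    score = 100
  )
  kept <- filter_pairs(pairs, min_identity = 80, max_evalue = 1e-9)
  expect_setequal(kept$pair_id, c("p1", "p3"))
  expect_equal(unname(attr(kept, "counters")), c(4, 2))
  expect_error(filter_pairs(pairs, min_identity = 150), "min_identity")
  expect_error(filter_pairs(pairs, max_evalue = -1), "max_evalue")
})

test_that("pairs without e-values fall back to the score floor, with notice", {
  pairs <- make_pairs(
    pair_id = c("p1", "p2"), percent_identity = c(95, 95),
    evalue = NA_real_, score = c(100, 10)
  )
  expect_message(
    kept <- filter_pairs(pairs, min_score = 50),
    "score floor"
  )
  expect_equal(kept$pair_id, "p1")
})

test_that("filtered survivors equal a direct threshold scan on simulated
           identities", {
  set.seed(14)
  pairs <- make_pairs(
    pair_id = sprintf("p%03d", 1:100),
    percent_identity = runif(100, 60, 100),
    evalue = 10^runif(100, -40, -2),
    score = 100
  )
  kept <- filter_pairs(pairs, min_identity = 80, max_evalue = 1e-9)
  oracle <- pairs$pair_id[pairs$percent_identity >= 80 &
                            pairs$evalue <= 1e-9]
  expect_identical(kept$pair_id, oracle)
})

test_that("purge_invalid removes pairs with in-frame stops or ambiguity
           codes and is order-independent with the identity filter", {
  pairs <- make_pairs(
    pair_id = c("ok", "stop", "ambig"),
    percent_identity = c(95, 95, 95), evalue = 1e-30, score = 100
  )
  cols <- dplyr::bind_rows(
    build_cols(c("ATG", "GCT"), c("ATG", "GCC"), "ok"),
    build_cols(c("ATG", "TAA"), c("ATG", "GCC"), "stop"),
    build_cols(c("ATG", "GNT"), c("ATG", "GCC"), "ambig")
  )
  purged <- purge_invalid(pairs, cols)
  expect_equal(purged$pair_id, "ok")
  expect_equal(attr(purged, "n_removed"), 2)

  # order independence of independent predicates
  lowid <- make_pairs(pair_id = "low", percent_identity = 10,
                      evalue = 1e-30, score = 100)
  all_pairs <- dplyr::bind_rows(pairs, lowid)
  cols_all <- dplyr::bind_rows(cols,
                               build_cols(c("ATG"), c("ATG"), "low"))
  a <- purge_invalid(filter_pairs(all_pairs), cols_all)
  b <- filter_pairs(purge_invalid(all_pairs, cols_all))
  expect_setequal(a$pair_id, b$pair_id)

  expect_error(purge_invalid(pairs, NULL), "classified")
  expect_error(purge_invalid(make_pairs(pair_id = "nope"), cols), "missing")
})

test_that("a clean simulated set suffers zero purge removals and recovers
           all well-assigned pairs above the identity threshold", {
  p <- sim_params(n_pairs = 30, codon_length = 60, p_misassign = 0,
                  n_decoys = 3, p_indel = 0.01, seed = 77)
  ds <- simulate_dataset(p)
  alns <- align_ortholog_candidates(ds$sequences, ds$orthology_a,
                                    ds$orthology_b)
  best <- select_best_pairs(alns)
  kept <- suppressMessages(filter_pairs(best, min_identity = 80))
  cols <- backtranslate_pairs(kept, ds$sequences)
  purged <- purge_invalid(kept, cols)
  expect_equal(attr(purged, "n_removed"), 0)
  # every true pair whose realized identity clears the threshold survives
  expect_gte(nrow(purged), sum(ds$truth$per_pair$identity >= 80) - 1)
  expect_false(any(grepl("DECOY", purged$group_id)))
})

test_that("outfmt-6 hit tables convert to candidate pairs with 0-based
           coordinates and keep their reported e-values", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "a1\tb1\t95.5\t100\t4\t1\t1\t100\t11\t110\t1e-30\t200",
    "a2\tb9\t90.0\t50\t5\t0\t3\t52\t1\t50\t1e-12\t80"
  ), path)
  hits <- read_blast_hits(path)
  expect_equal(hits$qstart, c(0L, 2L))
  orth_a <- tibble::tibble(seq_id = c("a1", "a2"), group_id = c("g1", "g2"),
                           bitscore = 1, evalue = 1e-40)
  orth_b <- tibble::tibble(seq_id = c("b1", "b2"), group_id = c("g1", "g2"),
                           bitscore = 1, evalue = 1e-40)
  cand <- pairs_from_hits(hits, orth_a, orth_b)
  expect_equal(nrow(cand), 1) # a2->b9 shares no group
  expect_equal(cand$evalue, 1e-30)
  expect_equal(cand$percent_identity, 95.5)
})
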