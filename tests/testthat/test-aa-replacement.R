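# Replacement counts, imbalance algebra, net usage, ERK Wilcoxon screen.

test_that("replacement counting puts exchanges off-diagonal and conserved
           columns on the diagonal", {
  # A = "ST", B = "SA": one conserved S, one T->A exchange
  cols <- build_cols(c("TCT", "ACT"), c("TCT", "GCT"))
  C <- count_replacements(cols)
  expect_equal(unname(C["S", "S"]), 1)
  expect_equal(unname(C["T", "A"]), 1)
  expect_equal(attr(C, "total_exchanged"), 1)
  expect_equal(sum(C) - sum(diag(C)), 1)
})

test_that("identical sequences give an all-diagonal matrix", {
  cols <- build_cols(c("ATG", "GAA", "TGG"), c("ATG", "GAA", "TGG"))
  C <- count_replacements(cols)
  expect_equal(sum(C) - sum(diag(C)), 0)
  expect_equal(attr(C, "total_exchanged"), 0)
})

test_that("replacement matrix equals the naive rescan oracle on simulated
           pairs", {
  p <- sim_params(n_pairs = 50, codon_length = 60, p_indel = 0.02, seed = 61)
  cols <- simulate_pair_columns(p)$columns
  C <- count_replacements(cols)
  o <- oracle_rescan(cols)
  expect_equal(unclass(C)[rownames(o$C), colnames(o$C)], o$C,
               ignore_attr = TRUE)
})

test_that("imbalance is the antisymmetric transform with the worked
           example values", {
  cols <- build_cols(rep(c("ACT", "ACT", "ACT", "GCT"), 1),
                     rep(c("GCT", "GCT", "GCT", "ACT"), 1))
  C <- count_replacements(cols) # C[T,A]=3, C[A,T]=1
  D <- imbalance(C)
  expect_equal(unname(D["T", "A"]), 2)
  expect_equal(unname(D["A", "T"]), -2)
  expect_true(all(unclass(D) + t(unclass(D)) == 0))
})

test_that("imbalance antisymmetry and net zero-sum hold over many random
           count matrices", {
  set.seed(8)
  for (i in 1:400) {
    C <- matrix(rpois(400, 3), 20, 20,
                dimnames = list(rownames(uniform_pref_matrix()),
                                colnames(uniform_pref_matrix())))
    class(C) <- c("replacement_matrix", "matrix")
    D <- imbalance(C)
    expect_true(all(unclass(D) == -t(unclass(D))))
    expect_equal(sum(diag(unclass(D))), 0)
    expect_equal(sum(net_usage(D)$net), 0)
  }
})

test_that("net usage reflects single-cell imbalances and species-swap
           negates C-transposition, D and the nets", {
  cols <- build_cols(c("ACT", "GCT"), c("GCT", "GCT"))
  C <- count_replacements(cols)
  D <- imbalance(C)
  nets <- net_usage(D)
  expect_equal(nets$net[nets$aa == "T"], 1)
  expect_equal(nets$net[nets$aa == "A"], -1)
  expect_equal(sum(abs(nets$net)), 2)

  # swap the species labels
  swapped <- cols |>
    dplyr::mutate(tmp = codon_a, codon_a = codon_b, codon_b = tmp,
                  tmp2 = aa_a, aa_a = aa_b, aa_b = tmp2)
  C2 <- count_replacements(swapped)
  expect_equal(unclass(C2), t(unclass(C)), ignore_attr = TRUE)
  D2 <- imbalance(C2)
  expect_equal(unclass(D2), -unclass(D), ignore_attr = TRUE)
  expect_equal(net_usage(D2)$net, -nets$net)
})

test_that("the lower-triangular rendering shows each unordered pair once", {
  p <- sim_params(n_pairs = 10, codon_length = 40, seed = 3)
  D <- imbalance(count_replacements(simulate_pair_columns(p)$columns))
  tri <- imbalance_lower_triangle(D)
  expect_equal(rownames(tri)[1], "R")
  expect_equal(sum(!is.na(as.matrix(tri))), 20 * 19 / 2)
})

test_that("class aggregation sums nets over a user partition", {
  cols <- build_cols(c("ACT", "GCT"), c("GCT", "GCT"))
  D <- imbalance(count_replacements(cols))
  partition <- setNames(rep("unpolar", 20), rownames(uniform_pref_matrix()))
  partition[c("S", "T", "N", "Q", "Y", "C")] <- "polar"
  agg <- aa_class_net(D, partition)
  expect_equal(sum(agg$net), 0)
  expect_equal(agg$net[agg$class == "polar"], 1) # the T gain
})

test_that("ERK records count E/R/K among exchanged positions only", {
  # A = DKA vs B = EKA: one exchanged position (D vs E)
  cols <- build_cols(c("GAT", "AAA", "GCT"), c("GAA", "AAA", "GCT"))
  res <- erk_test(cols)
  expect_equal(res$records$exchanged, 1)
  expect_equal(res$records$erk_a, 0)
  expect_equal(res$records$erk_b, 1)
})

test_that("five all-positive distinct differences give the exact two-sided
           p of 0.0625", {
  cols <- dplyr::bind_rows(lapply(1:5, function(k) {
    # pair k: k exchanged columns, each E (A) vs D (B) -> d = +k
    build_cols(rep("GAA", k), rep("GAT", k), sprintf("p%d", k))
  }))
  res <- erk_test(cols)
  expect_equal(res$n_effective, 5)
  expect_equal(res$p_value, 0.0625)
  expect_match(res$method, "exact")
})

test_that("exact ERK p-values match full sign enumeration for n <= 12", {
  set.seed(19)
  for (rep in 1:25) {
    n <- sample(4:12, 1)
    # random distinct positive magnitudes with random signs
    d <- sample(1:50, n) * sample(c(-1, 1), n, replace = TRUE)
    cols <- dplyr::bind_rows(lapply(seq_len(n), function(k) {
      m <- abs(d[k])
      if (d[k] > 0) build_cols(rep("GAA", m), rep("GCT", m), sprintf("p%d", k))
      else build_cols(rep("GCT", m), rep("GAA", m), sprintf("p%d", k))
    }))
    res <- erk_test(cols)
    expect_equal(res$p_value, oracle_wilcoxon_p(d), tolerance = 1e-12,
                 info = paste(d, collapse = ","))
  }
})

test_that("degenerate ERK inputs behave as documented", {
  cols <- build_cols(c("GCT", "GCT"), c("GCT", "GCC")) # no exchanges
  expect_error(erk_test(cols), "no pair with an exchanged position")
  # exchanges exist but never touch E/R/K: all differences zero
  cols2 <- build_cols(c("GCT"), c("ACT")) # A vs T
  expect_warning(res <- erk_test(cols2), "zero")
  expect_equal(res$p_value, 1.0)
})

test_that("the fraction variant divides by exchanged positions", {
  cols <- dplyr::bind_rows(
    build_cols(rep("GAA", 2), c("GAT", "GCT"), "p1"), # 2 exchanged, erk d=+2
    build_cols("GAA", "GAT", "p2")
  )
  res <- erk_test(cols, fraction = TRUE)
  expect_equal(res$records$d, c(1, 1))
})

test_that("tidy and glance methods expose records and the test summary", {
  p <- sim_params(n_pairs = 15, codon_length = 50, seed = 4)
  cols <- simulate_pair_columns(p)$columns
  res <- erk_test(cols)
  expect_s3_class(tidy(res), "tbl_df")
  g <- glance(res)
  expect_equal(g$n_pairs, 15)
  C <- count_replacements(cols)
  td <- tidy(C)
  expect_equal(sum(td$count), attr(C, "total_exchanged"))
  ti <- tidy(imbalance(C))
  expect_equal(nrow(ti), 380)
  expect_equal(sum(ti$imbalance), 0)
})
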