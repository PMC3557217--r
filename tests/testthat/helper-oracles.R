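# Independent oracles used across the suite. Each is a deliberately naive
# reimplementation (enumeration, rescans, brute-force DP) kept separate from
# the package's own code paths.

# Brute-force affine-gap Smith-Waterman score (no traceback): plain three-
# matrix DP written directly from the recurrences.
oracle_sw_score <- function(a, b, S, open, ext) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  M <- matrix(0, n + 1, m + 1)
  Ix <- matrix(-Inf, n + 1, m + 1)
  Iy <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- S[av[i], bv[j]]
      M[i + 1, j + 1] <- max(0, M[i, j], Ix[i, j], Iy[i, j]) + s
      if (M[i + 1, j + 1] < 0) M[i + 1, j + 1] <- 0
      Ix[i + 1, j + 1] <- max(M[i, j + 1] - open - ext, Ix[i, j + 1] - ext)
      Iy[i + 1, j + 1] <- max(M[i + 1, j] - open - ext, Iy[i + 1, j] - ext)
      best <- max(best, M[i + 1, j + 1])
    }
  }
  best
}

# Hypergeometric enumeration of the two-sided Fisher p for a 2x2 table
# (point-probability convention), using only choose().
oracle_fisher_p <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  ks <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- choose(r1, ks) * choose(n - r1, c1 - ks) / choose(n, c1)
  p_obs <- choose(r1, a) * choose(n - r1, c1 - a) / choose(n, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Full 2^n sign enumeration of the exact two-sided Wilcoxon signed-rank p
# for zero-free, tie-free differences d.
oracle_wilcoxon_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  stopifnot(n <= 20, !any(duplicated(abs(d))))
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.numeric(signs %*% r)
  p_low <- mean(v_all <= v_obs)
  p_high <- mean(v_all >= v_obs)
  min(1, 2 * min(p_low, p_high))
}

# Naive per-position rescan of a classified column table: recounts classes,
# the replacement matrix and the GC3 ledger directly from the codon strings
# with scalar loops and no shared helpers.
oracle_rescan <- function(cols) {
  code <- Biostrings::GENETIC_CODE
  aas <- sort(unique(code[code != "*"]))
  C <- matrix(0L, 20, 20, dimnames = list(aas, aas))
  gc3_to_at3 <- 0L; at3_to_gc3 <- 0L; n_syn12 <- 0L; n_aligned <- 0L
  classes <- character(nrow(cols))
  for (i in seq_len(nrow(cols))) {
    ca <- cols$codon_a[i]; cb <- cols$codon_b[i]
    if (ca == "---" || cb == "---") {
      classes[i] <- "indel"
      next
    }
    ok_a <- grepl("^[ACGT]{3}$", ca); ok_b <- grepl("^[ACGT]{3}$", cb)
    aa <- if (ok_a) code[[ca]] else "X"
    ab <- if (ok_b) code[[cb]] else "X"
    if (!ok_a || !ok_b || aa == "*" || ab == "*") {
      classes[i] <- "invalid"
      next
    }
    n_aligned <- n_aligned + 1L
    C[aa, ab] <- C[aa, ab] + 1L
    if (ca == cb) classes[i] <- "identical"
    else if (aa == ab) classes[i] <- "synonymous"
    else classes[i] <- "nonsynonymous"
    if (aa == ab && substr(ca, 1, 2) == substr(cb, 1, 2)) {
      n_syn12 <- n_syn12 + 1L
      third_a <- substr(ca, 3, 3); third_b <- substr(cb, 3, 3)
      a_at <- third_a %in% c("A", "T"); b_at <- third_b %in% c("A", "T")
      if (a_at && !b_at) gc3_to_at3 <- gc3_to_at3 + 1L
      if (!a_at && b_at) at3_to_gc3 <- at3_to_gc3 + 1L
    }
  }
  list(classes = classes, C = C, n_aligned = n_aligned,
       n_syn12 = n_syn12, gc3_to_at3 = gc3_to_at3,
       at3_to_gc3 = at3_to_gc3,
       net_gc3_loss_a = gc3_to_at3 - at3_to_gc3)
}

# Random protein string over the 20 amino acids.
random_protein <- function(n) {
  paste(sample(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                 "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
               n, replace = TRUE), collapse = "")
}

# Small hand-built classified column table from two aligned codon vectors.
build_cols <- function(codon_a, codon_b, pair_id = "p1") {
  classify_codon_columns(tibble::tibble(
    pair_id = pair_id, group_id = pair_id,
    column = seq_along(codon_a), codon_a = codon_a, codon_b = codon_b
  ))
}
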