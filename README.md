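# orthocodon

Comparative analysis of orthologous coding-sequence pairs from two closely
related species, built to detect thermal-adaptation signatures in
transcriptomes:

* **amino-acid replacement imbalances** at non-synonymous positions — the
  antisymmetric matrix `D[i, j] = C[i, j] − C[j, i]` of position-specific
  exchange counts, its per-amino-acid net usage `net(i) = Σ_j D[i, j]`, and
  a paired Wilcoxon screen on E+R+K usage at exchanged positions (the ERK
  proxy of thermal adaptation);
* **A/T vs G/C shifts at synonymous third codon positions** (GC3/AT3) —
  a paired ledger over synonymous codon columns with conserved first and
  second bases, per-codon usage-shift panels over the 59 informative sense
  codons with a Fisher exact contingency test, and a within-group
  correspondence analysis (WCA) that ordinates synonymous codon usage after
  removing amino-acid composition effects;
* **functional-category coverage profiles** — orthology-term hits pooled
  into COG/KOG categories, coverage against a reference gene set, and a
  per-term Fisher screen for library-specific terms.

The package is aimed at molecular evolution researchers comparing two
transcriptome or genome-scale coding-sequence libraries of confamiliar
species (the design case is an Antarctic vs a temperate zoarcid fish). It
ships every stage as a tested function: a Smith–Waterman local protein
aligner (BLOSUM62, affine 11/1) with orthology-group-wise best-pair
selection and identity/e-value filtering, codon back-translation with
per-column classification, all statistics above, and a synthetic-data
generator that produces diverging ortholog pairs with *known* injected
signatures so the whole pipeline is verifiable offline.

All user-facing functions take and return tibbles and compose with the
pipe; result objects have `tidy()`/`glance()` methods and
`plot_*()`/`autoplot()` figures.

## A worked example

`run_all()` chains every stage. With no input files it simulates a dataset
under the package's default study conditions — 200 ortholog pairs of
150-codon ancestors at ~96% translated identity, a lineage-A third-position
A/T preference of 0.15, decoys and 5% orthology misassignment — then pairs,
aligns, filters, back-translates and analyzes it:

```r
library(orthocodon)
report <- run_all(list(seed = 1))
report
```

```
orthocodon run report (config 05896317)
filter funnel:
  sequences_in                 420
  groups_seen                  183
  candidate_alignments         200
  best_pairs                   183
  pairs_after_identity_filter  180
  pairs_purged                 0
  pairs_retained               180
headline statistics:
  mean identity:            94.20%
  aligned residue pairs:    26724
  net GC3 loss (species A): 454 over 24259 synonymous pairs
  Fisher p (AT3/GC3 shift): 1.43e-09
  Wilcoxon p (ERK):         0.442
  mean GC:  A 48.653%  B 49.233%
```

Reading the output: of 200 simulated ortholog groups, 183 survive the
orthology tables (misassigned rows break some groups, decoy groups have no
partner), 180 clear the 80% identity filter, and none contain stops or
ambiguity codes. Species A shows a net loss of 454 GC3 codons over 24,259
synonymous nt1/nt2-conserved codon pairs — the injected wobble-position
A/T preference — and the Fisher test on the AT3/GC3 shift contingency is
strongly significant. The ERK Wilcoxon is non-significant, as it should
be: the default simulation injects no replacement preference.

Individual stages compose the same way on real data:

```r
seqs   <- dplyr::bind_rows(read_fasta("A.fasta", species = "A"),
                           read_fasta("B.fasta", species = "B"))
orth_a <- read_orthology("orthology_A.tsv")
orth_b <- read_orthology("orthology_B.tsv")

pairs <- align_ortholog_candidates(seqs, orth_a, orth_b) |>
  select_best_pairs() |>
  filter_pairs(min_identity = 80, max_evalue = 1e-9)
cols  <- backtranslate_pairs(pairs, seqs)
pairs <- purge_invalid(pairs, cols)
cols  <- dplyr::filter(cols, pair_id %in% pairs$pair_id)

net_usage(imbalance(count_replacements(cols)))  # Fig.-5-style net usage
gc3_ledger(cols)                                # GC3/AT3 shift ledger
erk_test(cols)                                  # ERK Wilcoxon
autoplot(wca(codon_usage_counts(cols)$counts,
             codon_usage_counts(cols)$species)) # factorial map + ellipses
```

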