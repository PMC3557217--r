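# Shared constants (loaded first in the collation order).

AA_LETTERS <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Amino-acid background frequencies typical of vertebrate proteomes
# (UniProt-style averages, normalized). Default ancestor composition in the
# synthetic-data generator.
VERTEBRATE_AA_FREQ <- local({
  f <- c(
    A = 0.074, R = 0.052, N = 0.045, D = 0.054, C = 0.023,
    Q = 0.045, E = 0.068, G = 0.063, H = 0.026, I = 0.045,
    L = 0.096, K = 0.058, M = 0.023, F = 0.037, P = 0.059,
    S = 0.081, T = 0.054, W = 0.013, Y = 0.033, V = 0.060
  )
  f / sum(f)
})

# COG/KOG single-letter functional category alphabet.
COG_CATEGORIES <- c(
  "A", "B", "C", "D", "E", "F", "G", "H", "I", "J", "K", "L", "M",
  "N", "O", "P", "Q", "R", "S", "T", "U", "V", "W", "Y", "Z"
)

`%||%` <- function(a, b) if (is.null(a)) b else a
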