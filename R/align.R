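# Local protein alignment (Smith-Waterman, affine gaps) used to pair
# orthologous translated segments. BLOSUM62 with gap open 11 / extend 1 by
# default, mirroring BLASTP defaults.

ALIGN_ALPHABET <- c(AA_LETTERS, "X", "*")

#' BLOSUM62 scoring matrix for the pairing aligner
#'
#' The BLOSUM62 matrix (from Biostrings) restricted to the 20 amino acids
#' plus `X` and `*`, with two pipeline-specific conventions: `X` scores 0
#' against everything (ambiguous translations neither help nor hurt), and
#' `*` is unalignable (a very large penalty, so a local alignment never
#' crosses a stop).
#'
#' @return A 22x22 numeric matrix.
#' @export
blosum62_scoring <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  m <- e$BLOSUM62[ALIGN_ALPHABET, ALIGN_ALPHABET]
  m["X", ] <- 0
  m[, "X"] <- 0
  m["*", ] <- -1e9
  m[, "*"] <- -1e9
  m
}

.align_env <- new.env(parent = emptyenv())
.default_scoring <- function() {
  if (is.null(.align_env$blosum62)) .align_env$blosum62 <- blosum62_scoring()
  .align_env$blosum62
}

.residue_index <- function(x) {
  idx <- match(strsplit(x, "")[[1]], ALIGN_ALPHABET)
  if (anyNA(idx)) {
    abort(paste0("residue(s) outside amino-acid alphabet in: ",
                 substr(x, 1, 30)))
  }
  idx
}

#' Optimal local alignment of two protein segments
#'
#' Smith-Waterman local alignment under an affine gap model (a gap of length
#' L costs `gap_open + L * gap_ext`). Traceback is deterministic: ties are
#' broken preferring diagonal, then up, then left, and the first maximal cell
#' in row-major order starts the traceback.
#'
#' @param a,b Residue strings (20 amino acids plus `X`; `*` is permitted but
#'   never alignable).
#' @param scoring Substitution matrix over the alignment alphabet; defaults
#'   to [blosum62_scoring()].
#' @param gap_open,gap_ext Affine gap penalties (positive).
#' @return One-row tibble with `score`, `percent_identity` (identical
#'   non-gap column pairs over total alignment columns, BLAST `pident`
#'   convention), gapped `aligned_a`/`aligned_b` strings, and 0-based
#'   half-open residue ranges `a_start`, `a_end`, `b_start`, `b_end`.
#' @examples
#' align_local("KAWAAK", "AWAA")
#' @export
align_local <- function(a, b, scoring = NULL,
                        gap_open = 11, gap_ext = 1) {
  stopifnot(nchar(a) > 0, nchar(b) > 0, gap_open >= 0, gap_ext >= 0)
  if (is.null(scoring)) scoring <- .default_scoring()
  ia <- .residue_index(a)
  ib <- .residue_index(b)
  res <- .sw_align_cpp(ia, ib, scoring, gap_open, gap_ext)
  ga <- ifelse(res$a_idx == 0, "-", ALIGN_ALPHABET[pmax(res$a_idx, 1)])
  gb <- ifelse(res$b_idx == 0, "-", ALIGN_ALPHABET[pmax(res$b_idx, 1)])
  len <- length(ga)
  n_ident <- sum(res$a_idx != 0 & res$a_idx == res$b_idx)
  tibble(
    score = res$score,
    percent_identity = if (len > 0) 100 * n_ident / len else 0,
    length = len,
    aligned_a = paste(ga, collapse = ""),
    aligned_b = paste(gb, collapse = ""),
    a_start = res$a_start - 1L, a_end = res$a_end,
    b_start = res$b_start - 1L, b_end = res$b_end
  )
}
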