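# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

# IUPAC nucleotide codes -> the set of bases each matches.
IUPAC_MAP <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Evaluate an expression under a fixed RNG seed
#'
#' Runs `expr` with the RNG seeded to `seed` and restores the caller's RNG
#' state afterwards, so generators are pure functions of (parameters, seed)
#' and leave no trace in the session.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("'seed' must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Reverse-complement a DNA string
#'
#' @param x Character vector of DNA strings (A/C/G/T/N and IUPAC codes).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  flipped <- chartr("ACGTRYSWKMBDHVNacgtryswkmbdhvn",
                    "TGCAYRSWMKVHDBNtgcayrswmkvhdbn", x)
  vapply(strsplit(flipped, "", fixed = TRUE),
         function(s) paste(rev(s), collapse = ""), character(1))
}

stopifnot_prob_vector <- function(p, what = "bg_freqs", tol = 1e-9) {
  if (length(p) != 4L || any(!is.finite(p)) || any(p < 0)) {
    stop(sprintf("'%s' must be 4 finite non-negative values", what), call. = FALSE)
  }
  if (abs(sum(p) - 1) > tol) {
    stop(sprintf("'%s' must sum to 1 (got %.12f)", what, sum(p)), call. = FALSE)
  }
  p <- as.numeric(p)
  names(p) <- DNA_BASES
  p
}

# Encode a DNA string as integer indices into DNA_BASES; non-ACGT -> NA.
encode_dna <- function(seq) {
  match(strsplit(seq, "", fixed = TRUE)[[1]], DNA_BASES)
}
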