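# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

#' @noRd
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Round half away from zero at a fixed number of decimals (printed-precision
# rule used throughout reporting; base round() is half-to-even).
#' @noRd
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Derive a reproducible 32-bit child seed from a master seed and an index.
# Keeps everything below 2^31 - 1 so it is a valid R integer seed.
#' @noRd
child_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 2654435) %% 2147483647)
}

#' @noRd
with_seed_if <- function(seed, expr) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
      stop("`seed` must be a single integer or NULL", call. = FALSE)
    }
    set.seed(as.integer(seed))
  }
  expr
}

# Reverse-complement a character vector of DNA sequences.
#' @noRd
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Phred+33 encoding of integer quality vectors; `q` is a list or a single
# integer vector, values clamped to [0, 41].
#' @noRd
phred33 <- function(q) {
  enc <- function(v) intToUtf8(clamp(as.integer(v), 0L, 41L) + 33L)
  if (is.list(q)) vapply(q, enc, character(1)) else enc(q)
}

# Integer Phred scores of a single quality string.
#' @noRd
phred_scores <- function(qual) utf8ToInt(qual) - 33L

# Fraction of bases at or above Q30 across a character vector of quality
# strings (the Illumina %Q30 run metric, as a proportion).
#' @noRd
fraction_q30 <- function(quals) {
  quals <- quals[nzchar(quals)]
  if (length(quals) == 0L) return(NA_real_)
  n_hi <- 0L
  n_tot <- 0L
  for (q in quals) {
    s <- utf8ToInt(q)
    n_hi <- n_hi + sum(s >= 63L)  # 30 + 33
    n_tot <- n_tot + length(s)
  }
  n_hi / n_tot
}

# Random DNA sequences as a character vector.
#' @noRd
random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
  }, character(1))
}

# Split equal-length sequences into an n x len character matrix.
#' @noRd
seq_matrix <- function(x) {
  if (length(x) == 0L) return(matrix(character(0), nrow = 0))
  lens <- unique(nchar(x))
  stopifnot(length(lens) == 1L)
  matrix(unlist(strsplit(x, "", fixed = TRUE), use.names = FALSE),
         nrow = length(x), ncol = lens, byrow = TRUE)
}

# Hamming distance between each row of a sequence character matrix and a
# reference sequence of the same width.
#' @noRd
hamming_to_ref <- function(mat, ref) {
  refv <- strsplit(ref, "", fixed = TRUE)[[1]]
  stopifnot(ncol(mat) == length(refv))
  rowSums(mat != matrix(refv, nrow = nrow(mat), ncol = ncol(mat), byrow = TRUE))
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
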