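DNA_BASES <- c("A", "C", "G", "T")
DPNII_SITE <- "GATC"

#' Hamming distance between two equal-length sequences
#'
#' Number of positions at which two fixed-length nucleotide sequences differ.
#' This is the distance underlying gene-family inference: signatures derived
#' from duplicated genes accumulate substitutions in the 3' UTR, so family
#' membership shows up as small pairwise mismatch counts.
#'
#' @param seq_a,seq_b Character scalars of equal length.
#' @return Integer mismatch count.
#' @examples
#' hamming("GATCA", "GATCC")
#' @export
hamming <- function(seq_a, seq_b) {
  stopifnot(is.character(seq_a), is.character(seq_b),
            length(seq_a) == 1L, length(seq_b) == 1L)
  if (nchar(seq_a) != nchar(seq_b)) {
    stop("sequences have unequal lengths (", nchar(seq_a), " vs ",
         nchar(seq_b), ")")
  }
  .hamming_mat_cpp(seq_a, seq_b)[1L, 1L]
}

#' All-pairs Hamming distance matrix
#'
#' @param a,b Character vectors of equal-length sequences; `b` defaults to `a`.
#' @return Integer matrix of dimension `length(a)` x `length(b)`.
#' @export
hamming_matrix <- function(a, b = a) {
  m <- .hamming_mat_cpp(as.character(a), as.character(b))
  rownames(m) <- names(a)
  colnames(m) <- names(b)
  m
}

# round half away from zero (base round() is round-half-even); TPM values are
# non-negative so this is round-half-up
round_half_up <- function(x) floor(x + 0.5)

# uniform random DNA strings (uses the session RNG)
random_dna <- function(n, len) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(DNA_BASES, n * len, replace = TRUE), nrow = n)
  apply(m, 1L, paste, collapse = "")
}

has_internal_anchor <- function(tails) {
  grepl(DPNII_SITE, tails, fixed = TRUE)
}

# longest single-nucleotide run in each sequence
max_homopolymer_run <- function(seqs) {
  vapply(seqs, function(s) {
    r <- rle(strsplit(s, "", fixed = TRUE)[[1L]])
    max(r$lengths)
  }, integer(1), USE.NAMES = FALSE)
}

is_count_table <- function(counts) {
  is.data.frame(counts) && ncol(counts) >= 2L &&
    identical(names(counts)[1L], "signature")
}

assert_count_table <- function(counts) {
  if (!is_count_table(counts)) {
    stop("expected a count table: a data.frame with a 'signature' column ",
         "followed by one integer column per library")
  }
  libcols <- counts[-1L]
  bad <- !vapply(libcols, is.numeric, logical(1))
  if (any(bad)) {
    stop("non-numeric library column(s): ",
         paste(names(libcols)[bad], collapse = ", "))
  }
  if (any(vapply(libcols, function(x) any(x < 0 | is.na(x)), logical(1)))) {
    stop("library counts must be non-negative and non-missing")
  }
  invisible(counts)
}

library_names <- function(counts) names(counts)[-1L]

config_hash <- function(config) rlang::hash(config)
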