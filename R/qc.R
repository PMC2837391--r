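#' Quality-control configuration for signature filtering
#'
#' Thresholds for the signature reliability filters and TPM normalization.
#' Defaults follow common MPSS practice: homopolymer runs strictly longer
#' than 7 nt mark likely sequencing artifacts, and signatures never reaching
#' 4 TPM in any library are treated as background.
#'
#' @param max_homopolymer_run Longest tolerated single-nucleotide run;
#'   sequences containing a strictly longer run are excluded. Default 7.
#' @param min_tpm Minimum TPM a signature must reach in at least one library
#'   to be retained. Default 4.
#' @param tpm_scale Normalization scale (tags per *million*). Default `1e6`.
#' @return An object of class `qc_config`.
#' @export
qc_config <- function(max_homopolymer_run = 7L, min_tpm = 4, tpm_scale = 1e6) {
  stopifnot(max_homopolymer_run > 0, min_tpm > 0, tpm_scale > 0)
  structure(list(max_homopolymer_run = as.integer(max_homopolymer_run),
                 min_tpm = min_tpm, tpm_scale = tpm_scale),
            class = "qc_config")
}

#' Remove signatures with ambiguous nucleotides
#'
#' Retains only signatures whose sequence consists solely of A, C, G and T;
#' IUPAC ambiguity codes (N, R, Y, ...) or any other character cause removal.
#' Row order is preserved. The number of removals is attached as the
#' `"n_removed"` attribute.
#'
#' @param counts Count table: data.frame with a `signature` column followed
#'   by one integer column per library.
#' @return The filtered count table.
#' @export
filter_deterministic <- function(counts) {
  assert_count_table(counts)
  keep <- grepl("^[ACGT]*$", counts$signature)
  out <- counts[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Remove signatures containing long homopolymer runs
#'
#' Excludes any signature containing a run of one nucleotide strictly longer
#' than `config$max_homopolymer_run` (default: runs > 7 nt). A run of exactly
#' the threshold length is retained.
#'
#' @inheritParams filter_deterministic
#' @param config A [qc_config()].
#' @return The filtered count table, with an `"n_removed"` attribute.
#' @export
filter_homopolymer <- function(counts, config = qc_config()) {
  assert_count_table(counts)
  if (nrow(counts) == 0L) {
    attr(counts, "n_removed") <- 0L
    return(counts)
  }
  pat <- sprintf("([ACGT])\\1{%d,}", config$max_homopolymer_run)
  keep <- !grepl(pat, counts$signature)
  out <- counts[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' TPM-normalize a count table
#'
#' A signature's normalized value is its count divided by the sum of counts
#' of all signatures in that library, times the scale (10^6): tags per
#' million. Totals are computed over the record set passed in, which in the
#' standard pipeline is the post-sequence-QC set (ambiguous and homopolymer
#' signatures removed first, abundance filtering applied afterwards).
#'
#' @inheritParams filter_homopolymer
#' @return An `mpss_expr` object: list with `tpm` (numeric matrix, rows =
#'   signatures, columns = libraries), `totals` (named raw library totals)
#'   and `tpm_scale`.
#' @export
normalize_tpm <- function(counts, config = qc_config()) {
  assert_count_table(counts)
  mat <- as.matrix(counts[-1L])
  rownames(mat) <- counts$signature
  totals <- colSums(mat)
  if (nrow(mat) > 0L && any(totals == 0)) {
    stop("library with zero total counts: ",
         paste(names(totals)[totals == 0], collapse = ", "))
  }
  tpm <- if (nrow(mat) > 0L) {
    sweep(mat, 2L, totals, "/") * config$tpm_scale
  } else {
    matrix(numeric(0), 0L, ncol(mat), dimnames = list(NULL, colnames(mat)))
  }
  new_mpss_expr(tpm, totals, config$tpm_scale)
}

new_mpss_expr <- function(tpm, totals, tpm_scale) {
  structure(list(tpm = tpm, totals = totals, tpm_scale = tpm_scale),
            class = "mpss_expr")
}

#' @export
print.mpss_expr <- function(x, ...) {
  cat(sprintf("mpss_expr: %d signatures x %d libraries (%s)\n",
              nrow(x$tpm), ncol(x$tpm),
              paste(colnames(x$tpm), collapse = ", ")))
  cat("raw library totals:",
      paste(sprintf("%s=%d", names(x$totals), x$totals), collapse = " "), "\n")
  invisible(x)
}

#' Discard signatures below the abundance threshold in every library
#'
#' Retains signatures reaching at least `min_tpm` (default 4 TPM) in at
#' least one library. Library totals are *not* recomputed: normalization
#' keeps its original denominator.
#'
#' @param expr An `mpss_expr` from [normalize_tpm()].
#' @param config A [qc_config()].
#' @return The filtered `mpss_expr`, with an `"n_removed"` attribute.
#' @export
filter_min_abundance <- function(expr, config = qc_config()) {
  stopifnot(inherits(expr, "mpss_expr"))
  if (nrow(expr$tpm) == 0L) {
    attr(expr, "n_removed") <- 0L
    return(expr)
  }
  keep <- apply(expr$tpm >= config$min_tpm, 1L, any)
  out <- new_mpss_expr(expr$tpm[keep, , drop = FALSE], expr$totals,
                       expr$tpm_scale)
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Per-library summary of retained signatures
#'
#' For each library reports: `unique` (signatures expressed, TPM > 0),
#' `specific` (expressed in that library only), `common` (unique -
#' specific), and the number of signatures at or above each TPM bin
#' threshold. An `Average` row (rounded mean over libraries) and a `Total`
#' row (union over libraries: expressed anywhere, specific summed, bins on
#' the per-signature maximum) follow.
#'
#' @param expr A filtered `mpss_expr`.
#' @param bins Ascending TPM thresholds for the abundance bins.
#' @return A data.frame with one row per library plus `Average` and `Total`.
#' @export
summarize_libraries <- function(expr, bins = c(10, 100, 1000)) {
  stopifnot(inherits(expr, "mpss_expr"), !is.unsorted(bins))
  tpm <- expr$tpm
  libs <- colnames(tpm)
  expressed <- tpm > 0
  n_expressed_in <- rowSums(expressed)
  per_lib <- lapply(libs, function(l) {
    uniq <- sum(expressed[, l])
    spec <- sum(expressed[, l] & n_expressed_in == 1L)
    c(common = uniq - spec, specific = spec, unique = uniq,
      vapply(bins, function(b) sum(tpm[, l] >= b), numeric(1)))
  })
  tab <- as.data.frame(do.call(rbind, per_lib))
  bin_names <- paste0("tpm_ge_", bins)
  names(tab) <- c("common", "specific", "unique", bin_names)
  avg <- round(colMeans(tab))
  max_tpm <- if (nrow(tpm) > 0L) apply(tpm, 1L, max) else numeric(0)
  total_unique <- sum(n_expressed_in > 0L)
  total_specific <- sum(n_expressed_in == 1L)
  total <- c(common = total_unique - total_specific,
             specific = total_specific, unique = total_unique,
             vapply(bins, function(b) sum(max_tpm >= b), numeric(1)))
  out <- rbind(tab, Average = avg, Total = total)
  cbind(library = c(libs, "Average", "Total"), out, row.names = NULL)
}
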