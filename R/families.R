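#' Within- versus between-family signature mismatch distributions
#'
#' Exhaustive all-pairs Hamming comparison of the annotated signatures,
#' split into pairs whose members carry the same family label and pairs
#' from different families. These two distributions are what the mismatch
#' threshold is calibrated on: duplicated genes accumulate few 3' UTR
#' substitutions, unrelated genes many.
#'
#' @param signatures Character vector of equal-length signatures. Names (if
#'   present) are used as ids.
#' @param families Character/factor vector of family labels, parallel to
#'   `signatures`; only annotated signatures should be passed.
#' @return An object of class `mismatch_distribution`: data.frame with
#'   columns `mismatches` (0..L), `within`, `between` (pair counts), plus
#'   attributes `n_within` and `n_between`.
#' @export
mismatch_distributions <- function(signatures, families) {
  stopifnot(length(signatures) == length(families), length(signatures) >= 2L)
  families <- as.character(families)
  L <- nchar(signatures[1L])
  d <- hamming_matrix(signatures)
  same <- outer(families, families, "==")
  ut <- upper.tri(d)
  within <- d[ut & same]
  between <- d[ut & !same]
  if (length(between) == 0L) {
    warning("all signatures share one family label: ",
            "between-family distribution is empty")
  }
  vals <- 0:L
  out <- data.frame(mismatches = vals,
                    within = as.integer(tabulate(within + 1L, nbins = L + 1L)),
                    between = as.integer(tabulate(between + 1L, nbins = L + 1L)))
  structure(out, n_within = length(within), n_between = length(between),
            class = c("mismatch_distribution", "data.frame"))
}

#' Calibrate the family mismatch threshold
#'
#' For each candidate threshold `t` in `0..(L-1)` a 2x2 table is formed --
#' pairs at `<= t` versus `> t` mismatches, within-family versus
#' between-family -- and a one-sided Fisher exact p-value for enrichment of
#' within-family pairs at small distances is computed. The chosen
#' threshold is the largest significant `t` that also minimizes total
#' misclassification (within-pairs above `t` plus between-pairs at or
#' below `t`).
#'
#' @param dist A [mismatch_distributions()] result.
#' @param alpha Significance level for a candidate threshold. Default
#'   `1e-10`, the stringent level used throughout the pipeline.
#' @return List of class `threshold_calibration` with `table` (per-`t`
#'   classification counts, `p` and `misclassified`) and `threshold` (the
#'   chosen `t`).
#' @export
calibrate_threshold <- function(dist, alpha = 1e-10) {
  stopifnot(inherits(dist, "mismatch_distribution"))
  n_within <- attr(dist, "n_within")
  n_between <- attr(dist, "n_between")
  if (n_within == 0L || n_between == 0L) {
    stop("both within- and between-family pair sets must be non-empty")
  }
  L <- max(dist$mismatches)
  ts <- 0:(L - 1L)
  cum_w <- cumsum(dist$within)[ts + 1L]     # within pairs at <= t
  cum_b <- cumsum(dist$between)[ts + 1L]    # between pairs at <= t
  p <- vapply(seq_along(ts), function(i) {
    # one-sided (greater) Fisher exact: within-pairs enriched at <= t
    stats::fisher.test(matrix(c(cum_w[i], n_within - cum_w[i],
                                cum_b[i], n_between - cum_b[i]), 2L,
                              byrow = TRUE),
                       alternative = "greater")$p.value
  }, numeric(1))
  misclass <- (n_within - cum_w) + cum_b
  tab <- data.frame(t = ts, within_le_t = cum_w,
                    within_gt_t = n_within - cum_w,
                    between_le_t = cum_b,
                    between_gt_t = n_between - cum_b,
                    p = p, misclassified = misclass)
  sig <- which(p < alpha)
  if (length(sig) == 0L) {
    stop("no threshold separates within- from between-family pairs at ",
         "alpha = ", alpha)
  }
  best <- sig[misclass[sig] == min(misclass[sig])]
  structure(list(table = tab, threshold = ts[max(best)], alpha = alpha),
            class = "threshold_calibration")
}

#' @export
print.threshold_calibration <- function(x, ...) {
  cat(sprintf("mismatch threshold calibration: chosen t = %d (alpha = %g)\n",
              x$threshold, x$alpha))
  print(head(x$table, x$threshold + 3L))
  invisible(x)
}

#' Single-linkage gene families from signature distances
#'
#' Families are the connected components of the graph joining signature
#' pairs at Hamming distance at most `t`: the transitive closure of "looks
#' like a recent duplicate". Family ids are deterministic: each family is
#' named after its lexicographically smallest member, and the assignment is
#' invariant to input order.
#'
#' @param signatures Character vector of equal-length signatures (unique).
#' @param t Mismatch threshold (5 in the calibrated regime this package
#'   targets).
#' @return An object of class `family_assignment`: data.frame with columns
#'   `signature` and `family`, in input order.
#' @export
cluster_families <- function(signatures, t) {
  stopifnot(is.character(signatures), t >= 0)
  if (anyDuplicated(signatures)) stop("signatures must be unique")
  n <- length(signatures)
  if (n == 0L) {
    return(structure(data.frame(signature = character(0),
                                family = character(0)),
                     class = c("family_assignment", "data.frame")))
  }
  d <- hamming_matrix(signatures)
  adj <- d <= t
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  fam_name <- vapply(split(signatures, comp), min, character(1))
  structure(data.frame(signature = signatures,
                       family = unname(fam_name[as.character(comp)])),
            class = c("family_assignment", "data.frame"))
}

#' Family-size histogram
#'
#' Counts of families per size class, plus the largest family and the
#' number of families above a size cutoff.
#'
#' @param assignment A [cluster_families()] result (or any data.frame with
#'   `signature` and `family` columns).
#' @param large_cutoff Families strictly larger than this are counted as
#'   "large". Default 100.
#' @return List with `histogram` (data.frame `size`, `n_families`),
#'   `largest` and `n_large`.
#' @export
family_size_histogram <- function(assignment, large_cutoff = 100L) {
  stopifnot(is.data.frame(assignment),
            all(c("signature", "family") %in% names(assignment)))
  sizes <- table(assignment$family)
  if (length(sizes) == 0L) {
    return(list(histogram = data.frame(size = integer(0),
                                       n_families = integer(0)),
                largest = 0L, n_large = 0L))
  }
  hist_tab <- table(factor(as.integer(sizes)))
  list(histogram = data.frame(size = as.integer(names(hist_tab)),
                              n_families = as.integer(hist_tab)),
       largest = max(as.integer(sizes)),
       n_large = sum(as.integer(sizes) > large_cutoff))
}
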