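#' Within-family expression co-regulation score
#'
#' Pearson correlation of family members' expression profiles across the
#' culture conditions. The family statistic is the mean of all pairwise
#' correlations; its square (`r_squared`) is the reported co-regulation
#' score, and `1 - r_squared` is reported as `p_convention` -- a reporting
#' convention, not a significance test -- alongside a seeded
#' permutation p-value (condition labels shuffled independently per member,
#' counting shuffles whose mean pairwise r reaches the observed value).
#'
#' Members with constant profiles (zero variance) have no defined
#' correlation; their pairs are excluded with a warning, and an error is
#' raised if no pair remains.
#'
#' @param expr An `mpss_expr`.
#' @param members Signature ids (rownames of `expr$tpm`) of the family;
#'   at least 2.
#' @param n_perm Number of permutations for the null. Default 10000.
#' @param log_tpm Score `log2(TPM + 1)` profiles instead of raw TPM.
#'   Default `FALSE` (raw TPM).
#' @param stat `"mean_r_squared_of_mean"` (square of the mean pairwise r;
#'   default, reduces to the single pairwise r^2 for two-member families)
#'   or `"mean_of_r_squared"`.
#' @return List of class `family_correlation`: `size`, `mean_r`,
#'   `r_squared`, `p_convention`, `perm_p`, `n_pairs`.
#' @export
family_correlation <- function(expr, members, n_perm = 10000L,
                               log_tpm = FALSE,
                               stat = c("mean_r_squared_of_mean",
                                        "mean_of_r_squared")) {
  stat <- match.arg(stat)
  stopifnot(inherits(expr, "mpss_expr"), length(members) >= 2L)
  missing_ids <- setdiff(members, rownames(expr$tpm))
  if (length(missing_ids) > 0L) {
    stop("members absent from expression matrix: ",
         paste(missing_ids, collapse = ", "))
  }
  prof <- t(expr$tpm[members, , drop = FALSE])  # conditions x members
  if (nrow(prof) < 3L) stop("need at least 3 conditions for correlation")
  if (log_tpm) prof <- log2(prof + 1)
  constant <- apply(prof, 2L, function(x) stats::sd(x) == 0)
  if (any(constant)) {
    warning("constant profile(s) excluded: ",
            paste(members[constant], collapse = ", "))
    prof <- prof[, !constant, drop = FALSE]
  }
  if (ncol(prof) < 2L) stop("fewer than two non-constant members: ",
                            "co-regulation undefined")
  score <- function(p) {
    r <- cor(p)[upper.tri(diag(ncol(p)))]
    if (stat == "mean_r_squared_of_mean") mean(r) else mean(r^2)
  }
  obs_mean_r <- mean(cor(prof)[upper.tri(diag(ncol(prof)))])
  obs <- score(prof)
  r_squared <- if (stat == "mean_r_squared_of_mean") obs^2 else obs
  hits <- 0L
  for (b in seq_len(n_perm)) {
    perm <- apply(prof, 2L, sample)
    if (score(perm) >= obs) hits <- hits + 1L
  }
  structure(list(size = length(members), n_scored = ncol(prof),
                 mean_r = obs_mean_r, r_squared = r_squared,
                 p_convention = 1 - r_squared,
                 perm_p = (hits + 1L) / (n_perm + 1L),
                 n_pairs = choose(ncol(prof), 2L)),
            class = "family_correlation")
}

#' @export
print.family_correlation <- function(x, ...) {
  cat(sprintf(
    "family of %d (%d scored): mean r = %.3f, r^2 = %.3f, 1 - r^2 = %.3g, perm p = %.3g\n",
    x$size, x$n_scored, x$mean_r, x$r_squared, x$p_convention, x$perm_p))
  invisible(x)
}

#' Screen all families for co-regulated expression
#'
#' Computes [family_correlation()] for every family of at least `min_size`
#' members present in the expression matrix, sorted by `r_squared`
#' descending.
#'
#' @param expr An `mpss_expr`.
#' @param assignment A [cluster_families()] result (columns `signature`,
#'   `family`).
#' @param min_size Smallest family to score. Default 2.
#' @param n_perm Permutations per family. Default 1000 (raise for final
#'   reporting).
#' @param ... Passed on to [family_correlation()].
#' @return data.frame with columns `family`, `size`, `mean_r`, `r_squared`,
#'   `p_convention`, `perm_p`; zero rows if no family qualifies.
#' @export
coregulation_screen <- function(expr, assignment, min_size = 2L,
                                n_perm = 1000L, ...) {
  stopifnot(inherits(expr, "mpss_expr"), is.data.frame(assignment))
  present <- assignment[assignment$signature %in% rownames(expr$tpm), ]
  fams <- split(present$signature, present$family)
  fams <- fams[lengths(fams) >= min_size]
  if (length(fams) == 0L) {
    return(data.frame(family = character(0), size = integer(0),
                      mean_r = numeric(0), r_squared = numeric(0),
                      p_convention = numeric(0), perm_p = numeric(0)))
  }
  rows <- lapply(names(fams), function(f) {
    fc <- family_correlation(expr, fams[[f]], n_perm = n_perm, ...)
    data.frame(family = f, size = fc$size, mean_r = fc$mean_r,
               r_squared = fc$r_squared, p_convention = fc$p_convention,
               perm_p = fc$perm_p)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$r_squared), , drop = FALSE]
  rownames(out) <- NULL
  out
}
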