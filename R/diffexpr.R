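#' Differential-expression configuration
#'
#' @param strict_alpha Stringent significance threshold on the BH-adjusted
#'   p-value used to call differential expression. Default `1e-10`.
#' @param permissive_alpha Relaxed threshold used for the permissive calls
#'   reported alongside. Default 0.05.
#' @param control Label of the control library (nutrient-replete culture in
#'   the motivating design). Default `"F"`.
#' @param tpm_scale Per-library total used for the contingency tables.
#'   Default `1e6` (TPM scale).
#' @return An object of class `de_config`.
#' @export
de_config <- function(strict_alpha = 1e-10, permissive_alpha = 0.05,
                      control = "F", tpm_scale = 1e6) {
  stopifnot(strict_alpha > 0, strict_alpha < permissive_alpha,
            permissive_alpha < 1, tpm_scale > 0)
  structure(list(strict_alpha = strict_alpha,
                 permissive_alpha = permissive_alpha,
                 control = control, tpm_scale = tpm_scale),
            class = "de_config")
}

#' Two-sided Fisher's exact test on a tag-abundance pair
#'
#' Tests the 2x2 contingency table
#' \preformatted{  [ x_treatment, scale - x_treatment ]
#'   [ x_control,   scale - x_control   ]}
#' i.e. a signature's count against the rest of its library, for two
#' libraries each of fixed total `scale`. The two-sided p-value is the sum
#' of hypergeometric point probabilities (margins fixed) not exceeding the
#' observed table's probability, with a relative tolerance of 1e-7 for ties
#' (the standard minimum-likelihood convention). Equal counts return
#' exactly 1.
#'
#' Vectorized over `x_treatment` / `x_control`.
#'
#' @param x_treatment,x_control Non-negative integer counts on the common
#'   `scale` (TPM-scale integers in the standard pipeline).
#' @param scale Per-library total (row margin of the table).
#' @return Numeric vector of two-sided p-values in (0, 1].
#' @examples
#' fisher_2x2(5, 0, scale = 10)      # the hand-enumerable 20-observation table
#' fisher_2x2(4038, 2534, 1e6)       # deeply significant at TPM scale
#' @export
fisher_2x2 <- function(x_treatment, x_control, scale = 1e6) {
  stopifnot(length(scale) == 1L, scale >= 1)
  n <- max(length(x_treatment), length(x_control))
  x_treatment <- rep_len(x_treatment, n)
  x_control <- rep_len(x_control, n)
  if (any(x_treatment < 0 | x_control < 0 |
          x_treatment > scale | x_control > scale)) {
    stop("counts must lie in [0, scale]")
  }
  if (any(x_treatment != round(x_treatment) | x_control != round(x_control))) {
    stop("counts must be integers (round TPM values first)")
  }
  vapply(seq_len(n), function(i) {
    .fisher_2x2_one(x_treatment[i], x_control[i], scale)
  }, numeric(1))
}

.fisher_2x2_one <- function(a, c, scale) {
  if (a == c) return(1)
  k <- a + c                       # first-column margin
  support <- max(0, k - scale):min(k, scale)
  # log space: point probabilities of deeply significant TPM-scale tables
  # underflow double precision (the motivating data reach p ~ 1e-230)
  ld <- dhyper(support, m = scale, n = scale, k = k, log = TRUE)
  ld_obs <- dhyper(a, m = scale, n = scale, k = k, log = TRUE)
  keep <- ld <= ld_obs + log1p(1e-7)
  mx <- max(ld[keep])
  p <- exp(mx + log(sum(exp(ld[keep] - mx))))
  min(max(p, .Machine$double.xmin), 1)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH adjustment controlling the false discovery rate across a
#' family of simultaneous exact tests; values are returned in input order.
#'
#' @param p_values Numeric vector of raw p-values in (0, 1].
#' @return Adjusted p-values (same length and order).
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (any(!is.finite(p_values) | p_values <= 0 | p_values > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

#' Log2 fold change of an expression pair
#'
#' `log2(x_a / x_b)`. Zero (or missing) input has no defined fold change --
#' that is the exclusive/absent case, handled by presence calls rather than
#' a ratio -- and yields `NA`.
#'
#' @param x_a,x_b Positive expression values (TPM); vectorized.
#' @return Numeric vector of signed log2 ratios, `NA` where undefined.
#' @examples
#' log2_fold_change(4038, 2534)  # 0.67, printed as 0.7 at one decimal
#' @export
log2_fold_change <- function(x_a, x_b) {
  n <- max(length(x_a), length(x_b))
  x_a <- rep_len(as.numeric(x_a), n)
  x_b <- rep_len(as.numeric(x_b), n)
  out <- rep(NA_real_, n)
  ok <- !is.na(x_a) & !is.na(x_b) & x_a > 0 & x_b > 0
  out[ok] <- log2(x_a[ok] / x_b[ok])
  out
}

#' Pairwise differential expression across libraries
#'
#' For every treatment library versus the control and every retained
#' signature: TPM values are integerized (round half away from zero), the
#' two-sided Fisher exact p-value of the signature-vs-rest-of-library table
#' is computed with both library totals fixed at `tpm_scale`, and BH
#' adjustment is applied within each treatment-control comparison.
#' Direction is the sign of treatment minus control; significance is
#' `adj_p < strict_alpha`.
#'
#' @param expr A filtered `mpss_expr`.
#' @param config A [de_config()]; `config$control` must name a library.
#' @return A data.frame of class `mpss_de` with columns `signature`,
#'   `treatment`, `control`, `a` (treatment TPM integer), `c` (control TPM
#'   integer), `raw_p`, `adj_p`, `log2fc` (signed, `NA` when either side is
#'   zero), `direction` (`"up"`, `"down"`, `"none"`), `significant` and
#'   `permissive`.
#' @export
run_pairwise_de <- function(expr, config = de_config()) {
  stopifnot(inherits(expr, "mpss_expr"))
  libs <- colnames(expr$tpm)
  if (!(config$control %in% libs)) {
    stop("control library '", config$control, "' not present (libraries: ",
         paste(libs, collapse = ", "), ")")
  }
  treatments <- setdiff(libs, config$control)
  if (length(treatments) == 0L) stop("need at least one treatment library")
  ints <- round_half_up(expr$tpm)
  res <- lapply(treatments, function(tr) {
    a <- ints[, tr]
    c_ <- ints[, config$control]
    p <- fisher_2x2(a, c_, scale = config$tpm_scale)
    adj <- bh_adjust(p)
    data.frame(signature = rownames(expr$tpm), treatment = tr,
               control = config$control, a = a, c = c_,
               raw_p = p, adj_p = adj,
               log2fc = log2_fold_change(expr$tpm[, tr],
                                         expr$tpm[, config$control]),
               direction = ifelse(a > c_, "up", ifelse(a < c_, "down", "none")),
               row.names = NULL)
  })
  out <- do.call(rbind, res)
  out$significant <- out$adj_p < config$strict_alpha & out$direction != "none"
  out$permissive <- out$adj_p < config$permissive_alpha & out$direction != "none"
  class(out) <- c("mpss_de", "data.frame")
  out
}

#' Condition-exclusive signatures
#'
#' Signatures expressed (TPM > 0) in exactly one library of a filtered
#' matrix, interpreted as condition-specific transcription.
#'
#' @param expr A filtered `mpss_expr`.
#' @return Named list (one element per library) of signature ids exclusive
#'   to that library.
#' @export
find_exclusive <- function(expr) {
  stopifnot(inherits(expr, "mpss_expr"))
  expressed <- expr$tpm > 0
  one_lib <- rowSums(expressed) == 1L
  libs <- colnames(expr$tpm)
  out <- lapply(libs, function(l) rownames(expr$tpm)[one_lib & expressed[, l]])
  names(out) <- libs
  out
}

#' Summarize differential-expression calls
#'
#' Per-treatment up/down/total counts at the stringent threshold, plus the
#' seven membership regions of the three-set intersection diagram over the
#' treatments (which signatures are called in which combination of
#' comparisons).
#'
#' @param de An `mpss_de` table from [run_pairwise_de()].
#' @param config The [de_config()] used.
#' @return List with `per_treatment` (data.frame treatment/up/down/total),
#'   `regions` (data.frame region/count, one row per non-empty treatment
#'   combination), and `n_de` (signatures significant in at least one
#'   comparison).
#' @export
summarize_de <- function(de, config = de_config()) {
  stopifnot(inherits(de, "mpss_de"))
  sig <- de[de$significant, , drop = FALSE]
  treatments <- unique(de$treatment)
  per_tr <- do.call(rbind, lapply(treatments, function(tr) {
    s <- sig[sig$treatment == tr, ]
    data.frame(treatment = tr, up = sum(s$direction == "up"),
               down = sum(s$direction == "down"), total = nrow(s))
  }))
  membership <- tapply(sig$treatment, sig$signature, function(x) {
    paste(sort(unique(x)), collapse = "&")
  })
  region_counts <- table(factor(unlist(membership)))
  regions <- data.frame(region = names(region_counts),
                        count = as.integer(region_counts),
                        row.names = NULL)
  list(per_treatment = per_tr, regions = regions,
       n_de = length(unique(sig$signature)))
}
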