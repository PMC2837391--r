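#' Published per-signature fold-change examples
#'
#' The per-signature TPM pairs, printed log2 fold changes (with the
#' precision each was printed at) and, where given, printed p-values for
#' the methionine-cycle and photosynthesis signatures reported by the
#' Alexandrium tamarense MPSS study this package's methods follow
#' (nutrient-replete control versus the xenic culture, all down-regulated).
#'
#' @return data.frame with columns `label`, `control_tpm`, `treatment_tpm`,
#'   `printed_log2fc`, `digits`, `printed_p`.
#' @export
reported_fold_changes <- function() {
  read_tsv_commented(system.file("extdata", "reported_fold_changes.tsv",
                                 package = "mpssr", mustWork = TRUE))
}

#' Published within-family co-regulation table
#'
#' The ten gene families reported with significant within-family
#' co-regulated expression in the Alexandrium tamarense MPSS study
#' (family label, functional definition, r^2, p-value, member count).
#' Every printed p-value equals `1 - r_squared` at the printed precision,
#' which is the reporting convention [family_correlation()] mirrors in its
#' `p_convention` field.
#'
#' @return data.frame with columns `gene`, `definition`, `r_squared`,
#'   `p_value`, `size`.
#' @export
reported_family_correlations <- function() {
  read_tsv_commented(system.file("extdata",
                                 "reported_family_correlations.tsv",
                                 package = "mpssr", mustWork = TRUE))
}

#' Recompute the published worked examples
#'
#' For each published TPM pair, recomputes the log2 fold change from the
#' printed counts (larger value in the numerator, matching the positive
#' printed magnitudes), rounds it at the precision the value was printed
#' at, and evaluates the two-sided Fisher exact classification at the
#' stringent threshold; emits one pass/fail row per example.
#'
#' @param strict_alpha Significance threshold for the classification check.
#'   Default `1e-10`.
#' @return data.frame with the recomputed `log2fc`, `rounded`, `fisher_p`,
#'   and logical columns `log2fc_ok` (rounded value equals the printed one)
#'   and `significant_ok` (p below `strict_alpha`).
#' @export
transcribe_worked_examples <- function(strict_alpha = 1e-10) {
  ref <- reported_fold_changes()
  hi <- pmax(ref$control_tpm, ref$treatment_tpm)
  lo <- pmin(ref$control_tpm, ref$treatment_tpm)
  lfc <- log2_fold_change(hi, lo)
  rounded <- round(lfc, ref$digits)
  p <- fisher_2x2(ref$treatment_tpm, ref$control_tpm, scale = 1e6)
  data.frame(label = ref$label, control_tpm = ref$control_tpm,
             treatment_tpm = ref$treatment_tpm, log2fc = lfc,
             rounded = rounded, printed_log2fc = ref$printed_log2fc,
             log2fc_ok = rounded == ref$printed_log2fc,
             fisher_p = p, significant_ok = p < strict_alpha)
}
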