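#' End-to-end pipeline configuration
#'
#' Exactly one input mode: either `simulation` (a [simulation_config()];
#' the dataset is generated) or the three `*_path` arguments pointing at a
#' count table, unigene FASTA and annotation map on disk.
#'
#' @param simulation Optional [simulation_config()].
#' @param counts_path,unigenes_path,annotations_path File inputs (all three
#'   required together when `simulation` is `NULL`).
#' @param qc A [qc_config()].
#' @param de A [de_config()].
#' @param match A [match_config()].
#' @param family_threshold Mismatch threshold used for family clustering
#'   when calibration is disabled or fails. Default 5.
#' @param calibrate Calibrate the threshold from the annotated mismatch
#'   distributions before clustering. Default `TRUE`.
#' @param min_family_size Smallest family scored for co-regulation.
#' @param n_perm Permutations per family in the co-regulation screen.
#' @param bins TPM thresholds for the library summary.
#' @param seed Seed for the pipeline's own randomness (permutation nulls);
#'   dataset generation is seeded by `simulation$seed`.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = NULL, counts_path = NULL,
                            unigenes_path = NULL, annotations_path = NULL,
                            qc = qc_config(), de = de_config(),
                            match = match_config(), family_threshold = 5L,
                            calibrate = TRUE, min_family_size = 2L,
                            n_perm = 1000L, bins = c(10, 100, 1000),
                            seed = 1L) {
  from_files <- !is.null(counts_path)
  if (is.null(simulation) && !from_files) {
    stop("provide either a simulation config or input file paths")
  }
  if (!is.null(simulation) && from_files) {
    stop("provide exactly one input mode: simulation or files, not both")
  }
  if (from_files && (is.null(unigenes_path) || is.null(annotations_path))) {
    stop("file mode needs counts_path, unigenes_path and annotations_path")
  }
  if (!is.null(simulation)) stopifnot(inherits(simulation,
                                               "simulation_config"))
  structure(list(simulation = simulation, counts_path = counts_path,
                 unigenes_path = unigenes_path,
                 annotations_path = annotations_path, qc = qc, de = de,
                 match = match, family_threshold = as.integer(family_threshold),
                 calibrate = calibrate,
                 min_family_size = as.integer(min_family_size),
                 n_perm = as.integer(n_perm), bins = bins,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full MPSS analysis pipeline
#'
#' simulate/read -> sequence QC -> TPM normalization -> abundance filter ->
#' pairwise Fisher differential expression -> exclusivity -> anchored
#' signature-to-unigene mapping and annotation transfer -> mismatch
#' distributions, threshold calibration and family clustering ->
#' within-family co-regulation screen -> report assembly. Deterministic
#' given the configuration (including seeds).
#'
#' @param config A [pipeline_config()].
#' @param output_dir Optional directory; when given, all report tables are
#'   written there as TSV (with a provenance header) plus a human-readable
#'   `summary.txt`.
#' @return An object of class `mpss_report`; see the fields in the
#'   examples/vignette: `library_summary`, `de`, `de_summary`, `exclusive`,
#'   `matches`, `labels`, `mismatch_dist`, `calibration`, `families`,
#'   `family_histogram`, `coregulation`, `top_de`, `counters`, `provenance`.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  counters <- list()

  input <- with_stage("input", {
    if (!is.null(config$simulation)) {
      ds <- generate_dataset(config$simulation)
      list(counts = ds$counts, unigenes = ds$unigenes,
           annotations = ds$annotations, truth = ds$truth)
    } else {
      list(counts = read_counts(config$counts_path),
           unigenes = Biostrings::readDNAStringSet(config$unigenes_path),
           annotations = read_annotations(config$annotations_path),
           truth = NULL)
    }
  })
  counters$raw_signatures <- nrow(input$counts)

  expr <- with_stage("qc", {
    clean <- filter_deterministic(input$counts)
    counters$removed_ambiguous <- attr(clean, "n_removed")
    clean <- filter_homopolymer(clean, config$qc)
    counters$removed_homopolymer <- attr(clean, "n_removed")
    mat <- normalize_tpm(clean, config$qc)
    mat <- filter_min_abundance(mat, config$qc)
    counters$removed_low_abundance <- attr(mat, "n_removed")
    mat
  })
  counters$retained_signatures <- nrow(expr$tpm)
  library_summary <- with_stage("qc", summarize_libraries(expr, config$bins))

  de <- with_stage("diffexpr", run_pairwise_de(expr, config$de))
  de_summary <- with_stage("diffexpr", summarize_de(de, config$de))
  exclusive <- with_stage("diffexpr", find_exclusive(expr))

  retained <- rownames(expr$tpm)
  matches <- with_stage("mapping",
                        match_signatures(retained, input$unigenes,
                                         config$match))
  labels <- with_stage("mapping",
                       transfer_annotations(matches, input$annotations,
                                            signatures = retained))
  counters$matched_signatures <- sum(labels$label != "unknown")

  fam <- with_stage("families", {
    known <- labels$label != "unknown"
    dist <- calibration <- NULL
    t_used <- config$family_threshold
    if (config$calibrate && sum(known) >= 2L &&
        length(unique(labels$label[known])) >= 2L) {
      dist <- mismatch_distributions(labels$signature[known],
                                     labels$label[known])
      calibration <- tryCatch(calibrate_threshold(dist),
                              error = function(e) {
                                warning("threshold calibration failed (",
                                        conditionMessage(e),
                                        "); using configured threshold ",
                                        t_used)
                                NULL
                              })
      if (!is.null(calibration)) t_used <- calibration$threshold
    }
    assignment <- cluster_families(retained, t_used)
    list(dist = dist, calibration = calibration, threshold = t_used,
         assignment = assignment,
         histogram = family_size_histogram(assignment))
  })

  coreg <- with_stage("coregulation", {
    set.seed(config$seed + 1L)  # sub-stream for the permutation nulls
    coregulation_screen(expr, fam$assignment,
                        min_size = config$min_family_size,
                        n_perm = config$n_perm)
  })

  sig <- de[de$significant, , drop = FALSE]
  top_de <- with_stage("report", {
    out <- merge(sig, labels, by = "signature", all.x = TRUE, sort = FALSE)
    out <- out[order(out$adj_p),
               c("signature", "label", "treatment", "log2fc", "a", "c",
                 "raw_p", "adj_p", "direction")]
    rownames(out) <- NULL
    out
  })

  provenance <- list(config_hash = config_hash(config), seed = config$seed,
                     package_version = as.character(
                       utils::packageVersion("mpssr")),
                     timestamp = NA_character_)  # kept NA: reports byte-stable

  report <- structure(list(library_summary = library_summary, de = de,
                           de_summary = de_summary, exclusive = exclusive,
                           matches = matches, labels = labels,
                           mismatch_dist = fam$dist,
                           calibration = fam$calibration,
                           family_threshold = fam$threshold,
                           families = fam$assignment,
                           family_histogram = fam$histogram,
                           coregulation = coreg, top_de = top_de,
                           counters = counters, provenance = provenance,
                           truth = input$truth),
                      class = "mpss_report")
  if (!is.null(output_dir)) write_report(report, output_dir)
  report
}

#' Write a pipeline report as a TSV set plus a readable summary
#'
#' @param report An `mpss_report` from [run_pipeline()].
#' @param directory Output directory (created if absent).
#' @return Invisibly, the written file paths.
#' @export
write_report <- function(report, directory) {
  stopifnot(inherits(report, "mpss_report"))
  if (!dir.exists(directory)) dir.create(directory, recursive = TRUE)
  h <- report$provenance$config_hash
  w <- function(df, file) {
    p <- file.path(directory, file)
    write_tsv_commented(df, p, h)
    p
  }
  paths <- c(
    w(report$library_summary, "library_summary.tsv"),
    w(as.data.frame(report$de), "de_table.tsv"),
    w(report$de_summary$regions, "de_regions.tsv"),
    w(data.frame(library = rep(names(report$exclusive),
                               lengths(report$exclusive)),
                 signature = unlist(report$exclusive, use.names = FALSE)),
      "exclusive_signatures.tsv"),
    w(report$matches, "matches.tsv"),
    w(as.data.frame(report$families), "families.tsv"),
    w(report$family_histogram$histogram, "family_histogram.tsv"),
    w(report$coregulation, "coregulation.tsv"),
    w(report$top_de, "top_de.tsv"))
  sum_path <- file.path(directory, "summary.txt")
  con <- file(sum_path, "w")
  writeLines(c(sprintf("mpssr pipeline report (config %s, seed %d)", h,
                       report$provenance$seed),
               sprintf("signatures: %d raw, %d retained",
                       report$counters$raw_signatures,
                       report$counters$retained_signatures),
               sprintf("removed: %d ambiguous, %d homopolymer, %d sub-threshold",
                       report$counters$removed_ambiguous,
                       report$counters$removed_homopolymer,
                       report$counters$removed_low_abundance),
               sprintf("DE signatures (strict): %d", report$de_summary$n_de),
               sprintf("family threshold: %d mismatches; %d families, largest %d",
                       report$family_threshold,
                       length(unique(report$families$family)),
                       report$family_histogram$largest)), con)
  close(con)
  invisible(c(paths, sum_path))
}

#' @export
print.mpss_report <- function(x, ...) {
  cat(sprintf("mpss_report: %d retained signatures, %d DE (strict), %d families (t = %d)\n",
              x$counters$retained_signatures, x$de_summary$n_de,
              length(unique(x$families$family)), x$family_threshold))
  cat("library summary:\n")
  print(x$library_summary)
  invisible(x)
}
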