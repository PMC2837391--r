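write_tsv_commented <- function(df, path, hash = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(hash)) writeLines(paste0("# mpssr config=", hash), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv_commented <- function(path) {
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  read.delim(path, sep = "\t", comment.char = "#",
             stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write a synthetic dataset to disk
#'
#' Emits `counts.tsv`, `unigenes.fasta`, `annotations.tsv` and
#' `ground_truth.tsv` into `directory`; all tables carry a header comment
#' with the generating configuration hash, and round-trip losslessly
#' through the package readers.
#'
#' @param dataset An `mpss_dataset` from [generate_dataset()].
#' @param directory Output directory (created if absent).
#' @return Invisibly, the named vector of written paths.
#' @export
write_dataset <- function(dataset, directory) {
  stopifnot(inherits(dataset, "mpss_dataset"))
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create directory '", directory, "'")
  }
  hash <- config_hash(dataset$config)
  paths <- c(counts = file.path(directory, "counts.tsv"),
             unigenes = file.path(directory, "unigenes.fasta"),
             annotations = file.path(directory, "annotations.tsv"),
             truth = file.path(directory, "ground_truth.tsv"))
  tryCatch({
    write_tsv_commented(dataset$counts, paths[["counts"]], hash)
    Biostrings::writeXStringSet(dataset$unigenes, paths[["unigenes"]],
                                width = 70L)
    write_tsv_commented(dataset$annotations, paths[["annotations"]], hash)
    write_tsv_commented(dataset$truth, paths[["truth"]], hash)
  }, error = function(e) {
    stop("failed writing dataset under '", directory, "': ",
         conditionMessage(e))
  })
  invisible(paths)
}

#' Read a signature count table
#'
#' Expects a TSV with a `signature` column followed by one integer column
#' per library; `#` lines are ignored.
#'
#' @param path File path.
#' @return A count table data.frame.
#' @export
read_counts <- function(path) {
  out <- read_tsv_commented(path)
  if (nrow(out) == 0L) {
    # header-only file: fix column types that read.delim cannot infer
    out[[1L]] <- as.character(out[[1L]])
    out[-1L] <- lapply(out[-1L], as.integer)
  }
  assert_count_table(out)
  out
}

#' Read a unigene-to-label annotation map
#'
#' @param path TSV whose first two columns are unigene id and label.
#' @return data.frame.
#' @export
read_annotations <- function(path) {
  out <- read_tsv_commented(path)
  if (ncol(out) < 2L) stop("annotation table needs at least two columns")
  out
}

#' Read a generator ground-truth table
#'
#' @param path TSV written by [write_dataset()].
#' @return data.frame.
#' @export
read_ground_truth <- function(path) {
  read_tsv_commented(path)
}

#' Read back a dataset directory written by [write_dataset()]
#'
#' @param directory Directory containing the four dataset files.
#' @return List with `counts`, `unigenes`, `annotations`, `truth`.
#' @export
read_dataset <- function(directory) {
  list(counts = read_counts(file.path(directory, "counts.tsv")),
       unigenes = Biostrings::readDNAStringSet(
         file.path(directory, "unigenes.fasta")),
       annotations = read_annotations(file.path(directory,
                                                "annotations.tsv")),
       truth = read_ground_truth(file.path(directory, "ground_truth.tsv")))
}
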