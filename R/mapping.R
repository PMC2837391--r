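#' Signature-to-unigene matching configuration
#'
#' MPSS tags begin at a DpnII restriction site (GATC), so a valid hit
#' requires an exact anchor match; substitutions are tolerated only in the
#' tail. The matcher is an exhaustive anchored scan: at every GATC site of
#' every unigene (both strands by default) the full signature is compared
#' against the window starting at the site. For fixed-length tags this is
#' exact and deterministic, and strictly dominates heuristic local-alignment
#' searches for the same validation rules.
#'
#' @param max_mismatches Maximum tail mismatches for a reportable hit.
#'   Default 3.
#' @param signature_length Full tag length `L` including the 4-nt anchor.
#'   Default 21.
#' @param search_strands `"both"` or `"forward"`.
#' @return An object of class `match_config`.
#' @export
match_config <- function(max_mismatches = 3L, signature_length = 21L,
                         search_strands = c("both", "forward")) {
  search_strands <- match.arg(search_strands)
  stopifnot(max_mismatches >= 0, max_mismatches < signature_length - 4L)
  structure(list(max_mismatches = as.integer(max_mismatches),
                 signature_length = as.integer(signature_length),
                 search_strands = search_strands),
            class = "match_config")
}

#' Locate DpnII (GATC) anchor sites on both strands
#'
#' All occurrences of GATC on the forward strand and on the reverse
#' complement, each reported 0-based in its own strand's coordinates.
#' GATC is its own reverse complement, so sites mirror across strands.
#'
#' @param unigene A single sequence (character scalar or
#'   `Biostrings::DNAString`); ambiguity codes never match the anchor.
#' @return data.frame with columns `strand` (`"+"`/`"-"`) and `offset`.
#' @export
find_anchor_sites <- function(unigene) {
  s <- toupper(as.character(unigene))
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  one <- function(x, strand) {
    hits <- gregexpr(DPNII_SITE, x, fixed = TRUE)[[1L]]
    if (hits[1L] == -1L) return(NULL)
    data.frame(strand = strand, offset = as.integer(hits) - 1L)
  }
  out <- rbind(one(s, "+"), one(rc, "-"))
  if (is.null(out)) {
    out <- data.frame(strand = character(0), offset = integer(0))
  }
  out
}

# index of all full-length candidate windows downstream of anchor sites;
# built once per unigene set and shared across signatures
anchor_windows <- function(unigenes, config) {
  L <- config$signature_length
  ids <- names(unigenes)
  seqs <- toupper(as.character(unigenes))
  if (length(seqs) == 0L) stop("unigene set is empty")
  names(seqs) <- if (is.null(ids)) paste0("unigene_", seq_along(seqs)) else ids
  strands <- if (config$search_strands == "both") c("+", "-") else "+"
  rows <- vector("list", length(seqs) * length(strands))
  k <- 0L
  for (i in seq_along(seqs)) {
    for (st in strands) {
      x <- if (st == "+") seqs[[i]] else
        as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(seqs[[i]])))
      anch <- gregexpr(DPNII_SITE, x, fixed = TRUE)[[1L]]
      if (anch[1L] == -1L) next
      anch <- as.integer(anch)                 # 1-based start of GATC
      anch <- anch[anch + L - 1L <= nchar(x)]  # need L bases from the anchor
      if (length(anch) == 0L) next
      k <- k + 1L
      rows[[k]] <- data.frame(unigene = names(seqs)[i], strand = st,
                              offset = anch - 1L,
                              window = substring(x, anch, anch + L - 1L))
    }
  }
  if (k == 0L) {
    return(data.frame(unigene = character(0), strand = character(0),
                      offset = integer(0), window = character(0)))
  }
  do.call(rbind, rows[seq_len(k)])
}

empty_match <- function() {
  data.frame(signature = character(0), unigene = character(0),
             strand = character(0), offset = integer(0),
             mismatches = integer(0), identity = numeric(0),
             rank = integer(0))
}

#' Match signatures against a unigene set
#'
#' At every anchor site with at least `L - 4` following bases, each
#' signature is compared to the unigene window by Hamming distance
#' (the anchor matches exactly by construction of the site index); hits
#' with at most `max_mismatches` are kept. Within each signature, hits are
#' ranked by identity (descending), ties broken by unigene id
#' (lexicographic) and then by the 3'-most offset (MPSS tags derive from
#' the 3'-most DpnII site).
#'
#' @param signatures Character vector of tag sequences, each beginning with
#'   GATC and of length `config$signature_length`.
#' @param unigenes Named character vector or `Biostrings::DNAStringSet`.
#' @param config A [match_config()].
#' @return data.frame with columns `signature`, `unigene`, `strand`,
#'   `offset` (0-based, on the hit strand), `mismatches`, `identity` and
#'   per-signature `rank` (1 = best hit).
#' @export
match_signatures <- function(signatures, unigenes, config = match_config()) {
  signatures <- toupper(as.character(signatures))
  L <- config$signature_length
  bad_len <- nchar(signatures) != L
  if (any(bad_len)) {
    stop("signature length != configured L = ", L, ": ",
         paste(head(signatures[bad_len], 3L), collapse = ", "))
  }
  bad_anchor <- substr(signatures, 1L, 4L) != DPNII_SITE
  if (any(bad_anchor)) {
    stop("signature(s) lacking the ", DPNII_SITE, " anchor prefix: ",
         paste(head(signatures[bad_anchor], 3L), collapse = ", "))
  }
  win <- anchor_windows(unigenes, config)
  if (length(signatures) == 0L || nrow(win) == 0L) return(empty_match())
  mm <- .hamming_mat_cpp(signatures, win$window)  # signatures x windows
  hit <- which(mm <= config$max_mismatches, arr.ind = TRUE)
  if (nrow(hit) == 0L) return(empty_match())
  out <- data.frame(signature = signatures[hit[, 1L]],
                    win[hit[, 2L], , drop = FALSE],
                    mismatches = mm[hit], row.names = NULL)
  out$window <- NULL
  out$identity <- (L - out$mismatches) / L
  ord <- order(out$signature, -out$identity, out$unigene, -out$offset)
  out <- out[ord, , drop = FALSE]
  out$rank <- as.integer(ave(seq_len(nrow(out)), out$signature,
                             FUN = seq_along))
  rownames(out) <- NULL
  out
}

#' Match a single signature
#'
#' Convenience wrapper around [match_signatures()] for one tag.
#'
#' @inheritParams match_signatures
#' @param signature One tag sequence (GATC-prefixed).
#' @return See [match_signatures()].
#' @export
match_signature <- function(signature, unigenes, config = match_config()) {
  stopifnot(length(signature) == 1L)
  match_signatures(signature, unigenes, config)
}

#' Transfer unigene annotations to signatures
#'
#' Each signature inherits the label of its rank-1 (maximum-identity) hit;
#' signatures without hits, or whose best unigene lacks an annotation, are
#' labelled `"unknown"` (the latter with a warning).
#'
#' @param matches A match table from [match_signatures()].
#' @param annotations data.frame whose first two columns are unigene id and
#'   label.
#' @param signatures Optional full set of signature sequences so unmatched
#'   signatures appear in the output (in the given order).
#' @return data.frame with columns `signature` and `label`.
#' @export
transfer_annotations <- function(matches, annotations, signatures = NULL) {
  stopifnot(is.data.frame(annotations), ncol(annotations) >= 2L)
  ann <- stats::setNames(as.character(annotations[[2L]]),
                         as.character(annotations[[1L]]))
  best <- matches[matches$rank == 1L, , drop = FALSE]
  lab <- ann[best$unigene]
  missing_ann <- is.na(lab)
  if (any(missing_ann)) {
    warning("no annotation for matched unigene(s): ",
            paste(unique(best$unigene[missing_ann]), collapse = ", "))
    lab[missing_ann] <- "unknown"
  }
  out <- data.frame(signature = best$signature, label = unname(lab))
  if (!is.null(signatures)) {
    unmatched <- setdiff(signatures, out$signature)
    if (length(unmatched) > 0L) {
      out <- rbind(out, data.frame(signature = unmatched, label = "unknown"))
    }
    out <- out[match(signatures, out$signature), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}
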