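#' Configuration for the synthetic MPSS library generator
#'
#' Defines the study conditions a generated dataset emulates: four
#' libraries (nutrient-replete control F, N-depleted, P-depleted, xenic X)
#' of fixed sequencing depth; a heavy-tailed baseline abundance law; gene
#' families whose member signatures co-segregate within a small mismatch
#' radius while unrelated signatures stay far apart; per-treatment planted
#' fold changes; condition-exclusive transcripts; and sequencing artifacts
#' (ambiguous bases, homopolymer runs, sub-threshold stray tags).
#'
#' @param seed Integer seed; all randomness in [generate_dataset()] flows
#'   from it.
#' @param n_genes Number of planted genes. Default 2000 (desk-scale run in
#'   the same statistical regime as a full MPSS experiment).
#' @param n_families Families drawn before reconciling sizes to `n_genes`.
#' @param family_size_mean Mean of the geometric family-size law
#'   (sizes are `1 + Geom`).
#' @param signature_length Tag length including the GATC anchor. Default 21.
#' @param within_family_max_mm Maximum pairwise mismatches within a family.
#'   Default 5.
#' @param between_family_min_mm Minimum pairwise mismatches between
#'   families. Default 8.
#' @param condition_labels Ordered library labels; first is the control.
#' @param library_depth Reads per library. Default `1e6`.
#' @param de_fraction Fraction of genes planted as differentially expressed
#'   per treatment. Default 0.1.
#' @param log2fc_range Magnitude range of planted log2 fold changes (sign
#'   is symmetric). Default `c(0.5, 3.5)`, the span of fold changes a tag
#'   experiment at this depth reports.
#' @param exclusive_counts Named per-condition counts of condition-exclusive
#'   genes. Default `c(F = 18, N = 2, P = 12, X = 487)`.
#' @param baseline_meanlog,baseline_sdlog Log-normal baseline abundance law
#'   (TPM-scale intensities). Defaults give a median near 125 TPM with a
#'   heavy upper tail.
#' @param baseline_floor,baseline_cap Clamp for non-exclusive baselines
#'   (default 10 and 15000 TPM): the floor keeps every planted gene
#'   reliably detected at the configured depth, the cap keeps single
#'   transcripts from dominating a library.
#' @param exclusive_floor,exclusive_cap Clamp for exclusive genes' own-
#'   condition abundance (default 50 and 500 TPM): exclusivity ground
#'   truth stays recoverable because a 50 TPM transcript essentially never
#'   samples below the 4 TPM retention threshold.
#' @param de_baseline_range Only genes with baseline in this TPM range are
#'   eligible for planted fold changes. Default `c(40, 5000)`.
#' @param n_ballast Number of balancing transcripts that absorb
#'   per-condition intensity imbalance so planted expected-TPM ratios equal
#'   planted fold changes exactly (tag counting is compositional). Default 20.
#' @param n_ambiguous,n_homopolymer,n_background Artifact signature counts:
#'   ambiguous-base tags, homopolymer-run tags, and sub-threshold stray
#'   background tags.
#' @param background_count_range Expected per-library read count range for
#'   each background tag. Default `c(0.01, 0.06)` (stray singleton-level
#'   tags, essentially always removed by the 4 TPM filter).
#' @param body_length Unigene length upstream of the 3' UTR. Default 200.
#' @param utr_length Simulated 3' UTR length (signature plus downstream
#'   sequence). Default 100.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(seed,
                              n_genes = 2000L,
                              n_families = 800L,
                              family_size_mean = 2.5,
                              signature_length = 21L,
                              within_family_max_mm = 5L,
                              between_family_min_mm = 8L,
                              condition_labels = c("F", "N", "P", "X"),
                              library_depth = 1e6,
                              de_fraction = 0.1,
                              log2fc_range = c(0.5, 3.5),
                              exclusive_counts = c(F = 18L, N = 2L,
                                                   P = 12L, X = 487L),
                              baseline_meanlog = log(125),
                              baseline_sdlog = 1.6,
                              baseline_floor = 10,
                              baseline_cap = 15000,
                              exclusive_floor = 50,
                              exclusive_cap = 500,
                              de_baseline_range = c(40, 5000),
                              n_ballast = 20L,
                              n_ambiguous = 100L,
                              n_homopolymer = 50L,
                              n_background = 3000L,
                              background_count_range = c(0.01, 0.06),
                              body_length = 200L,
                              utr_length = 100L) {
  if (missing(seed)) stop("seed is required")
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              n_families = as.integer(n_families),
              family_size_mean = family_size_mean,
              signature_length = as.integer(signature_length),
              within_family_max_mm = as.integer(within_family_max_mm),
              between_family_min_mm = as.integer(between_family_min_mm),
              condition_labels = condition_labels,
              library_depth = library_depth, de_fraction = de_fraction,
              log2fc_range = log2fc_range,
              exclusive_counts = exclusive_counts,
              baseline_meanlog = baseline_meanlog,
              baseline_sdlog = baseline_sdlog,
              baseline_floor = baseline_floor, baseline_cap = baseline_cap,
              exclusive_floor = exclusive_floor,
              exclusive_cap = exclusive_cap,
              de_baseline_range = de_baseline_range,
              n_ballast = as.integer(n_ballast),
              n_ambiguous = as.integer(n_ambiguous),
              n_homopolymer = as.integer(n_homopolymer),
              n_background = as.integer(n_background),
              background_count_range = background_count_range,
              body_length = as.integer(body_length),
              utr_length = as.integer(utr_length))
  validate_simulation_config(structure(cfg, class = "simulation_config"))
}

validate_simulation_config <- function(cfg) {
  fail <- function(...) stop("invalid simulation_config: ", ..., call. = FALSE)
  if (cfg$library_depth <= 0) fail("library_depth must be > 0")
  if (cfg$de_fraction < 0 || cfg$de_fraction > 1) {
    fail("de_fraction must lie in [0, 1]")
  }
  if (cfg$within_family_max_mm >= cfg$between_family_min_mm) {
    fail("within_family_max_mm (", cfg$within_family_max_mm,
         ") must be < between_family_min_mm (", cfg$between_family_min_mm, ")")
  }
  if (cfg$signature_length <= 4L) fail("signature_length must exceed the ",
                                       "4-nt anchor")
  if (cfg$between_family_min_mm > cfg$signature_length - 4L) {
    fail("between_family_min_mm exceeds the signature tail length")
  }
  if (length(cfg$condition_labels) < 2L) fail("need at least 2 conditions")
  if (anyDuplicated(cfg$condition_labels)) fail("duplicate condition labels")
  if (!all(names(cfg$exclusive_counts) %in% cfg$condition_labels)) {
    fail("exclusive_counts names must be condition labels")
  }
  if (sum(cfg$exclusive_counts) > cfg$n_genes) {
    fail("n_genes (", cfg$n_genes, ") < sum of exclusive_counts (",
         sum(cfg$exclusive_counts), ")")
  }
  if (cfg$utr_length < cfg$signature_length) {
    fail("utr_length must be at least signature_length")
  }
  cfg
}

# geometric family sizes reconciled to exactly n_genes
draw_family_sizes <- function(cfg) {
  p <- 1 / cfg$family_size_mean
  sizes <- 1L + rgeom(cfg$n_families, p)
  cum <- cumsum(sizes)
  keep <- cum <= cfg$n_genes
  sizes <- sizes[keep]
  left <- cfg$n_genes - sum(sizes)
  if (left > 0L) {
    # pad with one partial family, then singletons
    nxt <- min(left, 1L + rgeom(1L, p))
    sizes <- c(sizes, nxt, rep(1L, left - nxt))
  }
  sizes
}

# random tails with no internal GATC (the full signature is GATC + tail; a
# GATC-free tail guarantees the planted anchor is unique within the tag)
random_clean_tails <- function(n, len) {
  out <- character(0)
  while (length(out) < n) {
    cand <- random_dna(n - length(out) + 8L, len)
    out <- c(out, cand[!has_internal_anchor(cand)])
  }
  out[seq_len(n)]
}

#' Plant gene-family signature sets with controlled mismatch structure
#'
#' Builds one signature set per requested family size such that all
#' pairwise Hamming distances within a set are at most
#' `within_family_max_mm`, all distances across sets are at least
#' `between_family_min_mm`, and every signature starts with the GATC anchor
#' (never mutated) and contains no spurious internal GATC. Within-family
#' variation is confined to a per-family random set of
#' `within_family_max_mm` tail positions; between-family separation is
#' enforced by greedy rejection of realized signatures.
#'
#' Uses the session RNG (callers seed it; [generate_dataset()] does so from
#' its config).
#'
#' @param family_sizes Integer vector of member counts, all at least 1.
#' @param config A [simulation_config()].
#' @param max_tries Candidate draws allowed per placed signature before the
#'   geometry is declared infeasible.
#' @return List of character vectors (one per family) of full signatures.
#' @export
plant_family_signatures <- function(family_sizes, config,
                                    max_tries = 200000L) {
  stopifnot(all(family_sizes >= 1L))
  L <- config$signature_length
  tail_len <- L - 4L
  wm <- config$within_family_max_mm
  bm <- config$between_family_min_mm
  if (any(family_sizes > 1L) && wm < 1L) {
    stop("infeasible geometry: multi-member families need ",
         "within_family_max_mm >= 1")
  }
  # members differ from the family centroid at up to floor(wm/2) positions
  # (minimum 1) of a per-family variable set of wm positions, so pairwise
  # within-family distances stay <= wm by construction
  k_max <- max(1L, min(wm, tail_len) %/% 2L)
  n_var <- min(wm, tail_len)
  capacity <- 1L + sum(choose(n_var, seq_len(k_max)) * 3^seq_len(k_max))
  if (any(family_sizes > capacity)) {
    stop("infeasible geometry: family size ", max(family_sizes),
         " exceeds the ", capacity, " distinct signatures reachable ",
         "within the mismatch budget")
  }

  pool <- character(0)
  sets <- vector("list", length(family_sizes))
  tries_left <- max_tries

  draw_centroid <- function() {
    repeat {
      batch <- random_clean_tails(64L, tail_len)
      ok <- .min_dist_ok_cpp(batch, pool, bm)
      tries_left <<- tries_left - length(batch)
      if (any(ok)) return(batch[which(ok)[1L]])
      if (tries_left <= 0L) {
        stop("infeasible geometry: could not place a signature at ",
             "between_family_min_mm = ", bm, " within the draw budget")
      }
    }
  }
  mutate_tail <- function(centroid, var_pos) {
    k <- sample(k_max, 1L)
    pos <- var_pos[sample.int(length(var_pos), k)]
    s <- strsplit(centroid, "", fixed = TRUE)[[1L]]
    s[pos] <- vapply(s[pos], function(ch) {
      sample(setdiff(DNA_BASES, ch), 1L)
    }, character(1))
    paste(s, collapse = "")
  }
  build_family <- function(size) {
    # one attempt: fresh centroid, then rejection-sampled mutants; returns
    # NULL if a mutant cannot be placed (caller restarts with new centroid)
    centroid <- draw_centroid()
    members <- centroid
    if (size == 1L) return(members)
    var_pos <- sample(tail_len, n_var)
    for (j in seq_len(size - 1L)) {
      placed <- FALSE
      for (b in seq_len(150L)) {
        cand <- vapply(seq_len(16L), function(z) mutate_tail(centroid, var_pos),
                       character(1))
        ok <- !has_internal_anchor(cand) & !(cand %in% members) &
          .min_dist_ok_cpp(cand, pool, bm)
        if (any(ok)) {
          members <- c(members, cand[which(ok)[1L]])
          placed <- TRUE
          break
        }
      }
      if (!placed) return(NULL)
    }
    members
  }

  # large families first: mutants are easiest to place while the pool is
  # sparse; output order follows the requested sizes
  ord <- order(family_sizes, decreasing = TRUE)
  for (i in ord) {
    size <- family_sizes[i]
    members <- NULL
    for (attempt in seq_len(50L)) {
      members <- build_family(size)
      if (!is.null(members)) break
    }
    if (is.null(members)) {
      stop("infeasible geometry: could not build a family of ", size,
           " members at within <= ", wm, ", between >= ", bm)
    }
    pool <- c(pool, members)
    sets[[i]] <- paste0(DPNII_SITE, members)
  }
  sets
}

# GATC-free random sequence of given length
random_anchor_free <- function(len) {
  repeat {
    s <- random_dna(1L, len)
    if (!has_internal_anchor(s)) return(s)
  }
}

# unigene embedding its signature: body + signature + 3' remainder, with the
# signature's own anchor as the single GATC in the whole sequence
build_unigene <- function(signature, body_length, utr_length) {
  L <- nchar(signature)
  down_len <- utr_length - L
  body <- random_anchor_free(body_length)
  repeat {
    down <- if (down_len > 0L) random_anchor_free(down_len) else ""
    uni <- paste0(body, signature, down)
    n_sites <- length(gregexpr(DPNII_SITE, uni, fixed = TRUE)[[1L]])
    if (n_sites == 1L) return(uni)
  }
}

#' Generate a ground-truthed synthetic MPSS dataset
#'
#' Draws gene families with planted signature mismatch structure, baseline
#' abundances, per-treatment fold changes, condition-exclusive transcripts,
#' balancing (ballast) transcripts that keep per-library composition
#' constant, and artifact signatures; then samples each library as one
#' multinomial of `library_depth` reads over all signatures. Deterministic
#' for a fixed `config$seed`.
#'
#' Expected TPM recorded in the ground truth is the planted intensity
#' rescaled by the clean-signature mass, i.e. exactly what the QC +
#' normalization pipeline estimates in expectation; planted expected-TPM
#' ratios between conditions equal the planted fold changes.
#'
#' @param config A [simulation_config()].
#' @return An object of class `mpss_dataset`: list with `counts` (count
#'   table), `unigenes` (`Biostrings::DNAStringSet`), `annotations`
#'   (unigene id to family label), `truth` (per-gene ground truth) and
#'   `config`.
#' @export
generate_dataset <- function(config) {
  validate_simulation_config(config)
  set.seed(config$seed)
  conds <- config$condition_labels
  control <- conds[1L]
  treatments <- conds[-1L]

  ## family structure and signatures (ballast transcripts are singletons)
  sizes <- draw_family_sizes(config)
  all_sizes <- c(sizes, rep(1L, config$n_ballast))
  sets <- plant_family_signatures(all_sizes, config)
  fam_ids <- sprintf("FAM%04d", seq_along(all_sizes))
  n_genes <- config$n_genes
  n_total <- n_genes + config$n_ballast
  gene_tab <- data.frame(
    gene = sprintf("g%05d", seq_len(n_total)),
    unigene = sprintf("u%05d", seq_len(n_total)),
    signature = as.character(unlist(sets)),
    family = rep(fam_ids, all_sizes),
    role = rep(c("gene", "ballast"),
               c(n_genes, config$n_ballast)))

  ## exclusivity assignment (genes only, disjoint across conditions)
  excl <- rep(NA_character_, n_total)
  excl_counts <- config$exclusive_counts[config$exclusive_counts > 0]
  if (length(excl_counts) > 0L) {
    picked <- sample(n_genes, sum(excl_counts))
    excl[picked] <- rep(names(excl_counts), excl_counts)
  }
  gene_tab$exclusive_to <- excl

  ## baseline intensities (TPM-scale arbitrary units)
  is_excl <- !is.na(excl)
  is_ballast <- gene_tab$role == "ballast"
  baseline <- numeric(n_total)
  n_ord <- sum(!is_excl & !is_ballast)
  baseline[!is_excl & !is_ballast] <-
    pmin(pmax(rlnorm(n_ord, config$baseline_meanlog, config$baseline_sdlog),
              config$baseline_floor), config$baseline_cap)
  baseline[is_excl] <-
    pmin(pmax(rlnorm(sum(is_excl), log(100), 0.7),
              config$exclusive_floor), config$exclusive_cap)
  gene_tab$baseline <- baseline

  ## planted differential expression per treatment
  n_de <- round(config$de_fraction * n_genes)
  eligible <- which(!is_excl & !is_ballast &
                      baseline >= config$de_baseline_range[1L] &
                      baseline <= config$de_baseline_range[2L])
  lfc <- matrix(0, n_total, length(treatments),
                dimnames = list(NULL, treatments))
  for (tr in treatments) {
    if (n_de > length(eligible)) {
      stop("invalid simulation_config: de_fraction requests ", n_de,
           " DE genes per treatment but only ", length(eligible),
           " genes fall in de_baseline_range")
    }
    if (n_de > 0L) {
      idx <- sample(eligible, n_de)
      mag <- runif(n_de, config$log2fc_range[1L], config$log2fc_range[2L])
      lfc[idx, tr] <- mag * sample(c(-1, 1), n_de, replace = TRUE)
    }
  }

  ## intensity matrix: genes x conditions
  u <- matrix(0, n_total, length(conds), dimnames = list(NULL, conds))
  u[, control] <- baseline
  for (tr in treatments) u[, tr] <- baseline * 2^lfc[, tr]
  for (cc in conds) {
    off <- is_excl & excl != cc
    u[off, cc] <- 0
  }

  ## ballast transcripts equalize per-condition intensity totals so that
  ## planted fold changes survive the fixed-depth multinomial unchanged
  gene_mass <- colSums(u[!is_ballast, , drop = FALSE])
  ballast_total <- max(gene_mass) - gene_mass + 10000
  w <- runif(config$n_ballast, 0.8, 1.2)
  w <- w / sum(w)
  u[is_ballast, ] <- outer(w, ballast_total)

  ## artifact and background signatures
  L <- config$signature_length
  tail_len <- L - 4L
  gene_sigs <- gene_tab$signature
  bg_sigs <- unique_new_sigs(config$n_background, tail_len, gene_sigs)
  bg_lambda <- runif(config$n_background,
                     config$background_count_range[1L],
                     config$background_count_range[2L]) *
    1e6 / config$library_depth
  amb_sigs <- draw_unique(function(n) make_ambiguous_sigs(n, tail_len),
                          config$n_ambiguous, c(gene_sigs, bg_sigs))
  hp_sigs <- draw_unique(function(n) make_homopolymer_sigs(n, L),
                         config$n_homopolymer,
                         c(gene_sigs, bg_sigs, amb_sigs))
  art_intensity <- rlnorm(config$n_ambiguous + config$n_homopolymer,
                          log(20), 1)

  ## expected TPM over the clean (post-sequence-QC) signature set
  clean_mass <- sum(u[, control]) + sum(bg_lambda)  # equal in all conditions
  expected_tpm <- u * (1e6 / clean_mass)
  colnames(expected_tpm) <- paste0("expected_tpm_", conds)

  ## per-library multinomial sampling at fixed depth
  all_sigs <- c(gene_sigs, bg_sigs, amb_sigs, hp_sigs)
  intensity <- rbind(u,
                     matrix(bg_lambda, ncol = 1L)[, rep(1L, length(conds)),
                                                  drop = FALSE],
                     matrix(art_intensity, ncol = 1L)[, rep(1L, length(conds)),
                                                      drop = FALSE])
  colnames(intensity) <- conds
  if (length(all_sigs) > 0L) {
    counts <- vapply(conds, function(cc) {
      as.integer(rmultinom(1L, size = config$library_depth,
                           prob = intensity[, cc] / sum(intensity[, cc])))
    }, integer(length(all_sigs)))
    ord <- sample(length(all_sigs)) # shuffle rows: no structure in file order
    counts_df <- data.frame(signature = all_sigs[ord],
                            counts[ord, , drop = FALSE])
  } else {
    counts_df <- data.frame(signature = character(0),
                            matrix(integer(0), 0L, length(conds)))
  }
  names(counts_df) <- c("signature", conds)

  ## unigenes (genes and ballast transcripts only)
  unis <- vapply(gene_sigs, build_unigene, character(1),
                 body_length = config$body_length,
                 utr_length = config$utr_length, USE.NAMES = FALSE)
  unigenes <- Biostrings::DNAStringSet(stats::setNames(unis, gene_tab$unigene))

  truth <- cbind(gene_tab,
                 as.data.frame(lfc) |>
                   stats::setNames(paste0("log2fc_", treatments)),
                 as.data.frame(expected_tpm))
  de_status <- lapply(treatments, function(tr) {
    ifelse(lfc[, tr] > 0, "up", ifelse(lfc[, tr] < 0, "down", "none"))
  })
  names(de_status) <- paste0("de_", treatments)
  truth <- cbind(truth, as.data.frame(de_status))

  annotations <- data.frame(unigene = gene_tab$unigene,
                            family = gene_tab$family)

  ds <- structure(list(counts = counts_df, unigenes = unigenes,
                       annotations = annotations, truth = truth,
                       config = config),
                  class = "mpss_dataset")
  validate_dataset(ds)
  ds
}

# draw from `gen` until n signatures unique among themselves and `existing`
draw_unique <- function(gen, n, existing) {
  out <- character(0)
  while (length(out) < n) {
    cand <- gen(n - length(out) + 16L)
    cand <- setdiff(unique(cand), c(existing, out))
    out <- c(out, cand)
  }
  out[seq_len(n)]
}

# n unique GATC-anchored tags distinct from an existing set
unique_new_sigs <- function(n, tail_len, existing) {
  draw_unique(function(m) paste0(DPNII_SITE, random_dna(m, tail_len)),
              n, existing)
}

make_ambiguous_sigs <- function(n, tail_len) {
  if (n == 0L) return(character(0))
  amb <- c("N", "R", "Y", "S", "W", "K", "M")
  vapply(seq_len(n), function(i) {
    s <- strsplit(random_dna(1L, tail_len), "", fixed = TRUE)[[1L]]
    k <- sample(1:3, 1L)
    s[sample(tail_len, k)] <- sample(amb, k, replace = TRUE)
    paste0(DPNII_SITE, paste(s, collapse = ""))
  }, character(1))
}

make_homopolymer_sigs <- function(n, L) {
  if (n == 0L) return(character(0))
  vapply(seq_len(n), function(i) {
    run_len <- sample(8:12, 1L)
    base <- sample(DNA_BASES, 1L)
    fill_len <- L - 4L - run_len
    fill <- if (fill_len > 0L) random_dna(1L, fill_len) else ""
    s <- paste0(DPNII_SITE, strrep(base, run_len), fill)
    substr(s, 1L, L)
  }, character(1))
}

# structural self-checks: depth conservation, mismatch geometry, uniqueness
validate_dataset <- function(ds) {
  cfg <- ds$config
  if (nrow(ds$counts) > 0L) {
    depth_ok <- all(colSums(ds$counts[-1L]) == cfg$library_depth)
    if (!depth_ok) stop("internal error: library depth not conserved")
  }
  tr <- ds$truth
  d <- hamming_matrix(tr$signature)
  same_fam <- outer(tr$family, tr$family, "==")
  ut <- upper.tri(d)
  if (any(d[ut & same_fam] > cfg$within_family_max_mm)) {
    stop("internal error: within-family mismatch bound violated")
  }
  if (any(d[ut & !same_fam] < cfg$between_family_min_mm)) {
    stop("internal error: between-family separation violated")
  }
  if (anyDuplicated(ds$counts$signature)) {
    stop("internal error: duplicated signatures in count table")
  }
  invisible(ds)
}

#' @export
print.mpss_dataset <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "mpss_dataset: %d genes (+%d ballast) in %d families, %d signatures, %d libraries of %g reads (seed %d)\n",
    cfg$n_genes, cfg$n_ballast, length(unique(x$truth$family)),
    nrow(x$counts), length(cfg$condition_labels), cfg$library_depth,
    cfg$seed))
  invisible(x)
}
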