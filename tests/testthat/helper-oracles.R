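# Independent oracles the implementation is checked against. These stay
# deliberately naive: full enumeration, textbook definitions, quadratic scans.

# two-sided Fisher exact p by enumerating every table with the observed
# margins; point probabilities from log-binomial coefficients
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b
  r2 <- c + d
  c1 <- a + c
  n <- r1 + r2
  support <- max(0, c1 - r2):min(c1, r1)
  logp <- lchoose(r1, support) + lchoose(r2, c1 - support) - lchoose(n, c1)
  p_obs <- lchoose(r1, a) + lchoose(r2, c) - lchoose(n, c1)
  sum(exp(logp)[logp <= p_obs + log1p(1e-7)])
}

# textbook step-up Benjamini-Hochberg
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

revcomp <- function(s) {
  chartr("ACGT", "TGCA",
         paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = ""))
}

# all-offsets scan: every window of length L on either strand, kept when it
# starts with the GATC anchor and is within the mismatch budget
naive_match_oracle <- function(signature, unigenes, max_mm, L) {
  hits <- NULL
  for (u in names(unigenes)) {
    for (st in c("+", "-")) {
      x <- if (st == "+") unigenes[[u]] else revcomp(unigenes[[u]])
      if (nchar(x) < L) next
      for (off in 0:(nchar(x) - L)) {
        win <- substr(x, off + 1L, off + L)
        if (substr(win, 1L, 4L) != "GATC") next
        mm <- sum(strsplit(win, "", fixed = TRUE)[[1L]] !=
                    strsplit(signature, "", fixed = TRUE)[[1L]])
        if (mm <= max_mm) {
          hits <- rbind(hits, data.frame(unigene = u, strand = st,
                                         offset = off, mismatches = mm))
        }
      }
    }
  }
  hits
}

# single-linkage connected components by iterated merging
cluster_oracle <- function(signatures, t) {
  n <- length(signatures)
  comp <- seq_len(n)
  d <- outer(seq_len(n), seq_len(n), Vectorize(function(i, j) {
    sum(strsplit(signatures[i], "")[[1L]] != strsplit(signatures[j], "")[[1L]])
  }))
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, j] <= t && comp[i] != comp[j]) {
          comp[comp == comp[j]] <- comp[i]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  comp
}

# two labelled partitions of the same elements are identical
same_partition <- function(labels_a, labels_b) {
  canon <- function(l) {
    unname(vapply(split(seq_along(l), l), paste, character(1), collapse = ","))
  }
  setequal(canon(labels_a), canon(labels_b))
}
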