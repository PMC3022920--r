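# Independent oracles used by the test suite. These deliberately avoid
# the package's own code paths: the aligner oracle is a vectorised
# whole-genome Hamming scan in base R, the multiple-testing oracles
# evaluate the step-up/step-down definitions directly.

oracle_revcomp <- function(x) {
  chartr("ACGTN", "TGCAN",
         vapply(x, function(s) intToUtf8(rev(utf8ToInt(s))), character(1),
                USE.NAMES = FALSE))
}

# All placements of `tag` with at most max_mm mismatches over every
# window of every chromosome, both strands. N mismatches everything.
oracle_scan <- function(genome, tag, max_mm = 2) {
  N <- utf8ToInt("N")
  out <- list()
  for (chrom in names(genome)) {
    g <- utf8ToInt(genome[[chrom]])
    n <- length(g)
    L <- nchar(tag)
    if (n < L) next
    for (strand in c("+", "-")) {
      q <- if (strand == "+") tag else oracle_revcomp(tag)
      qi <- utf8ToInt(q)
      mm <- integer(n - L + 1)
      for (k in seq_len(L)) {
        gk <- g[k:(n - L + k)]
        mm <- mm + (gk != qi[k] | gk == N | qi[k] == N)
      }
      hit <- which(mm <= max_mm)
      if (length(hit)) {
        out[[length(out) + 1]] <- data.frame(
          chrom = chrom, start = hit - 1L, strand = strand,
          mismatches = mm[hit])
      }
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), start = integer(),
                      strand = character(), mismatches = integer()))
  }
  do.call(rbind, out)
}

oracle_stratum <- function(placements) {
  if (nrow(placements) == 0) return("NM")
  best <- min(placements$mismatches)
  n <- sum(placements$mismatches == best)
  if (n == 1) c("U0", "U1", "U2")[best + 1] else "R"
}

# canonical key set of the best-stratum placements, for set comparison
oracle_best_keys <- function(placements) {
  if (nrow(placements) == 0) return(character())
  best <- min(placements$mismatches)
  p <- placements[placements$mismatches == best, ]
  sort(paste(p$chrom, p$start, p$strand, p$mismatches))
}

# step-up BH from its definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(pmin(ps[i:m] * m / (i:m), 1))
  }
  q[order(o)]
}

# step-down Holm from its definition
oracle_holm <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  running <- 0
  for (i in seq_len(m)) {
    running <- max(running, min((m - i + 1) * ps[i], 1))
    adj[i] <- running
  }
  adj[order(o)]
}

# leftmost adapter window within the mismatch budget (1-based cut
# position), NA if none; independent re-derivation for trim checks
oracle_adapter_cut <- function(seq, prefix = "CGCCTTGG", max_mm = 1) {
  L <- nchar(seq)
  k <- nchar(prefix)
  if (L < k) return(NA_integer_)
  pv <- utf8ToInt(prefix)
  sv <- utf8ToInt(seq)
  N <- utf8ToInt("N")
  for (pos in seq_len(L - k + 1)) {
    w <- sv[pos:(pos + k - 1)]
    if (sum(w != pv | w == N) <= max_mm) return(pos)
  }
  NA_integer_
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_tag <- function(tag, n_mut) {
  if (n_mut == 0) return(tag)
  pos <- sample(nchar(tag), min(n_mut, nchar(tag)))
  s <- strsplit(tag, NULL)[[1]]
  for (p in pos) s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1)
  paste(s, collapse = "")
}
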