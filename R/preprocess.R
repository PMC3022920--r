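#' Trimming, length and barcode parameter constructors
#'
#' `trim_spec()` describes 3' adapter removal: the adapter is located by
#' its leading `adapter_prefix` (default the 8-nt `CGCCTTGG`) scanning
#' left to right and accepting the first window whose Hamming distance
#' is within `max_mismatch`; `N` never matches any adapter base.
#' `length_spec()` holds the post-trim length rules (drop below
#' `min_len`, truncate above `max_len`). `barcode_spec()` maps samples
#' to 6-nt multiplex tags and selects the matching policy.
#'
#' @param adapter_prefix Leading adapter bases used for matching
#'   (length >= 4).
#' @param max_mismatch Mismatch budget, `0 <= max_mismatch <
#'   nchar(adapter_prefix)`.
#' @return A spec list of the corresponding class.
#' @export
trim_spec <- function(adapter_prefix = "CGCCTTGG", max_mismatch = 1L) {
  adapter_prefix <- toupper(adapter_prefix)
  check_dna(adapter_prefix, "adapter_prefix")
  if (nchar(adapter_prefix) < 4) abort("adapter_prefix must be at least 4 nt")
  if (max_mismatch < 0 || max_mismatch >= nchar(adapter_prefix)) {
    abort("max_mismatch must satisfy 0 <= max_mismatch < nchar(adapter_prefix)")
  }
  structure(list(adapter_prefix = adapter_prefix,
                 max_mismatch = as.integer(max_mismatch)),
            class = "trim_spec")
}

#' @rdname trim_spec
#' @param min_len Minimum post-trim length kept (default 15).
#' @param max_len Maximum length; longer sequences are truncated
#'   (default 32).
#' @export
length_spec <- function(min_len = 15L, max_len = 32L) {
  if (min_len <= 0 || min_len > max_len) abort("need 0 < min_len <= max_len")
  structure(list(min_len = as.integer(min_len), max_len = as.integer(max_len)),
            class = "length_spec")
}

#' @rdname trim_spec
#' @param barcodes Named character vector: `sample name -> tag`
#'   (all tags the same length, unique).
#' @param policy `"exact"` (perfect tag match only) or `"levenshtein1"`
#'   (assign iff exactly one sample tag is within edit distance 1).
#' @param tag_source `"inline_prefix"` (the read begins with the tag,
#'   which is stripped on assignment) or `"separate_read"` (tags arrive
#'   as a parallel read stream).
#' @export
barcode_spec <- function(barcodes, policy = c("exact", "levenshtein1"),
                         tag_source = c("inline_prefix", "separate_read")) {
  policy <- match.arg(policy)
  tag_source <- match.arg(tag_source)
  barcodes <- toupper(barcodes)
  check_dna(barcodes, "barcode")
  if (is.null(names(barcodes)) || any(!nzchar(names(barcodes)))) {
    abort("barcodes must be a named vector (sample -> tag)")
  }
  if (length(unique(nchar(barcodes))) != 1) abort("all barcode tags must have the same length")
  if (anyDuplicated(barcodes)) abort("barcode tags must be unique")
  structure(list(barcodes = barcodes, policy = policy, tag_source = tag_source,
                 tag_len = nchar(barcodes[[1]])),
            class = "barcode_spec")
}

#' Demultiplex reads on their 6-nt sample tags
#'
#' Under the `exact` policy only perfect tag matches are assigned;
#' under `levenshtein1` a read is assigned iff exactly one sample tag
#' lies within edit distance 1 of the observed tag (equidistant reads
#' stay unassigned). Read counts are conserved: assigned plus
#' unassigned always equals the input.
#'
#' @param reads Read tibble from [read_reads()].
#' @param spec A [barcode_spec()].
#' @param tag_reads For `tag_source = "separate_read"`: a parallel read
#'   tibble of equal record count whose sequences are the observed tags.
#' @return A list of read tibbles, one per sample plus `unassigned`.
#'   For inline tags the assigned reads have the tag prefix removed.
#' @export
demultiplex <- function(reads, spec, tag_reads = NULL) {
  stopifnot(inherits(spec, "barcode_spec"))
  if (spec$tag_source == "separate_read") {
    if (is.null(tag_reads)) abort("tag_source 'separate_read' requires tag_reads")
    if (nrow(tag_reads) != nrow(reads)) {
      abort(sprintf("tag stream has %d records but read stream has %d",
                    nrow(tag_reads), nrow(reads)))
    }
    observed <- substr(tag_reads$sequence, 1, spec$tag_len)
    payload <- reads
  } else {
    observed <- substr(reads$sequence, 1, spec$tag_len)
    payload <- reads
  }
  assigned_to <- match_barcodes(observed, spec)
  out <- lapply(names(spec$barcodes), function(s) {
    sel <- which(!is.na(assigned_to) & assigned_to == s)
    res <- payload[sel, ]
    if (spec$tag_source == "inline_prefix" && nrow(res) > 0) {
      res$sequence <- substr(res$sequence, spec$tag_len + 1L, nchar(res$sequence))
      res$quality <- ifelse(nzchar(res$quality),
                            substr(res$quality, spec$tag_len + 1L, nchar(res$quality)),
                            res$quality)
    }
    res
  })
  names(out) <- names(spec$barcodes)
  out$unassigned <- payload[is.na(assigned_to), ]
  out
}

match_barcodes <- function(observed, spec) {
  tags <- spec$barcodes
  if (spec$policy == "exact") {
    hit <- match(observed, tags)
    return(names(tags)[hit])
  }
  # levenshtein1: unique tag within edit distance 1, else unassigned
  uo <- unique(observed)
  d <- adist(uo, tags)
  n_close <- rowSums(d <= 1)
  best <- apply(d, 1, which.min)
  assign_u <- ifelse(n_close == 1, names(tags)[best], NA_character_)
  assign_u[match(observed, uo)]
}

#' Remove the ligated 3' adapter from read sequences
#'
#' Scans each sequence left to right and truncates at the first
#' position where the window's Hamming distance to the adapter prefix
#' is within the mismatch budget. Windows shorter than the prefix never
#' match, and `N` counts as a mismatch against every adapter base.
#'
#' @param sequences Character vector of read sequences (ACGTN).
#' @param spec A [trim_spec()].
#' @return Tibble with `sequence` (trimmed) and `trimmed` (logical).
#' @examples
#' trim_adapter(c("TGAGGTAGTAGGTTGTATAGTTCGCCTTGGAAC"), trim_spec())
#' @export
trim_adapter <- function(sequences, spec = trim_spec()) {
  stopifnot(inherits(spec, "trim_spec"))
  if (any(!nzchar(sequences))) abort("empty sequence cannot be trimmed")
  check_dna(sequences, "read sequence")
  cut <- adapter_positions(sequences, spec$adapter_prefix, spec$max_mismatch)
  trimmed <- !is.na(cut)
  out <- sequences
  out[trimmed] <- substr(out[trimmed], 1L, cut[trimmed] - 1L)
  tibble(sequence = out, trimmed = trimmed)
}

# First window (1-based start) within the mismatch budget, NA if none.
# Vectorised over sequences: one pass per (offset, window position) pair
# on a matrix of candidate windows.
adapter_positions <- function(sequences, prefix, max_mm) {
  k <- nchar(prefix)
  pvec <- strsplit(prefix, NULL)[[1]]
  lens <- nchar(sequences)
  cut <- rep(NA_integer_, length(sequences))
  todo <- which(lens >= k)
  if (!length(todo)) return(cut)
  maxpos <- max(lens[todo]) - k + 1L
  for (pos in seq_len(maxpos)) {
    cand <- todo[lens[todo] - k + 1L >= pos & is.na(cut[todo])]
    if (!length(cand)) next
    mm <- integer(length(cand))
    for (j in seq_len(k)) {
      ch <- substr(sequences[cand], pos + j - 1L, pos + j - 1L)
      mm <- mm + (ch != pvec[j] | ch == "N")
    }
    hit <- mm <= max_mm
    cut[cand[hit]] <- pos
  }
  cut
}

#' Apply post-trim length rules
#'
#' Sequences shorter than `min_len` are dropped (and reported in the
#' below-minimum bucket); sequences longer than `max_len` keep their
#' first `max_len` bases.
#'
#' @param reads Tibble with at least `sequence` and `count`.
#' @param spec A [length_spec()].
#' @return List with `kept` (tibble, truncated where needed) and
#'   `below_min` (read count dropped as too short).
#' @export
filter_and_truncate <- function(reads, spec = length_spec()) {
  stopifnot(inherits(spec, "length_spec"))
  lens <- nchar(reads$sequence)
  short <- lens < spec$min_len
  kept <- reads[!short, ]
  kept$sequence <- substr(kept$sequence, 1L, spec$max_len)
  list(kept = kept, below_min = sum(reads$count[short]))
}

#' Collapse identical sequences to counted tags
#'
#' Sums the counts of identical post-trim sequences into one tag each,
#' ordered by descending count then lexicographic sequence for
#' reproducible output.
#'
#' @param reads Tibble with `sequence`, `count` and optionally
#'   `trimmed`.
#' @return Tibble of collapsed tags: `sequence`, `count`, `trimmed`
#'   (TRUE if any source read was adapter-trimmed).
#' @export
collapse_tags <- function(reads) {
  if (!"trimmed" %in% names(reads)) reads$trimmed <- NA
  reads |>
    group_by(.data$sequence) |>
    summarise(count = sum(.data$count), trimmed = any(.data$trimmed),
              .groups = "drop") |>
    arrange(dplyr::desc(.data$count), .data$sequence)
}
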