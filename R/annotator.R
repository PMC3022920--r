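#' Infer the unannotated arm of a miRNA precursor
#'
#' Given a precursor interval and one known mature arm, the other arm
#' is placed by reflecting the known arm through the hairpin midpoint
#' and shifting 2 nt toward the precursor 3' end, reproducing the
#' Dicer duplex's 2-nt 3' overhangs under perfect stem pairing. In
#' precursor-relative 1-based coordinates with precursor length `L` and
#' known arm `[p, q]`, the inferred arm is `[L+1-q+2, L+1-p+2]`,
#' clamped to `[1, L]`, then converted to genomic coordinates
#' respecting the precursor strand.
#'
#' @param precursor One-row tibble (or list) with `chrom`, `start`,
#'   `end` (1-based inclusive), `strand`.
#' @param known_arm One-row tibble (or list) with `start`, `end`
#'   (genomic, inside the precursor) and `arm` (`"5p"` or `"3p"`).
#' @return One-row tibble for the inferred arm: `arm` (the complement
#'   of the known arm), genomic `start`/`end`, `strand`, `chrom`,
#'   `inferred = TRUE`, and `clamped` (TRUE when the 2-nt shift ran off
#'   the precursor edge and the interval was truncated).
#' @export
infer_missing_arm <- function(precursor, known_arm) {
  P1 <- precursor$start[[1]]; P2 <- precursor$end[[1]]
  strand <- precursor$strand[[1]]
  L <- P2 - P1 + 1
  a1 <- known_arm$start[[1]]; a2 <- known_arm$end[[1]]
  if (a1 < P1 || a2 > P2) abort("known arm lies outside its precursor interval")
  # genomic -> precursor-relative (1 = precursor 5' end)
  if (strand == "+") {
    p <- a1 - P1 + 1; q <- a2 - P1 + 1
  } else {
    p <- P2 - a2 + 1; q <- P2 - a1 + 1
  }
  r1 <- L + 1 - q + 2
  r2 <- L + 1 - p + 2
  clamped <- r1 < 1 || r2 > L
  r1 <- max(r1, 1); r2 <- min(r2, L)
  if (strand == "+") {
    g1 <- P1 + r1 - 1; g2 <- P1 + r2 - 1
  } else {
    g1 <- P2 - r2 + 1; g2 <- P2 - r1 + 1
  }
  tibble(arm = if (known_arm$arm[[1]] == "5p") "3p" else "5p",
         chrom = precursor$chrom[[1]], start = g1, end = g2,
         strand = strand, inferred = TRUE, clamped = clamped)
}

#' Derive the full set of assignable transcript loci
#'
#' Expands an annotation table into one locus per assignable
#' transcript: each miRNA precursor contributes its 5p and 3p mature
#' arms (annotated where available, otherwise inferred via
#' [infer_missing_arm()] and flagged), and every non-miRNA record
#' contributes itself. Precursors with no annotated arm at all are
#' skipped with a warning.
#'
#' @param annotation Tibble from [read_annotation()].
#' @return Locus tibble: `locus_id`, `rna_class`, `transcript_id`,
#'   `name`, `chrom`, `start`, `end` (1-based inclusive), `strand`,
#'   `arm` (`5p`/`3p`/`n`), `inferred`.
#' @export
derive_arm_loci <- function(annotation) {
  non_mir <- annotation |>
    filter(.data$rna_class != "miRNA") |>
    mutate(arm = "n", inferred = FALSE)
  mir <- annotation |> filter(.data$rna_class == "miRNA")
  arm_rows <- list()
  skipped <- character()
  for (tid in unique(mir$transcript_id)) {
    rows <- mir[mir$transcript_id == tid, ]
    prec <- rows[rows$arm == "none", ]
    arms <- rows[rows$arm != "none", ]
    if (nrow(arms) == 0) {
      skipped <- c(skipped, tid)
      next
    }
    if (nrow(arms) == 1) {
      if (nrow(prec) == 0) {
        skipped <- c(skipped, tid)
        next
      }
      inf <- infer_missing_arm(prec, arms)
      arms <- bind_rows(
        arms |> select("rna_class", "transcript_id", "name", "chrom",
                       "start", "end", "strand", "arm", "inferred"),
        tibble(rna_class = "miRNA", transcript_id = tid,
               name = arms$name[[1]], chrom = inf$chrom, start = inf$start,
               end = inf$end, strand = inf$strand, arm = inf$arm,
               inferred = TRUE))
    } else {
      arms <- arms |> select("rna_class", "transcript_id", "name", "chrom",
                             "start", "end", "strand", "arm", "inferred")
    }
    arm_rows[[tid]] <- arms
  }
  if (length(skipped)) {
    warn(sprintf("%d miRNA precursor(s) without a usable annotated arm skipped: %s",
                 length(skipped), paste(head(skipped, 3), collapse = ", ")))
  }
  loci <- bind_rows(
    bind_rows(arm_rows),
    non_mir |> select("rna_class", "transcript_id", "name", "chrom",
                      "start", "end", "strand", "arm", "inferred")
  )
  loci |>
    arrange(.data$chrom, .data$start, .data$transcript_id, .data$arm) |>
    mutate(locus_id = dplyr::row_number(), .before = 1)
}

#' Compose a transcript identifier
#'
#' Identifiers are `class|transcript_id|arm[~]|name|orientation`, with
#' `~` appended to the arm when its coordinates were inferred rather
#' than annotated, and `n` as the arm field for non-miRNA classes.
#'
#' @param locus One or more locus rows from [derive_arm_loci()].
#' @param orientation `"sense"` or `"antisense"` (recycled).
#' @return Character vector of identifiers.
#' @examples
#' build_identifier(tibble::tibble(rna_class = "miRNA",
#'   transcript_id = "ENSGALT00000028942", arm = "5p", inferred = TRUE,
#'   name = "gga-mir-29a"), "sense")
#' @export
build_identifier <- function(locus, orientation = "sense") {
  arm <- ifelse(locus$arm == "n", "n",
                paste0(locus$arm, ifelse(locus$inferred, "~", "")))
  paste(locus$rna_class, locus$transcript_id, arm, locus$name, orientation,
        sep = "|")
}

format_location <- function(locus) {
  sprintf("%s:%d-%d|%s", locus$chrom, as.integer(locus$start),
          as.integer(locus$end), locus$strand)
}

#' Assign uniquely aligned tags to transcript loci
#'
#' Only tags in the `U0` and `U1` strata are assignable. A tag is
#' assigned to every locus on its chromosome that it overlaps by at
#' least 50% of the tag length (`overlap >= ceiling(0.5 * tag
#' length)`, measured against the tag so short 3'-trimmed isomirs
#' remain annotatable). Orientation is `sense` when the placement
#' strand equals the locus strand. A tag may be assigned to several
#' loci; every qualifying assignment is reported.
#'
#' @param alignment A `tag_alignment` from [align_tags()].
#' @param loci Locus tibble from [derive_arm_loci()].
#' @return Assignment tibble: `tag_id`, `sequence`, `count`,
#'   `locus_id`, `identifier`, `rna_class`, `orientation`, `overlap`,
#'   and the placement's `chrom`, `start`, `end` (0-based half-open),
#'   `strand`, `mismatches`.
#' @export
assign_transcripts <- function(alignment, loci) {
  u_tags <- alignment$tags |> filter(.data$stratum %in% c("U0", "U1"))
  pl <- alignment$placements |>
    filter(.data$tag_id %in% u_tags$tag_id) |>
    left_join(u_tags |> select("tag_id", "sequence", "count"), by = "tag_id")
  empty <- tibble(tag_id = integer(), sequence = character(),
                  count = integer(), locus_id = integer(),
                  identifier = character(), rna_class = character(),
                  orientation = character(), overlap = integer(),
                  chrom = character(), start = integer(), end = integer(),
                  strand = character(), mismatches = integer())
  if (nrow(pl) == 0 || nrow(loci) == 0) return(empty)
  ov <- overlap_pairs(pl, loci)
  if (nrow(ov) == 0) return(empty)
  ov <- ov |>
    mutate(tag_len = nchar(.data$sequence)) |>
    filter(.data$overlap >= ceiling(0.5 * .data$tag_len)) |>
    mutate(orientation = if_else(.data$strand == .data$locus_strand,
                                 "sense", "antisense"))
  ov$identifier <- build_identifier(ov, ov$orientation)
  ov |>
    select("tag_id", "sequence", "count", "locus_id", "identifier",
           "rna_class", "orientation", "overlap", "chrom", "start", "end",
           "strand", "mismatches") |>
    arrange(.data$tag_id, .data$locus_id)
}

# Interval-tree overlap join between 0-based half-open placements and
# 1-based inclusive loci, per chromosome.
overlap_pairs <- function(pl, loci) {
  pl_gr <- GenomicRanges::GRanges(
    seqnames = pl$chrom,
    ranges = IRanges::IRanges(start = pl$start + 1L, end = pl$end))
  loci_gr <- GenomicRanges::GRanges(
    seqnames = loci$chrom,
    ranges = IRanges::IRanges(start = loci$start, end = loci$end))
  hits <- GenomicRanges::findOverlaps(pl_gr, loci_gr, ignore.strand = TRUE)
  if (length(hits) == 0) {
    return(tibble())
  }
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  width <- IRanges::width(IRanges::pintersect(
    IRanges::ranges(pl_gr)[qi], IRanges::ranges(loci_gr)[si]))
  bind_cols(
    pl[qi, ],
    loci[si, ] |>
      select("locus_id", "rna_class", "transcript_id", "name", "arm",
             "inferred", locus_start = "start", locus_end = "end",
             locus_strand = "strand")) |>
    mutate(overlap = width)
}
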