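#' Build an exact k-mer index over a genome
#'
#' Indexes the forward strand of every chromosome; minus-strand hits
#' are found at query time from the reverse complement of the tag.
#' `N` runs are never indexed.
#'
#' @param genome A named character vector of chromosome sequences, a
#'   `Biostrings::DNAStringSet`, or a path to a FASTA file.
#' @param seed_len Exact seed length k (default 5, compatible with the
#'   pigeonhole segmenting of 15-nt tags at 2 mismatches).
#' @return A `genome_index` object.
#' @export
genome_index <- function(genome, seed_len = 5L) {
  if (is.character(genome) && length(genome) == 1 && file.exists(genome) &&
      is.null(names(genome))) {
    genome <- Biostrings::readDNAStringSet(genome)
  }
  if (methods::is(genome, "DNAStringSet")) {
    genome <- setNames(as.character(genome), sub("\\s.*$", "", names(genome)))
  }
  if (!is.character(genome) || is.null(names(genome)) ||
      anyDuplicated(names(genome))) {
    abort("genome must be a FASTA path or uniquely named character vector")
  }
  ptr <- .build_index_cpp(names(genome), unname(genome), as.integer(seed_len))
  info <- .index_info_cpp(ptr)
  structure(list(ptr = ptr, chrom_names = info$names,
                 chrom_lengths = setNames(info$lengths, info$names),
                 seed_len = info$k),
            class = "genome_index")
}

#' @export
print.genome_index <- function(x, ...) {
  cat(sprintf("<genome_index> %d chromosome(s), %s bp total, seed k=%d\n",
              length(x$chrom_lengths),
              format(sum(as.numeric(x$chrom_lengths)), big.mark = ","),
              x$seed_len))
  invisible(x)
}

#' Look up the genomic locations of one exact k-mer
#'
#' @param index A [genome_index()].
#' @param kmer A k-length ACGT string.
#' @return Tibble with `chrom` and 0-based `offset` of every exact
#'   forward-strand occurrence.
#' @export
index_lookup <- function(index, kmer) {
  stopifnot(inherits(index, "genome_index"))
  hits <- .index_lookup_cpp(index$ptr, toupper(kmer))
  tibble(chrom = index$chrom_names[hits$chrom], offset = hits$offset)
}

#' Place collapsed tags on the genome and classify uniqueness strata
#'
#' Finds all placements with at most `max_mismatch` substitutions on
#' both strands (pigeonhole seeding: a tag is split into
#' `max_mismatch + 1` segments, so every qualifying placement matches
#' at least one segment exactly). Each tag is classified at the lowest
#' populated mismatch level: `U0`/`U1`/`U2` when that level holds
#' exactly one placement, `R` when it holds several, `NM` when no
#' placement exists within the budget. Placements above the best level
#' are discarded; repeat placements are stored up to `max_placements`
#' (the stratum is still computed from the full placement count).
#'
#' @param tags Tibble with `sequence` and `count` (from
#'   [collapse_tags()]), or a character vector of sequences.
#' @param index A [genome_index()].
#' @param max_mismatch Mismatch budget (0, 1 or 2; default 2).
#' @param max_placements Cap on stored placements per repeat tag.
#' @return A `tag_alignment`: list with `tags` (tibble `tag_id`,
#'   `sequence`, `count`, `stratum`, `n_placements`) and `placements`
#'   (tibble `tag_id`, `chrom`, `start` 0-based, `end` half-open,
#'   `strand`, `mismatches`, best stratum only).
#' @export
align_tags <- function(tags, index, max_mismatch = 2L, max_placements = 64L) {
  stopifnot(inherits(index, "genome_index"))
  if (is.character(tags)) tags <- tibble(sequence = tags, count = 1L)
  if (max_mismatch < 0 || max_mismatch > 2) abort("max_mismatch must be 0, 1 or 2")
  check_dna(tags$sequence, "tag sequence")
  res <- .align_tags_cpp(index$ptr, tags$sequence, as.integer(max_mismatch),
                         as.integer(max_placements))
  if (any(res$too_short)) {
    warn(sprintf("%d tag(s) too short to seed at k=%d with %d mismatches; classified NM",
                 sum(res$too_short), index$seed_len, max_mismatch))
  }
  p <- res$placements
  tag_tbl <- tibble(tag_id = seq_len(nrow(tags)), sequence = tags$sequence,
                    count = as.integer(tags$count), stratum = res$stratum,
                    n_placements = res$n_best)
  placement_tbl <- tibble(
    tag_id = p$tag_id,
    chrom = index$chrom_names[p$chrom_id],
    start = p$start,
    end = p$start + nchar(tags$sequence[p$tag_id]),
    strand = p$strand,
    mismatches = p$mismatches
  )
  structure(list(tags = tag_tbl, placements = placement_tbl,
                 max_mismatch = as.integer(max_mismatch)),
            class = "tag_alignment")
}

#' @export
print.tag_alignment <- function(x, ...) {
  tab <- x$tags |>
    group_by(.data$stratum) |>
    summarise(tags = n(), reads = sum(.data$count), .groups = "drop")
  cat(sprintf("<tag_alignment> %d tags, %d reads\n", nrow(x$tags),
              sum(x$tags$count)))
  print(tab)
  invisible(x)
}

STRATA <- c("NM", "R", "U0", "U1", "U2")

#' Import pre-computed alignments from an external aligner
#'
#' Accepts the package's alignment interchange TSV (`sequence`,
#' `count`, `chrom`, `start` 0-based, `strand`, `mismatches`,
#' `stratum`) so Bowtie/Eland-style output converted to this layout
#' can replace the built-in aligner.
#'
#' @param path Path to the TSV.
#' @return A `tag_alignment` object.
#' @export
read_alignment <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    sequence = readr::col_character(), count = readr::col_integer(),
    chrom = readr::col_character(), start = readr::col_integer(),
    strand = readr::col_character(), mismatches = readr::col_integer(),
    stratum = readr::col_character()), progress = FALSE)
  if (any(!df$stratum %in% STRATA)) abort("unknown stratum in alignment import")
  tag_info <- df |>
    distinct(.data$sequence, .data$count, .data$stratum) |>
    mutate(tag_id = dplyr::row_number())
  pl <- df |>
    filter(!is.na(.data$chrom)) |>
    left_join(tag_info |> select("sequence", "tag_id"), by = "sequence")
  structure(list(
    tags = tag_info |>
      mutate(n_placements = vapply(.data$tag_id, function(i) {
        sum(pl$tag_id == i)
      }, integer(1))) |>
      select("tag_id", "sequence", "count", "stratum", "n_placements"),
    placements = tibble(tag_id = pl$tag_id, chrom = pl$chrom, start = pl$start,
                        end = pl$start + nchar(pl$sequence),
                        strand = pl$strand, mismatches = pl$mismatches),
    max_mismatch = 2L), class = "tag_alignment")
}

#' Export a `tag_alignment` to the interchange TSV
#'
#' @param alignment A `tag_alignment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(alignment, path) {
  out <- alignment$tags |>
    left_join(alignment$placements, by = "tag_id") |>
    select("sequence", "count", "chrom", "start", "strand", "mismatches",
           "stratum")
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
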