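#' Aggregate transcript assignments into isomir records
#'
#' Isomirs are keyed by placement and sequence: reads with the same
#' sequence aligned to the same place are one isomir with a summed
#' count, while the same sequence at a different placement is a
#' different isomir. The isomir id is
#' `chr|begin|end|strand|mismatches|sequence` with 1-based inclusive
#' coordinates.
#'
#' @param assignments Assignment tibble from [assign_transcripts()],
#'   optionally with a `sample` column (added by the pipeline).
#' @return Isomir tibble: (`sample`,) `identifier`, `isomir_id`,
#'   `sequence`, `count`, `mismatches`, `perfect`, ordered within
#'   transcript by descending count then id.
#' @export
accumulate_isomirs <- function(assignments) {
  if (!"sample" %in% names(assignments)) assignments$sample <- "sample1"
  assignments |>
    mutate(isomir_id = sprintf("%s|%d|%d|%s|%d|%s", .data$chrom,
                               .data$start + 1L, .data$end, .data$strand,
                               .data$mismatches, .data$sequence)) |>
    group_by(.data$sample, .data$identifier, .data$isomir_id,
             .data$sequence, .data$mismatches) |>
    summarise(count = sum(.data$count), .groups = "drop") |>
    mutate(perfect = .data$mismatches == 0L) |>
    arrange(.data$sample, .data$identifier, dplyr::desc(.data$count),
            .data$isomir_id) |>
    select("sample", "identifier", "isomir_id", "sequence", "count",
           "mismatches", "perfect")
}

#' Summarise isomirs into per-transcript expression rows
#'
#' Computes, per transcript and sample, the three expression summaries:
#' the total read count over all isomirs (`counts`), the
#' perfect-match-only count (`u0_counts`), and the most abundant isomir
#' (`highest_count`, `highest_seq`; ties broken by lexicographically
#' smallest isomir id), together with the number of distinct isomirs
#' (`unique`). Zero rows are emitted for every transcript in
#' `transcripts` so tables align row-wise across samples.
#'
#' @param isomirs Isomir tibble from [accumulate_isomirs()].
#' @param transcripts Tibble with `identifier` and `location` covering
#'   every transcript a row should be emitted for (e.g. from
#'   [transcript_table()]). Observed identifiers absent from it (such
#'   as antisense matches) are appended with their observed location.
#' @param samples Character vector of sample names to emit rows for;
#'   defaults to those present in `isomirs`.
#' @return Long tibble: `identifier`, `location`, `sample`, `unique`,
#'   `counts`, `u0_counts`, `highest_count`, `highest_seq`.
#' @export
summarize_expression <- function(isomirs, transcripts, samples = NULL) {
  if (is.null(samples)) samples <- unique(isomirs$sample)
  observed <- isomirs |>
    group_by(.data$sample, .data$identifier) |>
    summarise(
      unique = dplyr::n_distinct(.data$isomir_id),
      counts = sum(.data$count),
      u0_counts = sum(.data$count[.data$perfect]),
      highest_count = max(.data$count),
      highest_seq = .data$isomir_id[order(-.data$count, .data$isomir_id)][1],
      .groups = "drop")
  extra <- setdiff(unique(isomirs$identifier), transcripts$identifier)
  if (length(extra)) {
    locs <- isomirs |>
      filter(.data$identifier %in% extra) |>
      distinct(.data$identifier, .data$isomir_id) |>
      tidyr::separate_wider_delim("isomir_id", "|",
        names = c("chrom", "begin", "end", "strand", "mm", "seq")) |>
      group_by(.data$identifier) |>
      summarise(location = sprintf("%s:%d-%d|%s", .data$chrom[1],
                                   min(as.integer(.data$begin)),
                                   max(as.integer(.data$end)),
                                   .data$strand[1]),
                .groups = "drop")
    transcripts <- bind_rows(transcripts, locs)
  }
  grid <- tidyr::expand_grid(transcripts, sample = samples)
  grid |>
    left_join(observed, by = c("identifier", "sample")) |>
    mutate(unique = dplyr::coalesce(.data$unique, 0L),
           counts = dplyr::coalesce(.data$counts, 0L),
           u0_counts = dplyr::coalesce(.data$u0_counts, 0L),
           highest_count = dplyr::coalesce(.data$highest_count, 0L),
           highest_seq = dplyr::coalesce(.data$highest_seq, "")) |>
    arrange(.data$identifier, .data$sample)
}

#' Emit the transcript table for all annotated/inferred loci
#'
#' Sense-orientation identifiers and locations for every locus, the
#' row universe of the combined expression table.
#'
#' @param loci Locus tibble from [derive_arm_loci()].
#' @return Tibble with `identifier` and `location`.
#' @export
transcript_table <- function(loci) {
  tibble(identifier = build_identifier(loci, "sense"),
         location = format_location(loci))
}

#' Scale expression counts to tags-per-million and add sqrt(tpm)
#'
#' `tpm = counts / denominator * 1e6`, where the denominator is the
#' sample's aligned read total under the chosen policy:
#' `"aligned_all"` (default; reads in U0+U1+U2+R) or
#' `"aligned_unique"` (U0+U1 only). The square-root transform
#' stabilises the counting variance.
#'
#' @param rows Expression rows from [summarize_expression()].
#' @param denominators Named numeric vector: sample -> aligned read
#'   count (e.g. from [aligned_denominator()]).
#' @return `rows` with `tpm` and `sqrt_tpm` columns appended.
#' @export
normalize_tpm <- function(rows, denominators) {
  missing <- setdiff(unique(rows$sample), names(denominators))
  if (length(missing)) {
    abort(sprintf("no denominator for sample(s): %s",
                  paste(missing, collapse = ", ")))
  }
  if (any(denominators[unique(rows$sample)] <= 0)) {
    abort("tpm denominator must be positive")
  }
  rows |>
    mutate(tpm = .data$counts / unname(denominators[.data$sample]) * 1e6,
           sqrt_tpm = sqrt(.data$tpm))
}

#' @describeIn normalize_tpm Aligned-read denominator of one library.
#' @param alignment A `tag_alignment`.
#' @param policy `"aligned_all"` or `"aligned_unique"`.
#' @export
aligned_denominator <- function(alignment,
                                policy = c("aligned_all", "aligned_unique")) {
  policy <- match.arg(policy)
  strata <- if (policy == "aligned_all") c("U0", "U1", "U2", "R") else c("U0", "U1")
  sum(alignment$tags$count[alignment$tags$stratum %in% strata])
}
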