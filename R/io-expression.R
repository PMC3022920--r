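SAMPLE_EXPR_COLS <- c("unique", "counts", "u0_counts", "highest_count",
                      "highest_seq", "tpm", "sqrt")

#' Write the combined expression table
#'
#' One line per transcript: the identifier
#' (`class|transcript_id|arm[~]|name|orientation`), the genomic location
#' (`chrom:start-end|strand`, 1-based inclusive), then for every sample
#' seven columns: `unique` (number of distinct isomirs), `counts` (sum
#' of isomir counts), `u0_counts` (perfect-match counts only),
#' `highest_count` and `highest_seq` (the most abundant isomir and its
#' `chr|begin|end|strand|mismatches|sequence` id), `tpm`, and `sqrt`
#' (square root of tpm).
#'
#' @param rows Long expression tibble as returned by
#'   [normalize_tpm()], with columns `identifier`, `location`, `sample`,
#'   `unique`, `counts`, `u0_counts`, `highest_count`, `highest_seq`,
#'   `tpm`, `sqrt_tpm`.
#' @param samples Ordered character vector of sample names; every row
#'   set must cover every sample.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(rows, samples, path) {
  missing <- setdiff(samples, unique(rows$sample))
  if (length(missing)) {
    abort(sprintf("expression rows missing for sample(s): %s",
                  paste(missing, collapse = ", ")))
  }
  rows <- rows[rows$sample %in% samples, ]
  per_transcript <- split(rows, rows$identifier)
  bad <- names(per_transcript)[vapply(per_transcript, function(d) {
    !setequal(d$sample, samples)
  }, logical(1))]
  if (length(bad)) {
    abort(sprintf("transcript '%s' lacks values for some sample", bad[1]))
  }
  wide <- rows |>
    mutate(sqrt = round(.data$sqrt_tpm, 6)) |>
    select("identifier", "location", "sample", dplyr::all_of(SAMPLE_EXPR_COLS)) |>
    tidyr::pivot_wider(names_from = "sample",
                       values_from = dplyr::all_of(SAMPLE_EXPR_COLS),
                       names_glue = "{sample}_{.value}") |>
    arrange(.data$identifier)
  ordered_cols <- c("identifier", "location",
                    as.vector(t(outer(samples, SAMPLE_EXPR_COLS, paste, sep = "_"))))
  readr::write_tsv(wide[ordered_cols], path, progress = FALSE)
  invisible(path)
}

#' Read back an expression table into long form
#'
#' @param path Path written by [write_expression_table()].
#' @return Long tibble with one row per transcript and sample.
#' @export
read_expression_table <- function(path) {
  wide <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  long <- wide |>
    tidyr::pivot_longer(-c("identifier", "location"),
                        names_to = c("sample", "metric"),
                        names_pattern = sprintf("^(.*?)_(%s)$",
                                                paste(c("u0_counts", "highest_count",
                                                        "highest_seq", "unique",
                                                        "counts", "tpm", "sqrt"),
                                                      collapse = "|")),
                        values_transform = as.character) |>
    tidyr::pivot_wider(names_from = "metric", values_from = "value")
  long |>
    mutate(across(c("unique", "counts", "u0_counts", "highest_count",
                    "tpm", "sqrt"), as.numeric)) |>
    rename(sqrt_tpm = "sqrt")
}
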