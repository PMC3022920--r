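REPORT_CLASSES <- c("miRNA", "miscRNA", "pseudogene", "rRNA", "snRNA",
                    "snoRNA", "tRNA", "custom", "other")

#' Build the per-library processing report
#'
#' Accumulates read counts (not distinct-tag counts) into the standard
#' accounting rows: input, below-minimum-length, kept, the five
#' alignment strata, the annotatable total `U0&U1`, and per-annotation
#' class counts with percentages relative to `U0&U1`. The partition
#' identities `NM + R + U0 + U1 + U2 = kept` and
#' `sum(class counts incl. other) = U0&U1` hold on every input.
#'
#' @param alignment A `tag_alignment` covering every kept tag.
#' @param assignments Optional assignment tibble from
#'   [assign_transcripts()]; multi-locus tags are attributed to their
#'   single highest-overlap assignment for the class accounting only.
#' @param input Total read count entering the pipeline (pre-filter).
#' @param below_min_len Read count dropped as shorter than the minimum.
#' @return A `processing_report` tibble with `metric`, `reads`, `pct`.
#' @export
processing_report <- function(alignment, assignments = NULL,
                              input = NULL, below_min_len = 0) {
  tags <- alignment$tags
  kept <- sum(tags$count)
  if (is.null(input)) input <- kept + below_min_len
  stratum_reads <- vapply(STRATA, function(s) {
    sum(tags$count[tags$stratum == s])
  }, numeric(1))
  u01 <- stratum_reads[["U0"]] + stratum_reads[["U1"]]
  class_reads <- setNames(numeric(length(REPORT_CLASSES)), REPORT_CLASSES)
  if (u01 > 0) {
    annotated <- if (!is.null(assignments) && nrow(assignments) > 0) {
      assignments |>
        group_by(.data$tag_id) |>
        arrange(dplyr::desc(.data$overlap), .data$identifier, .by_group = TRUE) |>
        slice(1) |>
        ungroup() |>
        group_by(.data$rna_class) |>
        summarise(reads = sum(.data$count), .groups = "drop")
    } else {
      tibble(rna_class = character(), reads = numeric())
    }
    for (i in seq_len(nrow(annotated))) {
      class_reads[[annotated$rna_class[i]]] <- annotated$reads[i]
    }
    class_reads[["other"]] <- u01 - sum(class_reads[REPORT_CLASSES != "other"])
  }
  rows <- tibble(
    metric = c("input", "below_min_len", "kept", STRATA, "U0andU1",
               REPORT_CLASSES),
    reads = c(input, below_min_len, kept, unname(stratum_reads), u01,
              unname(class_reads)),
    pct = c(rep(NA_real_, 9),
            if (u01 > 0) round(100 * unname(class_reads) / u01, 2)
            else rep(0, length(REPORT_CLASSES)))
  )
  structure(rows, class = c("processing_report", class(rows)))
}

report_value <- function(report, metric) {
  report$reads[report$metric == metric]
}

#' Write a processing report as TSV
#'
#' @param report A [processing_report()] (or a combined multi-sample
#'   version with a `sample` column).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  readr::write_tsv(as_tibble(report), path, progress = FALSE)
  invisible(path)
}

#' @describeIn processing_report Bar chart of the stratum composition.
#' @param object,... Report and ignored arguments (autoplot interface).
#' @export
autoplot.processing_report <- function(object, ...) {
  d <- as_tibble(object) |>
    filter(.data$metric %in% STRATA) |>
    mutate(metric = factor(.data$metric, levels = STRATA))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$metric, y = .data$reads)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "alignment stratum", y = "reads",
                  title = "Library alignment composition") +
    ggplot2::theme_minimal()
}
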