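#' Write genome-browser BED track of tag placements
#'
#' Standard 6-column BED (0-based half-open), one line per placement,
#' with the score column holding the read count capped at 1000.
#'
#' @param placements Tibble with `chrom`, `start` (0-based), `end`
#'   (half-open), `name`, `count`, `strand`.
#' @param path Output path.
#' @param track_name Name written in the track header line.
#' @param chrom_sizes Optional named vector of chromosome lengths; when
#'   given, intervals outside a chromosome raise an error.
#' @return `path`, invisibly.
#' @export
write_bed <- function(placements, path, track_name = "mirprof_tags",
                      chrom_sizes = NULL) {
  check_track_intervals(placements, chrom_sizes)
  header <- sprintf('track name="%s" description="small RNA tag placements"',
                    track_name)
  if (nrow(placements) == 0) {
    writeLines(header, path)
    return(invisible(path))
  }
  score <- pmin(as.integer(placements$count), 1000L)
  body <- paste(placements$chrom, placements$start, placements$end,
                placements$name, score, placements$strand, sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write a variableStep WIG coverage track
#'
#' Per-base depth is the sum of counts of all placements covering the
#' base (span=1, positions 1-based), with one `variableStep`
#' declaration per chromosome.
#'
#' @inheritParams write_bed
#' @return `path`, invisibly.
#' @export
write_wig <- function(placements, path, track_name = "mirprof_coverage",
                      chrom_sizes = NULL) {
  check_track_intervals(placements, chrom_sizes)
  out <- sprintf('track type=wiggle_0 name="%s"', track_name)
  if (nrow(placements) > 0) {
    for (chr in sort(unique(placements$chrom))) {
      p <- placements[placements$chrom == chr, ]
      span <- range(c(p$start, p$end))
      offset <- span[1]
      depth <- numeric(span[2] - offset)
      for (i in seq_len(nrow(p))) {
        sel <- (p$start[i] - offset + 1L):(p$end[i] - offset)
        depth[sel] <- depth[sel] + p$count[i]
      }
      covered <- which(depth > 0)
      out <- c(out, sprintf("variableStep chrom=%s span=1", chr),
               paste(covered + offset, format(depth[covered], trim = TRUE,
                                              scientific = FALSE)))
    }
  }
  writeLines(out, path)
  invisible(path)
}

check_track_intervals <- function(placements, chrom_sizes) {
  need <- c("chrom", "start", "end", "count", "strand")
  missing <- setdiff(need, names(placements))
  if (length(missing)) {
    abort(sprintf("placements lack column(s): %s", paste(missing, collapse = ", ")))
  }
  if (nrow(placements) == 0) return(invisible(NULL))
  if (any(placements$start < 0 | placements$end <= placements$start)) {
    abort("invalid interval: need 0 <= start < end (0-based half-open)")
  }
  if (!is.null(chrom_sizes)) {
    unknown <- setdiff(unique(placements$chrom), names(chrom_sizes))
    if (length(unknown)) {
      abort(sprintf("placement on unknown chromosome '%s'", unknown[1]))
    }
    over <- placements$end > chrom_sizes[placements$chrom]
    if (any(over)) {
      i <- which(over)[1]
      abort(sprintf("interval %s:%d-%d extends past chromosome end",
                    placements$chrom[i], placements$start[i], placements$end[i]))
    }
  }
  invisible(NULL)
}
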