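CONFIG_KNOWN_KEYS <- c("samples", "genome", "annotation", "output_dir",
                       "adapter", "length", "align", "barcodes",
                       "normalize", "stats", "seed")

#' Load and validate a run-parameter config file
#'
#' The config is YAML. Mandatory keys: `samples` (a list of entries
#' with `name` and `reads`, optionally `format`, `group`, `barcode`),
#' `genome` (FASTA path) and `annotation` (TSV path). Optional
#' sections with their defaults: `adapter` (`sequence: CGCCTTGG`,
#' `max_mismatch: 1`), `length` (`min: 15`, `max: 32`), `align`
#' (`max_mismatch: 2`, `seed_len: 5`, or `import:` a TSV of external
#' alignments), `barcodes` (`policy: exact`, `tag_source:
#' inline_prefix`), `normalize` (`denominator: aligned_all`), `stats`
#' (`fdr: 0.05`, `fold: 1.5`, `min_tpm: 5`, `test: plain_t`,
#' `min_group_sum: 10`, `mab_tpm: 50`, `n_perm: 10000`), `output_dir`
#' (default `mirprof_out`), `seed`. Unknown keys produce a warning,
#' not an error.
#'
#' @param path Path to the YAML config.
#' @return A validated `run_config` list with defaults filled in.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file does not exist: %s", path))
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), CONFIG_KNOWN_KEYS)
  if (length(unknown)) {
    warn(sprintf("ignoring unknown config key(s): %s",
                 paste(unknown, collapse = ", ")))
  }
  for (key in c("samples", "genome", "annotation")) {
    if (is.null(raw[[key]])) abort(sprintf("config lacks mandatory key '%s'", key))
  }
  samples <- purrr::map(raw$samples, function(s) {
    if (is.null(s$name) || is.null(s$reads)) {
      abort("every sample entry needs 'name' and 'reads'")
    }
    list(name = s$name, reads = s$reads,
         format = s$format %||% "fastq",
         group = s$group %||% NA_character_,
         barcode = s$barcode %||% NULL)
  })
  for (p in c(raw$genome, raw$annotation,
              vapply(samples, `[[`, character(1), "reads"))) {
    if (!file.exists(p)) abort(sprintf("referenced path does not exist: %s", p))
  }
  cfg <- list(
    samples = samples,
    genome = raw$genome,
    annotation = raw$annotation,
    output_dir = raw$output_dir %||% "mirprof_out",
    adapter = trim_spec(raw$adapter$sequence %||% "CGCCTTGG",
                        raw$adapter$max_mismatch %||% 1L),
    length = length_spec(raw$length$min %||% 15L, raw$length$max %||% 32L),
    align = list(max_mismatch = raw$align$max_mismatch %||% 2L,
                 seed_len = raw$align$seed_len %||% 5L,
                 import = raw$align$import %||% NULL),
    barcodes = raw$barcodes %||% list(policy = "exact",
                                      tag_source = "inline_prefix"),
    normalize = list(denominator = raw$normalize$denominator %||% "aligned_all"),
    stats = list(fdr = raw$stats$fdr %||% 0.05,
                 fold = raw$stats$fold %||% 1.5,
                 min_tpm = raw$stats$min_tpm %||% 5,
                 test = raw$stats$test %||% "plain_t",
                 min_group_sum = raw$stats$min_group_sum %||% 10,
                 mab_tpm = raw$stats$mab_tpm %||% 50,
                 n_perm = raw$stats$n_perm %||% 10000),
    seed = raw$seed %||% 1L
  )
  structure(cfg, class = "run_config")
}

log_line <- function(con, fmt, ...) {
  msg <- sprintf(fmt, ...)
  writeLines(msg, con)
  message(msg)
}

#' Run the complete small-RNA processing pipeline
#'
#' Executes, per sample: (demultiplex where barcoded) -> adapter trim
#' -> length filter/truncation -> collapse to tags -> genome alignment
#' -> transcript assignment -> isomir quantification -> tpm
#' normalisation, then writes one combined expression table plus
#' per-sample BED, WIG and processing-report files. When sample
#' entries define at least two groups with two or more samples each,
#' the differential-expression and isomir global-test stages run as
#' well. Any stage error aborts with the stage and sample named, and
#' partially written outputs are removed.
#'
#' @param config A `run_config` from [load_config()] (or an equivalent
#'   list).
#' @return The output directory path, invisibly; outputs:
#'   `expression.tsv`, `<sample>.bed`, `<sample>.wig`,
#'   `<sample>_report.tsv`, `run.log`, and when groups are defined
#'   `diffexp.tsv` and `isomir_tests.tsv`.
#' @export
run_pipeline <- function(config) {
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  created <- character()
  out_path <- function(...) {
    p <- file.path(config$output_dir, paste0(...))
    created <<- c(created, p)
    p
  }
  log_con <- file(out_path("run.log"), open = "wt")
  on.exit(close(log_con), add = TRUE)
  stage <- "setup"
  current_sample <- ""
  result <- tryCatch({
    log_line(log_con, "adapter=%s max_mismatch=%d min_len=%d max_len=%d align_mm=%d denominator=%s seed=%d",
             config$adapter$adapter_prefix, config$adapter$max_mismatch,
             config$length$min_len, config$length$max_len,
             config$align$max_mismatch, config$normalize$denominator,
             config$seed)
    stage <- "annotation"
    annotation <- read_annotation(config$annotation)
    loci <- derive_arm_loci(annotation)
    transcripts <- transcript_table(loci)
    stage <- "genome index"
    index <- genome_index(config$genome, seed_len = config$align$seed_len)
    log_line(log_con, "genome: %d chromosome(s); annotation: %d loci",
             length(index$chrom_lengths), nrow(loci))

    stage <- "demultiplex"
    sample_reads <- list()
    by_file <- split(config$samples,
                     vapply(config$samples, `[[`, character(1), "reads"))
    for (entries in by_file) {
      first <- entries[[1]]
      reads <- read_reads(first$reads, first$format)
      barcoded <- !vapply(entries, function(e) is.null(e$barcode), logical(1))
      if (any(barcoded)) {
        tags <- vapply(entries[barcoded], `[[`, character(1), "barcode")
        names(tags) <- vapply(entries[barcoded], `[[`, character(1), "name")
        spec <- barcode_spec(tags,
                             policy = if (identical(config$barcodes$policy, "lev1"))
                               "levenshtein1" else config$barcodes$policy,
                             tag_source = config$barcodes$tag_source)
        demux <- demultiplex(reads, spec)
        log_line(log_con, "demultiplexed %s: %d reads, %d unassigned",
                 first$reads, nrow(reads), nrow(demux$unassigned))
        for (nm in names(tags)) sample_reads[[nm]] <- demux[[nm]]
      } else {
        for (e in entries) sample_reads[[e$name]] <- reads
      }
    }

    expr_rows <- list()
    isomir_rows <- list()
    denominators <- c()
    for (s in config$samples) {
      current_sample <- s$name
      reads <- sample_reads[[s$name]]
      input_reads <- sum(reads$count)
      stage <- "trim"
      tr <- trim_adapter(reads$sequence, config$adapter)
      reads$sequence <- tr$sequence
      reads$trimmed <- tr$trimmed
      stage <- "length filter"
      flt <- filter_and_truncate(reads, config$length)
      stage <- "collapse"
      tags <- collapse_tags(flt$kept)
      stage <- "align"
      alignment <- if (!is.null(config$align$import)) {
        read_alignment(config$align$import)
      } else {
        align_tags(tags, index, max_mismatch = config$align$max_mismatch)
      }
      stage <- "annotate"
      assignments <- assign_transcripts(alignment, loci)
      assignments$sample <- s$name
      stage <- "report"
      report <- processing_report(alignment, assignments,
                                  input = input_reads,
                                  below_min_len = flt$below_min)
      write_report(report, out_path(s$name, "_report.tsv"))
      log_line(log_con, "%s: input=%d kept=%d U0andU1=%d annotated_miRNA=%d",
               s$name, input_reads, report_value(report, "kept"),
               report_value(report, "U0andU1"), report_value(report, "miRNA"))
      stage <- "quantify"
      isomirs <- accumulate_isomirs(assignments)
      denominators[s$name] <- aligned_denominator(
        alignment, config$normalize$denominator)
      expr_rows[[s$name]] <- isomirs
      stage <- "tracks"
      u_tags <- alignment$tags |>
        filter(.data$stratum %in% c("U0", "U1"))
      placements <- alignment$placements |>
        filter(.data$tag_id %in% u_tags$tag_id) |>
        left_join(u_tags |> select("tag_id", "sequence", "count"),
                  by = "tag_id") |>
        mutate(name = .data$sequence)
      write_bed(placements, out_path(s$name, ".bed"),
                track_name = s$name, chrom_sizes = index$chrom_lengths)
      write_wig(placements, out_path(s$name, ".wig"),
                track_name = s$name, chrom_sizes = index$chrom_lengths)
    }
    current_sample <- ""
    stage <- "expression table"
    isomirs_all <- bind_rows(expr_rows)
    samples <- vapply(config$samples, `[[`, character(1), "name")
    expr <- summarize_expression(isomirs_all, transcripts, samples = samples)
    expr <- normalize_tpm(expr, denominators)
    write_expression_table(expr, samples, out_path("expression.tsv"))

    de <- NULL; gt <- NULL
    groups <- setNames(vapply(config$samples, `[[`, character(1), "group"),
                       samples)
    group_sizes <- table(groups[!is.na(groups)])
    if (length(group_sizes) == 2 && all(group_sizes >= 2)) {
      stage <- "diffexp"
      wide <- expr |>
        select("identifier", "sample", "tpm") |>
        tidyr::pivot_wider(names_from = "sample", values_from = "tpm")
      de <- diff_expression(
        wide, groups[setdiff(names(wide), "identifier")],
        de_params(config$stats$fdr, config$stats$fold, config$stats$min_tpm,
                  config$stats$test))
      readr::write_tsv(tidy(de), out_path("diffexp.tsv"), progress = FALSE)
      log_line(log_con, "diffexp: %d/%d significant",
               sum(de$significant), nrow(de))
      stage <- "isomir tests"
      iso_tpm <- isomirs_all |>
        left_join(tibble(sample = names(denominators),
                         denom = unname(denominators)), by = "sample") |>
        mutate(tpm = .data$count / .data$denom * 1e6) |>
        filter(.data$identifier %in% mirna_identifiers(expr))
      gt <- isomir_global_tests(iso_tpm, groups,
                                min_group_sum = config$stats$min_group_sum,
                                mab_tpm = config$stats$mab_tpm,
                                n_perm = config$stats$n_perm,
                                seed = config$seed)
      readr::write_tsv(as_tibble(gt) |> select(-"fits"),
                       out_path("isomir_tests.tsv"), progress = FALSE)
      log_line(log_con, "global test: %d/%d miRNAs at q<=0.05",
               sum(gt$q <= 0.05), nrow(gt))
    }
    invisible(config$output_dir)
  }, error = function(e) {
    for (p in created) if (file.exists(p) && !grepl("run\\.log$", p)) unlink(p)
    abort(sprintf("pipeline failed at stage '%s'%s: %s", stage,
                  if (nzchar(current_sample)) paste0(" (sample ", current_sample, ")") else "",
                  conditionMessage(e)))
  })
  result
}

mirna_identifiers <- function(expr) {
  unique(expr$identifier[startsWith(expr$identifier, "miRNA|")])
}
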