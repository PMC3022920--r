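# Shared fixture builders; everything is generated in code at test time.

write_lines_tmp <- function(lines, ext) {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# tiny annotation: one precursor with both arms, one with a single arm,
# plus a snoRNA
tiny_annotation <- function() {
  tibble::tribble(
    ~rna_class, ~transcript_id, ~name, ~chrom, ~start, ~end, ~strand, ~arm, ~inferred,
    "miRNA", "T1", "mir-1", "chr1", 1001, 1070, "+", "none", FALSE,
    "miRNA", "T1", "mir-1", "chr1", 1005, 1026, "+", "5p", FALSE,
    "miRNA", "T1", "mir-1", "chr1", 1047, 1068, "+", "3p", FALSE,
    "miRNA", "T2", "mir-2", "chr1", 2001, 2070, "+", "none", FALSE,
    "miRNA", "T2", "mir-2", "chr1", 2005, 2026, "+", "5p", FALSE,
    "snoRNA", "S1", "sno-1", "chr1", 3001, 3100, "+", "none", FALSE
  )
}

# deterministic mini study: reference + one library, small enough for
# fast per-test pipeline runs
mini_reference <- function(seed = 42, n_precursors = 8) {
  cfg <- mirprof::sim_config(seed = seed, n_precursors = n_precursors,
                             genome_length = 16000, depth = 4000)
  list(config = cfg, reference = mirprof::simulate_reference(cfg))
}

run_mini_pipeline_dir <- function(dir, seed = 42, groups = NULL,
                                  n_samples = 1, depth = 3000) {
  cfg <- mirprof::sim_config(seed = seed, n_precursors = 6,
                             genome_length = 12000, depth = depth)
  ref <- mirprof::simulate_reference(cfg)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(paste0(">", names(ref$genome), "\n", ref$genome),
             file.path(dir, "genome.fa"))
  mirprof::write_annotation(ref$annotation, file.path(dir, "annotation.tsv"))
  samples <- list()
  for (i in seq_len(n_samples)) {
    nm <- paste0("s", i)
    lib <- mirprof::simulate_library(cfg, ref, nm, seed = cfg$seed + i)
    mirprof::write_reads(lib$reads, file.path(dir, paste0(nm, ".fastq")), "fastq")
    samples[[i]] <- list(name = nm, reads = file.path(dir, paste0(nm, ".fastq")),
                         format = "fastq",
                         group = if (is.null(groups)) NULL else groups[i])
  }
  cfg_yaml <- list(samples = samples, genome = file.path(dir, "genome.fa"),
                   annotation = file.path(dir, "annotation.tsv"),
                   output_dir = file.path(dir, "out"))
  yaml::write_yaml(cfg_yaml, file.path(dir, "config.yaml"))
  file.path(dir, "config.yaml")
}
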