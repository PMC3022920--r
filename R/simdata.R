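#' Simulation configuration for synthetic small-RNA libraries
#'
#' Bundles every knob of the synthetic study: genome and precursor
#' geometry, the log-normal per-arm expression profile, the isomir
#' model (geometric 5'/3' end offsets, non-templated 3' additions,
#' internal substitutions), the ligated 3' adapter (beginning with the
#' 8-nt `CGCCTTGG` prefix the trimmer anchors on), fixed read length,
#' optional 6-nt barcodes, the unalignable-noise fraction and library
#' depth. Defaults describe the package's standard validation study:
#' 50 precursors, 100,000 reads.
#'
#' @param seed Integer seed driving all randomness, in documented
#'   order (reference first, then each library).
#' @param genome_length Total random-genome length in bp.
#' @param n_chrom Number of chromosomes the genome is split into.
#' @param n_precursors Number of non-overlapping hairpin precursors.
#' @param precursor_len Range of precursor lengths (bp).
#' @param arm_len Range of mature arm lengths (nt), default 20-24.
#' @param frac_one_arm Fraction of precursors annotated with only one
#'   arm (the other is left for inference).
#' @param expr_meanlog,expr_sdlog Log-normal parameters of the per-arm
#'   expression weights.
#' @param iso_p3,iso_p5 Geometric success probabilities of the 3' and
#'   5' end-offset magnitudes (larger = tighter ends).
#' @param nta_prob Probability of a non-templated 3' A/T addition.
#' @param sub_prob Probability of one internal substitution per read.
#' @param adapter Full 3' adapter sequence ligated after the insert.
#' @param read_length Sequencer read length (nt).
#' @param barcodes Optional named vector sample -> 6-nt tag; reads are
#'   then emitted with the tag as an inline prefix.
#' @param depth Reads per library.
#' @param noise_frac Fraction of random unalignable reads.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, genome_length = 50000L, n_chrom = 2L,
                       n_precursors = 50L, precursor_len = c(70L, 100L),
                       arm_len = c(20L, 24L), frac_one_arm = 0.3,
                       expr_meanlog = 0, expr_sdlog = 1.5,
                       iso_p3 = 0.6, iso_p5 = 0.8, nta_prob = 0.05,
                       sub_prob = 0.02,
                       adapter = "CGCCTTGGTGTCAGTCACTTAGCA",
                       read_length = 32L, barcodes = NULL,
                       depth = 100000L, noise_frac = 0.02) {
  adapter <- toupper(adapter)
  check_dna(adapter, "adapter")
  if (!startsWith(adapter, "CGCCTTGG")) {
    warn("adapter does not start with the canonical CGCCTTGG prefix")
  }
  if (genome_length < n_precursors * 200) {
    abort("genome_length must be at least n_precursors * 200 for feasible packing")
  }
  structure(list(seed = as.integer(seed), genome_length = as.integer(genome_length),
                 n_chrom = as.integer(n_chrom),
                 n_precursors = as.integer(n_precursors),
                 precursor_len = as.integer(precursor_len),
                 arm_len = as.integer(arm_len), frac_one_arm = frac_one_arm,
                 expr_meanlog = expr_meanlog, expr_sdlog = expr_sdlog,
                 iso_p3 = iso_p3, iso_p5 = iso_p5, nta_prob = nta_prob,
                 sub_prob = sub_prob, adapter = adapter,
                 read_length = as.integer(read_length), barcodes = barcodes,
                 depth = as.integer(depth), noise_frac = noise_frac),
            class = "sim_config")
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

#' Simulate a reference genome and precursor annotation
#'
#' Draws a uniform-random genome split over `n_chrom` chromosomes and
#' places non-overlapping miRNA precursors on random strands. Each
#' precursor carries a 5p and a 3p arm positioned so the two form a
#' duplex with 2-nt 3' overhangs (the inferred-arm geometry); for a
#' `frac_one_arm` fraction only one arm is written to the annotation,
#' exercising arm inference downstream. The truth table records both
#' arms' genomic coordinates for every precursor.
#'
#' @param config A [sim_config()].
#' @return List: `genome` (named character vector), `annotation`
#'   (annotation tibble with precursor and annotated-arm rows), and
#'   `arm_truth` (tibble of every arm's true coordinates, with
#'   `annotated` flag).
#' @export
simulate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  chrom_len <- rep(config$genome_length %/% config$n_chrom, config$n_chrom)
  chrom_len[1] <- chrom_len[1] + config$genome_length %% config$n_chrom
  genome <- setNames(vapply(chrom_len, random_dna, character(1)),
                     paste0("chr", seq_len(config$n_chrom)))
  ann_rows <- list()
  truth_rows <- list()
  if (config$n_precursors > 0) {
    # non-overlapping placement: per chromosome, slots with margin
    slot <- max(config$precursor_len) + 50L
    slots_per_chrom <- pmax((chrom_len - 50L) %/% slot, 0L)
    slot_tbl <- tibble(
      chrom = rep(names(genome), slots_per_chrom),
      slot_start = unlist(lapply(seq_along(chrom_len), function(i) {
        if (slots_per_chrom[i] == 0) integer() else
          25L + (seq_len(slots_per_chrom[i]) - 1L) * slot
      }))
    )
    if (nrow(slot_tbl) < config$n_precursors) {
      abort("infeasible precursor packing: genome too short for requested count")
    }
    chosen <- slot_tbl[sort(sample(nrow(slot_tbl), config$n_precursors)), ]
    for (i in seq_len(config$n_precursors)) {
      L <- sample(config$precursor_len[1]:config$precursor_len[2], 1)
      p_start <- chosen$slot_start[i] + sample(0:20, 1)
      p_end <- p_start + L - 1L
      strand <- sample(c("+", "-"), 1)
      tid <- sprintf("SIMT%08d", i)
      name <- sprintf("sim-mir-%d", i)
      len5 <- sample(config$arm_len[1]:config$arm_len[2], 1)
      off5 <- sample(1:4, 1)  # relative start of the 5p arm
      p5 <- c(off5, off5 + len5 - 1L)
      p3 <- c(L + 1 - p5[2] + 2, L + 1 - p5[1] + 2)
      p3[2] <- min(p3[2], L)
      rel2gen <- function(rel) {
        if (strand == "+") c(p_start + rel[1] - 1L, p_start + rel[2] - 1L)
        else c(p_end - rel[2] + 1L, p_end - rel[1] + 1L)
      }
      g5 <- rel2gen(p5); g3 <- rel2gen(p3)
      annotate_both <- runif(1) >= config$frac_one_arm
      annotated_arm <- sample(c("5p", "3p"), 1)
      arm_tbl <- tibble(
        arm = c("5p", "3p"),
        start = c(g5[1], g3[1]), end = c(g5[2], g3[2]),
        annotated = annotate_both | (c("5p", "3p") == annotated_arm))
      ann_rows[[i]] <- bind_rows(
        tibble(rna_class = "miRNA", transcript_id = tid, name = name,
               chrom = chosen$chrom[i], start = p_start, end = p_end,
               strand = strand, arm = "none", inferred = FALSE),
        tibble(rna_class = "miRNA", transcript_id = tid, name = name,
               chrom = chosen$chrom[i],
               start = arm_tbl$start[arm_tbl$annotated],
               end = arm_tbl$end[arm_tbl$annotated],
               strand = strand, arm = arm_tbl$arm[arm_tbl$annotated],
               inferred = FALSE))
      truth_rows[[i]] <- arm_tbl |>
        mutate(transcript_id = tid, name = name, chrom = chosen$chrom[i],
               strand = strand, precursor_start = p_start,
               precursor_end = p_end)
    }
  }
  annotation <- if (length(ann_rows)) validate_annotation(bind_rows(ann_rows)) else {
    tibble(rna_class = character(), transcript_id = character(),
           name = character(), chrom = character(), start = numeric(),
           end = numeric(), strand = character(), arm = character(),
           inferred = logical())
  }
  arm_truth <- if (length(truth_rows)) bind_rows(truth_rows) else tibble()
  list(genome = genome, annotation = annotation, arm_truth = arm_truth)
}

subseq_chr <- function(s, from, to) substr(s, from, to)

#' Simulate a small-RNA sequencing library with full truth
#'
#' Draws reads from the reference arms under a log-normal expression
#' profile. Each read is an isomir variant of its source arm (geometric
#' 5'/3' end offsets, optional non-templated 3' addition, optional
#' internal substitution), strand-correct, with the 3' adapter
#' appended and the whole truncated to the read length; a
#' `noise_frac` fraction of reads is random unalignable sequence.
#' Every generative choice is recorded in the truth table.
#'
#' @param config A [sim_config()].
#' @param reference Output of [simulate_reference()].
#' @param sample_name Sample name recorded in ids and truth rows.
#' @param arm_weights Optional named numeric vector
#'   (`transcript_id|arm` -> relative weight) overriding the random
#'   log-normal profile, e.g. to plant fold changes between groups.
#' @param seed Seed for this library draw (defaults to
#'   `config$seed + 1`).
#' @param barcode Optional 6-nt tag prepended inline to every read.
#' @return List: `reads` (tibble `read_id`, `sequence`, `quality`,
#'   `count`), `truth` (read-level tibble: source arm, offsets, edits,
#'   the arm's true proportion), and `arm_profile` (tibble
#'   `arm_id`, `true_prop`, noise row included).
#' @export
simulate_library <- function(config, reference, sample_name = "sample1",
                             arm_weights = NULL, seed = config$seed + 1L,
                             barcode = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  truth <- reference$arm_truth
  if (nrow(truth) == 0) abort("reference contains no arms to express")
  arm_id <- paste(truth$transcript_id, truth$arm, sep = "|")
  if (is.null(arm_weights)) {
    w <- rlnorm(nrow(truth), config$expr_meanlog, config$expr_sdlog)
  } else {
    w <- unname(arm_weights[arm_id])
    if (any(is.na(w))) abort("arm_weights must cover every 'transcript_id|arm'")
  }
  n_noise <- rbinom(1, config$depth, config$noise_frac)
  n_real <- config$depth - n_noise
  props <- w / sum(w)
  arm_profile <- tibble(arm_id = c(arm_id, "noise"),
                        true_prop = c(props * (1 - config$noise_frac),
                                      config$noise_frac))
  pick <- sample(nrow(truth), n_real, replace = TRUE, prob = props)
  d5 <- ifelse(runif(n_real) < 0.5, 0,
               sample(c(-1L, 1L), n_real, replace = TRUE) *
                 (1L + stats::rgeom(n_real, config$iso_p5)))
  d3 <- ifelse(runif(n_real) < 0.4, 0,
               sample(c(-1L, 1L), n_real, replace = TRUE) *
                 (1L + stats::rgeom(n_real, config$iso_p3)))
  d5 <- pmax(pmin(d5, 3L), -3L)
  d3 <- pmax(pmin(d3, 4L), -4L)
  nta <- runif(n_real) < config$nta_prob
  nsub <- as.integer(runif(n_real) < config$sub_prob)
  # end offsets in arm (5'->3') orientation; d5 moves the 5' end, d3
  # the 3' end, positive values extend the insert outward
  arm <- truth[pick, ]
  plus <- arm$strand == "+"
  g1 <- ifelse(plus, arm$start - d5, arm$start - d3)
  g2 <- ifelse(plus, arm$end + d3, arm$end + d5)
  chrom_len <- nchar(reference$genome)[arm$chrom]
  g1 <- pmax(1L, g1); g2 <- pmin(chrom_len, g2)
  inserts <- unname(substring(reference$genome[arm$chrom], g1, g2))
  if (any(!plus)) {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(inserts[!plus])))
    inserts[!plus] <- unname(rc)
  }
  for (i in which(nsub > 0 & nchar(inserts) > 4)) {
    s <- inserts[i]
    pos <- sample(3:(nchar(s) - 2), 1)
    old <- substr(s, pos, pos)
    substr(s, pos, pos) <- sample(setdiff(DNA_BASES, old), 1)
    inserts[i] <- s
  }
  add <- which(nta)
  if (length(add)) {
    inserts[add] <- paste0(inserts[add],
                           sample(c("A", "T"), length(add), replace = TRUE))
  }
  noise_seqs <- vapply(rep.int(22L, n_noise), random_dna, character(1))
  all_inserts <- c(inserts, noise_seqs)
  reads_seq <- substr(paste0(all_inserts, config$adapter), 1,
                      config$read_length)
  if (!is.null(barcode)) reads_seq <- paste0(toupper(barcode), reads_seq)
  ord <- sample(length(reads_seq))  # shuffle arm and noise reads together
  read_id <- sprintf("%s_r%06d", sample_name, seq_along(reads_seq))
  reads <- tibble(read_id = read_id, sequence = reads_seq[ord],
                  quality = strrep("I", nchar(reads_seq[ord])), count = 1L)
  truth_tbl <- tibble(
    read_id = read_id,
    sample = sample_name,
    arm_id = c(arm_id[pick], rep.int("noise", n_noise))[ord],
    d5 = c(d5, rep.int(NA_integer_, n_noise))[ord],
    d3 = c(d3, rep.int(NA_integer_, n_noise))[ord],
    n_sub = c(nsub, rep.int(NA_integer_, n_noise))[ord],
    nta = c(nta, rep.int(NA, n_noise))[ord],
    insert = all_inserts[ord],
    true_prop = arm_profile$true_prop[
      match(c(arm_id[pick], rep.int("noise", n_noise))[ord],
            arm_profile$arm_id)]
  )
  list(reads = reads, truth = truth_tbl, arm_profile = arm_profile)
}

#' Write / read the simulation truth table
#'
#' Read-level truth as a TSV with fixed, documented columns
#' (`read_id`, `sample`, `arm_id`, `d5`, `d3`, `n_sub`, `nta`,
#' `insert`, `true_prop`); round-trips through [read_truth()].
#'
#' @param truth Truth tibble from [simulate_library()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  cols <- c("read_id", "sample", "arm_id", "d5", "d3", "n_sub", "nta",
            "insert", "true_prop")
  readr::write_tsv(truth[cols], path, progress = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    read_id = readr::col_character(), sample = readr::col_character(),
    arm_id = readr::col_character(), d5 = readr::col_integer(),
    d3 = readr::col_integer(), n_sub = readr::col_integer(),
    nta = readr::col_logical(), insert = readr::col_character(),
    true_prop = readr::col_double()), progress = FALSE)
}

#' Write all simulation outputs to a directory
#'
#' Produces `genome.fa`, `annotation.tsv`, `reads.fastq` and
#' `truth.tsv` under `dir`.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @param sample_name Library sample name.
#' @return `dir`, invisibly.
#' @export
simulate_to_dir <- function(config, dir, sample_name = "sample1") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ref <- simulate_reference(config)
  lib <- simulate_library(config, ref, sample_name = sample_name)
  writeLines(paste0(">", names(ref$genome), "\n", ref$genome),
             file.path(dir, "genome.fa"))
  write_annotation(ref$annotation, file.path(dir, "annotation.tsv"))
  write_reads(lib$reads, file.path(dir, "reads.fastq"), "fastq")
  write_truth(lib$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}
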