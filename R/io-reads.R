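#' Read small-RNA sequencing reads
#'
#' Parses one of the three supported read formats into a tidy tibble.
#' FASTQ is the standard 4-line-per-record layout; SCARF is the legacy
#' single-line, colon-delimited Illumina format (sequence in the
#' second-to-last field, quality in the last, the joined leading fields
#' forming the read id); tagcount is a two-column `sequence<TAB>count`
#' table of pre-collapsed tags.
#'
#' @param path Path to the input file.
#' @param format One of `"fastq"`, `"scarf"`, `"tagcount"`. Never sniffed.
#' @return A tibble with columns `read_id`, `sequence` (upper-cased),
#'   `quality` (empty string where the format carries none) and `count`
#'   (1 for fastq/scarf; the stated count for tagcount). Input order is
#'   preserved.
#' @examples
#' fq <- tempfile(fileext = ".fastq")
#' writeLines(c("@r1", "ACGTACGTACGTACG", "+", "IIIIIIIIIIIIIII"), fq)
#' read_reads(fq, "fastq")
#' @export
read_reads <- function(path, format = c("fastq", "scarf", "tagcount")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("read file does not exist: %s", path))
  lines <- readLines(path, warn = FALSE)
  switch(format,
    fastq = parse_fastq_lines(lines, path),
    scarf = parse_scarf_lines(lines, path),
    tagcount = parse_tagcount_lines(lines, path)
  )
}

parse_error <- function(path, line, msg) {
  abort(sprintf("parse error in '%s' at line %d: %s", path, line, msg))
}

parse_fastq_lines <- function(lines, path) {
  n <- length(lines)
  if (n == 0) {
    return(tibble(read_id = character(), sequence = character(),
                  quality = character(), count = integer()))
  }
  if (n %% 4 != 0) parse_error(path, n, "truncated FASTQ record (file length not a multiple of 4)")
  idx <- seq(1, n, by = 4)
  hdr <- lines[idx]
  seqs <- toupper(lines[idx + 1])
  plus <- lines[idx + 2]
  qual <- lines[idx + 3]
  bad_hdr <- !startsWith(hdr, "@")
  if (any(bad_hdr)) parse_error(path, idx[which(bad_hdr)[1]], "expected '@' header")
  bad_plus <- !startsWith(plus, "+")
  if (any(bad_plus)) parse_error(path, idx[which(bad_plus)[1]] + 2L, "expected '+' separator")
  bad_len <- nchar(seqs) != nchar(qual) | nchar(seqs) == 0
  if (any(bad_len)) {
    parse_error(path, idx[which(bad_len)[1]] + 3L,
                "quality length does not match sequence length")
  }
  check_dna(seqs, sprintf("sequence in '%s'", path))
  tibble(read_id = sub("^@", "", hdr), sequence = seqs,
         quality = qual, count = 1L)
}

parse_scarf_lines <- function(lines, path) {
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble(read_id = character(), sequence = character(),
                  quality = character(), count = integer()))
  }
  parts <- strsplit(lines, ":", fixed = TRUE)
  nf <- lengths(parts)
  bad <- nf < 3
  if (any(bad)) parse_error(path, which(bad)[1], "SCARF line has fewer than 3 ':'-separated fields")
  seqs <- toupper(mapply(function(p, k) p[k - 1], parts, nf))
  qual <- mapply(function(p, k) p[k], parts, nf)
  ids <- mapply(function(p, k) paste(p[seq_len(k - 2)], collapse = ":"), parts, nf)
  bad_len <- nchar(seqs) != nchar(qual) | nchar(seqs) == 0
  if (any(bad_len)) {
    parse_error(path, which(bad_len)[1], "quality length does not match sequence length")
  }
  check_dna(seqs, sprintf("sequence in '%s'", path))
  tibble(read_id = ids, sequence = seqs, quality = qual, count = 1L)
}

parse_tagcount_lines <- function(lines, path) {
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble(read_id = character(), sequence = character(),
                  quality = character(), count = integer()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) != 2
  if (any(bad)) parse_error(path, which(bad)[1], "expected 'sequence<TAB>count'")
  seqs <- toupper(vapply(parts, `[`, character(1), 1))
  cnt_chr <- vapply(parts, `[`, character(1), 2)
  bad_cnt <- !grepl("^[0-9]+$", cnt_chr)
  if (any(bad_cnt)) parse_error(path, which(bad_cnt)[1], "count is not a non-negative integer")
  check_dna(seqs, sprintf("sequence in '%s'", path))
  tibble(read_id = paste0("tag", seq_along(seqs)), sequence = seqs,
         quality = "", count = as.integer(cnt_chr))
}

#' Write reads in FASTQ or tagcount form
#'
#' Companion writer used by the simulator and for round-trip checks.
#'
#' @param reads Tibble with `read_id`, `sequence`, `quality`, `count`.
#' @param path Output path.
#' @param format `"fastq"` (quality filled with `"I"` when empty) or
#'   `"tagcount"`.
#' @return `path`, invisibly.
#' @export
write_reads <- function(reads, path, format = c("fastq", "tagcount")) {
  format <- match.arg(format)
  if (format == "fastq") {
    qual <- ifelse(nzchar(reads$quality), reads$quality,
                   strrep("I", nchar(reads$sequence)))
    writeLines(rbind(paste0("@", reads$read_id), reads$sequence, "+", qual),
               path)
  } else {
    writeLines(paste(reads$sequence, reads$count, sep = "\t"), path)
  }
  invisible(path)
}
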