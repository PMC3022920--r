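RNA_CLASSES <- c("miRNA", "miscRNA", "pseudogene", "rRNA", "snRNA",
                 "snoRNA", "tRNA", "custom")

ANNOTATION_COLS <- c("rna_class", "transcript_id", "name", "chrom",
                     "start", "end", "strand", "arm", "inferred")

#' Read a non-coding RNA annotation table
#'
#' The annotation is a 9-column tab-delimited table with a header naming
#' `rna_class`, `transcript_id`, `name`, `chrom`, `start`, `end`,
#' `strand`, `arm`, `inferred`. Coordinates are 1-based inclusive.
#' miRNA precursor rows carry `arm = "none"`; their mature 5p/3p product
#' rows share the precursor's `transcript_id`. Non-miRNA classes must
#' have `arm = "none"`.
#'
#' @param path Path to the TSV.
#' @return Validated tibble of annotation records.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) abort(sprintf("annotation file does not exist: %s", path))
  df <- readr::read_tsv(path, col_types = readr::cols(
    rna_class = readr::col_character(),
    transcript_id = readr::col_character(),
    name = readr::col_character(),
    chrom = readr::col_character(),
    start = readr::col_double(),
    end = readr::col_double(),
    strand = readr::col_character(),
    arm = readr::col_character(),
    inferred = readr::col_logical()
  ), progress = FALSE)
  missing <- setdiff(ANNOTATION_COLS, names(df))
  if (length(missing)) {
    abort(sprintf("annotation header lacks column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  df <- as_tibble(df[ANNOTATION_COLS])
  df$name <- ifelse(is.na(df$name), "", df$name)
  validate_annotation(df)
}

validate_annotation <- function(df) {
  row_err <- function(i, msg) {
    abort(sprintf("invalid annotation row %d (%s): %s", i,
                  df$transcript_id[i], msg))
  }
  bad <- which(!df$rna_class %in% RNA_CLASSES)
  if (length(bad)) row_err(bad[1], sprintf("unknown class '%s'", df$rna_class[bad[1]]))
  bad <- which(!df$strand %in% c("+", "-"))
  if (length(bad)) row_err(bad[1], sprintf("unknown strand '%s'", df$strand[bad[1]]))
  bad <- which(df$start > df$end)
  if (length(bad)) row_err(bad[1], "start > end")
  bad <- which(df$start < 1)
  if (length(bad)) row_err(bad[1], "start < 1 (coordinates are 1-based)")
  bad <- which(!df$arm %in% c("5p", "3p", "none"))
  if (length(bad)) row_err(bad[1], sprintf("unknown arm '%s'", df$arm[bad[1]]))
  bad <- which(df$arm != "none" & df$rna_class != "miRNA")
  if (length(bad)) row_err(bad[1], "arm set on a non-miRNA record")
  key <- paste(df$transcript_id, df$arm)
  bad <- which(duplicated(key))
  if (length(bad)) row_err(bad[1], "duplicate transcript_id + arm pair")
  df
}

#' Write an annotation table
#'
#' @param annotation Tibble as returned by [read_annotation()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotation, path) {
  readr::write_tsv(annotation[ANNOTATION_COLS], path, progress = FALSE)
  invisible(path)
}
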