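test_that("missing-arm inference reflects through the hairpin with the 2-nt shift", {
  prec <- tibble::tibble(chrom = "chr1", start = 1001, end = 1070, strand = "+")
  known <- tibble::tibble(arm = "5p", start = 1005, end = 1026)
  inf <- infer_missing_arm(prec, known)
  expect_equal(inf$arm, "3p")
  expect_equal(c(inf$start, inf$end), c(1047, 1068))
  expect_true(inf$inferred)
  expect_false(inf$clamped)
})

test_that("inference clamps at the precursor edge and flags it", {
  # L = 60, known 5p relative [1, 22] -> reflected [39, 60] -> shifted
  # [41, 62] -> clamped [41, 60]
  prec <- tibble::tibble(chrom = "chr1", start = 101, end = 160, strand = "+")
  known <- tibble::tibble(arm = "5p", start = 101, end = 122)
  inf <- infer_missing_arm(prec, known)
  expect_equal(c(inf$start, inf$end), c(141, 160))
  expect_true(inf$clamped)
  expect_equal(inf$end - inf$start + 1, 20)
})

test_that("minus-strand inference mirrors the genomic conversion", {
  # 30-nt toy precursor on the minus strand, genomic 201..230.
  # Precursor-relative position r maps to genomic 230 - r + 1.
  # Known 5p at relative [3, 10] => genomic [221, 228].
  prec <- tibble::tibble(chrom = "chr1", start = 201, end = 230, strand = "-")
  known <- tibble::tibble(arm = "5p", start = 221, end = 228)
  inf <- infer_missing_arm(prec, known)
  # reflection of [3,10] in L=30: [21,28]; +2 shift: [23,30]
  # genomic: [230-30+1, 230-23+1] = [201, 208]
  expect_equal(c(inf$start, inf$end), c(201, 208))
  expect_equal(inf$strand, "-")
})

test_that("known arm outside the precursor is an error", {
  prec <- tibble::tibble(chrom = "chr1", start = 1001, end = 1070, strand = "+")
  expect_error(infer_missing_arm(prec, tibble::tibble(arm = "5p", start = 900,
                                                      end = 930)),
               "outside")
})

test_that("re-inferring from the inferred arm returns the original interval", {
  set.seed(53)
  for (i in 1:20) {
    L <- sample(60:100, 1)
    p_start <- sample(1000:5000, 1)
    strand <- sample(c("+", "-"), 1)
    prec <- tibble::tibble(chrom = "chr1", start = p_start,
                           end = p_start + L - 1, strand = strand)
    a <- sort(sample(5:28, 1) + c(0, sample(19:23, 1)))
    known <- if (strand == "+") {
      tibble::tibble(arm = "5p", start = p_start + a[1] - 1,
                     end = p_start + a[2] - 1)
    } else {
      tibble::tibble(arm = "5p", start = prec$end - a[2] + 1,
                     end = prec$end - a[1] + 1)
    }
    inf <- infer_missing_arm(prec, known)
    if (inf$clamped) next
    back <- infer_missing_arm(prec, inf)
    expect_equal(back$arm, "5p")
    expect_equal(c(back$start, back$end), c(known$start, known$end))
  }
})

test_that("every precursor yields exactly two arm loci", {
  loci <- derive_arm_loci(tiny_annotation())
  mir <- loci[loci$rna_class == "miRNA", ]
  expect_equal(nrow(mir), 4)  # 2 precursors x 2 arms
  expect_equal(sum(mir$inferred), 1)  # T2's 3p was inferred
  t2 <- mir[mir$transcript_id == "T2", ]
  expect_setequal(t2$arm, c("5p", "3p"))
  # inferred T2 3p: reflect [5,26] in L=70 -> [45,66], +2 -> [47,68]
  expect_equal(t2$start[t2$arm == "3p"], 2047)
  expect_equal(t2$end[t2$arm == "3p"], 2068)
  # non-miRNA record passes through as an 'n' locus
  expect_equal(loci$arm[loci$rna_class == "snoRNA"], "n")
  # precursor with no arm at all is skipped with a warning
  ann <- tiny_annotation()[c(1, 4, 5), ]  # T1 precursor only, T2 complete
  expect_warning(loci2 <- derive_arm_loci(ann), "skipped")
  expect_false("T1" %in% loci2$transcript_id)
})

test_that("identifiers follow class|id|arm[~]|name|orientation", {
  locus <- tibble::tibble(rna_class = "miRNA",
                          transcript_id = "ENSGALT00000028942", arm = "5p",
                          inferred = TRUE, name = "gga-mir-29a")
  expect_equal(build_identifier(locus, "sense"),
               "miRNA|ENSGALT00000028942|5p~|gga-mir-29a|sense")
  locus$inferred <- FALSE
  locus$arm <- "3p"
  expect_equal(build_identifier(locus, "antisense"),
               "miRNA|ENSGALT00000028942|3p|gga-mir-29a|antisense")
  sno <- tibble::tibble(rna_class = "snoRNA", transcript_id = "SNO1",
                        arm = "n", inferred = FALSE, name = "snord-1")
  expect_equal(build_identifier(sno, "sense"), "snoRNA|SNO1|n|snord-1|sense")
})

make_alignment <- function(placements, strata = NULL) {
  tags <- tibble::tibble(tag_id = seq_len(nrow(placements)),
                         sequence = placements$sequence,
                         count = placements$count,
                         stratum = strata %||% rep("U0", nrow(placements)),
                         n_placements = 1L)
  pl <- placements
  pl$tag_id <- tags$tag_id
  pl$end <- pl$start + nchar(pl$sequence)
  structure(list(tags = tags,
                 placements = pl[c("tag_id", "chrom", "start", "end",
                                   "strand", "mismatches")],
                 max_mismatch = 2L), class = "tag_alignment")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("the 50% overlap boundary is inclusive and measured on the tag", {
  loci <- derive_arm_loci(tiny_annotation())
  # locus T1 5p: chr1:1005-1026 (+). 22-nt tag overlapping by exactly 11
  # bases: placement 1-based 1016..1037 -> 0-based start 1015
  pl <- tibble::tibble(
    sequence = c(strrep("A", 22), strrep("C", 22)),
    count = c(4L, 6L),
    chrom = "chr1", start = c(1015L, 1016L), strand = "+", mismatches = 0L)
  al <- make_alignment(pl)
  asn <- assign_transcripts(al, loci)
  expect_true(1L %in% asn$tag_id)         # 11/22 assigned (boundary)
  expect_equal(asn$overlap[asn$tag_id == 1L], 11L)
  expect_false(2L %in% asn$tag_id)        # 10/22 falls short
})

test_that("antisense placements are assigned with antisense orientation", {
  loci <- derive_arm_loci(tiny_annotation())
  pl <- tibble::tibble(sequence = strrep("G", 22), count = 1L, chrom = "chr1",
                       start = 1004L, strand = "-", mismatches = 0L)
  asn <- assign_transcripts(make_alignment(pl), loci)
  expect_equal(asn$orientation, "antisense")
  expect_match(asn$identifier, "antisense$")
})

test_that("only U0/U1 tags are assignable and multi-locus hits are all reported", {
  loci <- derive_arm_loci(tibble::tribble(
    ~rna_class, ~transcript_id, ~name, ~chrom, ~start, ~end, ~strand, ~arm, ~inferred,
    "miRNA", "T1", "m1", "chr1", 1001, 1070, "+", "none", FALSE,
    "miRNA", "T1", "m1", "chr1", 1005, 1026, "+", "5p", FALSE,
    "miRNA", "T1", "m1", "chr1", 1041, 1062, "+", "3p", FALSE,
    "custom", "C1", "roi", "chr1", 1001, 1100, "+", "none", FALSE))
  pl <- tibble::tibble(sequence = rep(strrep("A", 22), 3), count = 1L,
                       chrom = "chr1", start = c(1004L, 1004L, 1004L),
                       strand = "+", mismatches = c(0L, 1L, 2L))
  al <- make_alignment(pl, strata = c("U0", "U1", "U2"))
  asn <- assign_transcripts(al, loci)
  expect_setequal(unique(asn$tag_id), c(1L, 2L))  # U2 never annotated
  # the U0 tag hits both the 5p arm and the overlapping custom region
  expect_equal(sum(asn$tag_id == 1L), 2)
  # assignment is translation-invariant
  shift <- 500L
  loci2 <- loci
  loci2$start <- loci2$start + shift
  loci2$end <- loci2$end + shift
  pl2 <- pl
  pl2$start <- pl2$start + shift
  asn2 <- assign_transcripts(make_alignment(pl2, strata = c("U0", "U1", "U2")),
                             loci2)
  expect_equal(asn2$overlap, asn$overlap)
  expect_equal(asn2$identifier, asn$identifier)
})
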