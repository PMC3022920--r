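test_that("k-mer index reports exact offsets and rejects bad input", {
  idx <- genome_index(c(chr1 = "ACGTACGT"), seed_len = 4)
  hits <- index_lookup(idx, "ACGT")
  expect_equal(sort(hits$offset), c(0L, 4L))
  expect_equal(unique(hits$chrom), "chr1")
  expect_error(genome_index(character(0)), "empty genome|named")
  expect_error(genome_index(c(chr1 = "")), "empty genome")
  expect_error(genome_index(c(chr1 = "ACGTXACGT")), "non-ACGTN")
})

test_that("index lookup of every k-mer of a random genome equals a naive scan", {
  set.seed(19)
  g <- c(chr1 = random_seq(6000), chr2 = random_seq(4000))
  k <- 6
  idx <- genome_index(g, seed_len = k)
  kmers <- unique(vapply(sample(5995, 60), function(i) {
    substr(g[["chr1"]], i, i + k - 1)
  }, character(1)))
  for (km in kmers) {
    got <- index_lookup(idx, km)
    got_key <- sort(paste(got$chrom, got$offset))
    naive <- unlist(lapply(names(g), function(chr) {
      starts <- gregexpr(km, g[[chr]], fixed = TRUE)[[1]]
      # gregexpr misses overlapping occurrences; rescan manually
      n <- nchar(g[[chr]])
      pos <- which(vapply(seq_len(n - k + 1), function(p) {
        substr(g[[chr]], p, p + k - 1) == km
      }, logical(1)))
      if (length(pos)) paste(chr, pos - 1) else character()
    }))
    expect_equal(got_key, sort(naive))
  }
})

test_that("single, repeated and mismatched tags land in the right strata", {
  set.seed(23)
  core <- random_seq(3000)
  uniq <- random_seq(22)
  rep2 <- random_seq(22)
  genome <- c(chr1 = paste0(core, uniq, random_seq(100), rep2,
                            random_seq(100), rep2))
  idx <- genome_index(genome)
  # exact unique substring -> U0 at the right coordinate
  al <- align_tags(uniq, idx)
  expect_equal(al$tags$stratum, "U0")
  expect_equal(al$placements$start, 3000L)
  expect_equal(al$placements$strand, "+")
  # exact double occurrence -> R with both placements
  al2 <- align_tags(rep2, idx)
  expect_equal(al2$tags$stratum, "R")
  expect_equal(nrow(al2$placements), 2)
  # one substitution, no exact hit anywhere -> U1
  mut <- mutate_tag(uniq, 1)
  al3 <- align_tags(mut, idx)
  expect_equal(al3$tags$stratum, "U1")
  expect_equal(al3$placements$mismatches, 1L)
  # unplaceable tag -> NM with no placements
  al4 <- align_tags(strrep("A", 22), idx)
  expect_true(al4$tags$stratum %in% c("NM", "R", "U0", "U1", "U2"))
})

test_that("stratum and placement set match the brute-force Hamming oracle", {
  set.seed(29)
  genome <- c(chr1 = random_seq(12000), chr2 = random_seq(8000))
  idx <- genome_index(genome)
  n_tags <- 150
  tags <- character(n_tags)
  for (i in seq_len(n_tags)) {
    L <- sample(15:32, 1)
    chr <- sample(names(genome), 1)
    at <- sample(nchar(genome[[chr]]) - L, 1)
    t0 <- substr(genome[[chr]], at, at + L - 1)
    if (runif(1) < 0.5) t0 <- oracle_revcomp(t0)
    tags[i] <- mutate_tag(t0, sample(0:3, 1))
  }
  al <- align_tags(tags, idx)
  for (i in seq_len(n_tags)) {
    oracle <- oracle_scan(genome, tags[i])
    expect_equal(al$tags$stratum[i], oracle_stratum(oracle), label = tags[i])
    got <- al$placements[al$placements$tag_id == i, ]
    got_key <- sort(paste(got$chrom, got$start, got$strand, got$mismatches))
    expect_equal(got_key, oracle_best_keys(oracle), label = tags[i])
  }
})

test_that("aligning the reverse complement mirrors placements with flipped strand", {
  set.seed(37)
  genome <- c(chr1 = random_seq(5000))
  idx <- genome_index(genome)
  tags <- vapply(1:20, function(i) {
    at <- sample(4970, 1)
    mutate_tag(substr(genome[[1]], at, at + 21), sample(0:1, 1))
  }, character(1))
  fwd <- align_tags(tags, idx)
  rev <- align_tags(oracle_revcomp(tags), idx)
  expect_equal(fwd$tags$stratum, rev$tags$stratum)
  flip <- c(`+` = "-", `-` = "+")
  for (i in seq_along(tags)) {
    a <- fwd$placements[fwd$placements$tag_id == i, ]
    b <- rev$placements[rev$placements$tag_id == i, ]
    expect_equal(sort(paste(a$chrom, a$start, flip[a$strand], a$mismatches)),
                 sort(paste(b$chrom, b$start, b$strand, b$mismatches)))
  }
})

test_that("repeat placements are capped but the stratum stays exact", {
  unit <- random_seq(25)
  genome <- c(chr1 = strrep(paste0(unit, random_seq(40)), 80))
  idx <- genome_index(genome)
  al <- align_tags(unit, idx, max_placements = 16)
  expect_equal(al$tags$stratum, "R")
  expect_equal(al$tags$n_placements, 80L)
  expect_equal(nrow(al$placements), 16)
})

test_that("alignment TSV import/export round-trips", {
  set.seed(41)
  genome <- c(chr1 = random_seq(4000))
  idx <- genome_index(genome)
  tags <- tibble::tibble(
    sequence = vapply(1:10, function(i) {
      at <- sample(3970, 1)
      substr(genome[[1]], at, at + 20)
    }, character(1)),
    count = sample(1:50, 10))
  al <- align_tags(tags, idx)
  path <- tempfile(fileext = ".tsv")
  write_alignment(al, path)
  back <- read_alignment(path)
  expect_equal(sort(back$tags$sequence), sort(al$tags$sequence))
  expect_equal(back$tags$stratum[match(al$tags$sequence, back$tags$sequence)],
               al$tags$stratum)
  expect_equal(nrow(back$placements), nrow(al$placements))
})

test_that("processing report partitions reads exactly", {
  set.seed(43)
  genome <- c(chr1 = random_seq(9000))
  idx <- genome_index(genome)
  tags <- tibble::tibble(
    sequence = c(
      vapply(1:30, function(i) {
        at <- sample(8960, 1)
        mutate_tag(substr(genome[[1]], at, at + sample(17:24, 1)),
                   sample(0:3, 1))
      }, character(1)),
      vapply(rep(22, 10), random_seq, character(1))),
    count = sample(1:100, 40, replace = TRUE))
  tags <- collapse_tags(tags)
  al <- align_tags(tags, idx)
  rep <- processing_report(al, input = sum(tags$count) + 55, below_min_len = 55)
  v <- function(m) rep$reads[rep$metric == m]
  expect_equal(v("NM") + v("R") + v("U0") + v("U1") + v("U2"), v("kept"))
  expect_equal(v("U0andU1"), v("U0") + v("U1"))
  expect_equal(v("input"), v("kept") + v("below_min_len"))
  cls <- c("miRNA", "miscRNA", "pseudogene", "rRNA", "snRNA", "snoRNA",
           "tRNA", "custom", "other")
  expect_equal(sum(rep$reads[rep$metric %in% cls]), v("U0andU1"))
  # all-U0 library: strata collapse onto kept
  u0 <- al$tags[al$tags$stratum == "U0", ]
  al_u0 <- list(tags = u0, placements = al$placements)
  class(al_u0) <- "tag_alignment"
  rep2 <- processing_report(al_u0)
  expect_equal(rep2$reads[rep2$metric == "U0andU1"],
               rep2$reads[rep2$metric == "kept"])
  # empty library: all-zero report
  al_empty <- list(tags = al$tags[0, ], placements = al$placements[0, ])
  class(al_empty) <- "tag_alignment"
  rep3 <- processing_report(al_empty)
  expect_true(all(rep3$reads == 0))
})

test_that("identical inputs yield byte-identical alignment output", {
  set.seed(47)
  genome <- c(chr1 = random_seq(5000))
  tags <- tibble::tibble(sequence = vapply(rep(20, 30), random_seq, character(1)),
                         count = 1L)
  f1 <- tempfile(); f2 <- tempfile()
  write_alignment(align_tags(tags, genome_index(genome)), f1)
  write_alignment(align_tags(tags, genome_index(genome)), f2)
  expect_identical(readLines(f1), readLines(f2))
})
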