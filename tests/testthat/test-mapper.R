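adapter <- "TGGAATTCTCGGGTGCCAAG"

test_that("adapter trimming truncates at the leftmost adapter match", {
  expect_equal(unname(trim_adapter(paste0("ACGT", adapter), adapter)),
               "ACGT")
  expect_equal(unname(trim_adapter("ACGTACGTACGT", adapter)),
               "ACGTACGTACGT")
  # partial adapter at the read end, matched down to min_match bases
  expect_equal(unname(trim_adapter("ACGTTGGAAT", adapter, min_match = 6L)),
               "ACGT")
  # below min_match the tail is left alone
  expect_equal(unname(trim_adapter("ACGTTGGA", adapter, min_match = 6L)),
               "ACGTTGGA")
  expect_error(trim_adapter("", adapter), "empty read")
  expect_error(trim_adapter("ACGT", adapter, min_match = 0L), "min_match")
})

test_that("trimming agrees with a brute-force scan and is idempotent", {
  set.seed(100)
  inserts <- vapply(1:50, function(i) {
    paste(sample(c("A", "C", "G", "T"), sample(10:30, 1), replace = TRUE),
          collapse = "")
  }, character(1))
  # mix: full adapter, partial adapter tails, no adapter
  reads <- c(paste0(inserts[1:20], adapter),
             paste0(inserts[21:35], substr(adapter, 1, 8)),
             inserts[36:50])
  for (mm in c(4L, 6L, 10L)) {
    got <- trim_adapter(reads, adapter, min_match = mm)
    want <- vapply(reads, bf_trim_one, character(1), adapter = adapter,
                   min_match = mm, USE.NAMES = FALSE)
    expect_equal(unname(got), want)
    expect_equal(unname(trim_adapter(got[nzchar(got)], adapter,
                                     min_match = mm)),
                 unname(got[nzchar(got)]))
  }
})

test_that("exact placements are reported with the stated conventions", {
  ref <- tiny_ref()
  S <- as.character(ref$sequences[["chr_sim"]])
  read <- substr(S, 11, 33)                      # 0-based [10, 33)
  h <- map_reads(c(r1 = read), ref$sequences["chr_sim"],
                 max_mismatches = 0L)
  expect_equal(nrow(h), 1L)
  expect_equal(h$start, 10L)
  expect_equal(h$end, 33L)
  expect_equal(h$strand, "+")
  expect_equal(h$mismatches, 0L)

  # reverse complement lands at the same interval on the minus strand
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(read)))
  h2 <- map_reads(c(r1 = rc), ref$sequences["chr_sim"], max_mismatches = 0L)
  expect_equal(h2$start, 10L)
  expect_equal(h2$end, 33L)
  expect_equal(h2$strand, "-")
})

test_that("mapper matches the exhaustive Hamming oracle at 0 and 1 mismatch", {
  set.seed(200)
  refseq <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE),
                  collapse = "")
  refs <- c(toy = refseq)
  # reads: exact substrings, 1- and 2-mutation variants, pure random
  mk <- function(n_mut) {
    p <- sample(1950, 1)
    s <- strsplit(substr(refseq, p, p + 24), "")[[1]]
    if (n_mut > 0) {
      at <- sample(25, n_mut)
      s[at] <- vapply(s[at], function(b) sample(setdiff(c("A", "C", "G", "T"),
                                                        b), 1), character(1))
    }
    paste(s, collapse = "")
  }
  reads <- c(
    vapply(1:20, function(i) mk(0), character(1)),
    vapply(1:20, function(i) mk(1), character(1)),
    vapply(1:10, function(i) mk(2), character(1)),
    vapply(1:10, function(i) paste(sample(c("A", "C", "G", "T"), 25,
                                          replace = TRUE), collapse = ""),
           character(1))
  )
  names(reads) <- sprintf("r%02d", seq_along(reads))
  for (mm in c(0L, 1L)) {
    got <- map_reads(reads, refs, max_mismatches = mm)
    want <- bf_map(as.list(reads), refs, mm)
    expect_identical(sort_hits(got), sort_hits(want))
  }
})

test_that("mapping revcomp reads swaps strands and preserves intervals", {
  set.seed(201)
  refs <- c(toy = paste(sample(c("A", "C", "G", "T"), 1500, replace = TRUE),
                        collapse = ""))
  reads <- vapply(1:15, function(i) {
    p <- sample(1400, 1)
    substr(refs[["toy"]], p, p + 23)
  }, character(1))
  names(reads) <- sprintf("r%02d", seq_along(reads))
  rc <- setNames(as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(reads))), names(reads))
  h1 <- sort_hits(map_reads(reads, refs, 1L))
  h2 <- sort_hits(map_reads(rc, refs, 1L))
  flip <- c("+" = "-", "-" = "+")
  h2$strand <- unname(flip[h2$strand])
  h2 <- sort_hits(h2)
  expect_identical(h1, h2)
})

test_that("N-containing reads are skipped and counted, not errors", {
  refs <- c(toy = strrep("ACGT", 50))
  h <- map_reads(c(a = "ACGTACGTACGT", b = "ACGNACGTACGT"), refs, 0L)
  expect_equal(attr(h, "skipped_n"), 1L)
  expect_false("b" %in% h$read_id)
  expect_true("a" %in% h$read_id)
})

test_that("length filtering keeps the closed 18-29 interval and is idempotent", {
  hits <- make_hits(sprintf("r%d", 1:4), "chr", c(0, 50, 100, 150),
                    c(17, 18, 29, 30), "+")
  kept <- filter_by_length(hits, 18, 29)
  expect_setequal(kept$read_length, c(18L, 29L))
  expect_identical(filter_by_length(kept, 18, 29), kept)
  sirna <- make_hits(sprintf("s%d", 1:5), "chr", seq(0, 80, 20), 21, "+")
  expect_equal(nrow(filter_by_length(sirna, 23, 29)), 0L)
  expect_error(filter_by_length(hits, 29, 18), "min_nt")
})

test_that("unique-mapper selection drops tandem-repeat reads, keeps flank reads", {
  ref <- tiny_ref()
  S <- as.character(ref$sequences[["chr_sim"]])
  blk <- ref$annotation[ref$annotation$name == "transgene_cluster", ]
  # reads from copy 1 of the 3-copy array vs reads from the unique flank
  rep_reads <- vapply(0:4, function(k) {
    p <- blk$start + 20 * k
    substr(S, p + 1, p + 25)
  }, character(1))
  flank_reads <- vapply(0:4, function(k) {
    p <- 100 + 30 * k
    substr(S, p + 1, p + 25)
  }, character(1))
  reads <- setNames(c(rep_reads, flank_reads),
                    c(sprintf("rep%d", 0:4), sprintf("flk%d", 0:4)))
  hits <- map_reads(reads, ref$sequences["chr_sim"], 0L)
  uh <- unique_mappers(hits)
  expect_setequal(unique(uh$read_id), sprintf("flk%d", 0:4))
  expect_true(all(table(hits$read_id[grepl("rep", hits$read_id)]) == 3L))
  # single-hit read kept, 2-position read removed
  expect_equal(nrow(unique_mappers(make_hits("x", "chr", c(0, 40), 25, "+",
                                             n_hits = 2L))), 0L)
})
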