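test_that("reference construction places identical tandem copies", {
  ref <- tiny_ref()
  ann <- ref$annotation
  blk <- ann[ann$name == "transgene_cluster", ]
  expect_equal(blk$start, 1000L)
  expect_equal(blk$end, 1000L + 3L * 200L)

  S <- as.character(ref$sequences[["chr_sim"]])
  copy0 <- substr(S, 1001, 1200)
  copy2 <- substr(S, 1401, 1600)
  expect_identical(copy0, copy2)

  # single-copy case: annotation block length equals the unit length
  ref1 <- build_reference(
    locus_spec(n_copies = 1L, unit_length = 300L, chrom_length = 2000L,
               insert_position = 500L), seed = 7L)
  blk1 <- ref1$annotation[ref1$annotation$name == "transgene_cluster", ]
  expect_equal(blk1$end - blk1$start, 300L)

  # 7-copy default geometry
  ref7 <- build_reference(locus_spec(), seed = 1L)
  blk7 <- ref7$annotation[ref7$annotation$name == "transgene_cluster", ]
  expect_equal(blk7$end - blk7$start, 7000L)
})

test_that("locus specs rejecting out-of-bounds repeat blocks", {
  expect_error(locus_spec(n_copies = 10L, unit_length = 1000L,
                          chrom_length = 5000L, insert_position = 0L),
               "overlaps the chromosome end")
  expect_error(locus_spec(unit_length = 50L), "unit_length")
  expect_error(library_spec(u1_bias = 1.5), "proportions")
})

test_that("identical spec and seed give byte-identical FASTQ output", {
  ref <- tiny_ref()
  spec <- library_spec(n_pirna = 200L, n_sirna = 50L, n_mirna = 50L,
                       seed = 11L)
  f1 <- tempfile(fileext = ".fastq")
  f2 <- tempfile(fileext = ".fastq")
  write_fastq(simulate_small_rna_library(ref, spec), f1)
  write_fastq(simulate_small_rna_library(ref, spec), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_equal(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("siRNA-only libraries put all length mass at 21 nt", {
  ref <- tiny_ref()
  lib <- simulate_small_rna_library(
    ref, library_spec(n_pirna = 0L, n_sirna = 1000L, n_mirna = 0L,
                      pingpong_fraction = 0, seed = 5L))
  expect_true(all(lib$reads$length == 21L))
  # strand balance within 3 binomial SE of 500/500
  n_plus <- sum(lib$reads$strand == "+")
  expect_lt(abs(n_plus - 500), 3 * sqrt(1000 * 0.25))
})

test_that("library composition biases are recovered from the reads", {
  ref <- build_reference(locus_spec(), seed = 1L)
  # 1U bias on unpaired piRNAs (3 binomial SE at n = 10000 is ~1.2%)
  lib_u <- simulate_small_rna_library(
    ref, library_spec(n_pirna = 10000L, n_sirna = 0L, n_mirna = 0L,
                      pingpong_fraction = 0, u1_bias = 0.8, seed = 2L))
  u1 <- first_u_fraction(truth_hits(lib_u), lib_u)
  expect_lt(abs(u1 - 80), 3 * 100 * sqrt(0.8 * 0.2 / 10000))

  # 10A bias among ping-pong paired reads
  lib_a <- simulate_small_rna_library(
    ref, library_spec(n_pirna = 10000L, n_sirna = 0L, n_mirna = 0L,
                      pingpong_fraction = 0.5, a10_bias = 0.9, seed = 3L))
  a10 <- tenth_a_fraction(truth_hits(lib_a), lib_a)
  expect_lt(abs(a10 - 90), 2)

  # length weights via the size distribution (peaked custom weights)
  w <- c("23" = 0.02, "24" = 0.08, "25" = 0.5, "26" = 0.2, "27" = 0.1,
         "28" = 0.06, "29" = 0.04)
  lib_l <- simulate_small_rna_library(
    ref, library_spec(n_pirna = 5000L, n_sirna = 0L, n_mirna = 0L,
                      pingpong_fraction = 0, pirna_length_weights = w,
                      seed = 4L))
  dist <- size_distribution(truth_hits(lib_l), split_by_strand = FALSE)
  expect_equal(dist$length[which.max(dist$count)], 25L)
  got <- dist$count[match(23:29, dist$length)] / 5000
  expect_true(all(abs(got - w) < 3 * sqrt(w * (1 - w) / 5000)))
})

test_that("generated reads trim cleanly and map back with 0 mismatches", {
  ref <- tiny_ref()
  spec <- library_spec(n_pirna = 60L, n_sirna = 20L, n_mirna = 20L,
                       seed = 9L)
  lib <- simulate_small_rna_library(ref, spec)
  raw <- setNames(lib$reads$raw, lib$reads$id)
  expect_true(all(nchar(raw) == 50L))
  trimmed <- trim_adapter(raw, spec$adapter)
  # trimming recovers the insert unless the insert itself contains the
  # adapter probe by chance; either way reads stay exact reference matches
  hits <- map_reads(trimmed[nchar(trimmed) >= 15], ref, max_mismatches = 0L)
  expect_setequal(unique(hits$read_id),
                  names(trimmed)[nchar(trimmed) >= 15])
  expect_true(all(hits$mismatches == 0L))
})

test_that("library generation rejects impossible requests", {
  ref <- tiny_ref()
  expect_error(simulate_small_rna_library(
    ref, library_spec(n_pirna = 1L, pingpong_fraction = 0.5)),
    "n_pirna >= 2")
})

test_that("qPCR plate simulator follows the amplification model", {
  q <- c(d1 = 1e5, d2 = 1e4, d3 = 1e3, d4 = 1e2)
  # efficiency 1, no noise: consecutive 10-fold dilutions differ by
  # log2(10) = 3.3219 cycles
  plate <- simulate_qpcr_plate(q, efficiency = 1, noise_sd = 0, seed = 1L)
  cq <- tapply(plate$Cq, plate$sample, mean)[names(q)]
  expect_equal(as.numeric(diff(cq)), rep(log2(10), 3), tolerance = 1e-12)

  # doubling the quantity lowers Cq by exactly one cycle
  p2 <- simulate_qpcr_plate(c(a = 100, b = 200), efficiency = 1,
                            noise_sd = 0, seed = 1L)
  m <- tapply(p2$Cq, p2$sample, mean)
  expect_equal(as.numeric(m["a"] - m["b"]), 1, tolerance = 1e-12)

  expect_error(simulate_qpcr_plate(c(a = 0), efficiency = 1), "positive")
  expect_error(simulate_qpcr_plate(c(a = 1), efficiency = 1.2),
               "efficiency")
})
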