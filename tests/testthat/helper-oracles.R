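# Independent brute-force oracles used to validate the fast implementations,
# plus small shared fixtures. The oracles deliberately use naive enumeration.

# Exhaustive ungapped Hamming-distance scan of one read over both strands of
# every reference. Returns the same columns as map_reads() (minus n_hits).
bf_map_one <- function(seq, refs, max_mm) {
  rows <- list()
  for (ref_name in names(refs)) {
    ref_chars <- strsplit(refs[[ref_name]], "")[[1]]
    N <- length(ref_chars)
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") seq else
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
      p <- strsplit(pat, "")[[1]]
      L <- length(p)
      if (L > N) next
      np <- N - L + 1L
      mm <- integer(np)
      for (i in seq_len(L)) {
        mm <- mm + (ref_chars[seq_len(np) + i - 1L] != p[i])
      }
      hit <- which(mm <= max_mm)
      if (length(hit)) {
        rows[[length(rows) + 1L]] <- data.frame(
          reference = ref_name, start = hit - 1L, end = hit - 1L + L,
          strand = strand, mismatches = mm[hit], read_length = L,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

bf_map <- function(reads, refs, max_mm) {
  pieces <- lapply(names(reads), function(id) {
    h <- bf_map_one(reads[[id]], refs, max_mm)
    if (is.null(h)) return(NULL)
    cbind(read_id = id, h, stringsAsFactors = FALSE)
  })
  pieces <- pieces[!vapply(pieces, is.null, logical(1))]
  if (!length(pieces)) return(NULL)
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

# Canonical sort for hit-table comparison.
sort_hits <- function(h) {
  h <- h[, c("read_id", "reference", "start", "end", "strand", "mismatches",
             "read_length")]
  h <- h[order(h$read_id, h$reference, h$start, h$strand, h$mismatches), ]
  rownames(h) <- NULL
  h
}

# O(n^2) all-pairs overlap counter: every (+, -) hit-instance pair on the
# same reference with 5' overlap i in 1..29 counts once.
bf_overlap <- function(hits) {
  O <- setNames(numeric(29), as.character(1:29))
  p5 <- ifelse(hits$strand == "+", hits$start, hits$end - 1L)
  plus <- which(hits$strand == "+")
  minus <- which(hits$strand == "-")
  for (i in plus) {
    for (j in minus) {
      if (hits$reference[i] != hits$reference[j]) next
      ov <- p5[j] - p5[i] + 1L
      if (ov >= 1L && ov <= 29L) O[ov] <- O[ov] + 1
    }
  }
  O
}

# Brute-force adapter trimming: scan every read position for a matching
# adapter prefix of length >= min_match (or the full adapter).
bf_trim_one <- function(seq, adapter, min_match) {
  n <- nchar(seq)
  la <- nchar(adapter)
  for (p in seq_len(n)) {
    L <- min(la, n - p + 1L)
    if (L < min(min_match, la)) next
    if (substr(seq, p, p + L - 1L) == substr(adapter, 1L, L)) {
      return(substr(seq, 1L, p - 1L))
    }
  }
  seq
}

# Hand-computed Pearson / Yates chi-square on a 2x2 table.
bf_chi2_2x2 <- function(m, yates = FALSE) {
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  d <- abs(m - e)
  if (yates) d <- pmax(d - 0.5, 0)
  sum(d^2 / e)
}

# Shared small fixture: 3-copy tandem locus on a 5-kb chromosome.
tiny_ref <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- build_reference(
        locus_spec(n_copies = 3L, unit_length = 200L,
                   flank_gene_length = 300L, chrom_length = 5000L,
                   insert_position = 1000L),
        seed = 42L
      )
    }
    cache
  }
})

# Manufacture a hit table directly (for unit tests that do not need a
# mapper run).
make_hits <- function(read_id, reference, start, length, strand,
                      n_hits = 1L) {
  n <- max(length(read_id), length(start), length(strand))
  data.frame(
    read_id = rep_len(read_id, n), reference = rep_len(reference, n),
    start = as.integer(rep_len(start, n)),
    end = as.integer(rep_len(start + length, n)),
    strand = rep_len(strand, n), mismatches = rep_len(0L, n),
    read_length = as.integer(rep_len(length, n)),
    n_hits = as.integer(rep_len(n_hits, n)),
    stringsAsFactors = FALSE
  )
}
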