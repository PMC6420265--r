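#' Trim the 3' sequencing adapter from small-RNA reads
#'
#' Truncates each read at the leftmost position where a prefix of the adapter
#' of length >= `min_match` (or the full adapter, when fewer than `min_match`
#' adapter bases would fit) matches exactly. Reads without such a match are
#' returned unchanged. The operation is idempotent.
#'
#' @param reads Character vector of read sequences (named or not), or any
#'   container accepted by the package (FASTQ import, `srna_library`).
#' @param adapter Adapter sequence, 5'->3' as it appears in the read.
#' @param min_match Minimum adapter prefix length required to trim.
#' @return Character vector of trimmed sequences (names preserved).
#' @export
trim_adapter <- function(reads, adapter, min_match = 6L) {
  seqs <- as_read_seqs(reads)
  if (!length(seqs)) return(seqs)
  if (any(!nzchar(seqs))) stop("empty read sequence")
  if (!nzchar(adapter)) stop("adapter must be non-empty")
  min_match <- as.integer(min_match)
  if (min_match < 1L) stop("min_match must be >= 1")
  la <- nchar(adapter)
  probe <- substr(adapter, 1L, min(min_match, la))
  n <- nchar(seqs)
  cand <- gregexpr(probe, seqs, fixed = TRUE)
  out <- vapply(seq_along(seqs), function(i) {
    ps <- cand[[i]]
    if (ps[1L] == -1L) return(seqs[[i]])
    for (p in ps) {
      # the match must extend over the full adapter or to the read end
      L <- min(la, n[i] - p + 1L)
      if (substr(seqs[[i]], p, p + L - 1L) == substr(adapter, 1L, L)) {
        return(substr(seqs[[i]], 1L, p - 1L))
      }
    }
    seqs[[i]]
  }, character(1))
  names(out) <- names(seqs)
  out
}

# Hamming mismatch count between a pattern and the reference substring
# starting at `at` (1-based). Assumes equal lengths.
hamming_at <- function(pattern, refseq, at) {
  a <- charToRaw(pattern)
  b <- charToRaw(substr(refseq, at, at + nchar(pattern) - 1L))
  sum(a != b)
}

#' Exhaustively place small-RNA reads on references with 0 or 1 mismatches
#'
#' Reports every ungapped placement of each read on either strand of each
#' reference with at most `max_mismatches` substitutions. Minus-strand hits
#' are placements of the reverse complement; coordinates are 0-based
#' half-open intervals on the forward reference. Matching is exact (no
#' heuristics): each unique read sequence is scanned against every reference
#' at C speed via [Biostrings::vmatchPattern()]. Reads containing N are
#' skipped and counted in the `skipped_n` attribute rather than treated as
#' errors.
#'
#' @param reads Named character vector of read sequences (or any accepted
#'   read container). Names are the read ids.
#' @param references Named character vector / `DNAStringSet` /
#'   `srna_reference`.
#' @param max_mismatches 0 or 1.
#' @return data.frame with columns read_id, reference, start, end, strand,
#'   mismatches, read_length, n_hits (total placements of that read across
#'   the whole reference set). Attribute `skipped_n` gives the number of
#'   N-containing reads skipped.
#' @export
map_reads <- function(reads, references, max_mismatches = 0L) {
  seqs <- as_read_seqs(reads)
  refs <- as_reference_seqs(references)
  max_mismatches <- as.integer(max_mismatches)
  if (!max_mismatches %in% c(0L, 1L)) stop("max_mismatches must be 0 or 1")
  if (is.null(names(seqs))) names(seqs) <- sprintf("read_%06d", seq_along(seqs))

  has_n <- grepl("N", seqs, fixed = TRUE)
  skipped <- sum(has_n)
  seqs <- seqs[!has_n]
  if (!length(seqs)) {
    out <- empty_hits()
    attr(out, "skipped_n") <- skipped
    return(out)
  }

  ref_set <- Biostrings::DNAStringSet(refs)
  uniq <- unique(unname(seqs))
  per_seq <- vector("list", length(uniq))
  for (k in seq_along(uniq)) {
    s <- uniq[k]
    L <- nchar(s)
    rows <- list()
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") s else revcomp(s)
      m <- Biostrings::vmatchPattern(pat, ref_set,
                                     max.mismatch = max_mismatches,
                                     with.indels = FALSE, fixed = TRUE)
      for (r in seq_along(ref_set)) {
        st <- IRanges::start(m[[r]])
        if (!length(st)) next
        # vmatchPattern can return out-of-bounds hits when mismatches are
        # allowed at the edges; keep fully contained placements only.
        ok <- st >= 1L & st + L - 1L <= nchar(refs[r])
        st <- st[ok]
        if (!length(st)) next
        mm <- vapply(st, function(a) hamming_at(pat, refs[[r]], a), numeric(1))
        keep <- mm <= max_mismatches
        if (!any(keep)) next
        rows[[length(rows) + 1L]] <- data.frame(
          reference = names(refs)[r], start = st[keep] - 1L,
          end = st[keep] - 1L + L, strand = strand,
          mismatches = as.integer(mm[keep]), read_length = L,
          stringsAsFactors = FALSE
        )
      }
    }
    per_seq[k] <- list(if (length(rows)) do.call(rbind, rows) else NULL)
  }
  names(per_seq) <- uniq

  # Expand per-sequence placements to per-read rows.
  idx <- match(unname(seqs), uniq)
  pieces <- lapply(seq_along(seqs), function(i) {
    h <- per_seq[[idx[i]]]
    if (is.null(h)) return(NULL)
    cbind(read_id = names(seqs)[i], h, stringsAsFactors = FALSE)
  })
  pieces <- pieces[!vapply(pieces, is.null, logical(1))]
  if (!length(pieces)) {
    out <- empty_hits()
    attr(out, "skipped_n") <- skipped
    return(out)
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  nh <- table(out$read_id)
  out$n_hits <- as.integer(nh[out$read_id])
  attr(out, "skipped_n") <- skipped
  out
}

#' Retain hits whose read length lies within a closed interval
#'
#' @param hits Hit table from [map_reads()].
#' @param min_nt,max_nt Inclusive bounds on read length.
#' @return Filtered hit table.
#' @export
filter_by_length <- function(hits, min_nt, max_nt) {
  check_hits(hits)
  if (min_nt > max_nt) stop("min_nt must be <= max_nt")
  out <- hits[hits$read_length >= min_nt & hits$read_length <= max_nt, ,
              drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Retain hits of reads with exactly one placement in the reference set
#'
#' Placements on both strands and all references count towards a read's
#' placement total (the `n_hits` column written by [map_reads()], falling
#' back to a within-table count if absent). Reads from a multi-copy tandem
#' array are therefore removed, reads from single-copy flanks kept.
#'
#' @param hits Hit table.
#' @return Hit table restricted to uniquely mapping reads.
#' @export
unique_mappers <- function(hits) {
  check_hits(hits)
  if (!nrow(hits)) return(hits)
  n <- if ("n_hits" %in% names(hits)) hits$n_hits else {
    tab <- table(hits$read_id)
    as.integer(tab[hits$read_id])
  }
  out <- hits[n == 1L, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a hit table as a tab-separated file
#'
#' @param hits Hit table.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_hits <- function(hits, path) {
  write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
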