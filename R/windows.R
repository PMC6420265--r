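#' Tile chromosomes into fixed-width windows
#'
#' Produces non-overlapping windows of nominal width (default 50 kb)
#' covering each chromosome; the last window of a chromosome is truncated.
#' Coordinates are 0-based half-open.
#'
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @param width Window width in bp.
#' @return data.frame chrom, start, end.
#' @export
tile_genome <- function(chrom_lengths, width = 50000L) {
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths)))) {
    stop("chrom_lengths must be named")
  }
  if (any(chrom_lengths < 1L)) stop("chromosome lengths must be >= 1")
  sl <- setNames(as.integer(chrom_lengths), names(chrom_lengths))
  gr <- GenomicRanges::tileGenome(sl, tilewidth = as.integer(width),
                                  cut.last.tile.in.chrom = TRUE)
  data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = IRanges::start(gr) - 1L,
    end = IRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

#' Normalized piRNA counts and densities per genome window
#'
#' Assigns each hit to exactly one window by its 5'-end coordinate, then
#' reports the raw count, the rpm-normalized count (1e6 / normalizer_total)
#' and the density in normalized counts per kb for each window. Hits are
#' expected to be unique 23-29 nt mappers.
#'
#' @param hits Hit table of unique mappers.
#' @param windows Window table from [tile_genome()].
#' @param normalizer_total Library normalizer total (> 0).
#' @return `windows` with added columns count, norm_count, density.
#' @export
window_densities <- function(hits, windows, normalizer_total) {
  check_hits(hits)
  if (normalizer_total <= 0) stop("normalizer total must be positive")
  counts <- numeric(nrow(windows))
  if (nrow(hits)) {
    p5 <- five_prime_ends(hits)
    for (chr in unique(windows$chrom)) {
      wi <- which(windows$chrom == chr)
      h <- p5[hits$reference == chr]
      if (!length(h)) next
      # windows are contiguous from 0, so the window index is a cut on
      # start positions
      brk <- c(windows$start[wi], windows$end[wi][length(wi)])
      idx <- findInterval(h, brk, rightmost.closed = FALSE)
      idx <- idx[idx >= 1L & idx <= length(wi)]
      tab <- table(idx)
      counts[wi[as.integer(names(tab))]] <-
        counts[wi[as.integer(names(tab))]] + as.integer(tab)
    }
  }
  windows$count <- counts
  windows$norm_count <- counts * 1e6 / normalizer_total
  windows$density <- windows$norm_count / ((windows$end - windows$start) / 1000)
  windows
}

#' Retain windows dense enough in one or both libraries
#'
#' Keeps windows whose piRNA density strictly exceeds `min_density`
#' (normalized counts per kb) in at least one library (`mode = "either"`,
#' the default) or in both (`mode = "both"`, the literal reading that would
#' discard a locus silent in one library).
#'
#' @param windows Window table with `density_a` and `density_b` columns.
#' @param min_density Density threshold (per kb).
#' @param mode `"either"` or `"both"`.
#' @return Filtered window table.
#' @export
candidate_windows <- function(windows, min_density = 5,
                              mode = c("either", "both")) {
  mode <- match.arg(mode)
  if (!all(c("density_a", "density_b") %in% names(windows))) {
    stop("windows must carry density_a and density_b")
  }
  keep <- if (mode == "either") {
    windows$density_a > min_density | windows$density_b > min_density
  } else {
    windows$density_a > min_density & windows$density_b > min_density
  }
  out <- windows[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pseudocounted log2 ratio of two window counts
#'
#' `log2((count_b + pseudocount) / (count_a + pseudocount))`; the
#' pseudocount keeps the ratio finite when the first library has zero
#' counts. Swapping the libraries negates the ratio.
#'
#' @param count_a,count_b Counts on a common (normalized) scale.
#' @param pseudocount Added to both counts.
#' @return Numeric vector of log2 ratios.
#' @export
log2_ratio <- function(count_a, count_b, pseudocount = 1) {
  log2((count_b + pseudocount) / (count_a + pseudocount))
}

#' Two-library genome window scan for de novo piRNA producing loci
#'
#' Tiles the genome, computes normalized window counts and densities for
#' both libraries, filters candidate windows by density, attaches the log2
#' ratio (library b over library a) and flags windows exceeding the ratio
#' threshold. This is the scan used to ask whether any locus outside a known
#' cluster started producing piRNAs between two conditions.
#'
#' @param hits_a,hits_b Unique-mapper hit tables for the two libraries.
#' @param chrom_lengths Named chromosome lengths.
#' @param normalizer_a,normalizer_b Library normalizer totals.
#' @param width Window width (bp).
#' @param min_density Candidate density threshold (per kb).
#' @param mode Candidate mode, see [candidate_windows()].
#' @param pseudocount Pseudocount for the ratio.
#' @param log2_threshold Windows with ratio strictly above this are flagged.
#' @return Window table with count/density columns for both libraries,
#'   `log2_ratio` and logical `flagged`.
#' @export
scan_windows <- function(hits_a, hits_b, chrom_lengths,
                         normalizer_a, normalizer_b, width = 50000L,
                         min_density = 5, mode = c("either", "both"),
                         pseudocount = 1, log2_threshold = 8.5) {
  mode <- match.arg(mode)
  win <- tile_genome(chrom_lengths, width)
  wa <- window_densities(hits_a, win, normalizer_a)
  wb <- window_densities(hits_b, win, normalizer_b)
  win$count_a <- wa$norm_count
  win$count_b <- wb$norm_count
  win$density_a <- wa$density
  win$density_b <- wb$density
  win <- candidate_windows(win, min_density = min_density, mode = mode)
  win$log2_ratio <- log2_ratio(win$count_a, win$count_b, pseudocount)
  win$flagged <- win$log2_ratio > log2_threshold
  win
}
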