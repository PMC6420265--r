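#' Size and strand distribution of aligned small RNAs
#'
#' Tabulates aligned read instances per (length, strand). Multi-mapping
#' reads can be counted once per placement (`weighting = "one"`) or with
#' weight 1/n_hits per placement (`weighting = "fractional"`), so that each
#' read contributes one unit to the library total. Antisense counts are kept
#' positive here; negating them is a rendering convention only.
#'
#' @param hits Hit table from [map_reads()].
#' @param range Integer vector of lengths to report (default 18:30).
#' @param split_by_strand If `FALSE`, strands are pooled.
#' @param weighting `"one"` or `"fractional"` (1/n_hits per placement).
#' @return data.frame with columns length, strand (if split), count.
#' @export
size_distribution <- function(hits, range = 18:30, split_by_strand = TRUE,
                              weighting = c("one", "fractional")) {
  check_hits(hits)
  weighting <- match.arg(weighting)
  w <- if (weighting == "fractional" && nrow(hits)) {
    if (!"n_hits" %in% names(hits)) stop("fractional weighting needs n_hits")
    1 / hits$n_hits
  } else rep(1, nrow(hits))
  if (split_by_strand) {
    grid <- expand.grid(length = range, strand = c("+", "-"),
                        stringsAsFactors = FALSE)
    key <- paste(hits$read_length, hits$strand)
    tot <- tapply(w, key, sum)
    grid$count <- as.numeric(tot[paste(grid$length, grid$strand)])
  } else {
    grid <- data.frame(length = range)
    tot <- tapply(w, hits$read_length, sum)
    grid$count <- as.numeric(tot[as.character(grid$length)])
  }
  grid$count[is.na(grid$count)] <- 0
  grid
}

#' Scale counts to reads per million of a normalizer class
#'
#' Multiplies counts by 1e6 / `normalizer_total`. The normalizer is either
#' the library's miRNA-matching read total (`"mirna_million"`) or its
#' genome-matching read total (`"genome_million"`); the mode used is recorded
#' as an attribute so each report carries its provenance.
#'
#' @param counts Numeric vector of raw counts.
#' @param normalizer_total Total reads of the normalizer class (> 0).
#' @param mode Normalization mode label.
#' @param library_name Optional library label used in error messages.
#' @return Numeric vector of rpm values, with attribute `mode`.
#' @export
normalize_rpm <- function(counts, normalizer_total,
                          mode = c("mirna_million", "genome_million"),
                          library_name = NULL) {
  mode <- match.arg(mode)
  if (length(normalizer_total) != 1L || is.na(normalizer_total) ||
      normalizer_total <= 0) {
    stop("normalizer total must be positive",
         if (!is.null(library_name)) paste0(" (library ", library_name, ")"))
  }
  out <- counts * 1e6 / normalizer_total
  attr(out, "mode") <- mode
  out
}

# 5' end coordinate (0-based) of each hit: plus-strand reads start at
# `start`; the 5' end of a minus-strand read is its highest coordinate,
# end - 1. All downstream overlap arithmetic uses this convention.
five_prime_ends <- function(hits) {
  ifelse(hits$strand == "+", hits$start, hits$end - 1L)
}

#' Per-position 5'-end coverage of one reference, split by strand
#'
#' Counts aligned 5' ends per position on each strand of a single reference,
#' typically from unique 23-29 nt mappers. Positions with zero counts are
#' omitted.
#'
#' @param hits Hit table (all rows must be on `reference`).
#' @param reference Reference name.
#' @return data.frame position (0-based), strand, count; attribute
#'   `reference` records the contig.
#' @export
coverage_profile <- function(hits, reference) {
  check_hits(hits)
  hits <- hits[hits$reference == reference, , drop = FALSE]
  if (!nrow(hits)) {
    out <- data.frame(position = integer(0), strand = character(0),
                      count = integer(0), stringsAsFactors = FALSE)
    attr(out, "reference") <- reference
    return(out)
  }
  p5 <- five_prime_ends(hits)
  key <- paste(p5, hits$strand)
  tab <- table(key)
  parts <- strsplit(names(tab), " ", fixed = TRUE)
  out <- data.frame(
    position = as.integer(vapply(parts, `[[`, character(1), 1L)),
    strand = vapply(parts, `[[`, character(1), 2L),
    count = as.integer(tab), stringsAsFactors = FALSE
  )
  out <- out[order(out$position, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "reference") <- reference
  out
}
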