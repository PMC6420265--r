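#' Fraction of 23-29 nt reads starting with uridine (1U)
#'
#' Computes 100 x (# aligned reads whose first nucleotide, read 5'->3', is
#' T) / n over the 23-29 nt hits. Each aligned read instance contributes
#' once per hit row. An empty hit set is not determined (n.d.) and returns
#' `NA_real_`.
#'
#' @param hits Hit table, restricted internally to 23-29 nt.
#' @param reads Read sequences (named character vector or accepted
#'   container) used to look up first nucleotides.
#' @return Percentage in `[0, 100]`, or `NA_real_` when no reads qualify.
#' @export
first_u_fraction <- function(hits, reads) {
  check_hits(hits)
  hits <- filter_by_length(hits, 23L, 29L)
  if (!nrow(hits)) return(NA_real_)
  seqs <- as_read_seqs(reads)
  s <- seqs[hits$read_id]
  if (anyNA(s)) stop("hit table references reads absent from `reads`")
  100 * mean(substr(s, 1L, 1L) == "T")
}

#' Count sense/antisense 5'-overlap pairs for overlaps 1..29
#'
#' For a plus-strand hit with 5' end p and a minus-strand hit with 5' end q
#' (its highest coordinate) on the same reference, the overlap is
#' i = q - p + 1. Every read-instance pair with i in 1..29 increments O(i);
#' with `collapse = TRUE` placements are first deduplicated to distinct
#' (reference, start, end, strand) alignments so duplicated reads count
#' once.
#'
#' @param hits Hit table (23-29 nt hits of one or more references; pairing
#'   is computed per reference).
#' @param collapse Count distinct aligned sequences instead of read
#'   instances.
#' @return Named numeric vector O with names "1".."29".
#' @export
overlap_pair_counts <- function(hits, collapse = FALSE) {
  check_hits(hits)
  hits <- filter_by_length(hits, 23L, 29L)
  O <- setNames(numeric(29L), as.character(1:29))
  if (!nrow(hits)) return(O)
  if (collapse) {
    hits <- hits[!duplicated(hits[, c("reference", "start", "end", "strand")]),
                 , drop = FALSE]
  }
  for (ref in unique(hits$reference)) {
    h <- hits[hits$reference == ref, , drop = FALSE]
    p5 <- five_prime_ends(h)
    plus <- table(p5[h$strand == "+"])
    minus <- table(p5[h$strand == "-"])
    if (!length(plus) || !length(minus)) next
    pp <- as.integer(names(plus))
    mp <- as.integer(names(minus))
    for (i in 1:29) {
      j <- match(pp + i - 1L, mp)
      ok <- !is.na(j)
      if (any(ok)) {
        O[i] <- O[i] + sum(as.numeric(plus[ok]) * as.numeric(minus[j[ok]]))
      }
    }
  }
  O
}

#' Z-scores of the overlap signature
#'
#' Standardizes the pair counts O(1..29) as z(i) = (O(i) - mean(O)) / sd(O).
#' The default uses the population standard deviation over the 29 overlap
#' values (the 29 overlaps being the full population of interest); the
#' sample standard deviation is available via `sd_type`. When sd(O) = 0 the
#' z-scores are undefined and a flagged all-`NA` vector is returned.
#'
#' @param O Named numeric vector over overlaps 1..29 (from
#'   [overlap_pair_counts()]).
#' @param sd_type `"population"` (divide by n) or `"sample"` (divide by
#'   n - 1).
#' @return Named numeric vector z over 1..29, with attribute
#'   `defined` (logical).
#' @export
overlap_zscores <- function(O, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  if (length(O) != 29L) stop("O must cover overlaps 1..29")
  m <- mean(O)
  s <- if (sd_type == "population") sqrt(mean((O - m)^2)) else sd(O)
  if (!is.finite(s) || s == 0) {
    z <- setNames(rep(NA_real_, 29L), names(O))
    attr(z, "defined") <- FALSE
    return(z)
  }
  z <- (O - m) / s
  attr(z, "defined") <- TRUE
  z
}

# Read ids engaged in at least one exact 10-nt overlap pair, split by the
# strand of the mate. Returns list(plus = ids, minus = ids).
paired_read_ids <- function(hits) {
  hits <- filter_by_length(hits, 23L, 29L)
  plus_ids <- character(0)
  minus_ids <- character(0)
  for (ref in unique(hits$reference)) {
    h <- hits[hits$reference == ref, , drop = FALSE]
    p5 <- five_prime_ends(h)
    hp <- h[h$strand == "+", , drop = FALSE]
    hm <- h[h$strand == "-", , drop = FALSE]
    p5p <- p5[h$strand == "+"]
    p5m <- p5[h$strand == "-"]
    plus_ids <- c(plus_ids, hp$read_id[p5p %in% (p5m - 9L)])
    minus_ids <- c(minus_ids, hm$read_id[p5m %in% (p5p + 9L)])
  }
  list(plus = unique(plus_ids), minus = unique(minus_ids))
}

#' Fraction of 10-nt-overlap paired reads with adenine at position 10 (10A)
#'
#' Among reads engaged in at least one exact 10-nt 5'-overlap pair, computes
#' 100 x (# reads whose tenth nucleotide, read 5'->3', is A) / (# engaged
#' reads). By default both mates of a pair enter the denominator; `mates`
#' restricts scoring to one strand's mates. With no 10-nt pairs the value is
#' not determined (n.d.) and `NA_real_` is returned.
#'
#' @param hits Hit table (restricted internally to 23-29 nt).
#' @param reads Read sequences.
#' @param mates `"both"`, `"plus"` or `"minus"`.
#' @return Percentage or `NA_real_`.
#' @export
tenth_a_fraction <- function(hits, reads, mates = c("both", "plus", "minus")) {
  check_hits(hits)
  mates <- match.arg(mates)
  ids <- paired_read_ids(hits)
  engaged <- switch(mates,
    both = unique(c(ids$plus, ids$minus)),
    plus = ids$plus,
    minus = ids$minus
  )
  if (!length(engaged)) return(NA_real_)
  seqs <- as_read_seqs(reads)
  s <- seqs[engaged]
  if (anyNA(s)) stop("hit table references reads absent from `reads`")
  100 * mean(substr(s, 10L, 10L) == "A")
}

#' Full ping-pong signature report for a hit set
#'
#' Convenience wrapper computing the overlap pair counts, z-scores, 1U and
#' 10A fractions and read tallies in one call.
#'
#' @param hits Hit table (23-29 nt selection applied internally).
#' @param reads Read sequences.
#' @param collapse,sd_type Passed to [overlap_pair_counts()] and
#'   [overlap_zscores()].
#' @return List with elements `O`, `z`, `u1_fraction`, `a10_fraction`,
#'   `n_reads` (23-29 nt hit instances) and `n_paired_reads`.
#' @export
pingpong_signature <- function(hits, reads, collapse = FALSE,
                               sd_type = "population") {
  hits29 <- filter_by_length(check_hits(hits), 23L, 29L)
  O <- overlap_pair_counts(hits29, collapse = collapse)
  z <- overlap_zscores(O, sd_type = sd_type)
  ids <- paired_read_ids(hits29)
  list(
    O = O, z = z,
    u1_fraction = first_u_fraction(hits29, reads),
    a10_fraction = tenth_a_fraction(hits29, reads),
    n_reads = nrow(hits29),
    n_paired_reads = length(unique(c(ids$plus, ids$minus)))
  )
}
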