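#' @keywords internal
"_PACKAGE"

#' @importFrom stats rbinom rnorm runif sd lm coef predict pchisq setNames
#'   aggregate t.test chisq.test prop.test
#' @importFrom utils write.table read.table
NULL

# Reverse complement for plain character vectors (delegates to Biostrings).
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# sample() that never falls into the 1:n trap on length-1 vectors.
resample <- function(x, k, prob = NULL) {
  x[sample.int(length(x), k, replace = TRUE, prob = prob)]
}

# Uniform random DNA string(s) of given length.
random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

# Coerce references to a named character vector of sequences.
as_reference_seqs <- function(references) {
  if (inherits(references, "srna_reference")) {
    references <- references$sequences
  }
  if (methods::is(references, "DNAStringSet")) {
    seqs <- as.character(references)
  } else {
    seqs <- as.character(references)
    names(seqs) <- names(references)
  }
  if (length(seqs) == 0L) stop("reference set is empty")
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop("references must be named")
  }
  seqs
}

# Coerce a read container (named character, DNAStringSet, srna_library or
# data.frame with id/seq) to a named character vector of sequences.
as_read_seqs <- function(reads) {
  if (inherits(reads, "srna_library")) {
    out <- reads$reads$seq
    names(out) <- reads$reads$id
    return(out)
  }
  if (methods::is(reads, "XStringSet")) {
    out <- as.character(reads)
    return(out)
  }
  if (is.data.frame(reads)) {
    out <- as.character(reads$seq)
    names(out) <- as.character(reads$id)
    return(out)
  }
  out <- as.character(reads)
  names(out) <- names(reads)
  out
}

empty_hits <- function() {
  data.frame(
    read_id = character(0), reference = character(0),
    start = integer(0), end = integer(0), strand = character(0),
    mismatches = integer(0), read_length = integer(0), n_hits = integer(0),
    stringsAsFactors = FALSE
  )
}

check_hits <- function(hits) {
  needed <- c("read_id", "reference", "start", "end", "strand",
              "read_length")
  missing <- setdiff(needed, names(hits))
  if (length(missing)) {
    stop("hit table is missing columns: ", paste(missing, collapse = ", "))
  }
  hits
}
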