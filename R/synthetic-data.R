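#' Describe a tandem transgene locus embedded in a toy chromosome
#'
#' A locus specification records the geometry of a tandem array of identical
#' transgene copies (such as a P-element derived cluster) inserted at a fixed
#' position of a synthetic chromosome, together with a flanking gene whose
#' orientation relative to the array can be convergent (the configuration in
#' which read-through antisense transcription can cover the array) or
#' divergent.
#'
#' @param n_copies Number of tandem transgene copies (default 7, the copy
#'   number of the BX2 array).
#' @param unit_length Length in bp of one transgene unit (>= 100).
#' @param flank_gene_length Length in bp of the annotated flanking gene.
#' @param flank_orientation `"convergent"` (flanking gene transcribed towards
#'   the array, annotated on the minus strand) or `"divergent"`.
#' @param chrom_length Total chromosome length in bp.
#' @param insert_position 0-based position of the first base of the array.
#' @return An object of class `locus_spec`.
#' @export
locus_spec <- function(n_copies = 7L, unit_length = 1000L,
                       flank_gene_length = 2000L,
                       flank_orientation = c("convergent", "divergent"),
                       chrom_length = 50000L, insert_position = 20000L) {
  flank_orientation <- match.arg(flank_orientation)
  n_copies <- as.integer(n_copies)
  unit_length <- as.integer(unit_length)
  chrom_length <- as.integer(chrom_length)
  insert_position <- as.integer(insert_position)
  if (n_copies < 1L) stop("n_copies must be >= 1")
  if (unit_length < 100L) stop("unit_length must be >= 100")
  if (insert_position < 0L) stop("insert_position must be >= 0")
  if (insert_position + n_copies * unit_length > chrom_length) {
    stop("repeat block [", insert_position, ", ",
         insert_position + n_copies * unit_length,
         ") overlaps the chromosome end (length ", chrom_length, ")")
  }
  structure(list(
    n_copies = n_copies, unit_length = unit_length,
    flank_gene_length = as.integer(flank_gene_length),
    flank_orientation = flank_orientation,
    chrom_length = chrom_length, insert_position = insert_position
  ), class = "locus_spec")
}

#' Build a synthetic reference genome around a tandem transgene array
#'
#' Constructs one chromosome carrying `n_copies` byte-identical repeats of a
#' random transgene unit at `insert_position`, plus a disjoint decoy contig
#' (`mir_ref`) from which miRNA reads are drawn, and a BED-like annotation of
#' the repeat block and the flanking gene. All coordinates are 0-based
#' half-open. The flanking gene starts at the end of the repeat block; under
#' convergent orientation it is annotated on the minus strand so that its
#' transcription points into the array.
#'
#' @param spec A [locus_spec()].
#' @param seed Integer seed; identical seeds give identical references.
#' @param mir_ref_length Length of the decoy miRNA contig.
#' @return An object of class `srna_reference`: a list with `sequences`
#'   (a named [Biostrings::DNAStringSet-class] with contigs `chr_sim` and
#'   `mir_ref`), `annotation` (data.frame chrom/start/end/name/strand) and
#'   the originating `spec`.
#' @export
build_reference <- function(spec, seed = 1L, mir_ref_length = 5000L) {
  stopifnot(inherits(spec, "locus_spec"))
  set.seed(as.integer(seed))
  unit <- random_dna(1L, spec$unit_length)
  background <- random_dna(1L, spec$chrom_length)
  block <- strrep(unit, spec$n_copies)
  b0 <- spec$insert_position            # 0-based block start
  b1 <- b0 + nchar(block)               # half-open end
  chrom <- paste0(
    substr(background, 1L, b0),
    block,
    substr(background, b1 + 1L, spec$chrom_length)
  )
  stopifnot(nchar(chrom) == spec$chrom_length)
  mir_ref <- random_dna(1L, mir_ref_length)
  sequences <- Biostrings::DNAStringSet(c(chr_sim = chrom, mir_ref = mir_ref))
  gene_end <- min(b1 + spec$flank_gene_length, spec$chrom_length)
  annotation <- data.frame(
    chrom = "chr_sim",
    start = c(b0, b1),
    end = c(b1, gene_end),
    name = c("transgene_cluster", "flank_gene"),
    strand = c("+", if (spec$flank_orientation == "convergent") "-" else "+"),
    stringsAsFactors = FALSE
  )
  structure(list(sequences = sequences, annotation = annotation, spec = spec),
            class = "srna_reference")
}

#' Write a synthetic reference to FASTA plus BED-like annotation
#'
#' @param ref An `srna_reference`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_reference <- function(ref, dir) {
  stopifnot(inherits(ref, "srna_reference"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fa <- file.path(dir, "reference.fa")
  bed <- file.path(dir, "annotation.bed")
  Biostrings::writeXStringSet(ref$sequences, fa)
  write.table(ref$annotation, bed, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(c(fasta = fa, annotation = bed))
}

#' Describe the composition of a synthetic small-RNA library
#'
#' Controls the class mixture and the sequence-composition biases of a
#' simulated ovarian small-RNA library: piRNAs (23-29 nt, drawn from the
#' transgene repeat block, 1U-biased, optionally emitted as ping-pong pairs
#' with exact 10-nt 5' overlap), siRNAs (21 nt, strand-balanced, from the
#' repeat block) and miRNAs (22 nt, from the decoy contig). Because ping-pong
#' partners are genuine reverse complements on the reference, a pair whose
#' initiator starts with U necessarily has a responder with A at position 10
#' (and vice versa); `a10_bias` therefore controls the composition of paired
#' reads while `u1_bias` controls unpaired piRNAs.
#'
#' @param n_pirna,n_sirna,n_mirna Read counts per class.
#' @param pingpong_fraction Fraction of piRNA reads emitted as exact 10-nt
#'   overlap sense/antisense pairs.
#' @param u1_bias Probability that an unpaired piRNA starts with U (T in
#'   read space).
#' @param a10_bias Probability that a ping-pong pair carries the 1U/10A
#'   ping-pong composition on both mates.
#' @param sense_fraction Fraction of unpaired piRNAs on the sense (+) strand.
#' @param pirna_length_weights Named nonnegative weights over lengths 23-29.
#' @param adapter 3' sequencing adapter appended to every read.
#' @param seed Integer seed.
#' @return An object of class `library_spec`.
#' @export
library_spec <- function(n_pirna = 10000L, n_sirna = 2000L, n_mirna = 5000L,
                         pingpong_fraction = 0.5, u1_bias = 0.9,
                         a10_bias = 0.9, sense_fraction = 0.5,
                         pirna_length_weights = c(
                           "23" = 0.05, "24" = 0.12, "25" = 0.25,
                           "26" = 0.25, "27" = 0.18, "28" = 0.10,
                           "29" = 0.05),
                         adapter = "TGGAATTCTCGGGTGCCAAG", seed = 1L) {
  props <- c(pingpong_fraction = pingpong_fraction, u1_bias = u1_bias,
             a10_bias = a10_bias, sense_fraction = sense_fraction)
  if (any(props < 0 | props > 1)) {
    stop("proportions must lie in [0, 1]: ",
         paste(names(props)[props < 0 | props > 1], collapse = ", "))
  }
  if (any(pirna_length_weights < 0) || sum(pirna_length_weights) <= 0) {
    stop("pirna_length_weights must be nonnegative with positive sum")
  }
  if (!identical(sort(as.integer(names(pirna_length_weights))), 23:29)) {
    stop("pirna_length_weights must be named by lengths 23..29")
  }
  if (!nzchar(adapter)) stop("adapter must be non-empty")
  structure(list(
    n_pirna = as.integer(n_pirna), n_sirna = as.integer(n_sirna),
    n_mirna = as.integer(n_mirna), pingpong_fraction = pingpong_fraction,
    u1_bias = u1_bias, a10_bias = a10_bias, sense_fraction = sense_fraction,
    pirna_length_weights = pirna_length_weights[as.character(23:29)],
    adapter = adapter, seed = as.integer(seed)
  ), class = "library_spec")
}

# Extract the read-space sequence of a placement. start is 0-based, length L.
# Plus: reference [start, start+L); minus: reverse complement of the same
# interval, with the read 5' end at coordinate start+L-1.
extract_read <- function(seq, start, len, strand) {
  # substring(), not substr(): start/len are vectors, seq is one string
  s <- substring(seq, start + 1L, start + len)
  n <- max(length(s), length(strand))
  s <- rep_len(s, n)
  neg <- rep_len(strand == "-", n)
  if (any(neg)) s[neg] <- revcomp(s[neg])
  s
}

# Draw n reads uniformly from a single reference interval [start, end).
# Used for background/spike-in unique mappers and by the library simulator.
draw_reads_from_region <- function(ref, contig, start, end, n,
                                   lengths = 23:29,
                                   length_weights = NULL,
                                   sense_fraction = 0.5,
                                   prefix = "region") {
  seqs <- as_reference_seqs(ref)
  if (!contig %in% names(seqs)) stop("unknown contig: ", contig)
  S <- seqs[[contig]]
  if (n == 0L) return(NULL)
  if (is.null(length_weights)) length_weights <- rep(1, length(lengths))
  len <- resample(lengths, n, prob = length_weights)
  strand <- ifelse(runif(n) < sense_fraction, "+", "-")
  p0 <- start + floor(runif(n) * (end - start - max(lengths)))
  data.frame(
    id = sprintf("%s_%06d", prefix, seq_len(n)),
    seq = extract_read(S, p0, len, strand),
    type = "region", contig = contig, start = as.integer(p0),
    strand = strand, length = as.integer(len),
    stringsAsFactors = FALSE
  )
}

#' Simulate a small-RNA sequencing library from a synthetic reference
#'
#' Draws piRNA, siRNA and miRNA reads from the reference according to a
#' [library_spec()]. Reads are exact substrings (or reverse complements of
#' substrings) of the reference, so every read maps back with 0 mismatches
#' after adapter removal. Composition biases (1U, 10A) are realised by
#' biased selection of 5' positions, never by mutating reads. A
#' `pingpong_fraction` of piRNA reads is emitted as sense/antisense pairs
#' whose 5' ends overlap by exactly 10 nt. Each read is then extended 3' with
#' the sequencing adapter (recycled as needed) and truncated to the fixed
#' 50-cycle read length, mimicking adapter read-through of short inserts.
#'
#' @param ref An `srna_reference` from [build_reference()].
#' @param spec A [library_spec()].
#' @param extra_regions Optional list of lists with fields `contig`, `start`,
#'   `end`, `n` (and optionally `lengths`, `sense_fraction`, `prefix`):
#'   additional uniquely-placed 23-29 nt reads drawn uniformly from the given
#'   interval, used for background and spike-in construction.
#' @param cycles Sequencer read length; reads are padded/truncated to this.
#' @return Object of class `srna_library`: list with `reads` (data.frame
#'   id, seq (insert), raw (adapter-terminated 50-cycle sequence), type,
#'   contig, start, strand, length) and `spec`.
#' @export
simulate_small_rna_library <- function(ref, spec, extra_regions = NULL,
                                       cycles = 50L) {
  stopifnot(inherits(ref, "srna_reference"), inherits(spec, "library_spec"))
  set.seed(spec$seed)
  seqs <- as_reference_seqs(ref)
  S <- seqs[["chr_sim"]]
  if (!nzchar(S)) stop("reference chromosome is empty")
  if (spec$pingpong_fraction > 0 && spec$n_pirna < 2L) {
    stop("pingpong_fraction > 0 requires n_pirna >= 2")
  }
  ann <- ref$annotation
  blk <- ann[ann$name == "transgene_cluster", ]
  b0 <- blk$start
  b1 <- blk$end

  chr_chars <- strsplit(S, "")[[1]]
  parts <- list()

  ## --- piRNAs ----------------------------------------------------------
  n_pairs <- floor(spec$pingpong_fraction * spec$n_pirna / 2)
  n_unpaired <- spec$n_pirna - 2L * n_pairs
  lengths <- 23:29
  lw <- spec$pirna_length_weights

  # Unpaired piRNAs: 5' position chosen among block positions whose read
  # first nucleotide is T (plus: ref base T; minus: ref base A) with
  # probability u1_bias.
  if (n_unpaired > 0L) {
    plus_pool <- b0:(b1 - 30L)        # 0-based 5' starts, any length fits
    minus_pool <- (b0 + 29L):(b1 - 1L) # 0-based 5' coords (highest base)
    plus_first <- chr_chars[plus_pool + 1L]
    minus_first <- chr_chars[minus_pool + 1L]
    strand <- ifelse(runif(n_unpaired) < spec$sense_fraction, "+", "-")
    want_u <- runif(n_unpaired) < spec$u1_bias
    p5 <- integer(n_unpaired)
    pick <- function(pool, classes, is_u, k) {
      cand <- pool[if (is_u) classes == "T" else classes != "T"]
      if (!length(cand)) stop("no candidate 5' positions of the required class")
      resample(cand, k)
    }
    for (st in c("+", "-")) {
      pool <- if (st == "+") plus_pool else minus_pool
      cls <- if (st == "+") plus_first else
        chartr("ACGT", "TGCA", minus_first)
      for (u in c(TRUE, FALSE)) {
        sel <- strand == st & want_u == u
        if (any(sel)) p5[sel] <- pick(pool, cls, u, sum(sel))
      }
    }
    len <- resample(lengths, n_unpaired, prob = lw)
    start0 <- ifelse(strand == "+", p5, p5 - len + 1L)
    parts$pirna <- data.frame(
      id = sprintf("pirna_%06d", seq_len(n_unpaired)),
      seq = extract_read(S, start0, len, strand),
      type = "piRNA", contig = "chr_sim", start = as.integer(start0),
      strand = strand, length = as.integer(len), stringsAsFactors = FALSE
    )
  }

  # Ping-pong pairs: anchor p is the plus-mate 5' end; the minus mate 5' end
  # sits at p+9 (exact 10-nt overlap). Anchors with ref[p]=="T" and
  # ref[p+9]=="A" give 1U on both mates and 10A on both mates (reverse
  # complementarity couples these); chosen with probability a10_bias.
  if (n_pairs > 0L) {
    anchor_pool <- (b0 + 19L):(b1 - 40L)
    first_nt <- chr_chars[anchor_pool + 1L]
    tenth_nt <- chr_chars[anchor_pool + 10L]
    pp_yes <- anchor_pool[first_nt == "T" & tenth_nt == "A"]
    pp_no <- anchor_pool[first_nt != "T" & tenth_nt != "A"]
    if (!length(pp_yes) || !length(pp_no)) {
      stop("reference block too short to place ping-pong anchors")
    }
    is_pp <- runif(n_pairs) < spec$a10_bias
    p <- integer(n_pairs)
    p[is_pp] <- resample(pp_yes, sum(is_pp))
    p[!is_pp] <- resample(pp_no, sum(!is_pp))
    len_p <- resample(lengths, n_pairs, prob = lw)
    len_m <- resample(lengths, n_pairs, prob = lw)
    m5 <- p + 9L                       # minus mate 5' coordinate
    start_m <- m5 - len_m + 1L
    parts$pp_plus <- data.frame(
      id = sprintf("pp_%06d_s", seq_len(n_pairs)),
      seq = extract_read(S, p, len_p, "+"),
      type = "piRNA_pp", contig = "chr_sim", start = as.integer(p),
      strand = "+", length = as.integer(len_p), stringsAsFactors = FALSE
    )
    parts$pp_minus <- data.frame(
      id = sprintf("pp_%06d_a", seq_len(n_pairs)),
      seq = extract_read(S, start_m, len_m, "-"),
      type = "piRNA_pp", contig = "chr_sim", start = as.integer(start_m),
      strand = "-", length = as.integer(len_m), stringsAsFactors = FALSE
    )
  }

  ## --- siRNAs: 21 nt, strand-balanced, from the repeat block ------------
  if (spec$n_sirna > 0L) {
    n <- spec$n_sirna
    strand <- ifelse(runif(n) < 0.5, "+", "-")
    start0 <- b0 + floor(runif(n) * (b1 - b0 - 21L))
    parts$sirna <- data.frame(
      id = sprintf("sirna_%06d", seq_len(n)),
      seq = extract_read(S, start0, 21L, strand),
      type = "siRNA", contig = "chr_sim", start = as.integer(start0),
      strand = strand, length = 21L, stringsAsFactors = FALSE
    )
  }

  ## --- miRNAs: 22 nt, plus strand, from the decoy contig ----------------
  if (spec$n_mirna > 0L) {
    M <- seqs[["mir_ref"]]
    n <- spec$n_mirna
    # A small set of fixed "miRNA gene" start positions, so the decoy
    # library looks like discrete species rather than uniform coverage.
    genes <- sort(sample.int(nchar(M) - 30L, 20L))
    start0 <- resample(genes, n)
    parts$mirna <- data.frame(
      id = sprintf("mirna_%06d", seq_len(n)),
      seq = extract_read(M, start0, 22L, "+"),
      type = "miRNA", contig = "mir_ref", start = as.integer(start0),
      strand = "+", length = 22L, stringsAsFactors = FALSE
    )
  }

  ## --- extra user-defined regions --------------------------------------
  if (!is.null(extra_regions)) {
    for (k in seq_along(extra_regions)) {
      r <- extra_regions[[k]]
      parts[[paste0("extra", k)]] <- draw_reads_from_region(
        ref, r$contig, r$start, r$end, r$n,
        lengths = if (is.null(r$lengths)) 23:29 else r$lengths,
        sense_fraction = if (is.null(r$sense_fraction)) 0.5
                         else r$sense_fraction,
        prefix = if (is.null(r$prefix)) paste0("extra", k) else r$prefix
      )
    }
  }

  reads <- do.call(rbind, parts)
  rownames(reads) <- NULL
  # 3' adapter read-through to the fixed cycle count.
  reads$raw <- substr(paste0(reads$seq, strrep(spec$adapter, 3L)), 1L, cycles)
  structure(list(reads = reads, spec = spec, cycles = as.integer(cycles)),
            class = "srna_library")
}

#' Write a simulated library as FASTQ (Sanger Phred+33, constant quality)
#'
#' @param lib An `srna_library`.
#' @param path Output FASTQ path.
#' @return Invisibly, `path`.
#' @export
write_fastq <- function(lib, path) {
  stopifnot(inherits(lib, "srna_library"))
  x <- Biostrings::DNAStringSet(lib$reads$raw)
  names(x) <- lib$reads$id
  q <- Biostrings::BStringSet(strrep("I", nchar(lib$reads$raw)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

#' Read a FASTQ file into a named vector of read sequences
#'
#' @param path FASTQ path.
#' @return Named character vector (names = read ids).
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Ground-truth alignment table of a simulated library
#'
#' Converts the generator's record of where each read was drawn into an
#' alignment-hit table in the same layout as [map_reads()] output (one
#' placement per read, 0 mismatches). Useful for statistics that do not
#' depend on multi-mapping structure.
#'
#' @param lib An `srna_library`.
#' @return Hit data.frame (see [map_reads()]).
#' @export
truth_hits <- function(lib) {
  stopifnot(inherits(lib, "srna_library"))
  r <- lib$reads
  data.frame(
    read_id = r$id, reference = r$contig,
    start = r$start, end = r$start + r$length,
    strand = r$strand, mismatches = 0L, read_length = r$length,
    n_hits = 1L, stringsAsFactors = FALSE
  )
}

#' Simulate a qPCR plate from known starting quantities
#'
#' Generates technical-replicate Cq values under the standard exponential
#' amplification model: `Cq = intercept - log10(quantity)/log10(1 +
#' efficiency) + noise`. At efficiency 1 a 10-fold dilution step therefore
#' shifts Cq by log2(10) = 3.3219 cycles.
#'
#' @param true_quantities Named numeric vector of starting quantities (> 0).
#' @param efficiency Amplification efficiency in (0, 1].
#' @param noise_sd Gaussian noise SD in Cq units.
#' @param seed Integer seed.
#' @param intercept Cq of one starting unit.
#' @param n_replicates Technical replicates per sample.
#' @param target Target label recorded in the table.
#' @return data.frame with columns sample, target, replicate, Cq.
#' @export
simulate_qpcr_plate <- function(true_quantities, efficiency = 1,
                                noise_sd = 0, seed = 1L, intercept = 36,
                                n_replicates = 3L, target = "gene") {
  if (is.null(names(true_quantities)) || any(!nzchar(names(true_quantities)))) {
    stop("true_quantities must be a named vector")
  }
  if (any(true_quantities <= 0)) stop("quantities must be positive")
  if (efficiency <= 0 || efficiency > 1) stop("efficiency must be in (0, 1]")
  set.seed(as.integer(seed))
  n <- length(true_quantities)
  out <- data.frame(
    sample = rep(names(true_quantities), each = n_replicates),
    target = target,
    replicate = rep(seq_len(n_replicates), times = n),
    stringsAsFactors = FALSE
  )
  mu <- intercept - log10(rep(true_quantities, each = n_replicates)) /
    log10(1 + efficiency)
  out$Cq <- mu + rnorm(nrow(out), 0, noise_sd)
  out
}
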