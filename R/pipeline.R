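#' Default end-to-end demonstration configuration
#'
#' A compact configuration exercising every stage: a 7-copy tandem locus on
#' a 150-kb chromosome (three 50-kb windows), an OFF library (background
#' unique mappers only) and an ON library that additionally produces piRNAs
#' from a single-copy region inside the second window, so the scan flags
#' exactly one window.
#'
#' @param seed Integer master seed.
#' @return Named list accepted by [run_pipeline()].
#' @export
demo_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    locus = list(n_copies = 7L, unit_length = 1000L, chrom_length = 150000L,
                 insert_position = 10000L),
    library = list(n_pirna = 2000L, n_sirna = 500L, n_mirna = 500L,
                   pingpong_fraction = 0.5, u1_bias = 0.9, a10_bias = 0.9),
    background = list(n = 100L, start = 100000L, end = 150000L),
    spike = list(start = 60000L, end = 62000L, n = 300L),
    trim = list(min_match = 6L),
    map = list(max_mismatches = 1L),
    window = list(width = 50000L, min_density = 5, mode = "either",
                  pseudocount = 1, log2_threshold = 8.5)
  )
}

pipeline_allowed_keys <- c("seed", "locus", "library", "library_b",
                           "background", "spike", "trim", "map", "window")

validate_config <- function(config) {
  if (!is.list(config)) stop("config must be a list")
  unknown <- setdiff(names(config), pipeline_allowed_keys)
  if (length(unknown)) {
    stop("unknown config key: ", paste(unknown, collapse = ", "))
  }
  if (is.null(config$seed)) stop("config requires a seed")
  invisible(config)
}

# One library through simulate -> FASTQ -> trim -> map; returns hit tables
# and intermediate paths.
pipeline_library <- function(ref, lspec, extras, config, out_dir, tag) {
  lib <- simulate_small_rna_library(ref, lspec, extra_regions = extras)
  fq <- file.path(out_dir, paste0("library_", tag, ".fastq"))
  write_fastq(lib, fq)
  raw <- read_fastq(fq)
  min_match <- config$trim$min_match %||% 6L
  trimmed <- trim_adapter(raw, lspec$adapter, min_match = min_match)
  trimmed <- trimmed[nchar(trimmed) >= 1L]
  mm <- config$map$max_mismatches %||% 1L
  hits <- map_reads(trimmed, ref, max_mismatches = mm)
  hits <- filter_by_length(hits, 18L, 29L)
  write_hits(hits, file.path(out_dir, paste0("hits_", tag, ".tsv")))
  list(lib = lib, reads = trimmed, hits = hits)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full small-RNA analysis pipeline on simulated data
#'
#' Orchestrates simulate -> trim -> map -> size profiles -> ping-pong
#' signature -> window scan with plain-file intermediates (FASTQ, TSV) and a
#' JSON summary, all deterministic under the configured seed. Unknown
#' configuration keys fail fast with the offending key named.
#'
#' @param config Configuration list, see [demo_config()] for the accepted
#'   keys. `library_b` (defaulting to `library`) plus `spike` define the
#'   second library of the window comparison; omit `spike` and `library_b`
#'   to skip the scan.
#' @param out_dir Output directory for the report bundle.
#' @return Invisibly, the summary list (also written to `summary.json`):
#'   per-library read totals, ping-pong z(10), 1U/10A percentages, and the
#'   flagged windows of the scan.
#' @export
run_pipeline <- function(config = demo_config(), out_dir = tempfile("run")) {
  validate_config(config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- as.integer(config$seed)

  lsp <- do.call(locus_spec, config$locus %||% list())
  ref <- build_reference(lsp, seed = seed)
  write_reference(ref, out_dir)
  chrom_lengths <- setNames(Biostrings::width(ref$sequences),
                            names(ref$sequences))

  lib_args <- config$library %||% list()
  lib_args$seed <- seed
  spec_a <- do.call(library_spec, lib_args)
  # background unique mappers are drawn away from the spiked window so an
  # ON-only producer stays ON-only in the comparison library
  bg <- if (!is.null(config$background)) {
    list(list(contig = "chr_sim",
              start = config$background$start %||% 0L,
              end = config$background$end %||% chrom_lengths[["chr_sim"]],
              n = config$background$n, prefix = "bg"))
  }
  a <- pipeline_library(ref, spec_a, bg, config, out_dir, "a")

  # Size distribution and ping-pong signature on library A.
  sizes <- size_distribution(a$hits, weighting = "fractional")
  n_genome <- length(unique(a$hits$read_id))
  sizes$rpm <- as.numeric(normalize_rpm(sizes$count, n_genome,
                                        mode = "genome_million"))
  write.table(sizes, file.path(out_dir, "size_distribution_a.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cluster_hits <- a$hits[a$hits$reference == "chr_sim", , drop = FALSE]
  sig <- pingpong_signature(filter_by_length(cluster_hits, 23L, 29L),
                            a$reads)
  write.table(
    data.frame(overlap = 1:29, count = as.numeric(sig$O),
               z = as.numeric(sig$z)),
    file.path(out_dir, "pingpong_signature_a.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )

  summary <- list(
    seed = seed,
    library_a = list(
      n_reads = length(a$reads),
      n_mapped = length(unique(a$hits$read_id)),
      z10 = as.numeric(sig$z[["10"]]),
      u1_fraction = sig$u1_fraction,
      a10_fraction = sig$a10_fraction
    )
  )

  # Window comparison when a second (spiked) library is configured.
  if (!is.null(config$spike) || !is.null(config$library_b)) {
    lib_b_args <- config$library_b %||% config$library %||% list()
    lib_b_args$seed <- seed + 1L
    spec_b <- do.call(library_spec, lib_b_args)
    extras_b <- bg
    if (!is.null(config$spike)) {
      sp <- config$spike
      extras_b <- c(extras_b, list(list(
        contig = sp$contig %||% "chr_sim", start = sp$start, end = sp$end,
        n = sp$n, prefix = "spike"
      )))
    }
    b <- pipeline_library(ref, spec_b, extras_b, config, out_dir, "b")
    ua <- filter_by_length(unique_mappers(a$hits), 23L, 29L)
    ub <- filter_by_length(unique_mappers(b$hits), 23L, 29L)
    wcfg <- config$window %||% list()
    win <- scan_windows(
      ua, ub, chrom_lengths,
      normalizer_a = length(unique(a$hits$read_id)),
      normalizer_b = length(unique(b$hits$read_id)),
      width = wcfg$width %||% 50000L,
      min_density = wcfg$min_density %||% 5,
      mode = wcfg$mode %||% "either",
      pseudocount = wcfg$pseudocount %||% 1,
      log2_threshold = wcfg$log2_threshold %||% 8.5
    )
    write.table(win, file.path(out_dir, "window_scan.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    summary$window_scan <- list(
      n_candidate = nrow(win),
      n_flagged = sum(win$flagged),
      flagged = win[win$flagged, c("chrom", "start", "end", "log2_ratio"),
                    drop = FALSE]
    )
  }

  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(summary)
}
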