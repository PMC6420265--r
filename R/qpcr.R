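#' Number of dsDNA molecules in a given mass
#'
#' Converts a double-stranded DNA mass to a molecule count using Avogadro's
#' number and an average base-pair weight of 650 g/mol:
#' `mass * 6.022e23 / (length * 650)`. 50 fg of an 11,191-bp plasmid is
#' about 4139 molecules.
#'
#' @param mass_g Mass in grams (>= 0).
#' @param length_bp dsDNA length in base pairs (> 0).
#' @param round Round to the nearest integer for reporting.
#' @return Molecule count.
#' @export
copies_from_mass <- function(mass_g, length_bp, round = TRUE) {
  if (any(length_bp <= 0)) stop("length_bp must be positive")
  if (any(mass_g < 0)) stop("mass_g must be >= 0")
  n <- mass_g * 6.022e23 / (length_bp * 650)
  if (round) round(n) else n
}

#' Fit a qPCR standard curve from a dilution series
#'
#' Least-squares line of Cq on log10(quantity) over at least three distinct
#' dilution points. The amplification efficiency follows from the slope as
#' `10^(-1/slope) - 1` (slope -3.3219 corresponds to 100% efficiency).
#'
#' @param quantity Known starting quantities (> 0).
#' @param cq Measured Cq values (mean of technical replicates, or raw).
#' @return Object of class `standard_curve`: slope, intercept, efficiency,
#'   r2, n and a `valid` flag (FALSE when the slope is nonnegative).
#' @export
fit_standard_curve <- function(quantity, cq) {
  if (length(quantity) != length(cq)) stop("quantity and cq lengths differ")
  if (length(unique(quantity)) < 3L) {
    stop("need at least 3 distinct dilution points")
  }
  if (any(quantity <= 0)) stop("quantities must be positive")
  fit <- lm(cq ~ log10(quantity))
  slope <- unname(coef(fit)[2])
  intercept <- unname(coef(fit)[1])
  # summary.lm warns on noiseless (perfect-fit) standards; that case is fine
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(list(
    slope = slope, intercept = intercept,
    efficiency = 10^(-1 / slope) - 1,
    r2 = r2, n = length(cq), valid = slope < 0
  ), class = "standard_curve")
}

#' Starting quantity (Sq) from a Cq via a fitted standard curve
#'
#' Inverts the standard-curve line: `Sq = 10^((cq - intercept) / slope)`.
#'
#' @param curve A [fit_standard_curve()] result.
#' @param cq Cq value(s).
#' @return Starting quantities on the scale of the curve's standards.
#' @export
quantity_from_cq <- function(curve, cq) {
  stopifnot(inherits(curve, "standard_curve"))
  if (!curve$valid) stop("standard curve has a nonnegative slope")
  10^((cq - curve$intercept) / curve$slope)
}

#' Mean starting quantity over technical replicates (meanSq)
#'
#' @param sq Replicate Sq values.
#' @return Arithmetic mean.
#' @export
mean_sq <- function(sq) {
  if (!length(sq)) stop("no replicate values")
  mean(sq)
}

#' Reference-normalized relative expression
#'
#' `meanSq(gene) / meanSq(reference)`, the per-sample normalization against
#' a housekeeping reference (e.g. RpL32).
#'
#' @param mean_sq_gene,mean_sq_reference Mean starting quantities.
#' @return Ratio (>= 0).
#' @export
relative_expression <- function(mean_sq_gene, mean_sq_reference) {
  if (any(mean_sq_reference <= 0)) stop("reference meanSq must be positive")
  mean_sq_gene / mean_sq_reference
}

#' Strand-specific transcript quantity with background subtraction
#'
#' Sense- or antisense-specific reverse transcription is quantified as
#' `meanSq(primed) - meanSq(no-primer control)`; the control RT measures
#' self-priming background. Negative differences are floored at zero and
#' flagged as at/below background.
#'
#' @param mean_sq_primed meanSq of the strand-specific primed RT.
#' @param mean_sq_control meanSq of the no-primer control RT.
#' @return List with `quantity` (floored at 0) and `below_background`.
#' @export
strand_specific_quantity <- function(mean_sq_primed, mean_sq_control) {
  d <- mean_sq_primed - mean_sq_control
  list(quantity = pmax(d, 0), below_background = d <= 0)
}

#' ChIP-qPCR enrichment normalized to input and reference regions
#'
#' Computes (IP/input) for the target and divides by the mean (IP/input)
#' over reference regions known to carry the mark, yielding an enrichment of
#' 1 for a target behaving like the references.
#'
#' @param ip_sq,input_sq Target IP and input quantities (input > 0).
#' @param reference_ratios Numeric vector of (IP/input) ratios of the
#'   reference regions (>= 1 region).
#' @return Normalized enrichment.
#' @export
chip_enrichment <- function(ip_sq, input_sq, reference_ratios) {
  if (any(input_sq <= 0)) stop("input quantity must be positive")
  if (!length(reference_ratios)) stop("need at least one reference region")
  (ip_sq / input_sq) / mean(reference_ratios)
}

#' Two-sample t test on group means
#'
#' Student's equal-variance two-sided test by default (`var_equal = TRUE`),
#' Welch's test behind the flag.
#'
#' @param group_a,group_b Numeric vectors (>= 2 values each).
#' @param var_equal Assume equal variances (Student) or not (Welch).
#' @return List with t, df, p_value.
#' @export
two_sample_t <- function(group_a, group_b, var_equal = TRUE) {
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("each group needs at least 2 values")
  }
  fit <- t.test(group_a, group_b, var.equal = var_equal)
  list(t = unname(fit$statistic), df = unname(fit$parameter),
       p_value = fit$p.value)
}
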