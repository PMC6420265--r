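#' Parameters of the transgenerational epiallele conversion model
#'
#' The simulator models a tandem-transgene epiallele that is OFF (no piRNA
#' production) or ON (producing piRNAs and repressing a homologous target).
#' At 29 degrees C, in the presence of a transcribed homologous target, each
#' germline progenitor of an OFF female converts independently with
#' probability `c_event` per generation; a converted progenitor gives rise
#' to `cluster_size` repressed egg chambers, so per-chamber and per-female
#' conversion rates decouple when conversion is clonal. Conversion never
#' occurs at 25 degrees C or without the target. ON mothers transmit the ON
#' state to each offspring with probability `paramutation_prob` (1 =
#' fully penetrant paramutation); paternal transmission yields OFF
#' offspring.
#'
#' @param c_event Conversion probability per germline progenitor per
#'   generation at 29 degrees C.
#' @param chambers_per_female Egg chambers per female (default 120 = 2
#'   ovaries x 60 chambers).
#' @param cluster_size Egg chambers descending from one converted germline
#'   progenitor (must divide `chambers_per_female`).
#' @param target_present Is a germline-transcribed homologous target
#'   present?
#' @param paramutation_prob Probability that an offspring of an ON mother
#'   is ON.
#' @param females_sampled Mothers sampled per generation in lineage runs.
#' @param offspring_per_female Offspring scored per mother in lineage runs.
#' @param seed Integer seed.
#' @return Object of class `sim_params`.
#' @export
sim_params <- function(c_event = 0.027, chambers_per_female = 120L,
                       cluster_size = 1L, target_present = TRUE,
                       paramutation_prob = 1, females_sampled = 50L,
                       offspring_per_female = 10L, seed = 1L) {
  if (c_event < 0 || c_event > 1) stop("c_event must be in [0, 1]")
  if (paramutation_prob < 0 || paramutation_prob > 1) {
    stop("paramutation_prob must be in [0, 1]")
  }
  chambers_per_female <- as.integer(chambers_per_female)
  cluster_size <- as.integer(cluster_size)
  if (cluster_size < 1L || cluster_size > chambers_per_female) {
    stop("cluster_size must lie in [1, chambers_per_female]")
  }
  if (chambers_per_female %% cluster_size != 0L) {
    stop("cluster_size must divide chambers_per_female")
  }
  structure(list(
    c_event = c_event, chambers_per_female = chambers_per_female,
    cluster_size = cluster_size, target_present = isTRUE(target_present),
    paramutation_prob = paramutation_prob,
    females_sampled = as.integer(females_sampled),
    offspring_per_female = as.integer(offspring_per_female),
    seed = as.integer(seed)
  ), class = "sim_params")
}

#' Simulate one female's germline conversion and offspring states
#'
#' An OFF female at 29 degrees C with the target present draws the number of
#' converted germline progenitors as Binomial(chambers/cluster_size,
#' c_event); each converted progenitor yields `cluster_size` repressed (ON)
#' egg chambers. Offspring each inherit the state of one uniformly chosen
#' maternal egg chamber. An ON mother produces ON offspring with probability
#' `paramutation_prob` each. At 25 degrees C or without the target no
#' conversion occurs. Uses the ambient RNG stream.
#'
#' @param state `"OFF"` or `"ON"` maternal epiallele state.
#' @param params A [sim_params()].
#' @param temperature 25 or 29.
#' @param n_offspring Number of offspring states to draw.
#' @return List with `n_converted_chambers` and character vector
#'   `offspring_states`.
#' @export
simulate_female <- function(state = c("OFF", "ON"), params,
                            temperature = 29, n_offspring = 0L) {
  state <- match.arg(state)
  stopifnot(inherits(params, "sim_params"))
  if (!temperature %in% c(25, 29)) stop("temperature must be 25 or 29")
  K <- params$chambers_per_female
  if (state == "ON") {
    off <- if (n_offspring > 0L) {
      ifelse(runif(n_offspring) < params$paramutation_prob, "ON", "OFF")
    } else character(0)
    return(list(n_converted_chambers = K, offspring_states = off))
  }
  n_conv <- 0L
  if (temperature == 29 && params$target_present && params$c_event > 0) {
    n_prog <- K %/% params$cluster_size
    n_conv <- rbinom(1L, n_prog, params$c_event) * params$cluster_size
  }
  off <- if (n_offspring > 0L) {
    ifelse(runif(n_offspring) < n_conv / K, "ON", "OFF")
  } else character(0)
  list(n_converted_chambers = n_conv, offspring_states = off)
}

#' Simulate a lineage of females across generations
#'
#' Each generation samples `females_sampled` mothers with replacement from
#' the current pool, applies [simulate_female()] to each, records the
#' fraction of repressed egg chambers, the fraction of mothers showing any
#' repression, and the epiallele composition of the next pool (the pooled
#' offspring). The small sample drawn each generation produces the drift
#' and between-line variance seen in repeated lineages.
#'
#' @param params A [sim_params()]; `params$seed` fixes the trajectory.
#' @param n_generations Number of generations (>= 1).
#' @param founder_states Character vector of founder epiallele states
#'   (recycled to `females_sampled` founders if length 1).
#' @param temperature_schedule Per-generation temperatures (25/29),
#'   recycled.
#' @return data.frame with one row per generation: generation,
#'   fraction_repressed_chambers, fraction_females_repressed,
#'   fraction_on_offspring, n_mothers.
#' @export
simulate_lineage <- function(params, n_generations,
                             founder_states = "OFF",
                             temperature_schedule = 29) {
  stopifnot(inherits(params, "sim_params"))
  if (n_generations < 1L) stop("n_generations must be >= 1")
  set.seed(params$seed)
  temps <- rep_len(temperature_schedule, n_generations)
  pool <- rep_len(founder_states, params$females_sampled)
  out <- vector("list", n_generations)
  for (g in seq_len(n_generations)) {
    if (!length(pool)) stop("population went extinct at generation ", g)
    mothers <- resample(pool, params$females_sampled)
    conv <- integer(length(mothers))
    offspring <- vector("list", length(mothers))
    for (i in seq_along(mothers)) {
      res <- simulate_female(mothers[i], params, temps[g],
                             params$offspring_per_female)
      conv[i] <- res$n_converted_chambers
      offspring[[i]] <- res$offspring_states
    }
    nxt <- unlist(offspring)
    out[[g]] <- data.frame(
      generation = g,
      fraction_repressed_chambers =
        sum(conv) / (length(mothers) * params$chambers_per_female),
      fraction_females_repressed = mean(conv > 0L),
      fraction_on_offspring = mean(nxt == "ON"),
      n_mothers = length(mothers)
    )
    pool <- nxt
  }
  do.call(rbind, out)
}

#' Maximum-likelihood recovery of the per-progenitor conversion rate
#'
#' From per-female converted-chamber counts of a single-generation design,
#' estimates `c_event` as the binomial MLE over germline progenitors
#' (converted chambers / cluster_size successes out of
#' chambers/cluster_size trials per female), with its standard error. With
#' all-zero data the estimate is 0 and a one-sided 95% upper bound
#' `1 - 0.05^(1/N)` is reported.
#'
#' @param n_converted_chambers Integer vector, one entry per female.
#' @param params A [sim_params()] fixing `chambers_per_female` and the
#'   assumed `cluster_size`.
#' @return List with estimate, se, upper95, n_females, n_trials.
#' @export
recover_rate <- function(n_converted_chambers, params) {
  stopifnot(inherits(params, "sim_params"))
  if (!length(n_converted_chambers)) stop("no observations")
  if (any(n_converted_chambers %% params$cluster_size != 0L)) {
    stop("converted-chamber counts are not multiples of cluster_size")
  }
  n_prog <- params$chambers_per_female %/% params$cluster_size
  x <- sum(n_converted_chambers) / params$cluster_size
  N <- length(n_converted_chambers) * n_prog
  p <- x / N
  list(
    estimate = p,
    se = sqrt(p * (1 - p) / N),
    upper95 = if (x == 0) 1 - 0.05^(1 / N) else NA_real_,
    n_females = length(n_converted_chambers),
    n_trials = N
  )
}
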