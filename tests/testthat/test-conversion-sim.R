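test_that("conversion is impossible without heat or without the target", {
  set.seed(601)
  p_heat <- sim_params(c_event = 0.2)
  p_no_target <- sim_params(c_event = 0.2, target_present = FALSE)
  for (i in 1:50) {
    expect_equal(simulate_female("OFF", p_heat, temperature = 25)$
                   n_converted_chambers, 0L)
    expect_equal(simulate_female("OFF", p_no_target, temperature = 29)$
                   n_converted_chambers, 0L)
  }
  p0 <- sim_params(c_event = 0)
  expect_equal(simulate_female("OFF", p0, 29)$n_converted_chambers, 0L)
  res <- simulate_female("OFF", p0, 29, n_offspring = 20L)
  expect_true(all(res$offspring_states == "OFF"))
})

test_that("per-chamber conversion matches the binomial closed form", {
  set.seed(602)
  params <- sim_params(c_event = 0.027, cluster_size = 1L)
  n_f <- 5000
  conv <- vapply(seq_len(n_f), function(i) {
    simulate_female("OFF", params, 29)$n_converted_chambers
  }, integer(1))
  # mean converted-chamber fraction ~ c_event
  frac <- mean(conv) / params$chambers_per_female
  se <- sqrt(0.027 * (1 - 0.027) / (n_f * 120))
  expect_lt(abs(frac - 0.027), 3 * se)
  # P(female has >= 1 converted chamber) = 1 - (1 - c)^120
  p_any <- 1 - (1 - 0.027)^120
  se_any <- sqrt(p_any * (1 - p_any) / n_f)
  expect_lt(abs(mean(conv > 0) - p_any), 3 * se_any)
})

test_that("clustered conversion lowers the per-female rate at a fixed per-chamber rate", {
  # with the per-chamber rate held, larger clusters concentrate conversions
  # in fewer females
  set.seed(603)
  frac_females <- vapply(c(1L, 10L, 40L), function(cs) {
    params <- sim_params(c_event = 0.027, cluster_size = cs)
    conv <- vapply(1:2000, function(i) {
      simulate_female("OFF", params, 29)$n_converted_chambers
    }, integer(1))
    mean(conv > 0)
  }, numeric(1))
  expect_true(all(diff(frac_females) < 0))
})

test_that("epiallele states are stable where the model says they must be", {
  # all-ON founders at 25 C with full paramutation: flat 100%
  p_on <- sim_params(paramutation_prob = 1, females_sampled = 30L,
                     offspring_per_female = 5L, seed = 10L)
  traj <- simulate_lineage(p_on, 10L, founder_states = "ON",
                           temperature_schedule = 25)
  expect_true(all(traj$fraction_females_repressed == 1))
  expect_true(all(traj$fraction_on_offspring == 1))

  # all-OFF founders at 25 C: flat 0%
  traj0 <- simulate_lineage(p_on, 10L, founder_states = "OFF",
                            temperature_schedule = 25)
  expect_true(all(traj0$fraction_repressed_chambers == 0))
  expect_true(all(traj0$fraction_on_offspring == 0))

  # determinism: identical seeds give identical trajectories
  p <- sim_params(c_event = 0.02, females_sampled = 40L, seed = 77L)
  expect_identical(simulate_lineage(p, 8L), simulate_lineage(p, 8L))
})

test_that("repression rises across generations at 29 C with drift", {
  trajs <- lapply(1:8, function(line) {
    p <- sim_params(c_event = 0.02, females_sampled = 25L,
                    offspring_per_female = 8L, seed = 700L + line)
    simulate_lineage(p, 25L)
  })
  final <- vapply(trajs, function(t) tail(t$fraction_females_repressed, 1),
                  numeric(1))
  first <- vapply(trajs, function(t) t$fraction_females_repressed[1],
                  numeric(1))
  # conversion accumulates in expectation over 25 generations
  expect_gt(mean(final), mean(first))
  # between-line variance exists (various dynamics across replicate lines)
  expect_gt(var(final), 0)
})

test_that("rate recovery is unbiased and handles the all-zero design", {
  set.seed(604)
  params <- sim_params(c_event = 0.027, cluster_size = 1L)
  conv <- vapply(1:5000, function(i) {
    simulate_female("OFF", params, 29)$n_converted_chambers
  }, integer(1))
  est <- recover_rate(conv, params)
  expect_lt(abs(est$estimate - 0.027), 3 * est$se)

  # all-zero data: point estimate 0 with a one-sided upper bound
  z <- recover_rate(rep(0L, 975), params)
  expect_equal(z$estimate, 0)
  expect_gt(z$upper95, 0)
  expect_lt(z$upper95, 1e-4)
  expect_error(recover_rate(integer(0), params), "no observations")
})

test_that("cluster-size misspecification inflates the inferred event count", {
  set.seed(605)
  truth <- sim_params(c_event = 0.027, cluster_size = 5L)
  conv <- vapply(1:4000, function(i) {
    simulate_female("OFF", truth, 29)$n_converted_chambers
  }, integer(1))
  # events inferred under the (wrong) independent-chamber model are ~5x the
  # true number of clonal conversion events
  assumed <- sim_params(c_event = 0.027, cluster_size = 1L)
  est1 <- recover_rate(conv, assumed)
  est5 <- recover_rate(conv, truth)
  events1 <- est1$estimate * est1$n_trials
  events5 <- est5$estimate * est5$n_trials
  expect_equal(events1 / events5, 5, tolerance = 1e-9)
})
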