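test_that("the vaccine-trial mechanism matches its stated laws", {
  trial <- suppressWarnings(generate_covid_trial(20000, seed = 2001))
  # placebo risk is the constant 0.1
  expect_true(all(trial$risk[trial$x == 0] == 0.1))
  # continuous B-cell response: mean 0.5 + 1.0 X, variance 1
  m1_1 <- trial$m1_raw[trial$x == 1]
  expect_lt(abs(mean(m1_1) - 1.5), 4 / sqrt(length(m1_1)))
  expect_lt(abs(sd(m1_1) - 1), 0.05)
  # log antibody: mean 6.5 + 0.5 X, sd 0.3
  lm2_0 <- log(trial$m2_raw[trial$x == 0])
  expect_lt(abs(mean(lm2_0) - 6.5), 4 * 0.3 / sqrt(length(lm2_0)))
  expect_lt(abs(sd(lm2_0) - 0.3), 0.02)
  # dichotomization thresholds
  expect_equal(trial$m1, as.integer(trial$m1_raw >= 1))
  expect_equal(trial$m2, as.integer(trial$m2_raw >= 1000))
})

test_that("risk clipping is detected and reported", {
  expect_warning(generate_covid_trial(5000, seed = 2101),
                 class = "crossmed_dgp_clipping_warning")
  trial <- suppressWarnings(generate_covid_trial(5000, seed = 2101))
  expect_gt(attr(trial, "clip_fraction"), 0.10)
  expect_true(all(trial$risk >= 0 & trial$risk <= 1))
  # the literal reading of the risk expression is not a probability: nearly
  # every vaccine-arm draw must be clipped
  lit <- suppressWarnings(
    generate_covid_trial(2000, covid_params(exponent_form = "literal"),
                         seed = 2102))
  expect_gt(attr(lit, "clip_fraction"), 0.95)
})

test_that("component substreams are independent of downstream parameters", {
  t1 <- suppressWarnings(generate_covid_trial(500, seed = 2201))
  t2 <- suppressWarnings(
    generate_covid_trial(500, covid_params(logm2_sd = 0.6), seed = 2201))
  expect_identical(t1$x, t2$x)
  expect_identical(t1$m1_raw, t2$m1_raw) # changing M2's law leaves M1 alone
  expect_false(identical(t1$m2_raw, t2$m2_raw))
  t3 <- suppressWarnings(generate_covid_trial(500, seed = 2201))
  expect_identical(t1, t3)
})

test_that("placebo events fall in the expected binomial range", {
  trial <- suppressWarnings(generate_covid_trial(1000, seed = 2301))
  s <- summarize_trial(trial)
  n0 <- s$arms$n[s$arms$x == 0]
  ev0 <- s$arms$events[s$arms$x == 0]
  band <- qbinom(c(0.005, 0.995), n0, 0.1)
  expect_gte(ev0, band[1])
  expect_lte(ev0, band[2])
  expect_equal(sum(s$arms$n), 1000)
  expect_equal(sum(s$cells$count), 1000)
})

test_that("trial summaries tabulate degenerate inputs", {
  empty <- data.frame(x = integer(), m1 = integer(), m2 = integer(),
                      y = integer())
  s <- summarize_trial(empty)
  expect_equal(sum(s$cells$count), 0)
  expect_equal(nrow(s$arms), 0)
})

test_that("structural simulation converges to the implied probability table", {
  s <- sample_compatible_distribution("B", concentration = 1, seed = 2401)
  sim <- generate_npsem(1e5, dag = "B", q = s$q, seed = 2402)
  emp <- observed_distribution(sim$data)
  tv0 <- sum(abs(emp$p[emp$x == 0] - s$dist$p[s$dist$x == 0])) / 2
  tv1 <- sum(abs(emp$p[emp$x == 1] - s$dist$p[s$dist$x == 1])) / 2
  expect_lt(tv0, 0.02)
  expect_lt(tv1, 0.02)
})

test_that("unconfounded configurations factor exactly", {
  sim <- generate_npsem(100, dag = "B", confounded = FALSE, seed = 2501)
  space <- response_profiles("B")
  q <- as.numeric(sim$q)
  qm1 <- rowsum(q, space$i_m1)[, 1]
  qm2 <- rowsum(q, space$i_m2)[, 1]
  qy <- rowsum(q, space$i_y)[, 1]
  rebuilt <- qm1[space$i_m1 + 1] * qm2[space$i_m2 + 1] * qy[space$i_y + 1]
  expect_lt(max(abs(q - rebuilt)), 1e-12)
  # confounded draws generally do not factor
  simc <- generate_npsem(100, dag = "B", confounded = TRUE, seed = 2501)
  qc <- as.numeric(simc$q)
  qm1c <- rowsum(qc, space$i_m1)[, 1]
  qm2c <- rowsum(qc, space$i_m2)[, 1]
  qyc <- rowsum(qc, space$i_y)[, 1]
  rebuiltc <- qm1c[space$i_m1 + 1] * qm2c[space$i_m2 + 1] * qyc[space$i_y + 1]
  expect_gt(max(abs(qc - rebuiltc)), 1e-6)
})

test_that("a point-mass profile law yields one pattern per arm", {
  space <- response_profiles("B")
  q <- rep(0, space$n_profiles)
  q[777] <- 1
  sim <- generate_npsem(200, dag = "B", q = profile_distribution(q, "B"),
                        seed = 2601)
  pat <- unique(sim$data[sim$data$x == 1, c("m1", "m2", "y")])
  expect_equal(nrow(pat), 1)
  pat0 <- unique(sim$data[sim$data$x == 0, c("m1", "m2", "y")])
  expect_equal(nrow(pat0), 1)
})

test_that("bounds from confounded simulations still contain the truth", {
  for (k in 1:3) {
    sim <- generate_npsem(5e4, dag = "B", confounded = TRUE,
                          concentration = 0.5, seed = 2700 + k)
    tr <- sim$truth
    b <- cross_bounds(sim$data, dag = "B", method = "symbolic")
    m <- merge(as.data.frame(b), as.data.frame(tr), by = "estimand")
    # sampling noise in the table can push a truth marginally outside
    expect_true(all(m$truth >= m$lower - 0.03 & m$truth <= m$upper + 0.03))
  }
})
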