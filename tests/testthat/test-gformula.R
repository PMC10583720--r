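test_that("saturated fits without covariates are stratified frequencies", {
  withr::with_seed(31, {
    n <- 400
    d <- data.frame(
      x = rep(0:1, each = n / 2),
      m1 = rbinom(n, 1, 0.5), m2 = rbinom(n, 1, 0.5), y = rbinom(n, 1, 0.5)
    )
  })
  models <- fit_mediation_models(d, dag = "B", model_form = "saturated")
  for (x in 0:1) for (m1 in 0:1) for (m2 in 0:1) {
    sel <- d$x == x & d$m1 == m1 & d$m2 == m2
    expect_equal(models$pY(x, m1, m2), mean(d$y[sel]))
  }
  expect_equal(models$pM1(1), mean(d$m1[d$x == 1]))
  expect_equal(models$pM2(0, 1), mean(d$m2[d$x == 0 & d$m1 == 1]))

  all_one <- d
  all_one$y <- 1
  m1mod <- fit_mediation_models(all_one, dag = "B")
  expect_equal(m1mod$pY(1, 0, 1), 1)
  expect_equal(po_mean_a(m1mod, 1, 0, 1), 1)
})

test_that("degenerate mediator laws reduce the g-formula sums", {
  d <- tidyr::expand_grid(x = 0:1, m1 = 1, m2 = 0:1, y = 0:1)
  d <- tidyr::uncount(d, weights = rep(c(3, 1), 4)) # pM1(x) = 1 for both arms
  models <- fit_mediation_models(d, dag = "B", model_form = "saturated")
  expect_equal(models$pM1(0), 1)
  expect_equal(po_mean_a(models, 1, 0, 0), models$pY(1, 1, 0))
  # pM2(x2 = 0, m1p) degenerate at 0 would collapse po_mean_b similarly
  d2 <- tidyr::expand_grid(x = 0:1, m1 = 0:1, m2 = 0, y = 0:1)
  models2 <- fit_mediation_models(tidyr::uncount(d2, weights = rep(1:2, 4)),
                                  dag = "B", model_form = "saturated")
  expect_equal(po_mean_b(models2, 1, 1, 0, 0), models2$pY(1, 1, 0))
  # degenerate inner mediator: pM1(x3) = 1 reduces (c) to (b) at m1' = 1
  expect_equal(po_mean_c(models, 1, 1, 1, 0),
               po_mean_b(models, 1, 1, 1, 1))
})

test_that("saturated estimation on a full enumeration recovers exact truth", {
  for (dag in c("B", "A")) {
    w <- random_product_weights(dag, seed = 101 + (dag == "A"))
    enum <- enumeration_data(w, dag)
    eff <- cross_effects(enum$data, dag = dag, model_form = "saturated")
    for (i in seq_len(nrow(eff))) {
      sp <- canonical_spec(eff$estimand[i], dag)
      expect_lt(abs(eff$estimate[i] - true_effects_from_q(enum$q, sp)), 1e-10)
    }
  }
})

test_that("null contrasts are exactly zero and outcomes ignore absent paths", {
  sim <- generate_npsem(500, dag = "B", seed = 41)
  models <- fit_mediation_models(sim$data, dag = "B")
  null_spec <- effect_spec("crossB_M2ctrl_inner",
                           levels = list(x = 1, xp = 1, m1 = 0, x2 = 0, m1p = 0),
                           dag = "B")
  expect_identical(as.numeric(estimate_effect(null_spec, models)), 0)

  # Y response functions that ignore the mediators: every cross effect
  # equals the total effect exactly
  space <- response_profiles("B")
  w <- random_product_weights("B", seed = 55)
  w$w_y <- integer(space$n_y)
  w$w_y[c(0, 15, 240, 255) + 1] <- c(2, 1, 3, 1) # truth tables constant in (m1, m2)
  enum <- enumeration_data(w, "B")
  eff <- cross_effects(enum$data, dag = "B", model_form = "saturated")
  te <- eff$estimate[eff$estimand == "total_effect"]
  for (v in eff$estimate) expect_lt(abs(v - te), 1e-12)
})

test_that("logistic models match a directly fitted glm", {
  withr::with_seed(61, {
    n <- 600
    c1 <- rbinom(n, 1, 0.5)
    x <- rbinom(n, 1, 0.5)
    m1 <- rbinom(n, 1, plogis(-0.3 + 0.8 * x + 0.4 * c1))
    m2 <- rbinom(n, 1, plogis(0.2 + 0.5 * x - 0.6 * m1 + 0.3 * c1))
    y <- rbinom(n, 1, plogis(-0.5 + 0.4 * x + 0.5 * m1 + 0.7 * m2 - 0.4 * c1))
    d <- data.frame(x = x, m1 = m1, m2 = m2, y = y, c1 = c1)
  })
  models <- fit_mediation_models(d, dag = "B", model_form = "main_effects")
  ref <- glm(y ~ c1 + x + m1 + m2, family = binomial(), data = d)
  nd <- data.frame(c1 = d$c1, x = 1, m1 = 0, m2 = 1)
  expect_equal(models$pY(1, 0, 1),
               unname(predict(ref, newdata = nd, type = "response")))
  refm2 <- glm(m2 ~ c1 + x + m1, family = binomial(), data = d)
  nd2 <- data.frame(c1 = d$c1, x = 0, m1 = 1)
  expect_equal(models$pM2(0, 1),
               unname(predict(refm2, newdata = nd2, type = "response")))

  # two-way form includes all pairwise interactions
  m2w <- fit_mediation_models(d, dag = "B", model_form = "two_way")
  ref2w <- glm(y ~ (c1 + x + m1 + m2)^2, family = binomial(), data = d)
  expect_equal(m2w$pY(1, 0, 1),
               unname(predict(ref2w, newdata = nd, type = "response")))

  # estimates stay inside the probability scale
  eff <- cross_effects(d, dag = "B", model_form = "two_way")
  expect_true(all(eff$treated >= 0 & eff$treated <= 1))
  expect_true(all(abs(eff$estimate) <= 1))
})

test_that("empty strata error only when they carry weight", {
  # no records with (x=1, m1=1): pY(1, 1, .) is undefined, but harmless
  # whenever the M1 law puts no mass there
  d <- data.frame(
    x = rep(0:1, each = 8),
    m1 = c(rep(0:1, 4), rep(0, 8)),
    m2 = rep(0:1, 8),
    y = rep(c(0, 1), 8)
  )
  models <- fit_mediation_models(d, dag = "B", model_form = "saturated")
  expect_equal(models$pM1(1), 0)
  expect_silent(po_mean_a(models, 1, 1, 0)) # weight on m1=1 stratum is zero
  expect_error(po_mean_a(models, 1, 0, 0),
               class = "crossmed_empty_stratum_error")
})

test_that("separation falls back to stratified frequencies with a warning", {
  withr::with_seed(71, {
    n <- 200
    d <- data.frame(
      x = rep(0:1, each = n / 2),
      m1 = rbinom(n, 1, 0.5), m2 = rbinom(n, 1, 0.5)
    )
    d$y <- d$m1 # perfect separation in the outcome model
  })
  expect_warning(
    models <- fit_mediation_models(d, dag = "B", model_form = "main_effects"),
    class = "crossmed_nonconvergence_warning"
  )
  expect_equal(models$pY(1, 1, 0), 1)
  expect_equal(models$pY(0, 0, 1), 0)
})

test_that("mediator symmetry holds when M2 ignores M1", {
  # dag A models: po_mean for a controlled-M1 / natural-M2 estimand equals
  # the relabeled natural-M1 / controlled-M2 estimand on swapped data
  sim <- generate_npsem(4000, dag = "A", seed = 81)
  spec <- effect_spec("crossA_M2nat", levels = list(m1 = 0, x2 = 0), dag = "A")
  models <- fit_mediation_models(sim$data, dag = "A", model_form = "saturated")
  est <- estimate_effect(spec, models)

  swapped <- sim$data
  names(swapped)[match(c("m1", "m2"), names(swapped))] <- c("m2", "m1")
  models_sw <- fit_mediation_models(swapped, dag = "A", model_form = "saturated")
  est_sw <- estimate_effect(relabel_mediators(spec), models_sw)
  expect_equal(as.numeric(est), as.numeric(est_sw))
})
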