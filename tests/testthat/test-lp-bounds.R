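test_that("profile spaces have the canonical sizes", {
  a <- response_profiles("A")
  b <- response_profiles("B")
  expect_equal(a$n_profiles, 4096L)
  expect_equal(b$n_profiles, 16384L)
  expect_equal(a$n_m2, 4L)
  expect_equal(b$n_m2, 16L)
  expect_equal(a$n_m1, 4L)
  expect_equal(a$n_y, 256L)
})

test_that("profiles generate observations by function composition", {
  b <- response_profiles("B")
  # profile 1: every function constant zero
  obs <- realized_observation(b, 1, profile = 1)
  expect_equal(unlist(obs[c("m1", "m2", "y")]), c(m1 = 0, m2 = 0, y = 0))

  # r_M1 = identity (index 1), r_M2 = constant one (index 15),
  # r_Y(x, m1, m2) = m1 (truth table 00110011 -> 51)
  r <- (1L * b$n_m2 + 15L) * 256L + 51L + 1L
  obs1 <- realized_observation(b, 1, profile = r)
  expect_equal(unlist(obs1[c("m1", "m2", "y")]), c(m1 = 1, m2 = 1, y = 1))
  obs0 <- realized_observation(b, 0, profile = r)
  expect_equal(unlist(obs0[c("m1", "m2", "y")]), c(m1 = 0, m2 = 1, y = 0))

  # counterfactual Y(1, M1(0), 0) on that profile: natural M1 at x = 0 is 0,
  # and y = m1 argument = 0
  sp <- canonical_spec("crossA_M1nat", "B")
  expect_equal(counterfactual_value(b, sp$treated, profile = r), 0L)

  # consistency: the TE component Y(x) equals the realized observation
  te <- canonical_spec("total_effect", "B")
  expect_equal(counterfactual_value(b, te$treated),
               realized_observation(b, 1)$y)
  # fully controlled Y(x, m1, m2) is the Y response function itself
  cde <- effect_spec("crossA_M1nat", levels = list(x1 = 0, m2 = 1), dag = "B")
  m1nat0 <- crossmed:::.rf_m1(b, 0)
  expect_equal(counterfactual_value(b, cde$treated),
               crossmed:::.rf_y(b, 1, m1nat0, rep(1L, b$n_profiles)))
})

test_that("the LP statement has the canonical structure", {
  dist <- uniform_dist()
  sp <- canonical_spec("crossB_M2ctrl_inner", "B")
  lp <- build_lp(dist, sp)
  expect_equal(dim(lp$constraints), c(16L, 16384L))
  expect_true(all(colSums(lp$constraints) == 2)) # one cell per arm
  # the 8 rows of one arm sum to the simplex constraint
  arm0 <- grepl("x0$", rownames(lp$constraints))
  expect_true(all(colSums(lp$constraints[arm0, ]) == 1))
  expect_equal(unname(lp$rhs), dist$p)

  null_sp <- effect_spec("crossB_M2ctrl_inner",
                         levels = list(x = 1, xp = 1, m1 = 0, x2 = 0, m1p = 0),
                         dag = "B")
  expect_true(all(build_lp(dist, null_sp)$objective == 0))

  lpA <- build_lp(dist, canonical_spec("crossA_M1nat", "A"))
  expect_equal(dim(lpA$constraints), c(16L, 4096L))
})

test_that("LP bounds reproduce the hand-derived intervals", {
  dist <- uniform_dist()
  for (nm in c("crossA_M1nat", "crossB_M2ctrl_inner",
               "crossB_bothnat_inner_ctrl", "crossB_M2nat_inner_nat")) {
    bi <- solve_bounds(dist, canonical_spec(nm, "B"))
    expect_equal(bi$lower, -0.75, tolerance = 1e-9)
    expect_equal(bi$upper, 0.75, tolerance = 1e-9)
  }
  pm <- pointmass_dist()
  for (nm in c("crossA_M1nat", "crossB_M2ctrl_inner",
               "crossB_bothnat_inner_ctrl", "crossB_M2nat_inner_nat")) {
    bi <- solve_bounds(pm, canonical_spec(nm, "B"))
    expect_equal(bi$lower, 0, tolerance = 1e-9)
    expect_equal(bi$upper, 0, tolerance = 1e-9)
  }
})

test_that("the reduced solve agrees with a direct full-size simplex solve", {
  # independent route: hand the full 16 x n_profiles LP to the solver with no
  # aggregation (one redundant row dropped for rank reasons)
  full_solve <- function(dist, spec) {
    lp <- build_lp(dist, spec)
    A <- lp$constraints[-16, ]
    vals <- vapply(c(FALSE, TRUE), function(maxi) {
      s <- boot::simplex(a = lp$objective, A3 = A, b3 = unname(lp$rhs[-16]),
                         maxi = maxi, n.iter = 2000, eps = 1e-10)
      expect_equal(s$solved, 1)
      s$value
    }, numeric(1))
    vals
  }
  for (k in 1:2) {
    s <- sample_compatible_distribution("A", concentration = 0.6,
                                        seed = 300 + k)
    sp <- canonical_spec("crossA_M1nat", "A")
    direct <- full_solve(s$dist, sp)
    red <- solve_bounds(s$dist, sp)
    expect_equal(red$lower, direct[1], tolerance = 1e-8)
    expect_equal(red$upper, direct[2], tolerance = 1e-8)
  }
  s <- sample_compatible_distribution("B", concentration = 0.6, seed = 310)
  sp <- canonical_spec("crossB_M2nat_inner_nat", "B")
  direct <- full_solve(s$dist, sp)
  red <- solve_bounds(s$dist, sp)
  expect_equal(red$lower, direct[1], tolerance = 1e-8)
  expect_equal(red$upper, direct[2], tolerance = 1e-8)
})

test_that("compatible draws marginalize consistently", {
  s <- sample_compatible_distribution("B", concentration = 0.5, seed = 17)
  expect_equal(sum(s$dist$p[s$dist$x == 0]), 1, tolerance = 1e-12)
  expect_equal(sum(s$dist$p[s$dist$x == 1]), 1, tolerance = 1e-12)
  expect_equal(sum(as.numeric(s$q)), 1, tolerance = 1e-12)
  # same seed reproduces the draw
  s2 <- sample_compatible_distribution("B", concentration = 0.5, seed = 17)
  expect_identical(s$dist$p, s2$dist$p)

  # a degenerate q gives a deterministic 0/1 table
  space <- response_profiles("A")
  q <- rep(0, space$n_profiles)
  q[123] <- 1
  dq <- marginal_distribution(profile_distribution(q, "A"))
  expect_setequal(unique(dq$p), c(0, 1))

  # large concentration approaches the uniform-profile marginal
  big <- sample_compatible_distribution("A", concentration = 5e4, seed = 23)
  unif_marg <- marginal_distribution(
    profile_distribution(rep(1 / space$n_profiles, space$n_profiles), "A"))
  expect_lt(max(abs(big$dist$p - unif_marg$p)), 0.01)
})

test_that("ground truth lies inside the LP interval on random draws", {
  for (dag in c("A", "B")) {
    nms <- setdiff(estimand_names(dag), "total_effect")
    for (k in 1:10) {
      s <- sample_compatible_distribution(dag, concentration = 0.8,
                                          seed = 500 + k)
      for (nm in nms) {
        sp <- canonical_spec(nm, dag)
        bi <- solve_bounds(s$dist, sp)
        tr <- true_effects_from_q(s$q, sp)
        expect_gte(tr, bi$lower - 1e-8)
        expect_lte(tr, bi$upper + 1e-8)
        expect_gte(bi$lower, -1 - 1e-9)
        expect_lte(bi$upper, 1 + 1e-9)
      }
    }
  }
})

test_that("the total effect is identified: its LP interval is a point", {
  s <- sample_compatible_distribution("B", concentration = 1, seed = 29)
  te <- canonical_spec("total_effect", "B")
  bi <- solve_bounds(s$dist, te)
  d <- s$dist
  emp <- sum(d$p[d$x == 1 & d$y == 1]) - sum(d$p[d$x == 0 & d$y == 1])
  expect_equal(bi$lower, emp, tolerance = 1e-9)
  expect_equal(bi$upper, emp, tolerance = 1e-9)
})

test_that("null contrasts and point-mass profile laws behave exactly", {
  s <- sample_compatible_distribution("B", concentration = 1, seed = 37)
  null_sp <- effect_spec("crossB_M2ctrl_inner",
                         levels = list(x = 1, xp = 1, m1 = 0, x2 = 0, m1p = 0),
                         dag = "B")
  expect_identical(true_effects_from_q(s$q, null_sp), 0)
  bi <- solve_bounds(s$dist, null_sp)
  expect_equal(bi$lower, 0, tolerance = 1e-9)
  expect_equal(bi$upper, 0, tolerance = 1e-9)

  space <- response_profiles("B")
  q <- rep(0, space$n_profiles)
  q[4242] <- 1
  tr <- true_effects_from_q(profile_distribution(q, "B"),
                            canonical_spec("crossA_M1nat", "B"))
  expect_true(tr %in% c(-1, 0, 1))
})

test_that("LP problems serialize to sparse JSON", {
  dist <- uniform_dist()
  lp <- build_lp(dist, canonical_spec("crossA_M1nat", "A"))
  path <- withr::local_tempfile(fileext = ".json")
  write_lp_json(lp, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(length(back$c), 4096)
  expect_equal(length(back$A$row), sum(lp$constraints != 0))
  expect_equal(unname(unlist(back$rhs)), unname(lp$rhs))
})
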