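# fixtures are built in code: probability tables with known bound intervals
# and exact-enumeration datasets whose empirical frequencies are rational

uniform_data <- function() {
  tidyr::expand_grid(x = 0:1, y = 0:1, m1 = 0:1, m2 = 0:1)
}

uniform_dist <- function() observed_distribution(uniform_data())

# point mass on (y, m1, m2) = (1, 0, 0) in both arms
pointmass_dist <- function() {
  p <- rep(0, 16)
  p[crossmed:::.cell_index(1, 0, 0, 0)] <- 1
  p[crossmed:::.cell_index(1, 0, 0, 1)] <- 1
  as_observed_distribution(p)
}

canonical_spec <- function(name, dag = "B") {
  effect_spec(name, levels = crossmed:::.canonical_levels(name), dag = dag)
}

# integer-weight product profile distribution: unconfounded by construction,
# and every implied cell probability is rational with denominator
# sum(w_m1) * sum(w_m2) * sum(w_y)
random_product_weights <- function(dag, seed) {
  space <- response_profiles(dag)
  withr::with_seed(seed, {
    w_m1 <- sample(1:3, space$n_m1, replace = TRUE)
    w_m2 <- sample(1:3, space$n_m2, replace = TRUE)
    w_y <- integer(space$n_y)
    w_y[sample.int(space$n_y, 12)] <- sample(1:4, 12, replace = TRUE)
    list(w_m1 = w_m1, w_m2 = w_m2, w_y = w_y)
  })
}

# dataset that is the full enumeration of the implied distribution: each of
# the 16 cells appears exactly (denominator * probability) times per arm
enumeration_data <- function(w, dag) {
  space <- response_profiles(dag)
  wq <- w$w_m1[space$i_m1 + 1] * w$w_m2[space$i_m2 + 1] * w$w_y[space$i_y + 1]
  W <- sum(wq)
  q <- profile_distribution(wq / W, dag)
  counts0 <- integer(8); counts1 <- integer(8)
  s0 <- rowsum(wq, space$cell0); s1 <- rowsum(wq, space$cell1)
  counts0[as.integer(rownames(s0))] <- s0
  counts1[as.integer(rownames(s1))] <- s1
  grid <- crossmed:::.cell_grid()
  grid$count <- c(counts0, counts1)
  data <- tidyr::uncount(grid, weights = count)
  list(data = data, q = q, denominator = W)
}

# strongly confounded profile distribution used for the bias demonstration:
# a mixture of two deterministic worlds plus a uniform smoothing component
# that keeps every observable cell populated. In world A the first mediator
# tracks the exposure (r_M1 = x) and the outcome tracks the first mediator
# (r_Y = m1); in world B the first mediator opposes the exposure (r_M1 =
# 1 - x) and the outcome is never 1. Membership is unmeasured, so the
# observed stratum (x, m1, m2) selects worlds and the g-formula conditionals
# no longer identify the counterfactual outcome responses.
confounded_mixture_q <- function(dag = "B", w_det = 0.45, w_unif = 0.10) {
  space <- response_profiles(dag)
  n <- space$n_profiles
  q <- rep(w_unif / n, n)
  # truth tables read MSB-first: i1 = 1 is r_M1(x) = x, i1 = 2 is 1 - x;
  # iy = 51 is r_Y(x, m1, m2) = m1 (bits 00110011)
  world_a <- which(space$i_m1 == 1L & space$i_m2 == 0L & space$i_y == 51L)
  world_b <- which(space$i_m1 == 2L & space$i_m2 == 0L & space$i_y == 0L)
  q[world_a] <- q[world_a] + w_det
  q[world_b] <- q[world_b] + w_det
  profile_distribution(q / sum(q), dag)
}

expect_interval_equal <- function(a, b, tol = 1e-6) {
  expect_lt(abs(a$lower - b$lower), tol)
  expect_lt(abs(a$upper - b$upper), tol)
}
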