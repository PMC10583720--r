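# Numeric tight bounds for any estimand at any level setting via the
# canonical response-function partition of the unmeasured confounder and
# linear programming.
#
# Enumeration order (frozen): a profile combines one response function per
# variable; the M1-function index varies slowest, then the M2-function index,
# then the Y-function index. Within each variable, functions are ordered by
# their truth table read as a binary integer with the first (lexicographically
# smallest, x slowest) input as the most significant bit. Profile indices are
# 1-based in R; the underlying function indices are 0-based.

.profile_cache <- new.env(parent = emptyenv())

#' Enumerate the canonical response-function profiles
#'
#' Each binary variable's structural equation is one of the \eqn{2^{2^k}}
#' maps from its \eqn{k} graph parents to \{0, 1\}: 4 for M1 (parent X), 4 or
#' 16 for M2 (parents X, or X and M1), and 256 for Y (parents X, M1, M2).
#' The joint distribution of the three response functions is the canonical
#' finite reduction of the unmeasured confounder; a profile is one joint
#' assignment.
#'
#' @param dag `"A"` (4 x 4 x 256 = 4096 profiles) or `"B"`
#'   (4 x 16 x 256 = 16384 profiles).
#' @returns A `response_profile_space`: list with `dag`, the per-variable
#'   function counts, `n_profiles`, and the 0-based function indices `i_m1`,
#'   `i_m2`, `i_y` of every profile in enumeration order.
#' @export
response_profiles <- function(dag) {
  dag <- .check_dag(dag)
  if (!is.null(.profile_cache[[dag]])) return(.profile_cache[[dag]])
  n_m2 <- if (dag == "A") 4L else 16L
  n <- 4L * n_m2 * 256L
  r <- 0:(n - 1L)
  space <- structure(
    list(
      dag = dag, n_m1 = 4L, n_m2 = n_m2, n_y = 256L, n_profiles = n,
      i_m1 = r %/% (256L * n_m2),
      i_m2 = (r %/% 256L) %% n_m2,
      i_y = r %% 256L
    ),
    class = "response_profile_space"
  )
  # realized cell of every profile under each arm, cached for the LP
  space$cell0 <- .realized_cell(space, 0L)
  space$cell1 <- .realized_cell(space, 1L)
  .profile_cache[[dag]] <- space
  space
}

#' @export
print.response_profile_space <- function(x, ...) {
  cat("<response_profile_space> dag", x$dag, "|", x$n_profiles,
      "profiles (", x$n_m1, "x", x$n_m2, "x", x$n_y, ")\n")
  invisible(x)
}

# response-function evaluation, vectorized over profiles
.rf_m1 <- function(space, x) (space$i_m1 %/% 2L^(1L - x)) %% 2L

.rf_m2 <- function(space, x, m1 = NULL) {
  if (space$dag == "A") {
    (space$i_m2 %/% 2L^(1L - x)) %% 2L
  } else {
    (space$i_m2 %/% 2L^(3L - (2L * x + m1))) %% 2L
  }
}

.rf_y <- function(space, x, m1, m2) {
  (space$i_y %/% 2L^(7L - (4L * x + 2L * m1 + m2))) %% 2L
}

# per-arm cell index (1..8, canonical y/m1/m2 order) of every profile
.realized_cell <- function(space, x) {
  m1 <- .rf_m1(space, x)
  m2 <- .rf_m2(space, x, m1)
  y <- .rf_y(space, x, m1, m2)
  as.integer(4L * y + 2L * m1 + m2 + 1L)
}

#' Observation a response profile generates under each exposure
#'
#' Given a profile, the observed data are a deterministic function of the
#' exposure: \eqn{M_1 = r_{M_1}(x)}, \eqn{M_2 = r_{M_2}(x)} or
#' \eqn{r_{M_2}(x, M_1)}, \eqn{Y = r_Y(x, M_1, M_2)}.
#'
#' @param space A `response_profile_space` (or a dag tag).
#' @param x Exposure level, 0 or 1.
#' @param profile Integer vector of 1-based profile indices; default all.
#' @returns A tibble with columns `profile`, `x`, `m1`, `m2`, `y`.
#' @export
realized_observation <- function(space, x, profile = NULL) {
  if (is.character(space)) space <- response_profiles(space)
  stopifnot(x %in% c(0, 1))
  m1 <- .rf_m1(space, x)
  m2 <- .rf_m2(space, x, m1)
  y <- .rf_y(space, x, m1, m2)
  out <- tibble::tibble(
    profile = seq_len(space$n_profiles), x = as.integer(x),
    m1 = m1, m2 = m2, y = y
  )
  if (!is.null(profile)) out <- out[profile, ]
  out
}

#' Counterfactual outcome of a response profile
#'
#' Evaluates the nested potential outcome defined by a `po_spec` for every
#' profile: inner natural mediator values are resolved through the mediator
#' response functions, the outer outcome through the Y response function.
#'
#' @param space A `response_profile_space` (or a dag tag).
#' @param po A `po_spec` (one arm of an [effect_spec()]) with the same dag.
#' @param profile Optional 1-based profile indices; default all.
#' @returns An integer 0/1 vector.
#' @export
counterfactual_value <- function(space, po, profile = NULL) {
  if (is.character(space)) space <- response_profiles(space)
  stopifnot(inherits(po, "po_spec"))
  if (po$dag != space$dag) {
    rlang::abort("potential outcome and profile space assume different DAGs",
                 class = "crossmed_dag_incompatible_error")
  }
  x <- po$x
  m1v <- switch(po$m1$kind,
    ctrl = rep(po$m1$level, space$n_profiles),
    nat = .rf_m1(space, po$m1$x1),
    self = .rf_m1(space, x)
  )
  m2v <- switch(po$m2$kind,
    ctrl = rep(po$m2$level, space$n_profiles),
    nat = if (space$dag == "A") .rf_m2(space, po$m2$x2) else
      .rf_m2(space, po$m2$x2, .rf_m1(space, po$m2$x2)),
    nat_ctrl = .rf_m2(space, po$m2$x2, rep(po$m2$m1p, space$n_profiles)),
    nat_nat = .rf_m2(space, po$m2$x2, .rf_m1(space, po$m2$x3)),
    self = if (space$dag == "A") .rf_m2(space, x) else
      .rf_m2(space, x, .rf_m1(space, x))
  )
  out <- .rf_y(space, x, m1v, m2v)
  if (!is.null(profile)) out <- out[profile]
  out
}

# effect objective over profiles: treated minus control counterfactual
.objective_vector <- function(space, spec) {
  counterfactual_value(space, spec$treated) -
    counterfactual_value(space, spec$control)
}

#' Assemble the linear program for a bound
#'
#' The decision variable is the probability vector q over response profiles.
#' The 16 observable probabilities constrain q linearly: each row of the 0/1
#' incidence matrix A sums the profiles whose realized observation under arm
#' x equals the row's (y, m1, m2) cell, so A q = p (these 16 equalities imply
#' that q sums to one). The objective is the difference of the two
#' counterfactual indicator vectors.
#'
#' @param dist An `observed_distribution`.
#' @param spec An [effect_spec()].
#' @returns An `lp_problem`: list with `objective` (length `n_profiles`),
#'   `constraints` (16 x n 0/1 matrix, rows named by canonical probability
#'   keys), `rhs` (the 16 probabilities), `dag`.
#' @export
build_lp <- function(dist, spec) {
  stopifnot(inherits(dist, "observed_distribution"),
            inherits(spec, "effect_spec"))
  space <- response_profiles(spec$dag)
  n <- space$n_profiles
  A <- matrix(0, 16L, n)
  A[cbind(space$cell0, seq_len(n))] <- 1
  A[cbind(8L + space$cell1, seq_len(n))] <- 1
  grid <- .cell_grid() # canonical order: arm-0 cells 1..8, then arm-1
  rownames(A) <- .cell_key(grid$y, grid$m1, grid$m2, grid$x)
  rhs <- dist$p
  names(rhs) <- rownames(A)
  structure(
    list(objective = .objective_vector(space, spec), constraints = A,
         rhs = rhs, dag = spec$dag, estimand = spec$label),
    class = "lp_problem"
  )
}

#' @export
print.lp_problem <- function(x, ...) {
  cat("<lp_problem>", x$estimand, "\n  ", nrow(x$constraints), "equality rows x",
      length(x$objective), "profile variables\n")
  invisible(x)
}

#' Write a linear program to JSON for external verification
#'
#' The constraint matrix is serialized as sparse triplets (1-based `row`,
#' `col`, `value`).
#'
#' @param lp An `lp_problem` from [build_lp()].
#' @param path File path.
#' @returns `path`, invisibly.
#' @export
write_lp_json <- function(lp, path) {
  nz <- which(lp$constraints != 0, arr.ind = TRUE)
  obj <- list(
    estimand = lp$estimand, dag = lp$dag,
    c = lp$objective,
    A = list(row = unname(nz[, 1]), col = unname(nz[, 2]),
             value = lp$constraints[nz]),
    rhs = as.list(lp$rhs)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

# Exact reduction of the profile LP to an 8x8 transportation problem.
# Every profile maps to one observable cell per arm; aggregating q over the
# (arm-0 cell, arm-1 cell) pair leaves a transportation polytope (row sums =
# arm-0 probabilities, column sums = arm-1 probabilities). Within a pair
# group the constraints cannot distinguish profiles, so for maximization all
# group mass may sit on a profile attaining the group's maximal objective
# value (minimization: minimal). The reduced LP has the same optimum as the
# full one and 64 instead of up to 16384 variables.
.go_cache <- new.env(parent = emptyenv())

.group_objective <- function(space, spec) {
  key <- paste(space$dag, spec$name,
               paste(names(spec$levels), unlist(spec$levels),
                     sep = "=", collapse = ","))
  hit <- .go_cache[[key]]
  if (!is.null(hit)) return(hit)
  out <- .group_objective_impl(space, spec)
  .go_cache[[key]] <- out
  out
}

# group objective depends on the estimand and profile space only, never on
# the observed table, so it is computed once per estimand
.group_objective_impl <- function(space, spec) {
  cvec <- .objective_vector(space, spec)
  key <- (space$cell1 - 1L) * 8L + space$cell0 # 1..64, column-major 8x8
  gmax <- matrix(-Inf, 8, 8)
  gmin <- matrix(Inf, 8, 8)
  mx <- tapply(cvec, key, max)
  mn <- tapply(cvec, key, min)
  gmax[as.integer(names(mx))] <- mx
  gmin[as.integer(names(mn))] <- mn
  list(gmax = gmax, gmin = gmin)
}

# transportation LP solve via boot::simplex; zero-mass rows/columns are
# eliminated first (degenerate zero right-hand sides break the solver) and
# one redundant constraint is dropped
.solve_tp <- function(g, a, b, maxi, eps = 1e-10) {
  ri <- which(a > 0)
  cj <- which(b > 0)
  g <- g[ri, cj, drop = FALSE]
  a <- a[ri]
  b <- b[cj]
  nr <- length(a)
  nc <- length(b)
  if (nr == 1L) return(unname(sum(b * g[1, ])))
  if (nc == 1L) return(unname(sum(a * g[, 1])))
  A <- matrix(0, nr + nc - 1L, nr * nc)
  for (i in seq_len(nr)) A[i, (seq_len(nc) - 1L) * nr + i] <- 1
  for (j in seq_len(nc - 1L)) A[nr + j, (j - 1L) * nr + seq_len(nr)] <- 1
  s <- boot::simplex(a = as.vector(g), A3 = A,
                     b3 = c(a, b[seq_len(nc - 1L)]),
                     maxi = maxi, n.iter = 1000, eps = eps)
  if (s$solved != 1) {
    rlang::abort(
      sprintf("LP solve failed (solver status %d)", s$solved),
      class = "crossmed_lp_failure_error"
    )
  }
  unname(s$value)
}

#' Tight bounds by linear programming
#'
#' Minimizes and maximizes the effect objective over all response-profile
#' distributions consistent with the observed probability table. Works for
#' any estimand at any level setting, under either DAG variant. The
#' response-function model is saturated, so every valid per-arm table is
#' feasible; an infeasible solve signals numerical trouble and raises an
#' error.
#'
#' @param dist An `observed_distribution`.
#' @param spec An [effect_spec()].
#' @param tol Feasibility tolerance passed to the simplex solver.
#' @returns A `bounds_interval` with `method = "lp"`.
#' @examples
#' d <- observed_distribution(tidyr::expand_grid(x = 0:1, y = 0:1, m1 = 0:1, m2 = 0:1))
#' sp <- effect_spec("crossA_M1nat", levels = list(x1 = 0, m2 = 0), dag = "B")
#' solve_bounds(d, sp) # [-0.75, 0.75], matches the symbolic bound
#' @export
solve_bounds <- function(dist, spec, tol = 1e-10) {
  stopifnot(inherits(dist, "observed_distribution"),
            inherits(spec, "effect_spec"))
  space <- response_profiles(spec$dag)
  go <- .group_objective(space, spec)
  p0 <- dist$p[dist$x == 0]
  p1 <- dist$p[dist$x == 1]
  up <- .solve_tp(go$gmax, p0, p1, maxi = TRUE, eps = tol)
  lo <- .solve_tp(go$gmin, p0, p1, maxi = FALSE, eps = tol)
  new_bounds_interval(lower = lo, upper = up, method = "lp",
                      estimand = spec$label)
}

#' Validate or construct a response-profile distribution
#'
#' @param q Nonnegative numeric vector over profiles (length 4096 for dag
#'   `"A"`, 16384 for `"B"`) summing to one.
#' @param dag `"A"` or `"B"`; inferred from `length(q)` if omitted.
#' @returns A `profile_distribution` (numeric vector with attribute `dag`).
#' @export
profile_distribution <- function(q, dag = NULL) {
  if (is.null(dag)) {
    dag <- switch(as.character(length(q)), "4096" = "A", "16384" = "B",
                  rlang::abort("q must have length 4096 (dag A) or 16384 (dag B)",
                               class = "crossmed_coding_error"))
  }
  dag <- .check_dag(dag)
  space <- response_profiles(dag)
  stopifnot(length(q) == space$n_profiles)
  if (any(q < 0) || abs(sum(q) - 1) > 1e-12) {
    rlang::abort("q must be nonnegative and sum to 1 (tolerance 1e-12)",
                 class = "crossmed_coding_error")
  }
  structure(as.numeric(q), dag = dag, class = "profile_distribution")
}

#' Product (unconfounded) response-profile distribution
#'
#' Builds the joint profile distribution as the outer product of independent
#' per-variable response-function distributions. Independence of the three
#' response functions is exactly the absence of residual confounding among
#' M1, M2 and Y.
#'
#' @param q_m1,q_m2,q_y Probability vectors over the per-variable response
#'   functions (lengths 4, 4 or 16, and 256).
#' @param dag `"A"` or `"B"`.
#' @returns A `profile_distribution` that factors exactly.
#' @export
product_profile_distribution <- function(q_m1, q_m2, q_y, dag) {
  dag <- .check_dag(dag)
  space <- response_profiles(dag)
  stopifnot(length(q_m1) == space$n_m1, length(q_m2) == space$n_m2,
            length(q_y) == space$n_y)
  for (qq in list(q_m1, q_m2, q_y)) {
    if (any(qq < 0) || abs(sum(qq) - 1) > 1e-12) {
      rlang::abort("each marginal must be a probability vector",
                   class = "crossmed_coding_error")
    }
  }
  q <- q_m1[space$i_m1 + 1L] * q_m2[space$i_m2 + 1L] * q_y[space$i_y + 1L]
  profile_distribution(q / sum(q), dag)
}

#' Marginalize a profile distribution to its observable probability table
#'
#' @param q A `profile_distribution`.
#' @returns An `observed_distribution` with the 16 implied probabilities.
#' @export
marginal_distribution <- function(q) {
  stopifnot(inherits(q, "profile_distribution"))
  space <- response_profiles(attr(q, "dag"))
  p0 <- numeric(8)
  p1 <- numeric(8)
  s0 <- rowsum(as.numeric(q), space$cell0)
  s1 <- rowsum(as.numeric(q), space$cell1)
  p0[as.integer(rownames(s0))] <- s0
  p1[as.integer(rownames(s1))] <- s1
  new_observed_distribution(c(p0, p1))
}

#' Draw a model-compatible observed distribution
#'
#' Samples a response-profile distribution q from a symmetric Dirichlet and
#' marginalizes it to the 16 observable probabilities. Every table produced
#' this way is compatible with the causal model, so tight bounds computed
#' from it must contain the true effect implied by q.
#'
#' @param dag `"A"` or `"B"`.
#' @param concentration Positive Dirichlet concentration; small values give
#'   near-degenerate q, large values approach the uniform profile law.
#' @param seed Optional integer seed.
#' @returns A list with elements `dist` (an `observed_distribution`) and `q`
#'   (the `profile_distribution` that generated it).
#' @export
sample_compatible_distribution <- function(dag, concentration = 1, seed = NULL) {
  stopifnot(concentration > 0)
  space <- response_profiles(dag)
  draw <- function() {
    g <- stats::rgamma(space$n_profiles, shape = concentration)
    if (sum(g) == 0) g[sample.int(space$n_profiles, 1L)] <- 1
    profile_distribution(g / sum(g), dag)
  }
  q <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  list(dist = marginal_distribution(q), q = q)
}

#' Exact effect implied by a known profile distribution
#'
#' The ground truth for validity checks:
#' \eqn{\sum_r q_r \{Y_r(\text{treated}) - Y_r(\text{control})\}}.
#'
#' @param q A `profile_distribution`.
#' @param spec An [effect_spec()] with the same dag.
#' @returns The true effect (numeric scalar).
#' @export
true_effects_from_q <- function(q, spec) {
  stopifnot(inherits(q, "profile_distribution"), inherits(spec, "effect_spec"))
  if (attr(q, "dag") != spec$dag) {
    rlang::abort("profile distribution and estimand assume different DAGs",
                 class = "crossmed_dag_incompatible_error")
  }
  space <- response_profiles(spec$dag)
  sum(as.numeric(q) * .objective_vector(space, spec))
}
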