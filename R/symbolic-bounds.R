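# Closed-form tight bounds on the canonical cross-effect contrasts under
# residual mediator-outcome confounding with randomized binary exposure.
# Each bound is the max (lower) or min (upper) of a small set of linear
# expressions in the 16 observed probabilities p_{y m1 m2 . x}. The
# expressions are stored as data (coefficient tables), not code, so the
# transcription can be unit-tested term by term and reused by reporting code.

# one expression: intercept + named coefficients; short keys "p{y}{m1}{m2}.{x}"
.ex <- function(intercept, ...) {
  co <- c(...)
  list(intercept = intercept, coef = co)
}

# the four canonical bound sets. Estimands (dag B unless noted):
#   result1: dE{Y(1->0, M1(0), 0)}        (valid under dag A or B)
#   result2: dE{Y(1->0, 0, M2(0, 0))}
#   result3: dE{Y(1->0, M1(0), M2(0, 0))}
#   result4: dE{Y(1->0, 0, M2(0, M1(0)))}
.bound_expressions <- local({
  tabs <- list(
    result1 = list(
      lower = list(
        .ex(-1, "p100.0" = -1, "p010.0" = 1, "p110.1" = 1, "p001.0" = -1,
            "p101.0" = -1),
        .ex(-2, "p000.0" = 2, "p100.0" = 1, "p100.1" = 1, "p010.0" = 1,
            "p001.0" = 1, "p101.0" = 1),
        .ex(-1, "p000.0" = 1, "p010.0" = 1)
      ),
      upper = list(
        .ex(1, "p000.0" = 1, "p010.1" = -1, "p110.0" = -1, "p001.0" = 1,
            "p101.0" = 1),
        .ex(1, "p100.0" = -1, "p110.0" = -1),
        .ex(2, "p000.0" = -1, "p000.1" = -1, "p100.0" = -2, "p110.0" = -1,
            "p001.0" = -1, "p101.0" = -1)
      )
    ),
    result2 = list(
      lower = list(
        .ex(-2, "p000.0" = 1, "p001.0" = 2, "p101.0" = 1, "p101.1" = 1),
        .ex(-2, "p000.0" = 2, "p100.0" = 1, "p100.1" = 1, "p001.0" = 1),
        .ex(-1, "p000.0" = 1, "p001.0" = 1)
      ),
      upper = list(
        .ex(2, "p100.0" = -1, "p001.0" = -1, "p001.1" = -1, "p101.0" = -2),
        .ex(1, "p100.0" = -1, "p101.0" = -1),
        .ex(2, "p000.0" = -1, "p000.1" = -1, "p100.0" = -2, "p101.0" = -1)
      )
    ),
    result3 = list(
      lower = list(
        .ex(-2, "p000.0" = 1, "p001.0" = 2, "p101.0" = 1, "p101.1" = 1),
        .ex(-2, "p000.0" = 2, "p100.0" = 1, "p100.1" = 1, "p001.0" = 1),
        .ex(-1, "p000.0" = 1, "p001.0" = 1),
        .ex(-1, "p000.0" = 1, "p000.1" = -1, "p100.1" = -1, "p010.0" = 1,
            "p010.1" = -1, "p110.1" = -1, "p001.0" = 1, "p001.1" = -1,
            "p101.1" = -1, "p011.1" = -1),
        .ex(-2, "p000.0" = 1, "p110.1" = 1, "p001.0" = 1, "p011.0" = 1)
      ),
      upper = list(
        .ex(2, "p100.0" = -1, "p001.0" = -1, "p001.1" = -1, "p101.0" = -2),
        .ex(2, "p100.0" = -1, "p110.0" = -1, "p101.0" = -1, "p011.1" = -1),
        .ex(1, "p000.0" = 1, "p010.0" = 1, "p010.1" = -1, "p110.0" = 1,
            "p001.0" = 1, "p011.0" = 1),
        .ex(1, "p100.0" = -1, "p101.0" = -1),
        .ex(2, "p000.0" = -1, "p000.1" = -1, "p100.0" = -2, "p101.0" = -1)
      )
    ),
    result4 = list(
      lower = list(
        .ex(-1, "p100.0" = -1, "p010.0" = -1, "p110.0" = -1, "p001.0" = 1,
            "p101.1" = 1),
        .ex(-2, "p000.0" = 2, "p100.0" = 1, "p100.1" = 1, "p010.0" = 1,
            "p110.0" = 1, "p001.0" = 1),
        .ex(-1, "p000.0" = 1, "p001.0" = 1)
      ),
      upper = list(
        .ex(1, "p000.0" = 1, "p010.0" = 1, "p110.0" = 1, "p001.1" = -1,
            "p101.0" = -1),
        .ex(1, "p100.0" = -1, "p101.0" = -1),
        .ex(2, "p000.0" = -1, "p000.1" = -1, "p100.0" = -2, "p010.0" = -1,
            "p110.0" = -1, "p101.0" = -1)
      )
    )
  )
  tabs
})

# expand short key "p{y}{m1}{m2}.{x}" to canonical index
.short_key_index <- function(keys) {
  y <- as.integer(substr(keys, 2, 2))
  m1 <- as.integer(substr(keys, 3, 3))
  m2 <- as.integer(substr(keys, 4, 4))
  x <- as.integer(substr(keys, 6, 6))
  .cell_index(y, m1, m2, x)
}

.eval_expressions <- function(exprs, pvec) {
  vapply(exprs, function(e) {
    e$intercept + sum(e$coef * pvec[.short_key_index(names(e$coef))])
  }, numeric(1))
}

#' The symbolic bound expressions as a tidy coefficient table
#'
#' One row per (result, side, expression, term); `term` is either
#' `"(intercept)"` or a canonical probability key.
#'
#' @returns A tibble with columns `result`, `side`, `expression`, `term`,
#'   `coefficient`.
#' @export
bound_expression_table <- function() {
  rows <- list()
  for (res in names(.bound_expressions)) {
    for (side in c("lower", "upper")) {
      exprs <- .bound_expressions[[res]][[side]]
      for (i in seq_along(exprs)) {
        e <- exprs[[i]]
        idx <- .short_key_index(names(e$coef))
        g <- .cell_grid()[idx, ]
        rows[[length(rows) + 1]] <- tibble::tibble(
          result = res, side = side, expression = i,
          term = c("(intercept)", .cell_key(g$y, g$m1, g$m2, g$x)),
          coefficient = c(e$intercept, unname(e$coef))
        )
      }
    }
  }
  dplyr::bind_rows(rows)
}

new_bounds_interval <- function(lower, upper, method, estimand,
                                active_lower = NA_integer_,
                                active_upper = NA_integer_) {
  if (lower < -1 - 1e-9 || upper > 1 + 1e-9) {
    rlang::warn(
      "bound interval escapes [-1, 1]: the input table is unlikely to be a valid per-arm distribution",
      class = "crossmed_incompatible_input_warning"
    )
  }
  structure(
    list(lower = lower, upper = upper, active_lower = active_lower,
         active_upper = active_upper, method = method, estimand = estimand),
    class = "bounds_interval"
  )
}

#' @export
print.bounds_interval <- function(x, ...) {
  cat(sprintf("<bounds_interval> %s\n  [%0.6f, %0.6f]  (method: %s)\n",
              x$estimand, x$lower, x$upper, x$method))
  invisible(x)
}

.symbolic_interval <- function(dist, result, estimand_label) {
  pvec <- dist$p
  lo <- .eval_expressions(.bound_expressions[[result]]$lower, pvec)
  up <- .eval_expressions(.bound_expressions[[result]]$upper, pvec)
  new_bounds_interval(
    lower = max(lo), upper = min(up),
    active_lower = which.max(lo), active_upper = which.min(up),
    method = "symbolic", estimand = estimand_label
  )
}

#' Tight symbolic bounds for the canonical cross-effect contrasts
#'
#' Evaluates the closed-form tight bounds on the cross-direct effects at the
#' canonical levels (treated exposure 1 vs 0, all reference levels 0) under
#' residual mediator-outcome confounding:
#'
#' * `bounds_result1()`: \eqn{\Delta E\{Y(1 \to 0, M_1(0), 0)\}} — valid
#'   under either DAG variant.
#' * `bounds_result2()`: \eqn{\Delta E\{Y(1 \to 0, 0, M_2(0, 0))\}} (dag `"B"`).
#' * `bounds_result3()`: \eqn{\Delta E\{Y(1 \to 0, M_1(0), M_2(0, 0))\}}
#'   (dag `"B"`).
#' * `bounds_result4()`: \eqn{\Delta E\{Y(1 \to 0, 0, M_2(0, M_1(0)))\}}
#'   (dag `"B"`).
#' * `bounds_result1_swapped()`: \eqn{\Delta E\{Y(1 \to 0, 0, M_2(0))\}} under
#'   dag `"A"`, obtained by evaluating the first bound set on the table with
#'   the mediator indices exchanged (mediator symmetry of dag `"A"`).
#'
#' The lower bound is the maximum of the lower expressions and the upper bound
#' the minimum of the upper expressions; the indices of the active expressions
#' are returned.
#'
#' @param dist An `observed_distribution`.
#' @returns A `bounds_interval`: list with `lower`, `upper`, `active_lower`,
#'   `active_upper`, `method`, `estimand`.
#' @examples
#' d <- observed_distribution(tidyr::expand_grid(x = 0:1, y = 0:1, m1 = 0:1, m2 = 0:1))
#' bounds_result1(d) # uniform table: [-0.75, 0.75]
#' @export
bounds_result1 <- function(dist) {
  .symbolic_interval(dist, "result1", "dE{Y(1->0, M1(0), 0)}")
}

#' @rdname bounds_result1
#' @export
bounds_result2 <- function(dist) {
  .symbolic_interval(dist, "result2", "dE{Y(1->0, 0, M2(0, 0))}")
}

#' @rdname bounds_result1
#' @export
bounds_result3 <- function(dist) {
  .symbolic_interval(dist, "result3", "dE{Y(1->0, M1(0), M2(0, 0))}")
}

#' @rdname bounds_result1
#' @export
bounds_result4 <- function(dist) {
  .symbolic_interval(dist, "result4", "dE{Y(1->0, 0, M2(0, M1(0)))}")
}

#' @rdname bounds_result1
#' @export
bounds_result1_swapped <- function(dist) {
  out <- .symbolic_interval(swap_mediators(dist), "result1",
                            "dE{Y(1->0, 0, M2(0))} [dag A]")
  out
}

# map a canonical-levels effect_spec to its symbolic bound set, or NULL
.symbolic_route <- function(spec) {
  lv <- spec$levels
  if (!(identical(lv$x, 1L) && identical(lv$xp, 0L))) return(NULL)
  others <- lv[setdiff(names(lv), c("x", "xp"))]
  if (length(others) && !all(unlist(others) == 0L)) return(NULL)
  switch(spec$name,
    crossA_M1nat = "result1",
    crossA_M2nat = if (spec$dag == "A") "result1_swapped" else NULL,
    crossB_M2ctrl_inner = "result2",
    crossB_bothnat_inner_ctrl = "result3",
    crossB_M2nat_inner_nat = "result4",
    NULL
  )
}

#' Bounds on a cross-direct effect under residual confounding
#'
#' Tidy front end: computes bound intervals for one or more estimands from
#' subject-level data or an observed probability table. Symbolic bounds are
#' available for the canonical contrasts (treated exposure 1 vs 0, all other
#' levels 0); any other level setting is handled by the linear-programming
#' engine (with a message when a symbolic bound was requested).
#'
#' @param data A data frame of binary records (columns `x`, `m1`, `m2`, `y`,
#'   any case) or an `observed_distribution`.
#' @param estimands Character vector of estimand names (see
#'   [estimand_names()]); defaults to all cross effects under `dag`.
#' @param dag `"A"` or `"B"`.
#' @param method `"symbolic"`, `"lp"`, or `"both"`.
#' @param levels Named list overriding the canonical levels.
#' @returns A tibble with one row per estimand and method: columns `estimand`,
#'   `label`, `method`, `lower`, `upper`, `active_lower`, `active_upper`.
#' @examples
#' sim <- generate_npsem(n = 2000, dag = "B", seed = 8)
#' cross_bounds(sim$data, dag = "B", method = "both")
#' @export
cross_bounds <- function(data, estimands = NULL, dag = "B",
                         method = c("symbolic", "lp", "both"),
                         levels = list()) {
  method <- match.arg(method)
  dag <- .check_dag(dag)
  dist <- if (inherits(data, "observed_distribution")) data else
    observed_distribution(data)
  if (is.null(estimands)) estimands <- setdiff(estimand_names(dag), "total_effect")
  rows <- list()
  for (nm in estimands) {
    sp <- effect_spec(nm, levels = .canonical_levels(nm, levels), dag = dag)
    want <- if (method == "both") c("symbolic", "lp") else method
    for (m in want) {
      bi <- if (m == "symbolic") {
        route <- .symbolic_route(sp)
        if (is.null(route)) {
          rlang::inform(sprintf(
            "no symbolic bound for estimand %s at these levels; using the LP engine",
            nm))
          solve_bounds(dist, sp)
        } else if (route == "result1_swapped") {
          bounds_result1_swapped(dist)
        } else {
          .symbolic_interval(dist, route, sp$label)
        }
      } else {
        solve_bounds(dist, sp)
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        estimand = nm, label = sp$label, method = bi$method,
        lower = bi$lower, upper = bi$upper,
        active_lower = bi$active_lower, active_upper = bi$active_upper
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("crossmed_bounds", class(out))
  out
}
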