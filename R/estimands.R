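# Cross-effect estimands. Each estimand contrasts two nested potential
# outcomes that differ only in the outer exposure level: one mediator is
# controlled to a constant while the other is set to the natural
# (subject-specific counterfactual) value it would take under a reference
# exposure. Five distinct contrasts exist when M1 affects M2 (dag "B");
# two of them remain meaningful when the mediators do not interact (dag "A").

# registry: required levels beyond x/xp, admissible dags, and how the two
# mediator arguments are formed from the levels
.estimand_registry <- list(
  crossA_M1nat = list(
    dags = c("A", "B"), required = c("x1", "m2"),
    label = "dE{Y(x->x', M1(x1), m2)}"
  ),
  crossA_M2nat = list(
    dags = c("A", "B"), required = c("m1", "x2"),
    label = "dE{Y(x->x', m1, M2(x2))}"
  ),
  crossB_M2ctrl_inner = list(
    dags = "B", required = c("m1", "x2", "m1p"),
    label = "dE{Y(x->x', m1, M2(x2, m1'))}"
  ),
  crossB_M2nat_inner_nat = list(
    dags = "B", required = c("m1", "x2", "x3"),
    label = "dE{Y(x->x', m1, M2(x2, M1(x3)))}"
  ),
  crossB_bothnat_inner_ctrl = list(
    dags = "B", required = c("x1", "x2", "m1p"),
    label = "dE{Y(x->x', M1(x1), M2(x2, m1'))}"
  ),
  total_effect = list(
    dags = c("A", "B"), required = character(),
    label = "E{Y(x)} - E{Y(x')}"
  )
)

#' Names of the supported estimands
#'
#' @param dag Optionally restrict to estimands defined under one DAG variant:
#'   `"A"` (mediators do not affect each other) or `"B"` (M1 affects M2).
#' @returns Character vector of estimand names accepted by [effect_spec()].
#' @export
estimand_names <- function(dag = NULL) {
  nm <- names(.estimand_registry)
  if (is.null(dag)) return(nm)
  dag <- .check_dag(dag)
  nm[vapply(.estimand_registry, function(e) dag %in% e$dags, logical(1))]
}

.check_dag <- function(dag) {
  if (!(is.character(dag) && length(dag) == 1 && dag %in% c("A", "B"))) {
    rlang::abort('`dag` must be "A" or "B"', class = "crossmed_coding_error")
  }
  dag
}

.check_level <- function(levels, name, estimand) {
  v <- levels[[name]]
  if (is.null(v)) {
    rlang::abort(
      sprintf('estimand "%s" requires level `%s`', estimand, name),
      class = "crossmed_underspecified_error"
    )
  }
  if (!(length(v) == 1 && v %in% c(0, 1))) {
    rlang::abort(sprintf("level `%s` must be 0 or 1", name),
                 class = "crossmed_coding_error")
  }
  as.integer(v)
}

# A potential-outcome specification: outer exposure x plus how each mediator
# argument is resolved. m1: ctrl(level) or nat(x1). m2: ctrl(level), nat(x2)
# (natural value under x2; under dag B this entails M1's natural value at x2),
# nat_ctrl(x2, m1p) or nat_nat(x2, x3). kind "self" means "at the outer x"
# (used by the total effect).
new_po_spec <- function(x, m1, m2, dag) {
  structure(list(x = x, m1 = m1, m2 = m2, dag = dag), class = "po_spec")
}

#' @export
format.po_spec <- function(x, ...) {
  f1 <- switch(x$m1$kind,
    ctrl = as.character(x$m1$level),
    nat = sprintf("M1(%d)", x$m1$x1),
    self = "M1(x)"
  )
  f2 <- switch(x$m2$kind,
    ctrl = as.character(x$m2$level),
    nat = sprintf("M2(%d)", x$m2$x2),
    nat_ctrl = sprintf("M2(%d, %d)", x$m2$x2, x$m2$m1p),
    nat_nat = sprintf("M2(%d, M1(%d))", x$m2$x2, x$m2$x3),
    self = "M2(x)"
  )
  if (x$m1$kind == "self" && x$m2$kind == "self") sprintf("Y(%d)", x$x)
  else sprintf("Y(%d, %s, %s)", x$x, f1, f2)
}

#' @export
print.po_spec <- function(x, ...) {
  cat("<po_spec>", format(x), "\n")
  invisible(x)
}

#' Build a cross-effect estimand specification
#'
#' Creates a validated contrast \eqn{E\{Y(x, \cdot, \cdot)\} - E\{Y(x', \cdot,
#' \cdot)\}} in which the two nested potential outcomes differ only in the
#' outer exposure level. The estimand names are:
#'
#' * `"crossA_M1nat"`: \eqn{\Delta E\{Y(x \to x', M_1(x_1), m_2)\}} — M2
#'   controlled, M1 natural (either DAG variant).
#' * `"crossA_M2nat"`: \eqn{\Delta E\{Y(x \to x', m_1, M_2(x_2))\}} — M1
#'   controlled, M2 natural. Under dag `"B"` the natural value of M2 at
#'   \eqn{x_2} entails M1's natural value at \eqn{x_2}.
#' * `"crossB_M2ctrl_inner"`: \eqn{\Delta E\{Y(x \to x', m_1, M_2(x_2, m_1'))\}}
#'   (dag `"B"` only).
#' * `"crossB_M2nat_inner_nat"`:
#'   \eqn{\Delta E\{Y(x \to x', m_1, M_2(x_2, M_1(x_3)))\}} (dag `"B"` only).
#' * `"crossB_bothnat_inner_ctrl"`:
#'   \eqn{\Delta E\{Y(x \to x', M_1(x_1), M_2(x_2, m_1'))\}} (dag `"B"` only).
#' * `"total_effect"`: \eqn{E\{Y(x)\} - E\{Y(x')\}}.
#'
#' @param name One of [estimand_names()].
#' @param levels Named list of 0/1 levels. `x` (treated exposure, default 1)
#'   and `xp` (control exposure, default 0) are always accepted; the remaining
#'   required names depend on the estimand (`x1`, `x2`, `x3`, `m1`, `m2`,
#'   `m1p`) and each must be supplied explicitly — a missing required level
#'   is an error, not a silent default.
#' @param dag `"A"` or `"B"`.
#' @returns An `effect_spec` object with elements `name`, `dag`, `levels`,
#'   `treated` and `control` (both `po_spec`), and `label`.
#' @examples
#' effect_spec("crossA_M1nat", levels = list(x1 = 0, m2 = 0), dag = "A")
#' @export
effect_spec <- function(name, levels = list(), dag = "B") {
  dag <- .check_dag(dag)
  if (!name %in% names(.estimand_registry)) {
    rlang::abort(
      paste0('unknown estimand "', name, '"; valid names: ',
             paste(names(.estimand_registry), collapse = ", ")),
      class = "crossmed_coding_error"
    )
  }
  reg <- .estimand_registry[[name]]
  if (!dag %in% reg$dags) {
    rlang::abort(
      sprintf('estimand "%s" requires an effect of M1 on M2 (dag "B")', name),
      class = "crossmed_dag_incompatible_error"
    )
  }
  if (is.null(levels[["x"]])) levels[["x"]] <- 1L
  if (is.null(levels[["xp"]])) levels[["xp"]] <- 0L
  x <- .check_level(levels, "x", name)
  xp <- .check_level(levels, "xp", name)
  for (r in reg$required) levels[[r]] <- .check_level(levels, r, name)

  args <- switch(name,
    crossA_M1nat = list(
      m1 = list(kind = "nat", x1 = levels[["x1"]]),
      m2 = list(kind = "ctrl", level = levels[["m2"]])
    ),
    crossA_M2nat = list(
      m1 = list(kind = "ctrl", level = levels[["m1"]]),
      m2 = list(kind = "nat", x2 = levels[["x2"]])
    ),
    crossB_M2ctrl_inner = list(
      m1 = list(kind = "ctrl", level = levels[["m1"]]),
      m2 = list(kind = "nat_ctrl", x2 = levels[["x2"]], m1p = levels[["m1p"]])
    ),
    crossB_M2nat_inner_nat = list(
      m1 = list(kind = "ctrl", level = levels[["m1"]]),
      m2 = list(kind = "nat_nat", x2 = levels[["x2"]], x3 = levels[["x3"]])
    ),
    crossB_bothnat_inner_ctrl = list(
      m1 = list(kind = "nat", x1 = levels[["x1"]]),
      m2 = list(kind = "nat_ctrl", x2 = levels[["x2"]], m1p = levels[["m1p"]])
    ),
    total_effect = list(
      m1 = list(kind = "self"),
      m2 = list(kind = "self")
    )
  )

  keep <- levels[c("x", "xp", reg$required)]
  structure(
    list(
      name = name, dag = dag, levels = keep,
      treated = new_po_spec(x, args$m1, args$m2, dag),
      control = new_po_spec(xp, args$m1, args$m2, dag),
      label = reg$label
    ),
    class = "effect_spec"
  )
}

#' @export
format.effect_spec <- function(x, ...) {
  sprintf("%s  [%s vs %s, dag %s]", x$label,
          format(x$treated), format(x$control), x$dag)
}

#' @export
print.effect_spec <- function(x, ...) {
  cat("<effect_spec>", format(x), "\n")
  invisible(x)
}

#' Exchange the mediator roles of an estimand
#'
#' When the mediators do not affect each other (dag `"A"`), the model is
#' symmetric in M1 and M2, so every estimand has a mirror image with the
#' mediator roles exchanged: \eqn{\Delta E\{Y(x \to x', M_1(x_1), m_2)\}}
#' maps to \eqn{\Delta E\{Y(x \to x', m_1 = m_2^{old}, M_2(x_2 = x_1^{old}))\}}
#' and vice versa. Applying the operation twice returns the original
#' estimand. Under dag `"B"` the model is asymmetric and the operation is an
#' error.
#'
#' @param spec An `effect_spec` with `dag = "A"`.
#' @returns The mirrored `effect_spec`.
#' @export
relabel_mediators <- function(spec) {
  stopifnot(inherits(spec, "effect_spec"))
  if (spec$dag != "A") {
    rlang::abort("mediator relabeling requires the symmetric model (dag \"A\")",
                 class = "crossmed_asymmetric_dag_error")
  }
  lv <- spec$levels
  switch(spec$name,
    crossA_M1nat = effect_spec(
      "crossA_M2nat",
      levels = list(x = lv$x, xp = lv$xp, m1 = lv$m2, x2 = lv$x1), dag = "A"
    ),
    crossA_M2nat = effect_spec(
      "crossA_M1nat",
      levels = list(x = lv$x, xp = lv$xp, x1 = lv$x2, m2 = lv$m1), dag = "A"
    ),
    total_effect = spec
  )
}
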