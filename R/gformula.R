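# g-formula engine: point identification of the component potential-outcome
# means under no residual mediator-outcome confounding. Each mean is a sum of
# outcome-model predictions weighted by mediator-model probabilities,
# standardized over the empirical covariate distribution.

#' Fit the conditional-probability models used by the g-formula
#'
#' Fits (i) an outcome model for \eqn{P(Y=1 \mid C, X, M_1, M_2)}, (ii) a
#' first-mediator model \eqn{P(M_1=1 \mid C, X)}, (iii) a second-mediator
#' model \eqn{P(M_2=1 \mid C, X)} (dag `"A"`) or
#' \eqn{P(M_2=1 \mid C, X, M_1)} (dag `"B"`), and (iv) a marginal outcome
#' model \eqn{P(Y=1 \mid C, X)} used only for the total effect. The empirical
#' covariate sample is retained: the population distribution of C is always
#' estimated by its sample distribution.
#'
#' @param data Data frame with 0/1 columns `x`, `m1`, `m2`, `y` (any case);
#'   all other columns are treated as covariates unless listed in `exclude`.
#' @param dag `"A"` (mediators do not affect each other) or `"B"` (M1 affects
#'   M2).
#' @param model_form `"saturated"` (stratified empirical frequencies; the
#'   default without covariates), `"main_effects"` or `"two_way"` (logistic
#'   regressions; `"two_way"`, the default with covariates, includes all
#'   pairwise interactions among covariates, exposure and mediators).
#' @param exclude Covariate columns to drop.
#' @returns A `mediation_models` object: list with closures `pY(x, m1, m2)`,
#'   `pM1(x)`, `pM2(x, m1)`, `pYx(x)` (each returning a vector over the
#'   covariate sample), plus `covariate_sample`, `dag`, `model_form`, `n`,
#'   `arm_means`.
#' @export
fit_mediation_models <- function(data, dag = "B",
                                 model_form = NULL, exclude = NULL) {
  dag <- .check_dag(dag)
  data <- .standardize_columns(data)
  if (!is.null(exclude)) data <- data[setdiff(names(data), exclude)]
  for (v in c("x", "m1", "m2", "y")) .check_binary(data[[v]], v)
  covs <- setdiff(names(data), c("x", "m1", "m2", "y"))
  if (is.null(model_form)) {
    model_form <- if (length(covs) == 0) "saturated" else "two_way"
  }
  model_form <- match.arg(model_form, c("saturated", "main_effects", "two_way"))

  n <- nrow(data)
  arm_means <- c(`0` = mean(data$y[data$x == 0]), `1` = mean(data$y[data$x == 1]))

  if (model_form == "saturated" && length(covs) == 0) {
    mods <- .saturated_models_nocov(data, dag)
    cov_sample <- data.frame(row.names = 1L) # single pseudo-row: no covariates
  } else if (model_form == "saturated") {
    mods <- .saturated_models_cov(data, dag, covs)
    cov_sample <- as.data.frame(data[covs])
  } else {
    mods <- .glm_models(data, dag, covs, model_form)
    cov_sample <- as.data.frame(data[covs])
  }

  structure(
    c(mods, list(
      covariate_sample = cov_sample, covariate_names = covs,
      dag = dag, model_form = model_form, n = n, arm_means = arm_means
    )),
    class = "mediation_models"
  )
}

#' @export
print.mediation_models <- function(x, ...) {
  cat("<mediation_models> dag", x$dag, "| form", x$model_form,
      "| n =", x$n, "\n")
  if (length(x$covariate_names)) {
    cat("  covariates:", paste(x$covariate_names, collapse = ", "), "\n")
  } else cat("  no covariates\n")
  invisible(x)
}

# saturated, no covariates: closures over the 16-cell table; empty strata
# yield NaN and only become an error if queried with positive weight
.saturated_models_nocov <- function(data, dag) {
  idx <- .cell_index(data$y, data$m1, data$m2, data$x)
  counts <- tabulate(idx, nbins = 16L)
  # counts arranged [m2 fastest, m1, y, x slowest]
  arr <- array(counts, dim = c(2, 2, 2, 2)) # [m2, m1, y, x]
  n_xm1m2 <- arr[, , 1, ] + arr[, , 2, ]    # [m2, m1, x]
  pY_tab <- arr[, , 2, ] / n_xm1m2          # P(Y=1 | x, m1, m2), NaN if empty
  n_x <- apply(arr, 4, sum)
  pM1_tab <- apply(n_xm1m2, c(2, 3), sum)[2, ] / n_x   # P(M1=1|x)
  if (dag == "A") {
    pM2A_tab <- apply(n_xm1m2, c(1, 3), sum)[2, ] / n_x # P(M2=1|x)
    pM2 <- function(x, m1 = NULL) pM2A_tab[x + 1]
  } else {
    n_xm1 <- apply(n_xm1m2, c(2, 3), sum)               # [m1, x]
    pM2B_tab <- n_xm1m2[2, , ] / n_xm1                  # P(M2=1|x,m1) [m1, x]
    pM2 <- function(x, m1) pM2B_tab[m1 + 1, x + 1]
  }
  ym <- c(mean(data$y[data$x == 0]), mean(data$y[data$x == 1]))
  list(
    pY = function(x, m1, m2) pY_tab[m2 + 1, m1 + 1, x + 1],
    pM1 = function(x) pM1_tab[x + 1],
    pM2 = pM2,
    pYx = function(x) ym[x + 1]
  )
}

# saturated with covariates: frequencies within joint covariate strata,
# evaluated back at every covariate sample row
.saturated_models_cov <- function(data, dag, covs) {
  ckey <- do.call(paste, c(as.list(data[covs]), sep = "\r"))
  # stratum-mean lookup: absent strata yield NaN, caught by .wprod if weighted
  lookup <- function(key, num) {
    nm <- tapply(num, key, sum)
    dn <- tapply(rep(1L, length(key)), key, sum)
    function(qk) as.numeric(nm[qk]) / as.numeric(dn[qk])
  }
  kY <- paste(ckey, data$x, data$m1, data$m2, sep = "\r")
  fY <- lookup(kY, data$y)
  kM1 <- paste(ckey, data$x, sep = "\r")
  fM1 <- lookup(kM1, data$m1)
  fYx <- lookup(kM1, data$y)
  if (dag == "A") {
    fM2 <- lookup(kM1, data$m2)
    pM2 <- function(x, m1 = NULL) fM2(paste(ckey, x, sep = "\r"))
  } else {
    kM2 <- paste(ckey, data$x, data$m1, sep = "\r")
    fM2 <- lookup(kM2, data$m2)
    pM2 <- function(x, m1) fM2(paste(ckey, x, m1, sep = "\r"))
  }
  list(
    pY = function(x, m1, m2) fY(paste(ckey, x, m1, m2, sep = "\r")),
    pM1 = function(x) fM1(paste(ckey, x, sep = "\r")),
    pM2 = pM2,
    pYx = function(x) fYx(paste(ckey, x, sep = "\r"))
  )
}

# logistic models; on nonconvergence or separation fall back to stratified
# frequencies with a warning
.glm_fit <- function(formula, data, label) {
  ok <- TRUE
  fit <- withCallingHandlers(
    stats::glm(formula, family = stats::binomial(), data = data),
    warning = function(w) {
      if (grepl("did not converge|fitted probabilities numerically 0 or 1",
                conditionMessage(w))) {
        ok <<- FALSE
        invokeRestart("muffleWarning")
      }
    }
  )
  if (!ok) {
    rlang::warn(
      sprintf("logistic model for %s did not converge cleanly; falling back to stratified frequencies",
              label),
      class = "crossmed_nonconvergence_warning"
    )
    return(NULL)
  }
  fit
}

.glm_models <- function(data, dag, covs, model_form) {
  rhs <- function(vars) {
    body <- paste(vars, collapse = " + ")
    if (model_form == "two_way" && length(vars) > 1) {
      body <- sprintf("(%s)^2", body)
    }
    body
  }
  df <- as.data.frame(data)
  fY <- .glm_fit(
    stats::as.formula(paste("y ~", rhs(c(covs, "x", "m1", "m2")))), df, "Y")
  fM1 <- .glm_fit(
    stats::as.formula(paste("m1 ~", rhs(c(covs, "x")))), df, "M1")
  m2vars <- if (dag == "B") c(covs, "x", "m1") else c(covs, "x")
  fM2 <- .glm_fit(stats::as.formula(paste("m2 ~", rhs(m2vars))), df, "M2")
  fYx <- .glm_fit(stats::as.formula(paste("y ~", rhs(c(covs, "x")))), df, "Y|C,X")

  sat <- if (is.null(fY) || is.null(fM1) || is.null(fM2) || is.null(fYx)) {
    if (length(covs) == 0) .saturated_models_nocov(df, dag)
    else .saturated_models_cov(df, dag, covs)
  }
  cov_df <- as.data.frame(data[covs])
  pred <- function(fit, consts) {
    nd <- cov_df
    for (nmv in names(consts)) nd[[nmv]] <- consts[[nmv]]
    as.numeric(stats::predict(fit, newdata = nd, type = "response"))
  }
  list(
    pY = if (is.null(fY)) sat$pY else
      function(x, m1, m2) pred(fY, list(x = x, m1 = m1, m2 = m2)),
    pM1 = if (is.null(fM1)) sat$pM1 else function(x) pred(fM1, list(x = x)),
    pM2 = if (is.null(fM2)) sat$pM2 else {
      if (dag == "B") function(x, m1) pred(fM2, list(x = x, m1 = m1))
      else function(x, m1 = NULL) pred(fM2, list(x = x))
    },
    pYx = if (is.null(fYx)) sat$pYx else function(x) pred(fYx, list(x = x))
  )
}

# weighted product that tolerates NaN predictions in zero-weight strata but
# errors when an empty stratum actually carries weight
.wprod <- function(w, p) {
  out <- w * p
  out[w == 0] <- 0
  if (anyNA(out)) {
    rlang::abort(
      "the g-formula conditions on an empty stratum (saturated model with a zero cell)",
      class = "crossmed_empty_stratum_error"
    )
  }
  out
}

#' Potential-outcome means identified by the g-formula
#'
#' Each function returns a plug-in estimate of one component mean, averaging
#' model predictions over the empirical covariate distribution:
#'
#' * `po_mean_a()`: \eqn{E\{Y(x, M_1(x_1), m_2)\}} — sum over \eqn{m_1} of
#'   the outcome model times the M1-model law at exposure \eqn{x_1}.
#' * `po_mean_b()`: \eqn{E\{Y(x, m_1, M_2(x_2, m_1'))\}} (dag `"B"`).
#' * `po_mean_c()`: \eqn{E\{Y(x, m_1, M_2(x_2, M_1(x_3)))\}} (dag `"B"`).
#' * `po_mean_d()`: \eqn{E\{Y(x, M_1(x_1), M_2(x_2, m_1'))\}} (dag `"B"`).
#'
#' @param models A `mediation_models` object from [fit_mediation_models()].
#' @param x,x1,x2,x3 Exposure levels (0/1) for the outer outcome and the
#'   natural-value arguments.
#' @param m1,m2,m1p Controlled mediator levels (0/1).
#' @returns A single probability in \[0, 1\].
#' @seealso [estimate_effect()] for contrasts of these means.
#' @export
po_mean_a <- function(models, x, x1, m2) {
  w1 <- models$pM1(x1)
  mean(.wprod(w1, models$pY(x, 1, m2)) + .wprod(1 - w1, models$pY(x, 0, m2)))
}

#' @rdname po_mean_a
#' @export
po_mean_b <- function(models, x, m1, x2, m1p) {
  .require_dag_b(models)
  w2 <- models$pM2(x2, m1p)
  mean(.wprod(w2, models$pY(x, m1, 1)) + .wprod(1 - w2, models$pY(x, m1, 0)))
}

#' @rdname po_mean_a
#' @export
po_mean_c <- function(models, x, m1, x2, x3) {
  .require_dag_b(models)
  w1 <- models$pM1(x3)
  # inner sums are only evaluated when their branch carries weight, so an
  # empty stratum behind a zero-probability branch stays harmless
  branch <- function(w, m1p) {
    if (all(w == 0)) return(0)
    w2 <- models$pM2(x2, m1p)
    .wprod(w, .wprod(w2, models$pY(x, m1, 1)) +
             .wprod(1 - w2, models$pY(x, m1, 0)))
  }
  mean(branch(w1, 1) + branch(1 - w1, 0))
}

#' @rdname po_mean_a
#' @export
po_mean_d <- function(models, x, x1, x2, m1p) {
  .require_dag_b(models)
  w1 <- models$pM1(x1)
  w2 <- models$pM2(x2, m1p)
  term <- function(m1v, m2v) {
    wm1 <- if (m1v == 1) w1 else 1 - w1
    wm2 <- if (m2v == 1) w2 else 1 - w2
    .wprod(wm1 * wm2, models$pY(x, m1v, m2v))
  }
  mean(term(0, 0) + term(0, 1) + term(1, 0) + term(1, 1))
}

# dag A mirror of po_mean_a: E{Y(x, m1, M2(x2))} with M2 not affected by M1
.po_mean_a_m2nat <- function(models, x, m1, x2) {
  w2 <- models$pM2(x2)
  mean(.wprod(w2, models$pY(x, m1, 1)) + .wprod(1 - w2, models$pY(x, m1, 0)))
}

.require_dag_b <- function(models) {
  if (models$dag != "B") {
    rlang::abort(
      'this potential-outcome mean requires an effect of M1 on M2 (dag "B")',
      class = "crossmed_dag_incompatible_error"
    )
  }
}

#' Evaluate one potential-outcome mean for an estimand arm
#'
#' Dispatches a `po_spec` (one arm of an [effect_spec()]) to the matching
#' g-formula expression.
#'
#' @param models A `mediation_models` object.
#' @param po A `po_spec` (e.g. `spec$treated`).
#' @returns A probability in \[0, 1\].
#' @export
po_mean <- function(models, po) {
  stopifnot(inherits(po, "po_spec"))
  if (po$dag != models$dag) {
    rlang::abort("estimand and fitted models assume different DAG variants",
                 class = "crossmed_dag_incompatible_error")
  }
  k1 <- po$m1$kind
  k2 <- po$m2$kind
  x <- po$x
  if (k1 == "self" && k2 == "self") {
    # E{Y(x)}: identified by randomization; standardized over C if present
    if (length(models$covariate_names) == 0) {
      return(unname(models$arm_means[as.character(x)]))
    }
    return(mean(models$pYx(x)))
  }
  if (k1 == "ctrl" && k2 == "ctrl") {
    return(mean(.wprod(1, models$pY(x, po$m1$level, po$m2$level))))
  }
  if (k1 == "nat" && k2 == "ctrl") {
    return(po_mean_a(models, x, po$m1$x1, po$m2$level))
  }
  if (k1 == "ctrl" && k2 == "nat") {
    if (models$dag == "A") {
      return(.po_mean_a_m2nat(models, x, po$m1$level, po$m2$x2))
    }
    # natural M2 at x2 entails M1's natural value at x2
    return(po_mean_c(models, x, po$m1$level, po$m2$x2, po$m2$x2))
  }
  if (k1 == "ctrl" && k2 == "nat_ctrl") {
    return(po_mean_b(models, x, po$m1$level, po$m2$x2, po$m2$m1p))
  }
  if (k1 == "ctrl" && k2 == "nat_nat") {
    return(po_mean_c(models, x, po$m1$level, po$m2$x2, po$m2$x3))
  }
  if (k1 == "nat" && k2 == "nat_ctrl") {
    return(po_mean_d(models, x, po$m1$x1, po$m2$x2, po$m2$m1p))
  }
  rlang::abort("unsupported potential-outcome form",
               class = "crossmed_coding_error")
}

#' Plug-in estimate of a cross-direct effect
#'
#' Evaluates both arms of the contrast with the matching g-formula expression
#' and returns treated minus control. Valid under no residual
#' mediator-outcome confounding and correct model specification.
#'
#' @param spec An [effect_spec()].
#' @param models A `mediation_models` object with the same DAG variant.
#' @returns The effect estimate (numeric scalar) with attribute `components`
#'   (the two potential-outcome means).
#' @export
estimate_effect <- function(spec, models) {
  stopifnot(inherits(spec, "effect_spec"), inherits(models, "mediation_models"))
  tr <- po_mean(models, spec$treated)
  ct <- po_mean(models, spec$control)
  structure(tr - ct, components = c(treated = tr, control = ct))
}

#' Estimate all cross-direct effects at the canonical levels
#'
#' Convenience wrapper: fits the g-formula models and estimates every estimand
#' defined under the chosen DAG variant at the canonical contrast (treated
#' exposure 1 vs control 0, all controlled mediator levels and natural-value
#' reference exposures at 0 unless overridden).
#'
#' @inheritParams fit_mediation_models
#' @param levels Named list overriding the canonical levels (applied to every
#'   estimand that uses the given name).
#' @param estimands Character vector of estimand names; defaults to all
#'   estimands available under `dag`.
#' @returns A tibble with columns `estimand`, `label`, `estimate`, `treated`,
#'   `control`; the fitted `mediation_models` object is attached as attribute
#'   `"models"`.
#' @examples
#' sim <- generate_npsem(n = 2000, dag = "B", confounded = FALSE, seed = 1)
#' cross_effects(sim$data, dag = "B")
#' @export
cross_effects <- function(data, dag = "B", model_form = NULL,
                          levels = list(), estimands = NULL, exclude = NULL) {
  dag <- .check_dag(dag)
  models <- fit_mediation_models(data, dag = dag, model_form = model_form,
                                 exclude = exclude)
  if (is.null(estimands)) estimands <- estimand_names(dag)
  rows <- lapply(estimands, function(nm) {
    sp <- effect_spec(nm, levels = .canonical_levels(nm, levels), dag = dag)
    est <- estimate_effect(sp, models)
    cmp <- attr(est, "components")
    tibble::tibble(
      estimand = nm, label = sp$label, estimate = as.numeric(est),
      treated = cmp[["treated"]], control = cmp[["control"]]
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "models") <- models
  class(out) <- c("crossmed_effects", class(out))
  out
}

# canonical contrast: x = 1 vs x' = 0, every other level 0
.canonical_levels <- function(name, overrides = list()) {
  req <- .estimand_registry[[name]]$required
  lv <- as.list(stats::setNames(rep(0L, length(req)), req))
  lv$x <- 1L
  lv$xp <- 0L
  for (nmv in names(overrides)) lv[[nmv]] <- overrides[[nmv]]
  lv
}
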