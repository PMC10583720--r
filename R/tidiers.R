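# broom-style tidiers for the package's result objects

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a bound interval
#'
#' @param x A `bounds_interval`.
#' @param ... Unused.
#' @returns A one-row tibble with `estimand`, `method`, `lower`, `upper`,
#'   `active_lower`, `active_upper`.
#' @method tidy bounds_interval
#' @export
tidy.bounds_interval <- function(x, ...) {
  tibble::tibble(
    estimand = x$estimand, method = x$method,
    lower = x$lower, upper = x$upper,
    active_lower = x$active_lower, active_upper = x$active_upper
  )
}

#' @rdname tidy.bounds_interval
#' @method glance bounds_interval
#' @export
glance.bounds_interval <- function(x, ...) {
  tibble::tibble(method = x$method, width = x$upper - x$lower,
                 covers_zero = x$lower <= 0 && x$upper >= 0)
}

#' Tidy a bootstrap result
#'
#' @param x A `bootstrap_ci`.
#' @param ... Unused.
#' @returns A tibble with one row per statistic: `statistic`, `point`,
#'   `lower`, `upper`.
#' @method tidy bootstrap_ci
#' @export
tidy.bootstrap_ci <- function(x, ...) {
  x$ci
}

#' @rdname tidy.bootstrap_ci
#' @method glance bootstrap_ci
#' @export
glance.bootstrap_ci <- function(x, ...) {
  tibble::tibble(B = x$B, level = x$level,
                 n_statistics = length(x$point))
}

#' Summarize fitted g-formula models
#'
#' @param x A `mediation_models` object.
#' @param ... Unused.
#' @returns A one-row tibble with `dag`, `model_form`, `n`, `n_covariates`.
#' @method glance mediation_models
#' @export
glance.mediation_models <- function(x, ...) {
  tibble::tibble(dag = x$dag, model_form = x$model_form, n = x$n,
                 n_covariates = length(x$covariate_names))
}
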