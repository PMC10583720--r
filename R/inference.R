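# Nonparametric bootstrap: percentile confidence intervals for point
# estimates and for bound endpoints. Subject-level records are resampled with
# replacement (rows, never aggregated cells), the statistic is recomputed per
# replicate, and the interval is the pair of empirical quantiles.

# row subset without rowname bookkeeping; the bootstrap calls this B times
.fast_rows <- function(data, idx) {
  out <- lapply(data, function(col) col[idx])
  attr(out, "row.names") <- c(NA_integer_, -length(idx))
  class(out) <- "data.frame"
  out
}

#' Percentile bootstrap for a statistic of binary mediation data
#'
#' Resamples records with replacement (optionally within exposure arms),
#' recomputes `statistic` on every replicate and returns the percentile
#' interval at the requested level. The statistic may return a single number
#' or a named numeric vector (e.g. several estimands computed from one fit);
#' intervals are then computed per component from the same resamples.
#'
#' A replicate on which the statistic fails (for instance an empty arm after
#' resampling) is retried with a fresh resample up to `max_retries` times
#' before the whole run errors.
#'
#' @param data Data frame of subject-level records.
#' @param statistic Function mapping a data frame to a numeric vector.
#' @param B Number of bootstrap replicates (default 1000).
#' @param level Confidence level in (0, 1) (default 0.95).
#' @param seed Optional integer seed; the run is fully reproducible given it.
#' @param stratify_by_arm Resample within levels of `x` instead of the whole
#'   data frame (default `FALSE`).
#' @param max_retries Fresh-resample attempts per failing replicate.
#' @returns A `bootstrap_ci`: list with `point` (statistic on the original
#'   data), `replicates` (B x k matrix), `ci` (tibble with `statistic`,
#'   `lower`, `upper`), `level`, `B`, `seed`.
#' @examples
#' sim <- generate_npsem(n = 500, dag = "B", confounded = FALSE, seed = 3)
#' te <- function(d) c(te = mean(d$y[d$x == 1]) - mean(d$y[d$x == 0]))
#' bootstrap_ci(sim$data, te, B = 200, seed = 5)
#' @export
bootstrap_ci <- function(data, statistic, B = 1000, level = 0.95, seed = NULL,
                         stratify_by_arm = FALSE, max_retries = 10) {
  stopifnot(B >= 1, level > 0, level < 1)
  data <- as.data.frame(data)
  n <- nrow(data)
  point <- statistic(data)
  k <- length(point)
  if (is.null(names(point))) {
    names(point) <- if (k == 1) "statistic" else paste0("statistic", seq_len(k))
  }
  arm_idx <- if (stratify_by_arm) split(seq_len(n), data$x)

  run <- function() {
    reps <- matrix(NA_real_, B, k)
    for (b in seq_len(B)) {
      for (attempt in seq_len(max_retries + 1L)) {
        idx <- if (stratify_by_arm) {
          unlist(lapply(arm_idx, function(ii) ii[sample.int(length(ii),
                                                            length(ii),
                                                            replace = TRUE)]))
        } else {
          sample.int(n, n, replace = TRUE)
        }
        val <- tryCatch(statistic(.fast_rows(data, idx)),
                        error = function(e) NULL)
        if (!is.null(val)) break
        if (attempt > max_retries) {
          rlang::abort(
            sprintf("statistic failed on %d consecutive resamples", attempt),
            class = "crossmed_degenerate_resamples_error"
          )
        }
      }
      reps[b, ] <- val
    }
    reps
  }
  reps <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  colnames(reps) <- names(point)

  alpha <- (1 - level) / 2
  qs <- apply(reps, 2, stats::quantile, probs = c(alpha, 1 - alpha),
              type = 7, names = FALSE)
  structure(
    list(
      point = point, replicates = reps,
      ci = tibble::tibble(statistic = names(point),
                          point = unname(point),
                          lower = unname(qs[1, ]), upper = unname(qs[2, ])),
      level = level, B = B, seed = seed
    ),
    class = "bootstrap_ci"
  )
}

#' @export
print.bootstrap_ci <- function(x, ...) {
  cat(sprintf("<bootstrap_ci> B = %d, level = %.2f\n", x$B, x$level))
  print(x$ci)
  invisible(x)
}

#' Bootstrap confidence intervals for bound endpoints
#'
#' Applies the percentile bootstrap separately to the lower and upper
#' endpoints of a bound interval, treating each endpoint as a functional of
#' the observed distribution.
#'
#' @inheritParams bootstrap_ci
#' @param spec An [effect_spec()].
#' @param dag `"A"` or `"B"` (must match `spec`).
#' @param method `"symbolic"` (canonical contrasts only) or `"lp"`.
#' @returns A tibble with rows `lower` and `upper`: columns `endpoint`,
#'   `point`, `ci_lower`, `ci_upper`; the underlying `bootstrap_ci` is
#'   attached as attribute `"boot"`.
#' @export
bound_cis <- function(data, spec, dag = spec$dag,
                      method = c("symbolic", "lp"),
                      B = 1000, level = 0.95, seed = NULL,
                      stratify_by_arm = FALSE) {
  method <- match.arg(method)
  stopifnot(inherits(spec, "effect_spec"), identical(dag, spec$dag))
  endpoint_fun <- function(d) {
    dist <- observed_distribution(d)
    bi <- if (method == "lp") {
      solve_bounds(dist, spec)
    } else {
      route <- .symbolic_route(spec)
      if (is.null(route)) {
        rlang::abort(
          "no symbolic bound at these levels; use method = \"lp\"",
          class = "crossmed_coding_error"
        )
      }
      if (route == "result1_swapped") bounds_result1_swapped(dist)
      else .symbolic_interval(dist, route, spec$label)
    }
    c(lower = bi$lower, upper = bi$upper)
  }
  bt <- bootstrap_ci(data, endpoint_fun, B = B, level = level, seed = seed,
                     stratify_by_arm = stratify_by_arm)
  out <- tibble::tibble(
    endpoint = bt$ci$statistic,
    point = bt$ci$point,
    ci_lower = bt$ci$lower,
    ci_upper = bt$ci$upper
  )
  attr(out, "boot") <- bt
  out
}
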