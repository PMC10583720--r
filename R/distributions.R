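# Observed-data distribution p_{y m1 m2 . x}: the 16 conditional probabilities
# P(Y = y, M1 = m1, M2 = m2 | X = x) that are the sufficient statistic for all
# bounds in this package. Stored as two conditional simplexes of 8 (one per
# exposure arm); the marginal law of X is retained only as per-arm counts.

# canonical cell order: x slowest, then y, then m1, then m2 (binary counting,
# m2 fastest). Frozen; the LP engine and the JSON key order rely on it.
.cell_grid <- function() {
  tidyr::expand_grid(x = 0:1, y = 0:1, m1 = 0:1, m2 = 0:1)
}

.cell_key <- function(y, m1, m2, x) {
  sprintf("p_y%dm1%dm2%d.x%d", y, m1, m2, x)
}

# 1-based index into the canonical 16-vector
.cell_index <- function(y, m1, m2, x) {
  8L * x + 4L * y + 2L * m1 + m2 + 1L
}

.check_binary <- function(v, name) {
  if (anyNA(v) || any(v != 0 & v != 1)) {
    rlang::abort(
      sprintf("column `%s` must be coded 0/1", name),
      class = "crossmed_coding_error"
    )
  }
}

#' Locate the required binary columns in a data frame
#'
#' Accepts any case for the required column names X, M1, M2, Y and returns the
#' data with lower-case names `x`, `m1`, `m2`, `y` first, followed by all
#' remaining (covariate) columns.
#'
#' @param data A data frame.
#' @returns A tibble with columns `x`, `m1`, `m2`, `y`, then covariates.
#' @keywords internal
#' @noRd
.standardize_columns <- function(data) {
  nm <- names(data)
  lower <- tolower(nm)
  req <- c("x", "m1", "m2", "y")
  hit <- match(req, lower)
  if (anyNA(hit)) {
    rlang::abort(
      paste0("missing required column(s): ",
             paste(toupper(req[is.na(hit)]), collapse = ", ")),
      class = "crossmed_coding_error"
    )
  }
  ord <- c(hit, setdiff(seq_along(nm), hit))
  if (identical(ord, seq_along(nm)) && identical(nm[hit], req)) {
    return(data) # already canonical; keep this path cheap for the bootstrap
  }
  data <- data[ord]
  names(data)[1:4] <- req
  data
}

#' Estimate the observed distribution from binary subject-level data
#'
#' Tabulates the 16 empirical conditional frequencies
#' \eqn{\hat p_{y m_1 m_2 \cdot x} = \hat P(Y=y, M_1=m_1, M_2=m_2 \mid X=x)}
#' from subject-level records with binary exposure `x`, mediators `m1`, `m2`
#' and outcome `y` (column names matched case-insensitively). These 16
#' probabilities are all the bounds machinery ever needs from the data.
#'
#' @param data A data frame with 0/1 columns `x`, `m1`, `m2`, `y` (any case).
#'   Additional columns are ignored here.
#' @returns An `observed_distribution`: a 16-row tibble with columns `x`, `y`,
#'   `m1`, `m2`, `p` and attributes `n_by_arm` (record counts per arm).
#' @examples
#' d <- tidyr::expand_grid(x = 0:1, y = 0:1, m1 = 0:1, m2 = 0:1)
#' observed_distribution(d) # uniform: every cell 1/8
#' @export
observed_distribution <- function(data) {
  data <- .standardize_columns(data)
  for (v in c("x", "m1", "m2", "y")) .check_binary(data[[v]], v)
  n_by_arm <- c(`0` = sum(data$x == 0), `1` = sum(data$x == 1))
  if (any(n_by_arm == 0)) {
    rlang::abort(
      "both exposure arms (X = 0 and X = 1) must be present",
      class = "crossmed_arm_absent_error"
    )
  }
  idx <- .cell_index(data$y, data$m1, data$m2, data$x)
  counts <- tabulate(idx, nbins = 16L)
  p <- counts / rep(n_by_arm, each = 8L)
  new_observed_distribution(p, n_by_arm = n_by_arm, counts = counts)
}

#' Construct an observed distribution from 16 probabilities
#'
#' @param p Numeric vector of length 16 in canonical order (`x` slowest, then
#'   `y`, `m1`, `m2`), or named with keys `"p_y{y}m1{m1}m2{m2}.x{x}"` in any
#'   order, or a data frame with columns `x`, `y`, `m1`, `m2`, `p`.
#' @param n_by_arm Optional record counts per arm, named `"0"` and `"1"`.
#' @param tol Tolerance for the per-arm sum-to-one check.
#' @returns An `observed_distribution`.
#' @export
as_observed_distribution <- function(p, n_by_arm = NULL, tol = 1e-8) {
  if (is.data.frame(p)) {
    grid <- .cell_grid()
    m <- dplyr::left_join(grid, tibble::as_tibble(p),
                          by = c("x", "y", "m1", "m2"))
    if (anyNA(m$p)) {
      rlang::abort("probability table must cover all 16 (x, y, m1, m2) cells",
                   class = "crossmed_coding_error")
    }
    p <- m$p
  } else if (!is.null(names(p))) {
    grid <- .cell_grid()
    keys <- .cell_key(grid$y, grid$m1, grid$m2, grid$x)
    if (!all(keys %in% names(p))) {
      rlang::abort("named probability vector must contain all 16 canonical keys",
                   class = "crossmed_coding_error")
    }
    p <- unname(p[keys])
  }
  stopifnot(is.numeric(p), length(p) == 16L)
  d <- new_observed_distribution(p, n_by_arm = n_by_arm, counts = NULL)
  rep_ <- validate_distribution(d, tol = tol)
  if (!attr(rep_, "valid")) {
    rlang::abort(
      paste0("invalid observed distribution: ",
             paste(rep_$check[!rep_$ok], collapse = ", ")),
      class = "crossmed_coding_error"
    )
  }
  d
}

new_observed_distribution <- function(p, n_by_arm = NULL, counts = NULL) {
  out <- .cell_grid()
  out$p <- as.numeric(p)
  out <- tibble::new_tibble(out, n_by_arm = n_by_arm, counts = counts,
                            class = "observed_distribution")
  out
}

#' @export
print.observed_distribution <- function(x, ...) {
  cat("<observed_distribution> p{Y, M1, M2 | X}\n")
  n <- attr(x, "n_by_arm")
  if (!is.null(n)) cat("  records: n(X=0) =", n[["0"]], " n(X=1) =", n[["1"]], "\n")
  NextMethod()
}

# the canonical 16-vector (x slowest, then y, m1, m2), named with JSON keys
dist_vector <- function(dist) {
  p <- dist$p
  names(p) <- .cell_key(dist$y, dist$m1, dist$m2, dist$x)
  p
}

#' Diagnostics for an observed distribution
#'
#' Reports nonnegativity, per-arm normalization and the number of empty cells.
#' Zero cells are flagged (plug-in estimators that condition on an empty
#' stratum will fail later) but are not an error at this level.
#'
#' @param dist An `observed_distribution`.
#' @param tol Tolerance for the per-arm sum-to-one check.
#' @returns A tibble with columns `check`, `ok`, `detail`, and attribute
#'   `valid` (all checks passed).
#' @export
validate_distribution <- function(dist, tol = 1e-8) {
  p <- dist$p
  s0 <- sum(p[dist$x == 0])
  s1 <- sum(p[dist$x == 1])
  nzero <- sum(p == 0)
  checks <- tibble::tibble(
    check = c("nonnegative", "sum_to_one_arm0", "sum_to_one_arm1", "zero_cells"),
    ok = c(all(p >= 0), abs(s0 - 1) <= tol, abs(s1 - 1) <= tol, TRUE),
    detail = c(
      if (all(p >= 0)) "all 16 entries >= 0" else
        sprintf("%d negative entries", sum(p < 0)),
      sprintf("sum over arm X=0 is %.12g", s0),
      sprintf("sum over arm X=1 is %.12g", s1),
      if (nzero == 0) "no zero cells" else
        sprintf("%d zero cells (empty plug-in strata possible)", nzero)
    )
  )
  attr(checks, "valid") <- all(checks$ok)
  attr(checks, "n_zero_cells") <- nzero
  checks
}

#' Exchange the roles of the two mediators in a probability table
#'
#' Returns the distribution of (Y, M2, M1) given X, i.e. the table with the
#' mediator indices swapped: \eqn{p'_{y m_1 m_2 \cdot x} = p_{y m_2 m_1 \cdot x}}.
#' Used to evaluate the mediator-symmetric bounds when the mediators do not
#' affect each other.
#'
#' @param dist An `observed_distribution`.
#' @returns An `observed_distribution` with `m1` and `m2` exchanged.
#' @export
swap_mediators <- function(dist) {
  stopifnot(inherits(dist, "observed_distribution"))
  p <- dist$p[.cell_index(dist$y, dist$m2, dist$m1, dist$x)]
  new_observed_distribution(p, n_by_arm = attr(dist, "n_by_arm"))
}

#' Dichotomize a numeric vector at a threshold
#'
#' Values at or above (`">="`, default) or strictly above (`">"`) the threshold
#' map to 1, all others to 0. The default tie side follows the convention of
#' cutting immunological mediators "at" a threshold value, so the threshold
#' itself codes as 1.
#'
#' @param values Numeric vector; all values must be finite.
#' @param threshold Finite numeric cut point.
#' @param direction `">="` (threshold maps to 1) or `">"`.
#' @returns An integer vector of 0/1 with the same length as `values`.
#' @examples
#' dichotomize(c(0.5, 1, 2.3), 1) # 0 1 1
#' @export
dichotomize <- function(values, threshold, direction = c(">=", ">")) {
  direction <- match.arg(direction)
  stopifnot(is.finite(threshold))
  if (length(values) == 0) return(integer(0))
  if (!all(is.finite(values))) {
    rlang::abort("`values` must be finite", class = "crossmed_coding_error")
  }
  if (direction == ">=") as.integer(values >= threshold) else
    as.integer(values > threshold)
}

#' Read subject-level binary mediation data from a CSV file
#'
#' The header must name columns X, M1, M2, Y (case-insensitive); every other
#' column is treated as a covariate unless listed in `exclude`.
#'
#' @param path Path to a CSV file.
#' @param exclude Character vector of column names to drop.
#' @returns A tibble with columns `x`, `m1`, `m2`, `y`, then covariates.
#' @export
read_mediation_csv <- function(path, exclude = NULL) {
  raw <- utils::read.csv(path, check.names = FALSE)
  out <- tibble::as_tibble(.standardize_columns(raw))
  if (!is.null(exclude)) out <- out[setdiff(names(out), exclude)]
  for (v in c("x", "m1", "m2", "y")) .check_binary(out[[v]], v)
  out
}

#' Write / read an observed distribution as JSON
#'
#' Probabilities are keyed `"p_y{y}m1{m1}m2{m2}.x{x}"` and serialized at full
#' double precision, so a round trip reproduces identical numbers.
#'
#' @param dist An `observed_distribution`.
#' @param path File path.
#' @returns `write_distribution_json` returns `path` invisibly;
#'   `read_distribution_json` returns an `observed_distribution`.
#' @export
write_distribution_json <- function(dist, path) {
  obj <- as.list(dist_vector(dist))
  n <- attr(dist, "n_by_arm")
  if (!is.null(n)) obj$n_by_arm <- as.list(stats::setNames(as.numeric(n), names(n)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_distribution_json
#' @export
read_distribution_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  n <- NULL
  if (!is.null(obj$n_by_arm)) {
    n <- unlist(obj$n_by_arm)
    obj$n_by_arm <- NULL
  }
  as_observed_distribution(unlist(obj), n_by_arm = n)
}
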