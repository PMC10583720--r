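# Synthetic-data generators: a COVID-19 vaccine-trial mechanism with
# continuous immunological mediators (memory B cells and circulating
# antibody) dichotomized for analysis, and binary structural-equation
# simulators driven by a response-profile distribution with exact ground
# truth for every estimand.

#' Parameters of the synthetic vaccine-trial mechanism
#'
#' Defaults encode the study conditions: vaccination X ~ Bernoulli(0.5); a
#' continuous B-cell response M1 ~ Normal(0.5 + 1.0 X, variance 1); antibody
#' M2 = exp(Z) with Z ~ Normal(6.5 + 0.5 X, sd 0.3); disease
#' Y ~ Bernoulli(0.1) under placebo and, under vaccination,
#' Y ~ Bernoulli(0.1 (exp(-0.87 M2 / 900) - 0.03 M1 - 0.2)) with the risk
#' clipped to \[0, 1\]. Mediators are dichotomized at M1 >= 1 and M2 >= 1000.
#'
#' `exponent_form` selects how the vaccine-arm risk expression is read:
#' `"exp_of_neg_ab_times_m2_over_denom"` (default) places the antibody term
#' inside the exponential, which keeps the risk a probability;
#' `"literal"` multiplies `exp(-0.87/900)` by M2, which produces values far
#' above one (antibody is on the order of e^7) and is retained only for
#' transparency about the alternative reading.
#'
#' @param p_treat Vaccination probability.
#' @param m1_mean_base,m1_effect,m1_var Mean intercept, vaccination shift and
#'   variance of the continuous B-cell response.
#' @param logm2_mean_base,logm2_effect,logm2_sd Mean intercept, vaccination
#'   shift and sd of log antibody.
#' @param risk_scale Multiplier of the vaccine-arm risk expression.
#' @param ab_coef,ab_denom Antibody coefficient and denominator.
#' @param bcell_coef B-cell coefficient.
#' @param risk_offset Constant subtracted inside the braces.
#' @param placebo_risk Event probability under placebo.
#' @param m1_cut,m2_cut Dichotomization thresholds.
#' @param exponent_form See Details.
#' @returns A `covid_params` list.
#' @export
covid_params <- function(p_treat = 0.5,
                         m1_mean_base = 0.5, m1_effect = 1.0, m1_var = 1,
                         logm2_mean_base = 6.5, logm2_effect = 0.5,
                         logm2_sd = 0.3,
                         risk_scale = 0.1, ab_coef = 0.87, ab_denom = 900,
                         bcell_coef = 0.03, risk_offset = 0.2,
                         placebo_risk = 0.1,
                         m1_cut = 1, m2_cut = 1000,
                         exponent_form = c("exp_of_neg_ab_times_m2_over_denom",
                                           "literal")) {
  exponent_form <- match.arg(exponent_form)
  stopifnot(
    p_treat > 0, p_treat < 1, m1_var > 0, logm2_sd > 0, risk_scale > 0,
    ab_denom > 0, placebo_risk >= 0, placebo_risk <= 1
  )
  structure(
    list(
      p_treat = p_treat, m1_mean_base = m1_mean_base, m1_effect = m1_effect,
      m1_var = m1_var, logm2_mean_base = logm2_mean_base,
      logm2_effect = logm2_effect, logm2_sd = logm2_sd,
      risk_scale = risk_scale, ab_coef = ab_coef, ab_denom = ab_denom,
      bcell_coef = bcell_coef, risk_offset = risk_offset,
      placebo_risk = placebo_risk, m1_cut = m1_cut, m2_cut = m2_cut,
      exponent_form = exponent_form
    ),
    class = "covid_params"
  )
}

# derive independent component substreams from one master seed so that
# toggling one component does not shift the draws of the others
.substreams <- function(seed, k) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, k))
}

#' Simulate the synthetic COVID-19 vaccine trial
#'
#' Generates continuous mediators and the binary disease outcome under the
#' mechanism described in [covid_params()], then dichotomizes the mediators.
#' Risks outside \[0, 1\] are clipped; if more than 10% of vaccine-arm risks
#' need clipping a `"crossmed_dgp_clipping_warning"` is raised (this happens
#' at the default parameters, where roughly one in six vaccinated subjects
#' has antibody high enough to drive the formula negative).
#'
#' @param n Number of subjects.
#' @param params A [covid_params()] list.
#' @param seed Optional master seed; split into independent substreams for X,
#'   M1, M2 and Y.
#' @returns A tibble with columns `x`, `m1_raw`, `m2_raw`, `risk`, `y`,
#'   `m1`, `m2`. The estimators consume the binary columns only: pass
#'   `dplyr::select(trial, x, m1, m2, y)` (otherwise the continuous columns
#'   are treated as covariates). Attributes: `clip_fraction`, `params`.
#' @examples
#' trial <- generate_covid_trial(1000, seed = 7)
#' summarize_trial(trial)
#' @export
generate_covid_trial <- function(n, params = covid_params(), seed = NULL) {
  stopifnot(n >= 1, inherits(params, "covid_params"))
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max - 1L, 1)
  ss <- .substreams(seed, 4L)
  x <- withr::with_seed(ss[1], stats::rbinom(n, 1L, params$p_treat))
  m1_raw <- withr::with_seed(
    ss[2],
    stats::rnorm(n, params$m1_mean_base + params$m1_effect * x,
                 sqrt(params$m1_var))
  )
  m2_raw <- withr::with_seed(
    ss[3],
    exp(stats::rnorm(n, params$logm2_mean_base + params$logm2_effect * x,
                     params$logm2_sd))
  )
  raw_risk <- if (params$exponent_form == "literal") {
    params$risk_scale * (exp(-params$ab_coef / params$ab_denom) * m2_raw -
                           params$bcell_coef * m1_raw - params$risk_offset)
  } else {
    params$risk_scale * (exp(-params$ab_coef * m2_raw / params$ab_denom) -
                           params$bcell_coef * m1_raw - params$risk_offset)
  }
  risk <- ifelse(x == 1, pmin(pmax(raw_risk, 0), 1), params$placebo_risk)
  clipped <- x == 1 & (raw_risk < 0 | raw_risk > 1)
  clip_fraction <- if (any(x == 1)) mean(clipped[x == 1]) else 0
  if (clip_fraction > 0.10) {
    rlang::warn(
      sprintf("%.1f%% of vaccine-arm risks were clipped to [0, 1]",
              100 * clip_fraction),
      class = "crossmed_dgp_clipping_warning"
    )
  }
  y <- withr::with_seed(ss[4], stats::rbinom(n, 1L, risk))
  out <- tibble::tibble(
    x = as.integer(x),
    m1_raw = m1_raw, m2_raw = m2_raw, risk = risk,
    y = as.integer(y),
    m1 = dichotomize(m1_raw, params$m1_cut),
    m2 = dichotomize(m2_raw, params$m2_cut)
  )
  attr(out, "clip_fraction") <- clip_fraction
  attr(out, "params") <- params
  out
}

#' Simulate binary data from a structural-equation model with known truth
#'
#' Draws a response profile per subject from `q` (the canonical reduction of
#' all confounding among M1, M2 and Y), a randomized exposure, and emits the
#' deterministic observation the profile generates. Because q is known, the
#' exact value of every estimand is available as ground truth.
#'
#' When `q` is not supplied it is drawn once from a symmetric Dirichlet over
#' profiles: jointly (residual confounding present) when `confounded = TRUE`,
#' or as an outer product of independent per-variable response-function
#' distributions (no residual confounding) when `confounded = FALSE`.
#'
#' @param n Number of subjects.
#' @param dag `"A"` or `"B"`.
#' @param q Optional `profile_distribution`; overrides `confounded` and
#'   `concentration`.
#' @param confounded Draw a jointly dependent q (`TRUE`, default) or an
#'   exactly factoring one (`FALSE`).
#' @param concentration Dirichlet concentration for the q draw.
#' @param p_treat Randomization probability of X = 1.
#' @param seed Optional master seed (substreams: q draw, profile draws,
#'   exposure draws).
#' @returns A list with `data` (tibble `x`, `m1`, `m2`, `y`), `q`, `truth`
#'   (tibble of exact effects for every estimand under `dag` at canonical
#'   levels), and `dag`.
#' @examples
#' sim <- generate_npsem(n = 1000, dag = "B", confounded = FALSE, seed = 11)
#' sim$truth
#' @export
generate_npsem <- function(n, dag = "B", q = NULL, confounded = TRUE,
                           concentration = 1, p_treat = 0.5, seed = NULL) {
  dag <- .check_dag(dag)
  stopifnot(n >= 1, p_treat > 0, p_treat < 1)
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max - 1L, 1)
  ss <- .substreams(seed, 3L)
  space <- response_profiles(dag)
  if (is.null(q)) {
    q <- withr::with_seed(ss[1], {
      if (confounded) {
        g <- stats::rgamma(space$n_profiles, shape = concentration)
        profile_distribution(g / sum(g), dag)
      } else {
        product_profile_distribution(
          .rdirichlet1(space$n_m1, concentration),
          .rdirichlet1(space$n_m2, concentration),
          .rdirichlet1(space$n_y, concentration),
          dag
        )
      }
    })
  } else {
    q <- profile_distribution(as.numeric(q), dag)
  }
  r <- withr::with_seed(ss[2], sample.int(space$n_profiles, n, replace = TRUE,
                                          prob = as.numeric(q)))
  x <- withr::with_seed(ss[3], stats::rbinom(n, 1L, p_treat))
  cell <- ifelse(x == 1L, space$cell1[r], space$cell0[r]) - 1L
  data <- tibble::tibble(
    x = as.integer(x),
    y = cell %/% 4L,
    m1 = (cell %/% 2L) %% 2L,
    m2 = cell %% 2L
  )
  truth <- dplyr::bind_rows(lapply(estimand_names(dag), function(nm) {
    sp <- effect_spec(nm, levels = .canonical_levels(nm), dag = dag)
    tibble::tibble(estimand = nm, label = sp$label,
                   truth = true_effects_from_q(q, sp))
  }))
  list(data = data, q = q, truth = truth, dag = dag)
}

.rdirichlet1 <- function(k, concentration) {
  g <- stats::rgamma(k, shape = concentration)
  if (sum(g) == 0) g[sample.int(k, 1L)] <- 1
  g / sum(g)
}

#' Tabulate a binary trial
#'
#' Event and record counts per arm plus the 16-cell contingency table.
#'
#' @param data Data frame with columns `x`, `m1`, `m2`, `y` (any case).
#' @returns A list with `arms` (tibble: `x`, `n`, `events`) and `cells`
#'   (tibble: `x`, `y`, `m1`, `m2`, `count`).
#' @export
summarize_trial <- function(data) {
  data <- .standardize_columns(data)
  arms <- data |>
    dplyr::group_by(x) |>
    dplyr::summarise(n = dplyr::n(), events = sum(y), .groups = "drop")
  cells <- .cell_grid()
  cells$count <- tabulate(.cell_index(data$y, data$m1, data$m2, data$x),
                          nbins = 16L)
  list(arms = arms, cells = cells)
}
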