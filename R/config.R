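#' European Standard Population (2013) weights
#'
#' The 2013 revision of the European Standard Population: 19 five-year
#' age bands (0-4 merges the ESP's <1 and 1-4 rows) summing to 100,000
#' persons, with identical weights applied to both sexes. Used as the
#' reference population for direct age-sex standardisation.
#'
#' @param adult_only If `TRUE` (default) return only the bands used for
#'   an adults-only (18+) analysis, `15-19` through `90+`. Ages 18-19
#'   are assigned to the 15-19 band, which keeps its full ESP weight.
#' @return A tibble with columns `age_band` and `weight`.
#' @export
#' @examples
#' esp_weights()
esp_weights <- function(adult_only = TRUE) {
  w <- tibble::tibble(
    age_band = c(
      "0-4", "5-9", "10-14", "15-19", "20-24", "25-29", "30-34",
      "35-39", "40-44", "45-49", "50-54", "55-59", "60-64", "65-69",
      "70-74", "75-79", "80-84", "85-89", "90+"
    ),
    weight = c(
      5000, 5500, 5500, 5500, 6000, 6000, 6500, 7000, 7000, 7000,
      7000, 6500, 6000, 5500, 5000, 4000, 2500, 1500, 1000
    )
  )
  if (adult_only) w <- w[match(adult_age_bands(), w$age_band), ]
  w
}

#' Default adult age bands
#'
#' Five-year bands `15-19` through `90+`, aligned with the ESP 2013
#' banding; an adults-only (18+) analysis places 18-19 year olds in the
#' 15-19 band.
#'
#' @return Character vector of band labels.
#' @export
adult_age_bands <- function() {
  c(
    "15-19", "20-24", "25-29", "30-34", "35-39", "40-44", "45-49",
    "50-54", "55-59", "60-64", "65-69", "70-74", "75-79", "80-84",
    "85-89", "90+"
  )
}

# Default age-sex rate multipliers: a unimodal incidence profile over
# adult ages peaking in the early 60s (elective back-pain hospital
# activity concentrates in late middle age), identical shape for both
# sexes with a mild female excess. Plausibility choices: the source data
# do not pin stratum-level rates.
default_age_sex_multipliers <- function(age_bands = adult_age_bands()) {
  shape <- c(
    0.05, 0.08, 0.12, 0.18, 0.26, 0.36, 0.48, 0.64,
    0.84, 1.00, 0.98, 0.84, 0.64, 0.45, 0.30, 0.20
  )
  if (length(age_bands) != length(shape)) {
    mids <- band_bounds(age_bands)$mid
    ref <- band_bounds(adult_age_bands())$mid
    shape <- stats::approx(ref, shape, xout = mids, rule = 2)$y
  }
  tidyr::expand_grid(
    age_band = age_bands,
    sex = c("F", "M")
  ) |>
    dplyr::mutate(
      multiplier = rep(shape, each = 2) * ifelse(.data$sex == "F", 1.05, 0.95)
    )
}

# Default three-intervention reinvestment portfolio: a digital
# self-management service, community back-pain classes, and case
# management for complex back pain.
default_portfolio_spec <- function() {
  tibble::tibble(
    name = c("digital_support", "back_pain_classes", "case_management"),
    n_treated = c(10000, 3000, 200),
    fixed_cost = c(0, 0, 0),
    variable_cost_per_person = c(2, 50, 500),
    qaly_per_person = c(0.07, 0.67, 1.90),
    evidence_category = c("benefit", "benefit", "benefit")
  )
}

# Representative IMD score by decile (1 = most deprived). Used to turn a
# practice's register decile mixture into a practice-level deprivation
# score; values approximate England's mean IMD score per decile.
imd_decile_scores <- function() {
  c(45.5, 33.4, 26.5, 21.3, 17.0, 13.4, 10.3, 7.7, 5.6, 3.6)
}

#' Simulation configuration
#'
#' Bundles and validates every parameter of the synthetic hospital
#' episode generator. Defaults emulate the study setting: 40 general
#' practices observed over four fiscal years, adults 18+, a log-normal
#' between-practice rate effect, a log-linear deprivation rate gradient,
#' and a downward shift in procedure age with deprivation.
#'
#' @param seed Integer seed; all randomness in the generators flows from
#'   it through named substreams.
#' @param n_practices Number of general practices.
#' @param years Character vector of fiscal-year labels.
#' @param age_bands Ordered, non-overlapping adult age bands covering
#'   ages 18 and over.
#' @param base_rate Events per person-year in a reference stratum
#'   (multiplier 1, least-deprived decile, average practice).
#' @param age_sex_multipliers Tibble `(age_band, sex, multiplier)` giving
#'   the rate multiplier per stratum.
#' @param practice_sigma Standard deviation of the log practice effect.
#' @param decile_rate_ratio Rate ratio of IMD decile 1 (most deprived)
#'   versus decile 10 (least deprived); the multiplier is log-linear in
#'   decile.
#' @param age_shift_years Mean reduction in procedure age per one-decile
#'   increase in deprivation (years); decile 1 procedures occur
#'   `9 * age_shift_years` younger than decile 10.
#' @param register_size_range Length-2 integer vector, min/max registered
#'   persons per practice.
#' @param procedure_fraction Probability that an episode is a procedure
#'   (vs. an attendance).
#' @param portfolio_spec Tibble describing the intervention portfolio
#'   (columns `name`, `n_treated`, `fixed_cost`,
#'   `variable_cost_per_person`, `qaly_per_person`,
#'   `evidence_category`).
#' @param repeat_episode_rate Probability that an episode belongs to a
#'   patient who already has one (default 0: patients are
#'   single-episode).
#'
#' @return A validated object of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, n_practices = 4,
#'                   register_size_range = c(500, 500))
#' cfg$n_practices
sim_config <- function(seed = 1L,
                       n_practices = 40L,
                       years = c("2016/17", "2017/18", "2018/19", "2019/20"),
                       age_bands = adult_age_bands(),
                       base_rate = 0.01,
                       age_sex_multipliers = default_age_sex_multipliers(age_bands),
                       practice_sigma = 0.45,
                       decile_rate_ratio = 2.0,
                       age_shift_years = 2.0,
                       register_size_range = c(4000L, 9000L),
                       procedure_fraction = 0.35,
                       portfolio_spec = default_portfolio_spec(),
                       repeat_episode_rate = 0) {
  cfg <- structure(
    list(
      seed = as.integer(seed),
      n_practices = as.integer(n_practices),
      years = as.character(years),
      age_bands = as.character(age_bands),
      base_rate = base_rate,
      age_sex_multipliers = age_sex_multipliers,
      practice_sigma = practice_sigma,
      decile_rate_ratio = decile_rate_ratio,
      age_shift_years = age_shift_years,
      register_size_range = as.integer(register_size_range),
      procedure_fraction = procedure_fraction,
      portfolio_spec = portfolio_spec,
      repeat_episode_rate = repeat_episode_rate
    ),
    class = "sim_config"
  )
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  if (is.na(cfg$seed)) abort_config("seed", "must be an integer")
  if (cfg$n_practices < 1) abort_config("n_practices", "must be >= 1")
  if (length(cfg$years) < 1) abort_config("years", "must be non-empty")
  if (anyDuplicated(cfg$years)) abort_config("years", "must be unique labels")
  if (!is.numeric(cfg$base_rate) || cfg$base_rate <= 0) {
    abort_config("base_rate", "must be > 0")
  }
  if (cfg$practice_sigma < 0) abort_config("practice_sigma", "must be >= 0")
  if (cfg$decile_rate_ratio < 1) abort_config("decile_rate_ratio", "must be >= 1")
  if (cfg$procedure_fraction < 0 || cfg$procedure_fraction > 1) {
    abort_config("procedure_fraction", "must be in [0, 1]")
  }
  if (cfg$repeat_episode_rate < 0 || cfg$repeat_episode_rate > 1) {
    abort_config("repeat_episode_rate", "must be in [0, 1]")
  }
  if (length(cfg$register_size_range) != 2 ||
      any(cfg$register_size_range < 1) ||
      cfg$register_size_range[1] > cfg$register_size_range[2]) {
    abort_config("register_size_range", "must be an increasing pair of positive sizes")
  }
  bb <- band_bounds(cfg$age_bands)
  if (is.unsorted(bb$lo, strictly = TRUE)) {
    abort_config("age_bands", "must be ordered by increasing lower bound")
  }
  if (any(bb$hi[-nrow(bb)] >= bb$lo[-1])) {
    abort_config("age_bands", "must be non-overlapping")
  }
  if (bb$lo[1] > 18) {
    abort_config("age_bands", "must cover ages 18 and over")
  }
  ms <- cfg$age_sex_multipliers
  need <- c("age_band", "sex", "multiplier")
  if (!all(need %in% names(ms))) {
    abort_config("age_sex_multipliers",
                 "must have columns age_band, sex, multiplier")
  }
  if (!all(cfg$age_bands %in% ms$age_band)) {
    abort_config("age_sex_multipliers", "must cover every configured age band")
  }
  if (any(ms$multiplier < 0)) {
    abort_config("age_sex_multipliers", "must be non-negative")
  }
  ps <- cfg$portfolio_spec
  if (!is.null(ps) && nrow(ps) > 0) {
    pneed <- c("name", "n_treated", "fixed_cost", "variable_cost_per_person",
               "qaly_per_person")
    if (!all(pneed %in% names(ps))) {
      abort_config("portfolio_spec",
                   paste("must have columns", paste(pneed, collapse = ", ")))
    }
    if (any(ps$n_treated < 0)) abort_config("portfolio_spec", "has negative n_treated")
    if (any(ps$fixed_cost < 0) || any(ps$variable_cost_per_person < 0)) {
      abort_config("portfolio_spec", "has negative costs")
    }
  }
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  seed: %d | practices: %d | years: %s\n",
              x$seed, x$n_practices, paste(x$years, collapse = ", ")))
  cat(sprintf("  base_rate: %g /person-year | practice_sigma: %g | decile_rate_ratio: %g\n",
              x$base_rate, x$practice_sigma, x$decile_rate_ratio))
  cat(sprintf("  age_shift_years: %g | procedure_fraction: %g | register size: %d-%d\n",
              x$age_shift_years, x$procedure_fraction,
              x$register_size_range[1], x$register_size_range[2]))
  cat(sprintf("  age bands: %s ... %s (%d) | portfolio: %d interventions\n",
              x$age_bands[1], x$age_bands[length(x$age_bands)],
              length(x$age_bands),
              if (is.null(x$portfolio_spec)) 0L else nrow(x$portfolio_spec)))
  invisible(x)
}
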