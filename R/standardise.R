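#' Crude rate per 10,000
#'
#' @param n_events Event count.
#' @param denominator Person-years at risk; must be positive.
#' @return Events per 10,000 person-years.
#' @export
#' @examples
#' crude_rate(7, 3500)  # 20 per 10,000
crude_rate <- function(n_events, denominator) {
  if (any(denominator <= 0)) abort_input("denominator must be > 0")
  10000 * n_events / denominator
}

#' 95% confidence interval for a rate per 10,000
#'
#' Crude rates use the Wilson score interval on the event proportion,
#' rescaled to per-10,000. Standardised rates use the Dobson method:
#' exact gamma limits for the total event count, transferred to the
#' standardised scale through the ratio of the standardised-rate
#' variance to the count variance. The lower limit is 0 when there are
#' no events.
#'
#' @param n_events Event count (total events for a standardised rate).
#' @param denominator Person-years (total for a standardised rate).
#' @param standardised If `TRUE`, compute the Dobson-style interval;
#'   requires `stratum_detail`.
#' @param stratum_detail For standardised rates, a list with numeric
#'   vectors `weights`, `events`, `denoms` over the contributing strata.
#' @param conf_level Confidence level (default 0.95).
#' @return Named numeric vector `c(ci_low, ci_high)` per 10,000.
#' @export
#' @examples
#' rate_ci(50, 10000)
rate_ci <- function(n_events, denominator, standardised = FALSE,
                    stratum_detail = NULL, conf_level = 0.95) {
  if (denominator <= 0) abort_input("denominator must be > 0")
  if (!standardised) {
    if (n_events == 0) {
      ci <- stats::prop.test(0, round(denominator), correct = FALSE,
                             conf.level = conf_level)$conf.int
      return(c(ci_low = 0, ci_high = 10000 * ci[2]))
    }
    ci <- stats::prop.test(round(n_events), round(denominator),
                           correct = FALSE, conf.level = conf_level)$conf.int
    return(c(ci_low = 10000 * ci[1], ci_high = 10000 * ci[2]))
  }
  if (is.null(stratum_detail)) {
    abort_input("stratum_detail is required for a standardised-rate interval")
  }
  dobson_ci(stratum_detail$weights, stratum_detail$events,
            stratum_detail$denoms, conf_level = conf_level)
}

# Dobson interval on the directly standardised rate (per 10,000).
dobson_ci <- function(weights, events, denoms, conf_level = 0.95) {
  alpha <- 1 - conf_level
  wsum <- sum(weights)
  dsr <- 10000 * sum(weights * events / denoms) / wsum
  x <- sum(events)
  if (x == 0) {
    # No events anywhere: lower limit 0; upper from the exact Poisson
    # upper bound on the total count spread over the total person-years.
    upper <- 10000 * stats::qgamma(1 - alpha / 2, 1) / sum(denoms)
    return(c(ci_low = 0, ci_high = upper))
  }
  var_dsr <- (10000^2) * sum(weights^2 * events / denoms^2) / wsum^2
  x_l <- stats::qgamma(alpha / 2, x)
  x_u <- stats::qgamma(1 - alpha / 2, x + 1)
  scale <- sqrt(var_dsr / x)
  c(ci_low = max(0, dsr + scale * (x_l - x)),
    ci_high = dsr + scale * (x_u - x))
}

#' Directly age-sex standardised rate per 10,000 (ESP)
#'
#' Weights stratum-specific rates by the standard-population weights,
#' applied identically to both sexes:
#' `rate = 10000 * sum(w_s * e_s / d_s) / sum(w_s)` over contributing
#' strata. Weights are normalised internally, so rescaling all weights
#' by a constant leaves the rate unchanged.
#'
#' @param stratum_events Tibble `(age_band, sex, events)`.
#' @param stratum_denoms Tibble `(age_band, sex, person_years)`;
#'   must cover every stratum with events.
#' @param std Standard population tibble `(age_band, weight)`; defaults
#'   to the adult ESP 2013 weights.
#' @param unit_id Optional identifier copied into the result.
#' @return One-row tibble: `unit_id`, `rate`, `ci_low`, `ci_high`,
#'   `n_events`, `denominator`, `ci_method`.
#' @export
#' @examples
#' ev <- tibble::tibble(age_band = c("40-44", "60-64"), sex = "F",
#'                      events = c(5, 10))
#' py <- tibble::tibble(age_band = c("40-44", "60-64"), sex = "F",
#'                      person_years = c(5000, 5000))
#' direct_standardised_rate(ev, py)
direct_standardised_rate <- function(stratum_events, stratum_denoms,
                                     std = esp_weights(), unit_id = NA_character_) {
  d <- dplyr::full_join(stratum_events, stratum_denoms,
                        by = c("age_band", "sex"))
  d$events[is.na(d$events)] <- 0
  d$person_years[is.na(d$person_years)] <- 0
  bad <- d$events > 0 & d$person_years <= 0
  if (any(bad)) {
    abort_input("stratum (%s, %s) has %d events but no person-years",
                d$age_band[bad][1], d$sex[bad][1], d$events[bad][1])
  }
  empty <- d$person_years <= 0
  if (any(empty)) {
    message(sprintf("skipping %d empty strata with no events and no person-years",
                    sum(empty)))
    d <- d[!empty, ]
  }
  if (nrow(d) == 0) abort_input("no strata with positive person-years")
  if (!all(d$age_band %in% std$age_band)) {
    missing <- setdiff(unique(d$age_band), std$age_band)
    abort_input("standard population has no weight for band(s): %s",
                paste(missing, collapse = ", "))
  }
  w <- std$weight[match(d$age_band, std$age_band)]
  rate <- 10000 * sum(w * d$events / d$person_years) / sum(w)
  ci <- dobson_ci(w, d$events, d$person_years)
  tibble::tibble(
    unit_id = unit_id,
    rate = rate,
    ci_low = unname(ci[1]),
    ci_high = unname(ci[2]),
    n_events = sum(d$events),
    denominator = sum(d$person_years),
    ci_method = "dobson"
  )
}

#' Pool episode counts and person-years over fiscal years
#'
#' Sums event counts over the selected years and accumulates
#' person-years as the register population times the number of pooled
#' years (the register is held constant per year).
#'
#' @param episodes Episode tibble (see [generate_episodes()]).
#' @param registers Register tibble (see [generate_registers()]).
#' @param years Years to pool; must appear in `episodes`' configured
#'   years (i.e. no unknown labels).
#' @param event_class `"all"`, `"procedure"` or `"attendance"`.
#' @param by Optional extra grouping column (`"practice_id"` or
#'   `"imd_decile"`).
#' @return Tibble of pooled strata: grouping columns, `age_band`, `sex`,
#'   `events`, `person_years`.
#' @export
pool_years <- function(episodes, registers, years,
                       event_class = "all", by = NULL) {
  if (length(years) == 0) abort_input("years must be non-empty")
  known <- unique(c(episodes$fiscal_year, attr(episodes, "years")))
  unknown <- setdiff(years, known)
  if (length(unknown) > 0 && nrow(episodes) > 0) {
    abort_input("unknown fiscal year label(s): %s",
                paste(unknown, collapse = ", "))
  }
  ep <- episodes[episodes$fiscal_year %in% years, ]
  if (!identical(event_class, "all")) {
    ep <- ep[ep$event_class == event_class, ]
  }
  bands <- unique(registers$age_band)
  ep$age_band <- age_to_band(ep$age, band_bounds(bands)$age_band)
  group_cols <- c(by, "age_band", "sex")
  ev <- ep |>
    dplyr::count(dplyr::across(dplyr::all_of(group_cols)), name = "events")
  py <- registers |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_cols))) |>
    dplyr::summarise(person_years = sum(.data$count) * length(years),
                     .groups = "drop")
  out <- dplyr::full_join(py, ev, by = group_cols)
  out$events[is.na(out$events)] <- 0L
  out$person_years[is.na(out$person_years)] <- 0
  out
}
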