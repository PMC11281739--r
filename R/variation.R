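#' Per-practice age-sex standardised rates
#'
#' One directly standardised rate per practice, sorted in descending
#' rate order (the bar-chart order used to display practice variation).
#' Practices with registered population but no events appear with rate
#' 0.
#'
#' @param episodes Episode tibble.
#' @param registers Register tibble; every episode's practice must
#'   appear here.
#' @param std Standard population tibble (default adult ESP 2013).
#' @param years Fiscal years to pool (default: all years in
#'   `episodes`).
#' @param event_class `"all"`, `"procedure"` or `"attendance"`.
#' @return Tibble of standardised rates per practice, with the
#'   practice-level `deprivation_score` carried through.
#' @export
practice_rates <- function(episodes, registers, std = esp_weights(),
                           years = NULL, event_class = "all") {
  years <- years %||% sort(unique(episodes$fiscal_year))
  unknown <- setdiff(unique(episodes$practice_id),
                     unique(registers$practice_id))
  if (length(unknown) > 0) {
    abort_input("episodes reference practice(s) absent from registers: %s",
                paste(unknown, collapse = ", "))
  }
  strata <- pool_years(episodes, registers, years,
                       event_class = event_class, by = "practice_id")
  scores <- registers |>
    dplyr::distinct(.data$practice_id, .data$deprivation_score)
  out <- strata |>
    dplyr::group_by(.data$practice_id) |>
    dplyr::group_modify(function(d, key) {
      direct_standardised_rate(
        d[, c("age_band", "sex", "events")],
        d[, c("age_band", "sex", "person_years")],
        std = std
      )[-1]
    }) |>
    dplyr::ungroup() |>
    dplyr::rename(unit_id = "practice_id") |>
    dplyr::left_join(scores, by = c(unit_id = "practice_id")) |>
    dplyr::arrange(dplyr::desc(.data$rate))
  out$years <- paste(years, collapse = ";")
  out
}

#' Fold-variation across practices
#'
#' Ratio of the highest to the lowest positive standardised rate.
#' Zero-rate units are excluded from the denominator and listed
#' explicitly rather than silently imputed. With a single unit, or with
#' no events at all, the fold is reported as 1 / NA with a flag.
#'
#' @param rates Tibble of standardised rates (e.g. from
#'   [practice_rates()]).
#' @param correlation_method Method for the deprivation correlation when
#'   rates carry a `deprivation_score` column (`"spearman"` default).
#' @return A `variation_summary` list: `n_units`, `min_rate`,
#'   `max_rate`, `fold_variation`, `excluded_units`,
#'   `deprivation_correlation`, and flags.
#' @export
#' @examples
#' r <- tibble::tibble(unit_id = c("A", "B", "C"), rate = c(5, 0, 40))
#' fold_variation(r)$fold_variation  # 8, with B excluded
fold_variation <- function(rates, correlation_method = "spearman") {
  pos <- rates[rates$rate > 0, ]
  excluded <- rates$unit_id[rates$rate <= 0]
  all_zero <- nrow(pos) == 0
  single <- nrow(rates) < 2
  fold <- if (all_zero) {
    NA_real_
  } else if (nrow(pos) < 2) {
    1
  } else {
    max(pos$rate) / min(pos$rate)
  }
  corr <- if ("deprivation_score" %in% names(rates) && nrow(rates) >= 3) {
    deprivation_correlation(rates, method = correlation_method)
  } else {
    NULL
  }
  structure(
    list(
      n_units = nrow(rates),
      min_rate = if (all_zero) NA_real_ else min(pos$rate),
      max_rate = if (nrow(rates)) max(rates$rate) else NA_real_,
      fold_variation = fold,
      excluded_units = as.character(excluded),
      deprivation_correlation = corr,
      no_events = all_zero,
      single_unit = single
    ),
    class = "variation_summary"
  )
}

#' @export
print.variation_summary <- function(x, ...) {
  cat("<variation_summary>\n")
  cat(sprintf("  units: %d | rate range: %.1f-%.1f per 10,000 | fold: %s\n",
              x$n_units, x$min_rate, x$max_rate,
              ifelse(is.na(x$fold_variation), "undefined (no events)",
                     sprintf("%.2f", x$fold_variation))))
  if (length(x$excluded_units)) {
    cat(sprintf("  zero-rate units excluded from fold denominator: %s\n",
                paste(x$excluded_units, collapse = ", ")))
  }
  if (!is.null(x$deprivation_correlation)) {
    cat(sprintf("  deprivation correlation (%s): %s\n",
                x$deprivation_correlation$method,
                ifelse(is.na(x$deprivation_correlation$coefficient), "undefined",
                       sprintf("%.3f", x$deprivation_correlation$coefficient))))
  }
  invisible(x)
}

#' Correlation of practice rates with practice deprivation
#'
#' Spearman rank correlation by default: the analysis asks only whether
#' deprivation orders the practice rates, without asserting linearity,
#' and no p-value is attached.
#'
#' @param rates Tibble with `rate` and `deprivation_score` columns (or
#'   pass `registers` to supply the scores).
#' @param registers Optional register tibble supplying
#'   `deprivation_score` per practice when `rates` lacks it.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return List with `coefficient`, `method`, `n`, and a `constant_score`
#'   flag (coefficient is `NA` when the scores are constant).
#' @export
deprivation_correlation <- function(rates, registers = NULL,
                                    method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (!"deprivation_score" %in% names(rates)) {
    if (is.null(registers)) {
      abort_input("rates lack deprivation_score and no registers supplied")
    }
    scores <- registers |>
      dplyr::distinct(.data$practice_id, .data$deprivation_score)
    rates <- dplyr::left_join(rates, scores, by = c(unit_id = "practice_id"))
  }
  if (any(is.na(rates$deprivation_score))) {
    abort_input("missing deprivation_score for unit(s): %s",
                paste(rates$unit_id[is.na(rates$deprivation_score)],
                      collapse = ", "))
  }
  constant <- stats::sd(rates$deprivation_score) == 0
  coef <- if (constant || nrow(rates) < 3) {
    NA_real_
  } else {
    stats::cor(rates$rate, rates$deprivation_score, method = method)
  }
  list(coefficient = coef, method = method, n = nrow(rates),
       constant_score = constant)
}
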