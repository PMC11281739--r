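#' Standardised procedure rates by deprivation decile
#'
#' One directly age-sex standardised rate per IMD decile of patient
#' residence (decile 1 = most deprived).
#'
#' @param episodes Episode tibble.
#' @param decile_denominators Person-years per decile x band x sex:
#'   tibble with columns `imd_decile`, `age_band`, `sex`, `count`
#'   (persons per year). Usually the register table, which carries these
#'   columns.
#' @param std Standard population tibble.
#' @param years Fiscal years to pool (default all in `episodes`).
#' @param event_class Defaults to `"procedure"`.
#' @return Tibble of standardised rates keyed by decile (`unit_id` is
#'   the decile, ordered 1..10).
#' @export
decile_rates <- function(episodes, decile_denominators, std = esp_weights(),
                         years = NULL, event_class = "procedure") {
  years <- years %||% sort(unique(episodes$fiscal_year))
  bad <- unique(c(
    episodes$imd_decile[!episodes$imd_decile %in% 1:10],
    decile_denominators$imd_decile[!decile_denominators$imd_decile %in% 1:10]
  ))
  if (length(bad) > 0) {
    abort_input("imd_decile outside 1..10: %s", paste(bad, collapse = ", "))
  }
  strata <- pool_years(episodes, decile_denominators, years,
                       event_class = event_class, by = "imd_decile")
  out <- strata |>
    dplyr::group_by(.data$imd_decile) |>
    dplyr::group_modify(function(d, key) {
      direct_standardised_rate(
        d[, c("age_band", "sex", "events")],
        d[, c("age_band", "sex", "person_years")],
        std = std
      )[-1]
    }) |>
    dplyr::ungroup() |>
    dplyr::rename(unit_id = "imd_decile") |>
    dplyr::arrange(.data$unit_id)
  out$years <- paste(years, collapse = ";")
  out
}

#' First procedure episode per patient
#'
#' The earliest procedure episode for each patient within the loaded
#' analysis window (no look-back beyond the data supplied). Ties within
#' the earliest year are broken deterministically by record order; the
#' number of patients with ties is attached as attribute `n_ties`.
#'
#' @param episodes Episode tibble.
#' @return Tibble with one procedure episode per patient.
#' @export
first_procedure_per_patient <- function(episodes) {
  proc <- episodes[episodes$event_class == "procedure", ]
  if (nrow(proc) == 0) {
    out <- proc
    attr(out, "n_ties") <- 0L
    return(out)
  }
  proc$.row <- seq_len(nrow(proc))
  yr_rank <- match(proc$fiscal_year, sort(unique(proc$fiscal_year)))
  proc$.yr <- yr_rank
  first <- proc |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      .keep_row = .data$.row[order(.data$.yr, .data$.row)][1],
      .ties = sum(.data$.yr == min(.data$.yr)) > 1,
      .groups = "drop"
    )
  out <- proc[first$.keep_row, !(names(proc) %in% c(".row", ".yr"))]
  attr(out, "n_ties") <- sum(first$.ties)
  out
}

#' Default decade bands for the age-deprivation matrix
#' @return Character vector `18-29`, `30-39`, ..., `80+`.
#' @export
equity_age_bands <- function() {
  c("18-29", "30-39", "40-49", "50-59", "60-69", "70-79", "80+")
}

#' Age x deprivation percentage matrix of first procedures
#'
#' Column-normalised percentages: each deprivation group's first
#' procedures distributed over age bands (decades by default), plus the
#' modal band per group. Empty groups are flagged, not errored.
#'
#' @param first_episodes One procedure episode per patient (see
#'   [first_procedure_per_patient()]).
#' @param age_bands Age band labels (default decade bands).
#' @param grouping `"decile"` (default) or `"quintile"` grouping of IMD
#'   deciles; quintile 1 pools deciles 1-2 (most deprived).
#' @return An `age_deprivation_matrix` list: `cells` (matrix of
#'   percentages, rows = age bands, columns = deprivation groups),
#'   `modal_band` (named character), `n_per_group`, `empty_groups`.
#' @export
age_deprivation_matrix <- function(first_episodes,
                                   age_bands = equity_age_bands(),
                                   grouping = c("decile", "quintile")) {
  grouping <- match.arg(grouping)
  groups <- if (grouping == "decile") {
    as.character(1:10)
  } else {
    c("1-2", "3-4", "5-6", "7-8", "9-10")
  }
  ep <- first_episodes
  g <- if (grouping == "decile") {
    as.character(ep$imd_decile)
  } else {
    groups[ceiling(ep$imd_decile / 2)]
  }
  band <- age_to_band(ep$age, age_bands)
  cells <- matrix(0, nrow = length(age_bands), ncol = length(groups),
                  dimnames = list(age_bands, groups))
  if (nrow(ep) > 0) {
    tab <- table(factor(band, levels = age_bands),
                 factor(g, levels = groups))
    cells[] <- unclass(tab)
  }
  n_per_group <- colSums(cells)
  empty <- names(n_per_group)[n_per_group == 0]
  pct <- cells
  for (j in seq_along(groups)) {
    pct[, j] <- if (n_per_group[j] > 0) 100 * cells[, j] / n_per_group[j] else NA_real_
  }
  modal <- vapply(seq_along(groups), function(j) {
    if (n_per_group[j] == 0) NA_character_ else age_bands[which.max(cells[, j])]
  }, character(1))
  names(modal) <- groups
  structure(
    list(cells = pct, counts = cells, modal_band = modal,
         n_per_group = n_per_group, empty_groups = empty,
         grouping = grouping),
    class = "age_deprivation_matrix"
  )
}

#' @export
print.age_deprivation_matrix <- function(x, ...) {
  cat(sprintf("<age_deprivation_matrix> (%s grouping; %d first procedures)\n",
              x$grouping, sum(x$n_per_group)))
  print(round(x$cells, 1))
  cat("modal band per group:\n")
  print(x$modal_band)
  if (length(x$empty_groups)) {
    cat("empty groups:", paste(x$empty_groups, collapse = ", "), "\n")
  }
  invisible(x)
}

# Gap, in band steps, between the modal age band of the most-deprived
# and least-deprived non-empty groups (positive when the most deprived
# are younger).
modal_band_gap <- function(adm) {
  bands <- rownames(adm$cells)
  ok <- !is.na(adm$modal_band)
  if (sum(ok) < 2) return(NA_real_)
  groups <- names(adm$modal_band)[ok]
  most <- adm$modal_band[ok][1]
  least <- adm$modal_band[ok][length(groups)]
  match(least, bands) - match(most, bands)
}
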