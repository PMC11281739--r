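# CSV/JSON/YAML readers and writers with column-contract validation.
# Unknown columns are preserved; missing required columns and malformed
# rows are errored with names and row numbers.

check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort_input("%s file is missing required column(s): %s",
                what, paste(missing, collapse = ", "))
  }
  df
}

#' Read and write episode records
#'
#' Episode CSVs carry one row per elective hospital contact with
#' columns `patient_id`, `age`, `sex`, `practice_id`, `imd_decile`,
#' `fiscal_year`, `event_class`, `intervention_id`. Reading validates
#' ages (18+), deciles (1..10) and event classes, reporting offending
#' row numbers.
#'
#' @param path File path.
#' @param episodes Episode tibble to write.
#' @return `read_episodes()` returns the validated tibble;
#'   `write_episodes()` returns `path` invisibly.
#' @export
read_episodes <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(df, c("patient_id", "age", "sex", "practice_id",
                      "imd_decile", "fiscal_year", "event_class"),
                "episodes")
  bad <- which(!df$imd_decile %in% 1:10)
  if (length(bad) > 0) {
    abort_input("episodes row %d: imd_decile %s outside 1..10",
                bad[1], df$imd_decile[bad[1]])
  }
  bad <- which(is.na(df$age) | df$age < 18)
  if (length(bad) > 0) {
    abort_input("episodes row %d: age %s below 18", bad[1], df$age[bad[1]])
  }
  bad <- which(!df$event_class %in% c("attendance", "procedure"))
  if (length(bad) > 0) {
    abort_input("episodes row %d: unknown event_class '%s'",
                bad[1], df$event_class[bad[1]])
  }
  if (!"intervention_id" %in% names(df)) df$intervention_id <- ""
  df$intervention_id[is.na(df$intervention_id)] <- ""
  df$age <- as.integer(df$age)
  df$imd_decile <- as.integer(df$imd_decile)
  df
}

#' @rdname read_episodes
#' @export
write_episodes <- function(episodes, path) {
  readr::write_csv(episodes, path, progress = FALSE)
  invisible(path)
}

#' Read and write practice registers
#'
#' Long-format register CSVs: `practice_id`, `age_band`, `sex`,
#' `imd_decile`, `count`, `deprivation_score`.
#'
#' @param path File path.
#' @param registers Register tibble to write.
#' @export
read_registers <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(df, c("practice_id", "age_band", "sex", "imd_decile",
                      "count", "deprivation_score"), "registers")
  bad <- which(is.na(df$count) | df$count < 0)
  if (length(bad) > 0) {
    abort_input("registers row %d: count must be non-negative", bad[1])
  }
  df$count <- as.integer(df$count)
  df$imd_decile <- as.integer(df$imd_decile)
  df
}

#' @rdname read_registers
#' @export
write_registers <- function(registers, path) {
  readr::write_csv(registers, path, progress = FALSE)
  invisible(path)
}

#' Read and write an intervention portfolio
#'
#' Portfolio CSVs use columns `id`, `name`, `n_treated`, `fixed_cost`,
#' `variable_cost_per_person`, `qaly_per_person`, `evidence_category`,
#' `provider`. Alternatively a single `total_cost` column may be
#' supplied with an optional `variable_share` (default 1, i.e. fully
#' variable); it is split into fixed and variable components on read.
#'
#' @param path File path.
#' @param portfolio Portfolio tibble to write.
#' @export
read_portfolio <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"id" %in% names(df) && "name" %in% names(df)) df$id <- df$name
  if ("total_cost" %in% names(df) &&
      !all(c("fixed_cost", "variable_cost_per_person") %in% names(df))) {
    share <- if ("variable_share" %in% names(df)) df$variable_share else 1
    share[is.na(share)] <- 1
    variable_total <- df$total_cost * share
    df$fixed_cost <- df$total_cost - variable_total
    df$variable_cost_per_person <- ifelse(df$n_treated > 0,
                                          variable_total / df$n_treated, 0)
  }
  check_columns(df, c("id", "n_treated", "fixed_cost",
                      "variable_cost_per_person", "qaly_per_person",
                      "evidence_category"), "portfolio")
  bad <- which(is.na(df$n_treated) | df$n_treated < 0)
  if (length(bad) > 0) {
    abort_input("portfolio row %d, column n_treated: must be non-negative",
                bad[1])
  }
  validate_portfolio(df)
}

#' @rdname read_portfolio
#' @export
write_portfolio <- function(portfolio, path) {
  readr::write_csv(validate_portfolio(portfolio), path, progress = FALSE)
  invisible(path)
}

#' Read and write a reallocation plan (JSON or YAML)
#'
#' The file holds `disinvestments` (list of `id`, `fraction_stopped`,
#' `releasable_cost_fraction`), `reinvestments` (portfolio rows),
#' `budget_mode` and, for `fixed_envelope` mode, `envelope`.
#'
#' @param path File path; format chosen by extension (`.json` vs
#'   `.yaml`/`.yml`).
#' @param plan A [reallocation_plan()] to write.
#' @export
read_plan <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  as_rows <- function(x) {
    if (is.data.frame(x)) tibble::as_tibble(x) else dplyr::bind_rows(x)
  }
  dis <- if (!is.null(raw$disinvestments)) {
    as_rows(raw$disinvestments)
  } else {
    NULL
  }
  re <- if (!is.null(raw$reinvestments)) {
    df <- as_rows(raw$reinvestments)
    if (!"id" %in% names(df) && "name" %in% names(df)) df$id <- df$name
    df
  } else {
    NULL
  }
  reallocation_plan(
    disinvestments = dis,
    reinvestments = re,
    budget_mode = raw$budget_mode %||% "released_only",
    envelope = raw$envelope
  )
}

#' @rdname read_plan
#' @export
write_plan <- function(plan, path) {
  obj <- list(
    disinvestments = plan$disinvestments,
    reinvestments = plan$reinvestments,
    budget_mode = plan$budget_mode,
    envelope = plan$envelope
  )
  obj <- obj[!vapply(obj, is.null, logical(1))]
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(lapply(obj, function(x) {
      if (is.data.frame(x)) lapply(seq_len(nrow(x)), function(i) as.list(x[i, ])) else x
    }), path)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", pretty = TRUE)
  }
  invisible(path)
}

#' Write a rates table
#'
#' @param rates Standardised-rate tibble (e.g. [practice_rates()]).
#' @param path File path.
#' @export
write_rates <- function(rates, path) {
  readr::write_csv(rates, path, progress = FALSE)
  invisible(path)
}
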