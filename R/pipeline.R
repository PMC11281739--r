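#' Read a pipeline/simulation configuration from YAML or JSON
#'
#' Top-level keys mirror the [sim_config()] arguments; unknown keys are
#' ignored with a message. `age_sex_multipliers` and `portfolio_spec`
#' may be given as lists of rows. An optional `plan` key names a
#' reallocation-plan file (resolved relative to the config file).
#'
#' @param path Config file path.
#' @return A list with elements `config` (a [sim_config()]) and `plan`
#'   (a [reallocation_plan()] or `NULL`).
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  args <- raw
  args$plan <- NULL
  known <- names(formals(sim_config))
  unknown <- setdiff(names(args), known)
  if (length(unknown) > 0) {
    message("ignoring unknown config key(s): ", paste(unknown, collapse = ", "))
    args <- args[intersect(names(args), known)]
  }
  for (tab in c("age_sex_multipliers", "portfolio_spec")) {
    if (!is.null(args[[tab]]) && !is.data.frame(args[[tab]])) {
      args[[tab]] <- dplyr::bind_rows(lapply(args[[tab]], tibble::as_tibble))
    }
  }
  plan <- NULL
  if (!is.null(raw$plan)) {
    plan_path <- raw$plan
    if (!file.exists(plan_path)) {
      plan_path <- file.path(dirname(path), raw$plan)
    }
    plan <- read_plan(plan_path)
  }
  list(config = do.call(sim_config, args), plan = plan)
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> standardise -> variation -> equity -> STAR in
#' order, writing every stage output plus a combined JSON report and a
#' run manifest with content checksums. All randomness flows from the
#' configured seed, so the same config yields byte-identical stage
#' outputs.
#'
#' @param config A [sim_config()] or a path to a YAML/JSON config file.
#' @param out_dir Output directory (created if absent).
#' @param plan Optional [reallocation_plan()]; overrides any plan named
#'   in a config file.
#' @return The run manifest (list), invisibly; also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config, out_dir, plan = NULL) {
  if (is.character(config)) {
    cfg <- read_pipeline_config(config)
    plan <- plan %||% cfg$plan
    config <- cfg$config
  }
  if (!inherits(config, "sim_config")) {
    abort_input("config must be a sim_config or a config file path")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  files <- character()
  emit <- function(obj, fname, writer) {
    p <- file.path(out_dir, fname)
    writer(obj, p)
    files[[fname]] <<- p
    p
  }

  message("stage simulate: generating registers, episodes, portfolio")
  registers <- stage("simulate", generate_registers(config))
  episodes <- stage("simulate", generate_episodes(config, registers))
  portfolio <- stage("simulate", generate_portfolio(config))
  emit(registers, "registers.csv", write_registers)
  emit(episodes, "episodes.csv", write_episodes)
  emit(portfolio, "portfolio.csv", write_portfolio)
  message(sprintf("  %d practices, %d episodes, %d interventions",
                  dplyr::n_distinct(registers$practice_id), nrow(episodes),
                  nrow(portfolio)))

  message("stage standardise/variation: per-practice standardised rates")
  prates <- stage("variation", practice_rates(episodes, registers,
                                              years = config$years))
  emit(prates, "practice_rates.csv", write_rates)
  vsum <- stage("variation", fold_variation(prates))
  proc_rates <- stage("variation", practice_rates(episodes, registers,
                                                  years = config$years,
                                                  event_class = "procedure"))
  emit(proc_rates, "practice_rates_procedures.csv", write_rates)
  vsum_proc <- stage("variation", fold_variation(proc_rates))
  if (length(vsum$excluded_units) > 0) {
    message(sprintf("  %d zero-rate practice(s) excluded from fold denominator",
                    length(vsum$excluded_units)))
  }

  message("stage equity: decile rates and age-deprivation matrix")
  drates <- stage("equity", decile_rates(episodes, registers,
                                         years = config$years))
  emit(drates, "decile_rates.csv", write_rates)
  firsts <- stage("equity", first_procedure_per_patient(episodes))
  adm <- stage("equity", age_deprivation_matrix(firsts, grouping = "quintile"))
  adm_out <- tibble::as_tibble(adm$cells, rownames = "age_band")
  emit(adm_out, "age_deprivation_matrix.csv",
       function(x, p) readr::write_csv(x, p, progress = FALSE))

  message("stage star: triangles, frontier, reallocation")
  frontier <- stage("star", build_frontier(value_triangle(portfolio)))
  emit(frontier, "frontier.csv",
       function(x, p) readr::write_csv(x, p, progress = FALSE))
  base_sum <- stage("star", portfolio_summary(portfolio))
  realloc <- NULL
  if (!is.null(plan)) {
    realloc <- stage("star", apply_reallocation(portfolio, plan))
    emit(realloc$portfolio, "portfolio_post_plan.csv", write_portfolio)
    post_frontier <- stage("star", build_frontier(value_triangle(realloc$portfolio)))
    emit(post_frontier, "frontier_post_plan.csv",
         function(x, p) readr::write_csv(x, p, progress = FALSE))
  }

  gradient <- if (all(c(1, 10) %in% drates$unit_id)) {
    drates$rate[drates$unit_id == 1] / drates$rate[drates$unit_id == 10]
  } else {
    NA_real_
  }
  report <- list(
    seed = config$seed,
    years = config$years,
    variation = list(
      all_services = list(fold = vsum$fold_variation, n_units = vsum$n_units,
                          excluded_units = vsum$excluded_units,
                          deprivation_correlation = vsum$deprivation_correlation),
      procedures = list(fold = vsum_proc$fold_variation,
                        excluded_units = vsum_proc$excluded_units)
    ),
    equity = list(
      decile1_vs_decile10_rate_ratio = gradient,
      modal_band_by_group = as.list(adm$modal_band),
      modal_band_gap = modal_band_gap(adm)
    ),
    portfolio = list(
      baseline = unclass(base_sum)
    )
  )
  if (!is.null(realloc)) {
    report$portfolio$post_plan <- unclass(realloc$summary)
    report$portfolio$released_budget <- realloc$released_budget
    report$portfolio$deltas <- realloc$deltas
  }
  report_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  files[["report.json"]] <- report_path

  manifest <- list(
    seed = config$seed,
    generated_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    ci_method = "wilson (crude) / dobson (standardised)",
    esp_version = "ESP 2013",
    n_episodes = nrow(episodes),
    n_practices = dplyr::n_distinct(registers$practice_id),
    outputs = lapply(names(files), function(f) {
      list(file = f,
           md5 = unname(tools::md5sum(files[[f]])),
           rows = if (grepl("\\.csv$", f)) {
             length(readr::read_lines(files[[f]], progress = FALSE)) - 1L
           } else {
             NA_integer_
           })
    })
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  message("pipeline complete: ", length(files) + 1L, " output files in ", out_dir)
  invisible(manifest)
}
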