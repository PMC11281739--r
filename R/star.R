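portfolio_columns <- c(
  "id", "name", "n_treated", "fixed_cost", "variable_cost_per_person",
  "qaly_per_person", "evidence_category", "provider"
)

evidence_categories <- c("benefit", "no_evidence", "no_benefit", "possible_harm")

#' Validate an intervention portfolio table
#'
#' Checks the column contract of a portfolio tibble: unique ids,
#' non-negative people and costs, recognised evidence categories.
#' Errors name the offending row and column.
#'
#' @param portfolio A portfolio tibble (see [generate_portfolio()] for
#'   the columns).
#' @return The validated portfolio, invisibly coerced to canonical
#'   column order.
#' @export
validate_portfolio <- function(portfolio) {
  need <- setdiff(portfolio_columns, c("provider", "name"))
  missing <- setdiff(need, names(portfolio))
  if (length(missing) > 0) {
    abort_input("portfolio is missing required column(s): %s",
                paste(missing, collapse = ", "))
  }
  if (!"name" %in% names(portfolio)) portfolio$name <- portfolio$id
  if (!"provider" %in% names(portfolio)) portfolio$provider <- NA_character_
  dup <- portfolio$id[duplicated(portfolio$id)]
  if (length(dup) > 0) {
    abort_input("duplicate intervention id(s): %s",
                paste(unique(dup), collapse = ", "))
  }
  for (col in c("n_treated", "fixed_cost", "variable_cost_per_person")) {
    bad <- which(is.na(portfolio[[col]]) | portfolio[[col]] < 0)
    if (length(bad) > 0) {
      abort_input("portfolio row %d ('%s'): column %s must be non-negative",
                  bad[1], portfolio$id[bad[1]], col)
    }
  }
  badcat <- which(!portfolio$evidence_category %in% evidence_categories)
  if (length(badcat) > 0) {
    abort_input("portfolio row %d ('%s'): unknown evidence_category '%s'",
                badcat[1], portfolio$id[badcat[1]],
                portfolio$evidence_category[badcat[1]])
  }
  portfolio[, portfolio_columns]
}

#' STAR value-for-money triangles
#'
#' For each intervention: total QALY gain (number treated x mean QALY
#' gain per person) on the vertical axis, total cost (fixed cost +
#' number treated x variable cost per person) on the horizontal axis,
#' and value for money as the slope of the hypotenuse (QALYs per pound).
#'
#' @param portfolio A portfolio tibble.
#' @return Tibble with `intervention_id`, `total_cost`, `total_qaly`,
#'   `slope`, and `evidence_category` carried through. The slope is
#'   `Inf` (flagged by message) for a costless intervention with
#'   non-zero QALYs, and `NA` when both are zero.
#' @export
#' @examples
#' value_triangle(generate_portfolio(sim_config(seed = 1)))
value_triangle <- function(portfolio) {
  portfolio <- validate_portfolio(portfolio)
  # costs and QALY gains are decimal quantities (pounds, QALYs to a few
  # decimal places); snap away binary floating drift so the triangle
  # identities hold exactly at those scales
  total_cost <- round(portfolio$fixed_cost +
    portfolio$n_treated * portfolio$variable_cost_per_person, 6)
  total_qaly <- round(portfolio$n_treated * portfolio$qaly_per_person, 6)
  slope <- ifelse(total_cost > 0, total_qaly / total_cost,
                  ifelse(total_qaly != 0, Inf, NA_real_))
  if (any(is.infinite(slope))) {
    message(sprintf("%d intervention(s) have zero cost but non-zero QALYs; slope flagged infinite",
                    sum(is.infinite(slope))))
  }
  tibble::tibble(
    intervention_id = portfolio$id,
    total_cost = total_cost,
    total_qaly = total_qaly,
    slope = slope,
    evidence_category = portfolio$evidence_category
  )
}

#' Cost per QALY, rounded to the nearest pound
#'
#' @param portfolio A portfolio tibble.
#' @return Numeric vector, one value per intervention; `NA` (reported as
#'   not applicable, never 0) where the total QALY gain is zero or
#'   negative.
#' @export
cost_per_qaly <- function(portfolio) {
  tri <- value_triangle(portfolio)
  ifelse(tri$total_qaly > 0, round(tri$total_cost / tri$total_qaly),
         NA_real_)
}

#' Efficiency frontier
#'
#' Stacks the value-for-money triangles in order of slope, steepest
#' first, and accumulates cost and QALYs. Slope ties are broken by lower
#' total cost, then id. Interventions with zero or negative QALY gain
#' are placed last, in evidence-category order `no_evidence`,
#' `no_benefit`, `possible_harm` (a zero-QALY `benefit` entry sorts
#' before those).
#'
#' @param triangles Output of [value_triangle()] (or a portfolio tibble,
#'   which is converted).
#' @return Tibble of frontier points: `rank`, `intervention_id`,
#'   `slope`, `total_cost`, `total_qaly`, `cumulative_cost`,
#'   `cumulative_qaly`.
#' @export
build_frontier <- function(triangles) {
  if (!"slope" %in% names(triangles)) triangles <- value_triangle(triangles)
  if (nrow(triangles) == 0) abort_input("at least one triangle is required")
  pos <- triangles[triangles$total_qaly > 0, ]
  rest <- triangles[triangles$total_qaly <= 0, ]
  pos <- pos[order(-pos$slope, pos$total_cost, pos$intervention_id), ]
  cat_rank <- match(rest$evidence_category,
                    c("benefit", "no_evidence", "no_benefit", "possible_harm"))
  cat_rank[is.na(cat_rank)] <- 2L
  rest <- rest[order(cat_rank, rest$intervention_id), ]
  out <- dplyr::bind_rows(pos, rest)
  out$rank <- seq_len(nrow(out))
  out$cumulative_cost <- round(cumsum(out$total_cost), 6)
  out$cumulative_qaly <- round(cumsum(out$total_qaly), 6)
  out[, c("rank", "intervention_id", "slope", "total_cost", "total_qaly",
          "cumulative_cost", "cumulative_qaly")]
}

#' Portfolio summary
#'
#' Treatment-course counting: `n_people` is the sum of `n_treated`
#' across interventions (one person receiving two interventions counts
#' twice; person-level deduplication requires patient-linked data).
#'
#' @param portfolio A portfolio tibble.
#' @return A `portfolio_summary` list: `n_interventions`, `n_people`,
#'   `total_cost`, `total_qaly`, `category_counts`.
#' @export
portfolio_summary <- function(portfolio) {
  if (nrow(portfolio) == 0) {
    return(structure(
      list(n_interventions = 0L, n_people = 0, total_cost = 0,
           total_qaly = 0,
           category_counts = stats::setNames(rep(0L, 4), evidence_categories)),
      class = "portfolio_summary"
    ))
  }
  portfolio <- validate_portfolio(portfolio)
  tri <- value_triangle(portfolio)
  counts <- table(factor(portfolio$evidence_category,
                         levels = evidence_categories))
  structure(
    list(
      n_interventions = nrow(portfolio),
      n_people = sum(portfolio$n_treated),
      total_cost = round(sum(tri$total_cost), 6),
      total_qaly = round(sum(tri$total_qaly), 6),
      category_counts = stats::setNames(as.integer(counts), names(counts))
    ),
    class = "portfolio_summary"
  )
}

#' @export
print.portfolio_summary <- function(x, ...) {
  cat("<portfolio_summary>\n")
  cat(sprintf("  %d interventions | %s people treated | cost £%s | %s QALYs\n",
              x$n_interventions, format(x$n_people, big.mark = ","),
              format(x$total_cost, big.mark = ","),
              format(round(x$total_qaly), big.mark = ",")))
  cat("  evidence categories:",
      paste(sprintf("%s=%d", names(x$category_counts), x$category_counts),
            collapse = ", "), "\n")
  invisible(x)
}

#' Construct a reallocation plan
#'
#' A plan pairs disinvestments (fractions of existing interventions
#' stopped, with the fraction of the freed variable cost that can
#' actually be released for reinvestment — facility-type costs often
#' cannot) with reinvestment interventions, under either a
#' released-only budget (spend no more than what disinvestment
#' releases) or a fixed envelope (total spend after the plan must equal
#' the envelope).
#'
#' @param disinvestments Tibble with columns `id`, `fraction_stopped`
#'   (in `[0, 1]`) and `releasable_cost_fraction` (in `[0, 1]`).
#' @param reinvestments Portfolio tibble of new interventions.
#' @param budget_mode `"released_only"` (default) or `"fixed_envelope"`.
#' @param envelope Total spend envelope in pounds; required for
#'   `"fixed_envelope"`.
#' @return A validated `reallocation_plan` list.
#' @export
reallocation_plan <- function(disinvestments = NULL, reinvestments = NULL,
                              budget_mode = c("released_only", "fixed_envelope"),
                              envelope = NULL) {
  budget_mode <- match.arg(budget_mode)
  if (is.null(disinvestments)) {
    disinvestments <- tibble::tibble(id = character(),
                                     fraction_stopped = numeric(),
                                     releasable_cost_fraction = numeric())
  }
  need <- c("id", "fraction_stopped", "releasable_cost_fraction")
  if (!all(need %in% names(disinvestments))) {
    abort_input("disinvestments must have columns %s",
                paste(need, collapse = ", "))
  }
  if (any(disinvestments$fraction_stopped < 0 |
          disinvestments$fraction_stopped > 1)) {
    abort_input("fraction_stopped must be in [0, 1]")
  }
  if (any(disinvestments$releasable_cost_fraction < 0 |
          disinvestments$releasable_cost_fraction > 1)) {
    abort_input("releasable_cost_fraction must be in [0, 1]")
  }
  if (!is.null(reinvestments) && nrow(reinvestments) > 0) {
    reinvestments <- validate_portfolio(reinvestments)
  }
  if (budget_mode == "fixed_envelope" &&
      (is.null(envelope) || !is.numeric(envelope) || envelope < 0)) {
    abort_input("fixed_envelope mode requires a non-negative envelope in pounds")
  }
  structure(
    list(disinvestments = disinvestments,
         reinvestments = reinvestments,
         budget_mode = budget_mode,
         envelope = envelope),
    class = "reallocation_plan"
  )
}

#' Apply a budget-neutral reallocation plan
#'
#' For each disinvestment, the stopped share of the intervention's
#' variable cost is a saving; the releasable fraction of that saving
#' funds the reinvestments, the remainder simply leaves the spend (it
#' was never reinvestable). Scaled-down interventions keep their fixed
#' cost and lose QALYs in proportion to the people no longer treated.
#' In `released_only` mode the reinvestment spend must not exceed the
#' released budget; in `fixed_envelope` mode total spend after the plan
#' must match the envelope to within 1 pound.
#'
#' @param baseline Baseline portfolio tibble.
#' @param plan A [reallocation_plan()].
#' @return A `reallocation_result` list: `portfolio` (post-plan),
#'   `summary` (its [portfolio_summary()]), `baseline_summary`,
#'   `released_budget`, `reinvestment_cost`, and `deltas` (absolute and
#'   percentage change in total QALYs, people treated, and spend).
#' @export
apply_reallocation <- function(baseline, plan) {
  baseline <- validate_portfolio(baseline)
  if (!inherits(plan, "reallocation_plan")) {
    abort_input("plan must be a reallocation_plan object")
  }
  dis <- plan$disinvestments
  unknown <- setdiff(dis$id, baseline$id)
  if (length(unknown) > 0) {
    abort_input("disinvestment id(s) not in baseline portfolio: %s",
                paste(unknown, collapse = ", "))
  }
  before <- portfolio_summary(baseline)

  new_pf <- baseline
  released <- 0
  if (nrow(dis) > 0) {
    i <- match(dis$id, new_pf$id)
    savings <- dis$fraction_stopped * new_pf$n_treated[i] *
      new_pf$variable_cost_per_person[i]
    released <- sum(savings * dis$releasable_cost_fraction)
    new_pf$n_treated[i] <- new_pf$n_treated[i] * (1 - dis$fraction_stopped)
  }
  reinvest_cost <- 0
  if (!is.null(plan$reinvestments) && nrow(plan$reinvestments) > 0) {
    clash <- intersect(plan$reinvestments$id, new_pf$id)
    if (length(clash) > 0) {
      abort_input("reinvestment id(s) already in baseline: %s",
                  paste(clash, collapse = ", "))
    }
    reinvest_cost <- sum(plan$reinvestments$fixed_cost +
                           plan$reinvestments$n_treated *
                           plan$reinvestments$variable_cost_per_person)
    new_pf <- dplyr::bind_rows(new_pf, plan$reinvestments)
  }
  if (plan$budget_mode == "released_only" && reinvest_cost > released + 1) {
    abort_input("plan infeasible: reinvestment spend £%.0f exceeds released budget £%.0f by £%.0f",
                reinvest_cost, released, reinvest_cost - released)
  }
  after <- portfolio_summary(new_pf)
  if (plan$budget_mode == "fixed_envelope") {
    if (after$total_cost > plan$envelope + 1) {
      abort_input("plan infeasible: total spend £%.0f exceeds the £%.0f envelope by £%.0f",
                  after$total_cost, plan$envelope,
                  after$total_cost - plan$envelope)
    }
    if (after$total_cost < plan$envelope - 1) {
      warning(sprintf("plan is not budget-neutral: total spend £%.0f is £%.0f under the envelope",
                      after$total_cost, plan$envelope - after$total_cost),
              call. = FALSE)
    }
  }
  pct <- function(delta, base) if (base != 0) 100 * delta / base else NA_real_
  deltas <- list(
    qaly_abs = after$total_qaly - before$total_qaly,
    qaly_pct = pct(after$total_qaly - before$total_qaly, before$total_qaly),
    people_abs = after$n_people - before$n_people,
    people_pct = pct(after$n_people - before$n_people, before$n_people),
    cost_abs = after$total_cost - before$total_cost
  )
  structure(
    list(portfolio = new_pf, summary = after, baseline_summary = before,
         released_budget = released, reinvestment_cost = reinvest_cost,
         deltas = deltas, budget_mode = plan$budget_mode),
    class = "reallocation_result"
  )
}

#' @export
print.reallocation_result <- function(x, ...) {
  cat("<reallocation_result>\n")
  cat(sprintf("  released £%s | reinvested £%s (%s mode)\n",
              format(round(x$released_budget), big.mark = ","),
              format(round(x$reinvestment_cost), big.mark = ","),
              x$budget_mode))
  cat(sprintf("  QALYs: %s -> %s (%+.1f%%) | people: %s -> %s | spend change £%s\n",
              format(round(x$baseline_summary$total_qaly), big.mark = ","),
              format(round(x$summary$total_qaly), big.mark = ","),
              x$deltas$qaly_pct,
              format(x$baseline_summary$n_people, big.mark = ","),
              format(x$summary$n_people, big.mark = ","),
              format(round(x$deltas$cost_abs), big.mark = ",")))
  invisible(x)
}

#' Synthetic baseline portfolio
#'
#' A synthetic 29-intervention back-pain portfolio constructed to match
#' the published study-level totals, which are inputs to the analysis
#' rather than recomputable quantities: 17,225 treatment courses, a
#' spend of 4.5 million pounds, a QALY gain of 4,571, and an evidence
#' tally of 16 beneficial / 9 no-evidence / 3 no-benefit / 1
#' possible-harm interventions. The intervention-level rows are
#' invented; only the totals and tally are anchored.
#'
#' @return A portfolio tibble.
#' @export
#' @examples
#' portfolio_summary(synthetic_baseline_portfolio())
synthetic_baseline_portfolio <- function() {
  path <- system.file("extdata", "synthetic_portfolio_mid_notts.csv",
                      package = "starvalue")
  read_portfolio(path)
}

#' Synthetic worked-example reallocation plan
#'
#' Stops the zero-benefit imaging and injection interventions of the
#' synthetic baseline (releasing 270,000 pounds of variable cost) and
#' reinvests in the three worked-example interventions (digital
#' support, back-pain classes, case management) under a fixed 4.5
#' million pound envelope.
#'
#' @return A [reallocation_plan()].
#' @export
synthetic_reallocation_plan <- function() {
  path <- system.file("extdata", "synthetic_reallocation_plan.json",
                      package = "starvalue")
  read_plan(path)
}
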