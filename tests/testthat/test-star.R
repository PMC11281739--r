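test_that("value triangles satisfy the cost and QALY identities", {
  tri <- value_triangle(worked_example_portfolio())
  expect_equal(tri$total_cost, c(20000, 150000, 100000))
  expect_equal(tri$total_qaly, c(700, 2010, 380))
  # empty intervention: zero QALYs, cost = fixed cost
  empty <- tibble::tibble(id = "e", name = "e", n_treated = 0,
                          fixed_cost = 500, variable_cost_per_person = 10,
                          qaly_per_person = 1, evidence_category = "benefit",
                          provider = NA_character_)
  te <- value_triangle(empty)
  expect_equal(te$total_cost, 500)
  expect_equal(te$total_qaly, 0)
  # zero cost with non-zero QALYs: slope flagged infinite with a message
  free <- dplyr::mutate(empty, n_treated = 10, fixed_cost = 0,
                        variable_cost_per_person = 0)
  expect_message(tf <- value_triangle(free), "infinite")
  expect_true(is.infinite(tf$slope))
})

test_that("cost per QALY matches the worked-example rows to the pound", {
  cpq <- cost_per_qaly(worked_example_portfolio())
  expect_equal(cpq, c(29, 75, 263))
  one <- tibble::tibble(id = "x", name = "x", n_treated = 1, fixed_cost = 0,
                        variable_cost_per_person = 100, qaly_per_person = 1,
                        evidence_category = "benefit", provider = NA_character_)
  expect_equal(cost_per_qaly(one), 100)
  zero <- dplyr::mutate(one, qaly_per_person = 0)
  expect_true(is.na(cost_per_qaly(zero)))
})

test_that("the frontier stacks triangles steepest-first with cumulative sums", {
  single <- worked_example_portfolio()[1, ]
  f1 <- build_frontier(value_triangle(single))
  expect_equal(nrow(f1), 1)
  expect_equal(f1$cumulative_cost, 20000)
  expect_equal(f1$cumulative_qaly, 700)
  fr <- build_frontier(value_triangle(worked_example_portfolio()))
  expect_equal(fr$intervention_id,
               c("digital_support", "back_pain_classes", "case_management"))
  expect_equal(fr$cumulative_cost[3], 270000)
  expect_equal(fr$cumulative_qaly[3], 3090)
  expect_true(all(diff(fr$slope) <= 0))
  expect_true(all(diff(fr$cumulative_cost) >= 0))
  # zero/negative-QALY entries go last in evidence-category order
  pf <- synthetic_baseline_portfolio()
  f <- build_frontier(value_triangle(pf))
  tail_cat <- f |>
    dplyr::left_join(pf[, c("id", "evidence_category")],
                     by = c(intervention_id = "id")) |>
    dplyr::filter(total_qaly <= 0)
  expect_equal(tail_cat$rank, seq(nrow(f) - nrow(tail_cat) + 1, nrow(f)))
  ranks <- match(tail_cat$evidence_category,
                 c("no_evidence", "no_benefit", "possible_harm"))
  expect_true(all(diff(ranks) >= 0))
})

test_that("the slope-ordered frontier dominates every other stacking order", {
  set.seed(404)
  curve_at <- function(ord, tri, grid) {
    cc <- cumsum(tri$total_cost[ord])
    cq <- cumsum(tri$total_qaly[ord])
    stats::approx(c(0, cc), c(0, cq), xout = grid, rule = 2)$y
  }
  for (i in 1:20) {
    n <- sample(3:6, 1)
    tri <- tibble::tibble(
      intervention_id = letters[1:n],
      total_cost = round(runif(n, 100, 10000)),
      total_qaly = round(runif(n, 1, 500)),
      slope = NA_real_, evidence_category = "benefit"
    )
    tri$slope <- tri$total_qaly / tri$total_cost
    fr <- build_frontier(tri)
    grid <- c(0, cumsum(fr$total_cost))
    best <- curve_at(match(fr$intervention_id, tri$intervention_id), tri, grid)
    perms <- combinat_perms(n)
    for (p in perms) {
      expect_true(all(best >= curve_at(p, tri, grid) - 1e-9))
    }
  }
})

test_that("portfolio summaries tally people, spend, QALYs and categories", {
  empty <- portfolio_summary(worked_example_portfolio()[0, ])
  expect_equal(empty$n_people, 0)
  expect_equal(empty$total_cost, 0)
  expect_equal(empty$total_qaly, 0)
  s <- portfolio_summary(worked_example_portfolio())
  expect_equal(s$n_people, 13200)
  expect_equal(s$total_cost, 270000)
  expect_equal(s$total_qaly, 3090)
  base <- portfolio_summary(synthetic_baseline_portfolio())
  expect_equal(base$n_interventions, 29)
  expect_equal(sum(base$category_counts), 29)
  expect_equal(unname(base$category_counts),
               c(16L, 9L, 3L, 1L))
  dup <- dplyr::bind_rows(worked_example_portfolio(),
                          worked_example_portfolio()[1, ])
  expect_error(portfolio_summary(dup), "duplicate")
})

test_that("an empty reallocation plan leaves the portfolio unchanged", {
  base <- synthetic_baseline_portfolio()
  res <- apply_reallocation(base, reallocation_plan())
  expect_equal(res$summary$total_qaly, portfolio_summary(base)$total_qaly)
  expect_equal(res$deltas$qaly_abs, 0)
  expect_equal(res$deltas$people_abs, 0)
  expect_equal(res$released_budget, 0)
})

test_that("the worked-example reallocation yields 7,661 QALYs within the envelope", {
  base <- synthetic_baseline_portfolio()
  plan <- synthetic_reallocation_plan()
  res <- apply_reallocation(base, plan)
  expect_equal(res$baseline_summary$total_qaly, 4571)
  expect_equal(res$released_budget, 270000)
  expect_equal(res$summary$total_qaly, 7661)
  expect_equal(res$summary$total_cost, 4500000)
  expect_equal(res$deltas$qaly_pct, 100 * 3090 / 4571, tolerance = 1e-10)
})

test_that("fixed-cost-locked disinvestment releases nothing but drops its QALYs", {
  base <- toy_portfolio()
  plan <- reallocation_plan(
    disinvestments = tibble::tibble(id = "a", fraction_stopped = 1,
                                    releasable_cost_fraction = 0))
  res <- apply_reallocation(base, plan)
  expect_equal(res$released_budget, 0)
  expect_equal(res$deltas$qaly_abs, -50)  # a: 100 x 0.5
})

test_that("infeasible plans error with the shortfall", {
  base <- toy_portfolio()
  plan <- reallocation_plan(
    disinvestments = tibble::tibble(id = "a", fraction_stopped = 0.5,
                                    releasable_cost_fraction = 1),
    reinvestments = tibble::tibble(
      id = "new", name = "new", n_treated = 100, fixed_cost = 0,
      variable_cost_per_person = 50, qaly_per_person = 1,
      evidence_category = "benefit", provider = NA_character_))
  expect_error(apply_reallocation(base, plan), "exceeds released budget")
  expect_error(
    apply_reallocation(base, reallocation_plan(
      disinvestments = plan$disinvestments,
      reinvestments = plan$reinvestments,
      budget_mode = "fixed_envelope", envelope = 1000)),
    "envelope")
  bad_dis <- tibble::tibble(id = "zzz", fraction_stopped = 1,
                            releasable_cost_fraction = 1)
  expect_error(apply_reallocation(base, reallocation_plan(bad_dis)), "zzz")
  expect_error(reallocation_plan(
    tibble::tibble(id = "a", fraction_stopped = 2,
                   releasable_cost_fraction = 1)), "fraction_stopped")
})

test_that("released-only reallocation conserves spend exactly", {
  set.seed(555)
  for (i in 1:20) {
    base <- toy_portfolio()
    f <- runif(1)
    rel <- runif(1)
    spend_target <- f * base$n_treated[1] * base$variable_cost_per_person[1] * rel
    plan <- reallocation_plan(
      disinvestments = tibble::tibble(id = "a", fraction_stopped = f,
                                      releasable_cost_fraction = rel),
      reinvestments = tibble::tibble(
        id = "new", name = "new", n_treated = 1, fixed_cost = spend_target,
        variable_cost_per_person = 0, qaly_per_person = runif(1, 0, 5),
        evidence_category = "benefit", provider = NA_character_))
    res <- apply_reallocation(base, plan)
    savings <- f * base$n_treated[1] * base$variable_cost_per_person[1]
    unreleased <- savings * (1 - rel)
    expect_equal(res$summary$total_cost,
                 res$baseline_summary$total_cost - unreleased,
                 tolerance = 1e-9)
  }
})

test_that("raising a reinvestment's QALY gain never lowers the post-plan total", {
  base <- synthetic_baseline_portfolio()
  plan <- synthetic_reallocation_plan()
  totals <- vapply(c(0.07, 0.2, 0.5, 1), function(q) {
    p2 <- plan
    p2$reinvestments$qaly_per_person[1] <- q
    apply_reallocation(base, p2)$summary$total_qaly
  }, numeric(1))
  expect_true(all(diff(totals) >= 0))
})
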