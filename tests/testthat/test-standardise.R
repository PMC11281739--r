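test_that("crude rates scale to per-10,000 and reject bad denominators", {
  expect_equal(crude_rate(0, 5000), 0)
  expect_equal(crude_rate(50, 10000), 50)
  expect_equal(crude_rate(7, 3500), 20)
  expect_error(crude_rate(1, 0), "denominator")
})

test_that("standardisation returns uniform stratum rates unchanged", {
  d <- tidyr::expand_grid(age_band = adult_age_bands(), sex = c("F", "M"))
  d$person_years <- 1000
  d$events <- 5  # every stratum at 50 per 10,000
  r <- direct_standardised_rate(d[, c("age_band", "sex", "events")],
                                d[, c("age_band", "sex", "person_years")])
  expect_equal(r$rate, 50)
  expect_equal(r$n_events, sum(d$events))
})

test_that("equal weights average two stratum rates symmetrically", {
  std <- tibble::tibble(age_band = c("40-44", "45-49"), weight = c(7, 7))
  ev <- tibble::tibble(age_band = c("40-44", "45-49"), sex = "F",
                       events = c(10, 30))
  py <- tibble::tibble(age_band = c("40-44", "45-49"), sex = "F",
                       person_years = c(10000, 10000))
  r <- direct_standardised_rate(ev, py, std = std)
  expect_equal(r$rate, 20)
})

test_that("the weighted mean matches hand arithmetic on three strata", {
  # (5500*10 + 6000*20 + 6500*40) / 18000 = 435000/18000 = 24.1667
  std <- tibble::tibble(age_band = c("a", "b", "c"),
                        weight = c(5500, 6000, 6500))
  ev <- tibble::tibble(age_band = c("a", "b", "c"), sex = "F",
                       events = c(10, 20, 40))
  py <- tibble::tibble(age_band = c("a", "b", "c"), sex = "F",
                       person_years = 10000)
  r <- direct_standardised_rate(ev, py, std = std)
  expect_equal(r$rate, 435000 / 18000, tolerance = 1e-12)
})

test_that("rescaling all standard weights leaves the rate unchanged", {
  s <- manual_strata()
  std1 <- esp_weights()
  std2 <- dplyr::mutate(std1, weight = weight * 37.5)
  r1 <- direct_standardised_rate(s$events, s$denoms, std = std1)
  r2 <- direct_standardised_rate(s$events, s$denoms, std = std2)
  expect_equal(r1$rate, r2$rate, tolerance = 1e-12)
  expect_equal(r1$ci_low, r2$ci_low, tolerance = 1e-10)
  expect_equal(r1$ci_high, r2$ci_high, tolerance = 1e-10)
})

test_that("adding events to any stratum never decreases the standardised rate", {
  set.seed(101)
  for (i in 1:25) {
    n <- sample(3:8, 1)
    bands <- sample(adult_age_bands(), n)
    ev <- tibble::tibble(age_band = bands, sex = "F",
                         events = rpois(n, 5))
    py <- tibble::tibble(age_band = bands, sex = "F",
                         person_years = runif(n, 500, 5000))
    r0 <- direct_standardised_rate(ev, py)$rate
    k <- sample(n, 1)
    ev2 <- ev
    ev2$events[k] <- ev2$events[k] + sample(1:5, 1)
    expect_gte(direct_standardised_rate(ev2, py)$rate, r0)
  }
})

test_that("strata with events but no person-years are a data-integrity error", {
  ev <- tibble::tibble(age_band = "40-44", sex = "F", events = 3)
  py <- tibble::tibble(age_band = "40-44", sex = "F", person_years = 0)
  expect_error(direct_standardised_rate(ev, py), "40-44")
  # zero events + zero person-years is skipped with a message, not an error
  ev2 <- tibble::tibble(age_band = c("40-44", "45-49"), sex = "F",
                        events = c(3, 0))
  py2 <- tibble::tibble(age_band = c("40-44", "45-49"), sex = "F",
                        person_years = c(1000, 0))
  expect_message(r <- direct_standardised_rate(ev2, py2), "skipping")
  expect_equal(r$n_events, 3)
})

test_that("confidence intervals have a zero lower bound with zero events", {
  ci <- rate_ci(0, 1000)
  expect_equal(unname(ci[1]), 0)
  expect_gt(unname(ci[2]), 0)
  s <- manual_strata()
  r0 <- direct_standardised_rate(
    dplyr::mutate(s$events, events = 0), s$denoms)
  expect_equal(r0$ci_low, 0)
  expect_true(r0$ci_low <= r0$rate && r0$rate <= r0$ci_high)
})

test_that("Wilson intervals achieve nominal coverage at p = 0.01", {
  set.seed(2024)
  n <- 5000
  p <- 0.01
  draws <- rbinom(2000, n, p)
  covered <- vapply(draws, function(x) {
    ci <- rate_ci(x, n)
    10000 * p >= ci[1] && 10000 * p <= ci[2]
  }, logical(1))
  expect_gte(mean(covered), 0.93)
  expect_lte(mean(covered), 0.97)
})

test_that("interval width shrinks like 1/sqrt(n)", {
  ci1 <- rate_ci(50, 10000)
  ci4 <- rate_ci(200, 40000)
  ratio <- diff(ci4) / diff(ci1)
  expect_lt(abs(ratio - 0.5), 0.05)
  s <- manual_strata()
  r1 <- direct_standardised_rate(s$events, s$denoms)
  s4 <- list(events = dplyr::mutate(s$events, events = events * 4),
             denoms = dplyr::mutate(s$denoms, person_years = person_years * 4))
  r4 <- direct_standardised_rate(s4$events, s4$denoms)
  ratio_d <- (r4$ci_high - r4$ci_low) / (r1$ci_high - r1$ci_low)
  expect_lt(abs(ratio_d - 0.5), 0.05)
})

test_that("pooling years sums counts and person-years coherently", {
  cfg <- tiny_config(seed = 12)
  reg <- generate_registers(cfg)
  ep <- generate_episodes(cfg, reg)
  one <- pool_years(ep, reg, years = "2019/20")
  expect_equal(sum(one$events), sum(ep$fiscal_year == "2019/20"))
  expect_equal(sum(one$person_years), sum(reg$count))
  both <- pool_years(ep, reg, years = cfg$years)
  expect_equal(sum(both$events), nrow(ep))
  expect_equal(sum(both$person_years), 2 * sum(reg$count))
  expect_error(pool_years(ep, reg, years = "1999/00"), "1999/00")
})

test_that("pooling identical years leaves the rate unchanged and narrows the CI", {
  cfg <- sim_config(seed = 19, n_practices = 6, practice_sigma = 0,
                    register_size_range = c(4000, 4000),
                    years = sprintf("Y%d", 1:4))
  reg <- generate_registers(cfg)
  ep <- generate_episodes(cfg, reg)
  dsr_of <- function(years) {
    s <- pool_years(ep, reg, years)
    direct_standardised_rate(s[, c("age_band", "sex", "events")],
                             s[, c("age_band", "sex", "person_years")])
  }
  r1 <- dsr_of("Y1")
  r4 <- dsr_of(sprintf("Y%d", 1:4))
  expect_equal(r4$denominator, 4 * r1$denominator)
  # same underlying rates: point estimates agree within sampling noise,
  # and the pooled CI is about half as wide (1/sqrt(4))
  expect_lt(abs(r4$rate - r1$rate) / r1$rate, 0.25)
  w_ratio <- (r4$ci_high - r4$ci_low) / (r1$ci_high - r1$ci_low)
  expect_lt(abs(w_ratio - 0.5), 0.10)
})
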