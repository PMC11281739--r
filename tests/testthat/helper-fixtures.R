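# Small fixture builders shared across test files.

tiny_config <- function(seed = 1, ...) {
  sim_config(seed = seed, n_practices = 4,
             years = c("2018/19", "2019/20"),
             register_size_range = c(600, 900), ...)
}

# A hand-built two-practice dataset with known stratum counts, used for
# brute-force recomputation oracles.
manual_strata <- function() {
  list(
    events = tibble::tibble(
      age_band = c("40-44", "60-64", "40-44", "60-64"),
      sex = c("F", "F", "M", "M"),
      events = c(4, 9, 2, 6)
    ),
    denoms = tibble::tibble(
      age_band = c("40-44", "60-64", "40-44", "60-64"),
      sex = c("F", "F", "M", "M"),
      person_years = c(2000, 1500, 1800, 1600)
    )
  )
}

# Minimal portfolio with distinct slopes for frontier tests.
toy_portfolio <- function() {
  tibble::tibble(
    id = c("a", "b", "c"),
    name = c("a", "b", "c"),
    n_treated = c(100, 50, 10),
    fixed_cost = c(0, 100, 0),
    variable_cost_per_person = c(10, 20, 50),
    qaly_per_person = c(0.5, 0.2, 1.0),
    evidence_category = "benefit",
    provider = NA_character_
  )
}

# All permutations of 1..n (n <= 7), for brute-force dominance checks.
combinat_perms <- function(n) {
  if (n == 1) return(list(1L))
  sub <- combinat_perms(n - 1L)
  out <- list()
  for (p in sub) {
    for (k in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = k - 1L)
    }
  }
  out
}

worked_example_portfolio <- function() {
  tibble::tibble(
    id = c("digital_support", "back_pain_classes", "case_management"),
    name = id,
    n_treated = c(10000, 3000, 200),
    fixed_cost = c(0, 0, 0),
    variable_cost_per_person = c(2, 50, 500),
    qaly_per_person = c(0.07, 0.67, 1.90),
    evidence_category = "benefit",
    provider = NA_character_
  )
}
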