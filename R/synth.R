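#' Generate synthetic practice registers
#'
#' Draws one register per practice: registered persons allocated to
#' age-band x sex x IMD-decile cells. Each practice draws its own decile
#' mixture (a discretised Gaussian around a practice-specific centre),
#' so the practice-level deprivation score — the register-weighted mean
#' decile IMD score — is deliberately a noisy proxy for the deprivation
#' of individual patients, as practice catchments mix markedly different
#' neighbourhoods.
#'
#' @param config A [sim_config()].
#' @return A tibble in long format with columns `practice_id`,
#'   `age_band`, `sex`, `imd_decile`, `count`, `deprivation_score`.
#'   Every (band, sex, decile) cell is present, zeros included.
#' @export
#' @examples
#' cfg <- sim_config(seed = 7, n_practices = 3,
#'                   register_size_range = c(800, 800))
#' reg <- generate_registers(cfg)
#' sum(reg$count)
generate_registers <- function(config) {
  if (!inherits(config, "sim_config")) {
    abort_input("config must be a sim_config object")
  }
  config <- validate_sim_config(config)
  bands <- config$age_bands
  bb <- band_bounds(bands)
  # Adult register age structure proportional to the ESP adult weights;
  # a band only partially adult (e.g. 15-19 holding just 18-19 year
  # olds) is down-weighted by its adult share.
  esp <- esp_weights(adult_only = FALSE)
  w <- stats::approx(band_bounds(esp$age_band)$mid, esp$weight,
                     xout = bb$mid, rule = 2)$y
  adult_share <- pmin(1, pmax(0, (bb$hi - pmax(bb$lo, 18) + 1) / (bb$hi - bb$lo + 1)))
  band_p <- w * adult_share
  band_p <- band_p / sum(band_p)
  scores <- imd_decile_scores()

  withr::with_seed(substream_seed(config$seed, "registers"), {
    out <- vector("list", config$n_practices)
    for (p in seq_len(config$n_practices)) {
      pid <- sprintf("PRAC%02d", p)
      size <- if (config$register_size_range[1] == config$register_size_range[2]) {
        config$register_size_range[1]
      } else {
        sample(config$register_size_range[1]:config$register_size_range[2], 1)
      }
      # centre range extends past the decile ends so that the marginal
      # decile distribution across practices is roughly uniform (IMD
      # deciles are population deciles), while individual practices
      # still skew deprived or affluent
      centre <- stats::runif(1, -2, 13)
      dec_p <- exp(-((1:10 - centre)^2) / (2 * 2.5^2))
      dec_p <- dec_p / sum(dec_p)
      cells <- tidyr::expand_grid(
        age_band = bands, sex = c("F", "M"), imd_decile = 1:10
      )
      joint <- band_p[match(cells$age_band, bands)] * 0.5 *
        dec_p[cells$imd_decile]
      cells$count <- as.integer(stats::rmultinom(1, size, joint))
      cells$practice_id <- pid
      cells$deprivation_score <- sum(cells$count * scores[cells$imd_decile]) / size
      out[[p]] <- cells
    }
    dplyr::bind_rows(out) |>
      dplyr::select("practice_id", "age_band", "sex", "imd_decile",
                    "count", "deprivation_score")
  })
}

# Piecewise-linear age profile of the rate multipliers, evaluated at
# arbitrary ages (constant extrapolation beyond the band midpoints).
multiplier_profile <- function(config, ages, sex) {
  ms <- config$age_sex_multipliers
  mids <- band_bounds(config$age_bands)$mid
  out <- numeric(length(ages))
  for (s in unique(sex)) {
    sel <- sex == s
    m <- ms$multiplier[ms$sex == s][match(config$age_bands,
                                          ms$age_band[ms$sex == s])]
    out[sel] <- stats::approx(mids, m, xout = ages[sel], rule = 2)$y
  }
  out
}

#' Generate synthetic episode records
#'
#' Stratum event counts are Poisson with mean
#' `base_rate x age_sex_multiplier x exp(practice_effect) x
#' decile_multiplier x person_years`, where the practice effect is
#' Normal(0, practice_sigma^2) on the log scale and the decile
#' multiplier is log-linear in decile so that decile 1 (most deprived)
#' versus decile 10 equals `decile_rate_ratio`. Procedure rates use an
#' age profile shifted towards younger ages with deprivation: in decile
#' `d` the procedure rate at age `a` equals the least-deprived rate at
#' age `a + age_shift_years * (10 - d)`, so mean procedure age falls by
#' `age_shift_years` per decile step.
#'
#' @param config A [sim_config()].
#' @param registers Output of [generate_registers()] under the same
#'   config.
#' @return A tibble of episode records: `patient_id`, `age`, `sex`,
#'   `practice_id`, `imd_decile`, `fiscal_year`, `event_class`
#'   (`attendance` or `procedure`), `intervention_id`.
#' @export
generate_episodes <- function(config, registers) {
  if (!inherits(config, "sim_config")) {
    abort_input("config must be a sim_config object")
  }
  if (is.null(registers) || nrow(registers) == 0) {
    abort_input("registers must be non-empty; run generate_registers() first")
  }
  config <- validate_sim_config(config)
  bb <- band_bounds(config$age_bands)
  pf <- config$procedure_fraction

  withr::with_seed(substream_seed(config$seed, "episodes"), {
    pids <- sort(unique(registers$practice_id))
    effect <- stats::rnorm(length(pids), 0, config$practice_sigma)
    names(effect) <- pids

    strata <- tidyr::expand_grid(
      registers |>
        dplyr::select("practice_id", "age_band", "sex", "imd_decile", "count"),
      fiscal_year = config$years
    )
    strata <- strata[strata$count > 0, ]
    i <- match(strata$age_band, bb$age_band)
    mid <- bb$mid[i]
    shift <- config$age_shift_years * (10 - strata$imd_decile)
    dec_mult <- config$decile_rate_ratio^((10 - strata$imd_decile) / 9)
    m_att <- multiplier_profile(config, mid, strata$sex)
    m_proc <- multiplier_profile(config, mid + shift, strata$sex)
    lam_common <- config$base_rate * exp(effect[strata$practice_id]) *
      dec_mult * strata$count
    n_att <- stats::rpois(nrow(strata), lam_common * m_att * (1 - pf))
    n_proc <- stats::rpois(nrow(strata), lam_common * m_proc * pf)

    expand_class <- function(n, class) {
      keep <- which(n > 0)
      idx <- rep(keep, n[keep])
      s <- strata[idx, ]
      lo <- pmax(bb$lo[match(s$age_band, bb$age_band)], 18)
      hi <- bb$hi[match(s$age_band, bb$age_band)]
      tibble::tibble(
        age = lo + floor(stats::runif(nrow(s)) * (hi - lo + 1)),
        sex = s$sex,
        practice_id = s$practice_id,
        imd_decile = s$imd_decile,
        fiscal_year = s$fiscal_year,
        event_class = class
      )
    }
    ep <- dplyr::bind_rows(
      expand_class(n_att, "attendance"),
      expand_class(n_proc, "procedure")
    )
    if (nrow(ep) == 0) {
      return(tibble::tibble(
        patient_id = character(), age = integer(), sex = character(),
        practice_id = character(), imd_decile = integer(),
        fiscal_year = character(), event_class = character(),
        intervention_id = character()
      ))
    }
    ep <- dplyr::arrange(ep, .data$practice_id, .data$fiscal_year,
                         .data$sex, .data$imd_decile, .data$age,
                         .data$event_class)
    ep$patient_id <- sprintf("P%07d", seq_len(nrow(ep)))
    # Optional repeat episodes: reassign some episodes to an existing
    # patient with the same practice, sex and decile.
    r <- config$repeat_episode_rate
    if (r > 0 && nrow(ep) > 1) {
      is_rep <- stats::runif(nrow(ep)) < r
      key <- paste(ep$practice_id, ep$sex, ep$imd_decile)
      for (k in unique(key[is_rep])) {
        members <- which(key == k)
        reps <- members[is_rep[members]]
        donors <- setdiff(members, reps)
        if (length(donors) == 0) next
        ep$patient_id[reps] <- ep$patient_id[
          donors[1 + (seq_along(reps) - 1) %% length(donors)]
        ]
      }
    }
    ep$intervention_id <- ""
    ep$age <- as.integer(ep$age)
    ep$imd_decile <- as.integer(ep$imd_decile)
    dplyr::select(ep, "patient_id", "age", "sex", "practice_id",
                  "imd_decile", "fiscal_year", "event_class",
                  "intervention_id")
  })
}

#' Generate an intervention portfolio
#'
#' Materialises the configured `portfolio_spec` as a validated
#' intervention table, one row per portfolio entry. The default spec
#' carries the three reinvestment interventions of the worked example
#' (digital support, back-pain classes, case management).
#'
#' @param config A [sim_config()].
#' @return A portfolio tibble with columns `id`, `name`, `n_treated`,
#'   `fixed_cost`, `variable_cost_per_person`, `qaly_per_person`,
#'   `evidence_category`, `provider`.
#' @export
#' @examples
#' generate_portfolio(sim_config(seed = 1))
generate_portfolio <- function(config) {
  if (!inherits(config, "sim_config")) {
    abort_input("config must be a sim_config object")
  }
  spec <- config$portfolio_spec
  if (is.null(spec) || nrow(spec) == 0) {
    abort_input("portfolio_spec is empty; nothing to generate")
  }
  if (any(spec$n_treated < 0)) abort_input("portfolio_spec has negative n_treated")
  if (any(spec$fixed_cost < 0) || any(spec$variable_cost_per_person < 0)) {
    abort_input("portfolio_spec has negative costs")
  }
  cat_col <- if ("evidence_category" %in% names(spec)) {
    spec$evidence_category
  } else {
    rep(NA_character_, nrow(spec))
  }
  cat_col[is.na(cat_col) | cat_col == ""] <- "benefit"
  out <- tibble::tibble(
    id = if ("id" %in% names(spec)) spec$id else spec$name,
    name = spec$name,
    n_treated = as.numeric(spec$n_treated),
    fixed_cost = as.numeric(spec$fixed_cost),
    variable_cost_per_person = as.numeric(spec$variable_cost_per_person),
    qaly_per_person = as.numeric(spec$qaly_per_person),
    evidence_category = cat_col,
    provider = if ("provider" %in% names(spec)) spec$provider else NA_character_
  )
  validate_portfolio(out)
}
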