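#' Simulate a facility birth line list
#'
#' Draws one row per delivery for a single facility under a [site_profile()].
#' The record count is `round(annual_births * duration_weeks / 52)` (or
#' Poisson around it when the profile enables jitter). Gestational age is a
#' two-component mixture: a term component, truncated normal with mean 276 d
#' and SD 8 d on [259, 294], and a preterm component 259 - d with d
#' exponential (mean 16 d) truncated so gestational age stays above the
#' profile's viability floor. Birthweight and head circumference are drawn
#' normally around the growth reference's sex- and gestational-age-specific
#' median with the reference SD, so the implied SGA fraction is the
#' reference percentile itself; a `microcephaly_excess_prob` fraction of
#' head circumferences is redrawn from below the reference 1st percentile.
#' Stillbirth, neonatal death and infection are Bernoulli per the profile.
#' Output is deterministic given `(profile, seed)`.
#'
#' @param profile A [site_profile()].
#' @param seed Integer seed; the caller's RNG state is untouched.
#' @param reference Growth reference used for anthropometry draws.
#' @return A tibble with columns `site_id`, `birth_date`, `delivery_outcome`,
#'   `sex`, `gestational_age_days`, `birthweight_g`, `head_circumference_cm`,
#'   `neonatal_death_day`, `infection_subtype`.
#' @export
#' @examples
#' prof <- site_profile("demo", annual_births = 1000)
#' births <- simulate_site(prof, seed = 1)
#' table(births$delivery_outcome)
simulate_site <- function(profile, seed,
                          reference = load_growth_reference()) {
  stopifnot(inherits(profile, "site_profile"))
  if (profile$duration_weeks == 0) {
    stop("empty cohort: `duration_weeks` is 0", call. = FALSE)
  }
  with_local_seed(seed, {
    n_expected <- profile$annual_births * profile$duration_weeks / 52
    n <- if (profile$poisson_jitter) rpois(1, n_expected) else round(n_expected)
    if (n == 0) stop("empty cohort: expected record count rounds to 0",
                     call. = FALSE)

    span_days <- profile$duration_weeks * 7
    birth_date <- profile$start_date + floor(runif(n, 0, span_days))
    birth_date <- sort(birth_date)
    sex <- ifelse(runif(n) < profile$sex_ratio_male, "male", "female")
    delivery_outcome <- ifelse(runif(n) < profile$stillbirth_prob,
                               "stillbirth", "livebirth")

    # gestational age mixture (days, integer)
    is_preterm <- runif(n) < profile$preterm_prob
    d_max <- 259 - profile$min_ga_days
    u <- runif(n)
    # preterm: exponential(16) truncated to [1, d_max] by inversion
    f_lo <- 1 - exp(-1 / 16)
    f_hi <- 1 - exp(-d_max / 16)
    d <- -16 * log(1 - (f_lo + u * (f_hi - f_lo)))
    ga_pre <- 259 - pmin(pmax(round(d), 1), d_max)
    # term: normal(276, 8) truncated to [259, 294] by inversion
    p_lo <- pnorm(259, 276, 8)
    p_hi <- pnorm(294, 276, 8)
    ga_term <- round(qnorm(p_lo + u * (p_hi - p_lo), 276, 8))
    ga_term <- pmin(pmax(ga_term, 259), 294)
    ga <- ifelse(is_preterm, ga_pre, ga_term)

    bw_med <- lookup_reference(reference, sex, ga, "weight_median")
    bw_sd <- lookup_reference(reference, sex, ga, "weight_sd")
    birthweight_g <- round(pmax(bw_med + bw_sd * qnorm(runif(n)), 250))

    hc_med <- lookup_reference(reference, sex, ga, "hc_median")
    hc_sd <- lookup_reference(reference, sex, ga, "hc_sd")
    hc <- hc_med + hc_sd * qnorm(runif(n))
    patho <- runif(n) < profile$microcephaly_excess_prob
    # pathological redraw: truncated normal below the 1st percentile
    hc[patho] <- hc_med[patho] +
      hc_sd[patho] * qnorm(runif(sum(patho)) * pnorm(qnorm(0.01)))
    head_circumference_cm <- round(hc, 1)

    live <- delivery_outcome == "livebirth"
    dies <- live & runif(n) < profile$neonatal_death_prob
    death_day <- pmin(floor(rexp(n, rate = 1 / 4)), 27)
    neonatal_death_day <- ifelse(dies, death_day, NA_integer_)

    infected <- live & runif(n) < profile$infection_prob
    subtype_draw <- INFECTION_SUBTYPES[
      findInterval(runif(n), cumsum(profile$infection_subtype_mix),
                   left.open = TRUE) + 1]
    infection_subtype <- ifelse(infected, subtype_draw, "none")

    miss <- profile$measurement_missingness
    ga[runif(n) < miss[["gestational_age"]]] <- NA_integer_
    birthweight_g[runif(n) < miss[["birthweight"]]] <- NA_real_
    head_circumference_cm[runif(n) < miss[["head_circumference"]]] <- NA_real_

    tibble::tibble(site_id = profile$site_id,
                   birth_date = birth_date,
                   delivery_outcome = delivery_outcome,
                   sex = sex,
                   gestational_age_days = as.integer(ga),
                   birthweight_g = as.numeric(birthweight_g),
                   head_circumference_cm = head_circumference_cm,
                   neonatal_death_day = as.integer(neonatal_death_day),
                   infection_subtype = infection_subtype)
  })
}

#' Overlay imperfect routine site ascertainment on a line list
#'
#' Derives each record's true outcome labels with the standardized rules,
#' then writes per-outcome site flags: a true case is flagged with the
#' profile's `ascertainment_sensitivity` for that outcome and a non-case
#' with its `false_flag_prob`. Flags for different outcomes are drawn
#' independently. Measurements are never altered.
#'
#' @param records A line list from [simulate_site()].
#' @param profile The generating [site_profile()].
#' @param seed Integer seed (independent of the simulation seed).
#' @param config,reference Classification inputs used to derive truth.
#' @return `records` with logical `flag_<outcome>` columns appended.
#' @export
apply_site_ascertainment <- function(records, profile, seed,
                                     config = classification_config(),
                                     reference = load_growth_reference()) {
  stopifnot(inherits(profile, "site_profile"))
  labelled <- classify_births(records, config, reference)
  n <- nrow(records)
  with_local_seed(seed, {
    for (o in OUTCOMES) {
      truth <- labelled[[paste0("label_", o)]]
      sens <- profile$ascertainment_sensitivity[[o]]
      ffp <- profile$false_flag_prob[[o]]
      u <- runif(n)
      records[[paste0("flag_", o)]] <- ifelse(truth, u < sens, u < ffp)
    }
  })
  records
}

#' Simulate the whole surveillance network
#'
#' Runs [simulate_site()] and [apply_site_ascertainment()] for every profile,
#' with per-site seeds derived deterministically from `seed`.
#'
#' @param profiles Named list of [site_profile()]s, e.g. from
#'   [load_site_profiles()].
#' @param seed Integer master seed.
#' @inheritParams apply_site_ascertainment
#' @return One tibble binding all sites' flagged line lists.
#' @export
simulate_network <- function(profiles, seed,
                             config = classification_config(),
                             reference = load_growth_reference()) {
  dplyr::bind_rows(lapply(seq_along(profiles), function(i) {
    site_seed <- (seed + 7919L * i) %% .Machine$integer.max
    recs <- simulate_site(profiles[[i]], site_seed, reference)
    apply_site_ascertainment(recs, profiles[[i]], site_seed + 1L,
                             config, reference)
  }))
}

#' Aggregate a line list to monthly facility totals
#'
#' Mirrors the monthly aggregated reporting format: births and livebirths
#' per site and calendar month, plus per-outcome site-flag counts when flag
#' columns are present. Counts partition the line list, so summing over
#' months reproduces whole-period totals.
#'
#' @param records A birth line list (flagged or not).
#' @return A tibble keyed by (`site_id`, `month`).
#' @export
aggregate_monthly <- function(records) {
  if (nrow(records) == 0) {
    return(tibble::tibble(site_id = character(), month = character(),
                          births = integer(), livebirths = integer()))
  }
  flag_cols <- grep("^flag_", names(records), value = TRUE)
  records |>
    dplyr::mutate(month = format(.data$birth_date, "%Y-%m")) |>
    dplyr::group_by(.data$site_id, .data$month) |>
    dplyr::summarise(
      births = dplyr::n(),
      livebirths = sum(.data$delivery_outcome == "livebirth"),
      dplyr::across(dplyr::all_of(flag_cols), sum),
      .groups = "drop") |>
    dplyr::arrange(.data$site_id, .data$month)
}
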