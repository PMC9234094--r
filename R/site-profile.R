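#' Define a facility simulation profile
#'
#' A site profile holds everything the line-list generator needs for one
#' facility: obstetric load, outcome probabilities, the infection subtype
#' mix, measurement missingness, and per-outcome ascertainment behaviour
#' (the probability routine site surveillance flags a true case, and the
#' probability it flags a non-case). The packaged network configuration
#' (see [load_site_profiles()]) carries 21 profiles spanning annual loads
#' from 864 to 10,554 births.
#'
#' @param site_id Facility identifier.
#' @param annual_births Expected births per 52-week year (>= 1).
#' @param facility_level `"primary"`, `"secondary"` or `"tertiary"`.
#' @param duration_weeks Surveillance duration in weeks (default 52).
#' @param sex_ratio_male Probability a birth is male.
#' @param stillbirth_prob Stillbirth probability per total birth.
#' @param preterm_prob Preterm probability per livebirth.
#' @param neonatal_death_prob In-hospital neonatal death probability per
#'   livebirth.
#' @param infection_prob Neonatal infection probability per livebirth.
#' @param infection_subtype_mix Named probabilities over
#'   `invasive_bloodstream`, `meningitis`, `respiratory`; must sum to 1.
#' @param microcephaly_excess_prob Probability a livebirth's head
#'   circumference is redrawn from below the reference 1st percentile
#'   (pathological smallness on top of the distributional tail).
#' @param measurement_missingness Named probabilities that
#'   `gestational_age`, `birthweight`, `head_circumference` are missing.
#' @param ascertainment_sensitivity Named per-outcome probabilities that a
#'   true case is site-flagged (defaults: all 1).
#' @param false_flag_prob Named per-outcome probabilities that a non-case is
#'   site-flagged (defaults: all 0).
#' @param poisson_jitter If `TRUE`, the record count is Poisson around the
#'   expected load; default `FALSE` (fixed count) for reproducibility.
#' @param start_date First surveillance day (ISO date).
#' @param min_ga_days Viability floor: no simulated birth below this
#'   gestational age (default 154 days = 22 weeks).
#' @return A list of class `site_profile`.
#' @export
site_profile <- function(site_id,
                         annual_births,
                         facility_level = c("tertiary", "secondary", "primary"),
                         duration_weeks = 52,
                         sex_ratio_male = 0.515,
                         stillbirth_prob = 0.015,
                         preterm_prob = 0.10,
                         neonatal_death_prob = 0.012,
                         infection_prob = 0.015,
                         infection_subtype_mix = c(invasive_bloodstream = 0.8,
                                                   meningitis = 0.05,
                                                   respiratory = 0.15),
                         microcephaly_excess_prob = 0.001,
                         measurement_missingness = c(gestational_age = 0,
                                                     birthweight = 0,
                                                     head_circumference = 0),
                         ascertainment_sensitivity = NULL,
                         false_flag_prob = NULL,
                         poisson_jitter = FALSE,
                         start_date = as.Date("2019-05-01"),
                         min_ga_days = 154) {
  facility_level <- match.arg(facility_level)
  if (!is.numeric(annual_births) || annual_births < 1) {
    stop("`annual_births` must be >= 1", call. = FALSE)
  }
  if (duration_weeks < 0) stop("`duration_weeks` must be >= 0", call. = FALSE)
  for (nm in c("sex_ratio_male", "stillbirth_prob", "preterm_prob",
               "neonatal_death_prob", "infection_prob",
               "microcephaly_excess_prob")) {
    check_probability(get(nm), nm)
  }
  mix <- unlist(infection_subtype_mix)
  if (is.null(names(mix)) && length(mix) == 3) names(mix) <- INFECTION_SUBTYPES
  if (!all(INFECTION_SUBTYPES %in% names(mix))) {
    stop("`infection_subtype_mix` must name all three subtypes",
         call. = FALSE)
  }
  mix <- mix[INFECTION_SUBTYPES]
  check_probability(mix, "infection_subtype_mix")
  if (abs(sum(mix) - 1) > 1e-9) {
    stop("`infection_subtype_mix` must sum to 1", call. = FALSE)
  }
  miss <- unlist(measurement_missingness)
  miss <- setNames(
    vapply(c("gestational_age", "birthweight", "head_circumference"),
           function(k) if (k %in% names(miss)) miss[[k]] else 0, numeric(1)),
    c("gestational_age", "birthweight", "head_circumference"))
  check_probability(miss, "measurement_missingness")
  sens <- fill_outcome_probs(ascertainment_sensitivity, default = 1,
                             what = "ascertainment_sensitivity")
  ffp <- fill_outcome_probs(false_flag_prob, default = 0,
                            what = "false_flag_prob")
  structure(list(site_id = as.character(site_id),
                 facility_level = facility_level,
                 annual_births = annual_births,
                 duration_weeks = duration_weeks,
                 sex_ratio_male = sex_ratio_male,
                 stillbirth_prob = stillbirth_prob,
                 preterm_prob = preterm_prob,
                 neonatal_death_prob = neonatal_death_prob,
                 infection_prob = infection_prob,
                 infection_subtype_mix = mix,
                 microcephaly_excess_prob = microcephaly_excess_prob,
                 measurement_missingness = miss,
                 ascertainment_sensitivity = sens,
                 false_flag_prob = ffp,
                 poisson_jitter = isTRUE(poisson_jitter),
                 start_date = as.Date(start_date),
                 min_ga_days = min_ga_days),
            class = "site_profile")
}

fill_outcome_probs <- function(x, default, what) {
  out <- setNames(rep(default, length(OUTCOMES)), OUTCOMES)
  if (!is.null(x)) {
    x <- unlist(x)
    unknown <- setdiff(names(x), OUTCOMES)
    if (length(unknown) > 0) {
      stop("unknown outcome in `", what, "`: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    out[names(x)] <- x
  }
  check_probability(out, what)
  out
}

#' Load site profiles from a structured config file
#'
#' Reads a YAML file with a top-level `sites:` list whose entries hold
#' [site_profile()] fields. The packaged default encodes 21 facility
#' profiles with loads, outcome probabilities and per-outcome ascertainment
#' sensitivities transcribed from the surveillance network's published
#' summary tables.
#'
#' @param path YAML config path; defaults to the packaged network config.
#' @return A named list of `site_profile` objects.
#' @export
load_site_profiles <- function(path = NULL) {
  path <- path %||% system.file("extdata", "site_profiles.yaml",
                                package = "perisurv", mustWork = TRUE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$sites)) stop("config has no `sites:` entry", call. = FALSE)
  profiles <- lapply(cfg$sites, function(s) do.call(site_profile, s))
  setNames(profiles, vapply(profiles, `[[`, character(1), "site_id"))
}
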