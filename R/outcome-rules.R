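#' Classification thresholds for the surveillance outcomes
#'
#' Bundles the standardized cut-offs applied when re-identifying outcomes
#' from measurements. Defaults are the internationally conventional ones:
#' low birthweight below 2,500 g, preterm before 37 completed weeks (259
#' days), SGA below the 10th weight percentile for sex and gestational age,
#' congenital microcephaly below the 3rd head-circumference percentile,
#' stillbirth from 28 completed weeks (196 days), and a 28-day neonatal
#' period. All thresholds are strict (`<`): a value exactly at a cut-off is
#' not a case. Facilities use diverse charts and cut-offs in practice, so
#' every threshold is overridable.
#'
#' @param lbw_threshold_g Low-birthweight cut-off in grams (strict `<`).
#' @param preterm_threshold_days Preterm cut-off in gestational days
#'   (strict `<`; 259 = 37 completed weeks).
#' @param sga_percentile Weight percentile defining SGA; only the packaged
#'   10th percentile column is tabulated, so this is fixed at 10.
#' @param microcephaly_rule `"p3"` (3rd percentile), `"minus2sd"` or
#'   `"minus3sd"` (mean minus 2 or 3 SD) head-circumference rule.
#' @param stillbirth_min_ga_days Minimum gestational age for a fetal death
#'   to count as stillbirth (default 196 days = 28 weeks).
#' @param stillbirth_count_missing_ga Count fetal deaths with missing
#'   gestational age as stillbirths (default `TRUE`).
#' @param neonatal_period_days Length of the neonatal period in days; fixed
#'   at 28 by definition.
#' @return A list of class `classification_config`.
#' @export
classification_config <- function(lbw_threshold_g = 2500,
                                  preterm_threshold_days = 259,
                                  sga_percentile = 10,
                                  microcephaly_rule = c("p3", "minus2sd", "minus3sd"),
                                  stillbirth_min_ga_days = 196,
                                  stillbirth_count_missing_ga = TRUE,
                                  neonatal_period_days = 28) {
  microcephaly_rule <- match.arg(microcephaly_rule)
  stopifnot(lbw_threshold_g > 0, preterm_threshold_days > 0,
            stillbirth_min_ga_days > 0, neonatal_period_days == 28,
            sga_percentile == 10)
  structure(list(lbw_threshold_g = lbw_threshold_g,
                 preterm_threshold_days = preterm_threshold_days,
                 sga_percentile = sga_percentile,
                 microcephaly_rule = microcephaly_rule,
                 stillbirth_min_ga_days = stillbirth_min_ga_days,
                 stillbirth_count_missing_ga = stillbirth_count_missing_ga,
                 neonatal_period_days = neonatal_period_days),
            class = "classification_config")
}

microcephaly_cutoff <- function(reference, sex, ga_days, rule) {
  switch(rule,
         p3 = lookup_reference(reference, sex, ga_days, "hc_p3"),
         minus2sd = lookup_reference(reference, sex, ga_days, "hc_median") -
           2 * lookup_reference(reference, sex, ga_days, "hc_sd"),
         minus3sd = lookup_reference(reference, sex, ga_days, "hc_median") -
           3 * lookup_reference(reference, sex, ga_days, "hc_sd"))
}

#' Apply the standardized outcome definitions to a cohort
#'
#' Adds one logical `label_<outcome>` column per surveillance outcome.
#' Livebirth-only outcomes are `FALSE` for stillbirths; a rule whose inputs
#' are missing yields `FALSE` (the record is tallied as unassessable, not
#' dropped, so denominators keep all livebirths).
#'
#' @param records A birth line list (see [simulate_site()] for the schema).
#' @param config A [classification_config()].
#' @param reference A [load_growth_reference()] table.
#' @return `records` with `label_*` columns appended.
#' @export
classify_births <- function(records, config = classification_config(),
                            reference = load_growth_reference()) {
  stopifnot(inherits(config, "classification_config"))
  live <- records$delivery_outcome == "livebirth"
  ga <- records$gestational_age_days
  bw <- records$birthweight_g
  hc <- records$head_circumference_cm
  sex <- records$sex

  lbw <- live & !is.na(bw) & bw < config$lbw_threshold_g
  preterm <- live & !is.na(ga) & ga < config$preterm_threshold_days

  sga <- rep(FALSE, nrow(records))
  micro <- rep(FALSE, nrow(records))
  ok_ref <- live & !is.na(ga) & !is.na(sex)
  ok_sga <- ok_ref & !is.na(bw)
  if (any(ok_sga)) {
    p10 <- lookup_reference(reference, sex[ok_sga], ga[ok_sga], "weight_p10")
    sga[ok_sga] <- bw[ok_sga] < p10
  }
  ok_hc <- ok_ref & !is.na(hc)
  if (any(ok_hc)) {
    cut <- microcephaly_cutoff(reference, sex[ok_hc], ga[ok_hc],
                               config$microcephaly_rule)
    micro[ok_hc] <- hc[ok_hc] < cut
  }

  still <- records$delivery_outcome == "stillbirth" &
    (ifelse(is.na(ga), config$stillbirth_count_missing_ga,
            ga >= config$stillbirth_min_ga_days))
  ndeath <- live & !is.na(records$neonatal_death_day) &
    records$neonatal_death_day < config$neonatal_period_days
  ninf <- live & records$infection_subtype != "none"

  records$label_low_birthweight <- lbw
  records$label_preterm <- preterm
  records$label_sga <- sga
  records$label_microcephaly <- micro
  records$label_stillbirth <- still
  records$label_neonatal_death <- ndeath
  records$label_neonatal_infection <- ninf
  records
}

#' Classify one birth record
#'
#' Single-record convenience wrapper around [classify_births()].
#'
#' @inheritParams classify_births
#' @param record A one-row birth line list.
#' @return Character vector of outcome labels present.
#' @export
classify_birth <- function(record, config = classification_config(),
                           reference = load_growth_reference()) {
  stopifnot(nrow(record) == 1)
  lab <- classify_births(record, config, reference)
  OUTCOMES[vapply(OUTCOMES, function(o) lab[[paste0("label_", o)]], logical(1))]
}

#' Classify a cohort and tabulate per-outcome counts
#'
#' Runs [classify_births()] and aggregates per site: case counts,
#' denominators (livebirths, except total births for stillbirth), and an
#' unassessable tally of livebirths whose measurements could not support the
#' rule (kept in denominators, mirroring the use of all livebirths as the
#' rate denominator).
#'
#' @inheritParams classify_births
#' @param by_site Aggregate per `site_id` (default) or over the whole input.
#' @return A list with `records` (labelled line list) and `counts` (tibble:
#'   `site_id`, `outcome`, `numerator`, `denominator`, `denominator_kind`,
#'   `unassessable`).
#' @export
classify_cohort <- function(records, config = classification_config(),
                            reference = load_growth_reference(),
                            by_site = TRUE) {
  labelled <- classify_births(records, config, reference)
  site <- if (by_site) labelled$site_id else rep("all", nrow(labelled))
  live <- labelled$delivery_outcome == "livebirth"
  unassessable_for <- function(outcome) {
    switch(outcome,
           low_birthweight = live & is.na(labelled$birthweight_g),
           preterm = live & is.na(labelled$gestational_age_days),
           sga = live & (is.na(labelled$birthweight_g) |
                           is.na(labelled$gestational_age_days)),
           microcephaly = live & (is.na(labelled$head_circumference_cm) |
                                    is.na(labelled$gestational_age_days)),
           rep(FALSE, nrow(labelled)))
  }
  counts <- dplyr::bind_rows(lapply(OUTCOMES, function(o) {
    lab <- labelled[[paste0("label_", o)]]
    denom_live <- o != "stillbirth"
    unass <- unassessable_for(o)
    tibble::tibble(site_id = site, lab = lab, live = live, unass = unass) |>
      dplyr::group_by(.data$site_id) |>
      dplyr::summarise(numerator = sum(.data$lab),
                       denominator = if (denom_live) sum(.data$live)
                                     else dplyr::n(),
                       unassessable = sum(.data$unass),
                       .groups = "drop") |>
      dplyr::mutate(outcome = o,
                    denominator_kind = if (denom_live) "livebirths"
                                       else "total_births")
  }))
  counts <- counts[, c("site_id", "outcome", "numerator", "denominator",
                       "denominator_kind", "unassessable")]
  list(records = labelled, counts = counts)
}
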