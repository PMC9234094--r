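#' Union of site-flagged and rule-identified cases for one outcome
#'
#' The ascertainment sensitivity analysis compares what routine site
#' surveillance flagged against what the standardized rules re-identify
#' from the measurements. `n_total` counts records that are a case by
#' either route (per-record union, never double counted); `n_site` counts
#' those the site flagged. Records the site flagged but the rule could not
#' assess (missing measurements) stay in the union — they were identified
#' by the site — and are reported separately as `n_unconfirmable`.
#'
#' @param records A line list with `flag_<outcome>` and `label_<outcome>`
#'   columns (see [apply_site_ascertainment()] and [classify_births()]).
#' @param outcome One of [OUTCOMES].
#' @param mode `"union"` (default) counts a record once however many routes
#'   found it; `"sum"` adds the site-flagged and rule-identified counts
#'   without de-duplication, for comparison with strictly additive
#'   bookkeeping (it can double-count and is not used in the sensitivity
#'   tables).
#' @return A one-row tibble: `outcome`, `n_total`, `n_site`, `n_rule`,
#'   `n_unconfirmable`.
#' @export
union_cases <- function(records, outcome, mode = c("union", "sum")) {
  outcome <- match.arg(outcome, OUTCOMES)
  mode <- match.arg(mode)
  fcol <- paste0("flag_", outcome)
  lcol <- paste0("label_", outcome)
  stopifnot(fcol %in% names(records), lcol %in% names(records))
  flag <- records[[fcol]]
  lab <- records[[lcol]]
  assessable <- switch(outcome,
    low_birthweight = !is.na(records$birthweight_g),
    preterm = !is.na(records$gestational_age_days),
    sga = !is.na(records$birthweight_g) & !is.na(records$gestational_age_days),
    microcephaly = !is.na(records$head_circumference_cm) &
      !is.na(records$gestational_age_days),
    rep(TRUE, nrow(records)))
  in_union <- flag | lab
  tibble::tibble(outcome = outcome,
                 n_total = if (mode == "sum") sum(flag) + sum(lab)
                           else sum(in_union),
                 n_site = sum(flag[in_union]),
                 n_rule = sum(lab),
                 n_unconfirmable = sum(flag & !lab & !assessable))
}

#' Proportion of cases identified by routine site surveillance
#'
#' Estimates the site-identification proportion `n_site / n_total` with an
#' exact Clopper-Pearson interval, in percent at one decimal — the
#' site-level sensitivity of routine surveillance relative to all cases
#' found by site or statistician.
#'
#' @param n_site Cases identified by the site.
#' @param n_total All cases identified by site or standardized rules
#'   (`n_site <= n_total`). When 0, the proportion is returned as `NA`.
#' @param conf_level Two-sided confidence level.
#' @param outcome,site_id Optional identifiers carried through.
#' @return A tibble: `outcome`, `site_id`, `n_total`, `n_site`,
#'   `proportion_pct`, `ci_low_pct`, `ci_high_pct` (percent, one decimal).
#' @export
#' @examples
#' ascertainment_proportion(58, 61)   # 95.1% (86.3-99)
ascertainment_proportion <- function(n_site, n_total, conf_level = 0.95,
                                     outcome = NA_character_,
                                     site_id = NA_character_) {
  if (any(n_site > n_total)) {
    stop("`n_site` cannot exceed `n_total`", call. = FALSE)
  }
  defined <- n_total >= 1
  pct <- lo <- hi <- rep(NA_real_, length(n_total))
  if (any(defined)) {
    est <- clopper_pearson(n_site[defined], n_total[defined], conf_level)
    pct[defined] <- round_half_up(100 * est$proportion, 1)
    lo[defined] <- round_half_up(100 * est$ci_low, 1)
    hi[defined] <- round_half_up(100 * est$ci_high, 1)
  }
  tibble::tibble(outcome = outcome, site_id = site_id,
                 n_total = n_total, n_site = n_site,
                 proportion_pct = pct, ci_low_pct = lo, ci_high_pct = hi)
}

#' Site-by-outcome ascertainment sensitivity table
#'
#' Restricts each site's line list to its post-amendment window (the final
#' `weeks` weeks of observed data), unions site flags with rule labels per
#' outcome, and tabulates the site-identification proportion with exact
#' confidence intervals — one row per site and outcome.
#'
#' @param records A flagged line list covering one or more sites.
#' @param windows A tibble (`site_id`, `weeks`) giving each site's
#'   post-amendment duration in weeks; sites absent from `windows` are
#'   omitted with a warning.
#' @param config,reference Classification inputs (labels are recomputed if
#'   absent from `records`).
#' @param outcomes Outcomes to tabulate; default the four
#'   measurement-defined ones examined in the sensitivity analysis.
#' @param conf_level Two-sided confidence level.
#' @return A tibble of [ascertainment_proportion()] rows with
#'   `n_unconfirmable` diagnostics.
#' @export
sensitivity_table <- function(records, windows,
                              config = classification_config(),
                              reference = load_growth_reference(),
                              outcomes = c("low_birthweight", "preterm",
                                           "sga", "microcephaly"),
                              conf_level = 0.95) {
  outcomes <- match.arg(outcomes, OUTCOMES, several.ok = TRUE)
  if (!all(paste0("label_", outcomes) %in% names(records))) {
    records <- classify_births(records, config, reference)
  }
  sites <- unique(records$site_id)
  missing_sites <- setdiff(sites, windows$site_id)
  if (length(missing_sites) > 0) {
    warning("no post-amendment window for site(s): ",
            paste(missing_sites, collapse = ", "), "; omitted",
            call. = FALSE)
  }
  dplyr::bind_rows(lapply(intersect(sites, windows$site_id), function(s) {
    weeks <- windows$weeks[windows$site_id == s][1]
    recs <- records[records$site_id == s, ]
    cutoff <- max(recs$birth_date) - weeks * 7 + 1
    recs <- recs[recs$birth_date >= cutoff, ]
    dplyr::bind_rows(lapply(outcomes, function(o) {
      u <- union_cases(recs, o)
      res <- ascertainment_proportion(u$n_site, u$n_total, conf_level,
                                      outcome = o, site_id = s)
      res$n_unconfirmable <- u$n_unconfirmable
      res$weeks <- weeks
      res
    }))
  }))
}
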