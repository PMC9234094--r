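#' Exact (Clopper-Pearson) binomial estimate
#'
#' Computes the binomial point estimate x/n with the exact Clopper-Pearson
#' confidence interval from beta quantiles: the lower bound is the
#' (1-conf)/2 quantile of Beta(x, n-x+1) (0 when x = 0) and the upper bound
#' the 1-(1-conf)/2 quantile of Beta(x+1, n-x) (1 when x = n). Equivalent to
#' inverting the binomial tail sums; always conservative.
#'
#' @param x Event count(s), `0 <= x <= n` (vectorised).
#' @param n Trial count(s), `n >= 1`.
#' @param conf_level Two-sided confidence level (default 0.95).
#' @return A tibble with `x`, `n`, `proportion`, `ci_low`, `ci_high`,
#'   `conf_level`.
#' @export
#' @examples
#' clopper_pearson(32, 1632)   # stillbirths at one facility
clopper_pearson <- function(x, n, conf_level = 0.95) {
  if (any(n < 1)) stop("undefined denominator: `n` must be >= 1", call. = FALSE)
  if (any(x < 0) || any(x > n)) {
    stop("`x` must satisfy 0 <= x <= n", call. = FALSE)
  }
  check_probability(conf_level, "conf_level")
  alpha <- 1 - conf_level
  lo <- ifelse(x == 0, 0, qbeta(alpha / 2, x, n - x + 1))
  hi <- ifelse(x == n, 1, qbeta(1 - alpha / 2, x + 1, n - x))
  tibble::tibble(x = x, n = n, proportion = x / n,
                 ci_low = lo, ci_high = hi, conf_level = conf_level)
}

#' Outcome rate per 1,000 with exact confidence interval
#'
#' Wraps [clopper_pearson()] and scales to events per 1,000 denominators
#' (livebirths for all outcomes except stillbirth, which uses total births).
#' Scaling is applied to the unrounded proportion; display values round to
#' one decimal, half away from zero.
#'
#' @param numerator Event count(s).
#' @param denominator Denominator count(s) (>= 1).
#' @param denominator_kind `"livebirths"` or `"total_births"` (recycled).
#' @param outcome Optional outcome label(s) carried through.
#' @param site_id Optional site identifier(s) carried through.
#' @param conf_level Two-sided confidence level.
#' @return A tibble with unrounded `rate_per_1000`, `ci_low_per_1000`,
#'   `ci_high_per_1000` and one-decimal `rate_display`, `ci_low_display`,
#'   `ci_high_display`.
#' @export
#' @examples
#' outcome_rate(753, 5238)   # prints 143.8 (134.4-153.6)
outcome_rate <- function(numerator, denominator,
                         denominator_kind = "livebirths",
                         outcome = NA_character_, site_id = NA_character_,
                         conf_level = 0.95) {
  est <- clopper_pearson(numerator, denominator, conf_level)
  tibble::tibble(outcome = outcome, site_id = site_id,
                 numerator = numerator, denominator = denominator,
                 denominator_kind = denominator_kind,
                 rate_per_1000 = 1000 * est$proportion,
                 ci_low_per_1000 = 1000 * est$ci_low,
                 ci_high_per_1000 = 1000 * est$ci_high,
                 rate_display = round_half_up(1000 * est$proportion, 1),
                 ci_low_display = round_half_up(1000 * est$ci_low, 1),
                 ci_high_display = round_half_up(1000 * est$ci_high, 1))
}

#' Format a rate estimate as "rate (low-high)"
#'
#' @param rate A row-set from [outcome_rate()].
#' @return Character vector like `"143.8 (134.4-153.6)"`.
#' @export
format_rate <- function(rate) {
  fmt <- function(v) sub("\\.0$", "", formatC(v, format = "f", digits = 1))
  paste0(fmt(rate$rate_display), " (", fmt(rate$ci_low_display), "-",
         fmt(rate$ci_high_display), ")")
}

#' Infection subtype shares and rates
#'
#' For the three neonatal infection subtypes, computes each subtype's
#' percentage among all neonatal infections (one decimal) and its rate per
#' 1,000 livebirths with exact confidence interval.
#'
#' @param subtype_counts Named or positional counts for
#'   `invasive_bloodstream`, `meningitis`, `respiratory`.
#' @param total_infections All neonatal infection cases (>= sum of subtype
#'   counts). When 0, shares are returned as `NA`.
#' @param livebirths Livebirth denominator for the rates.
#' @param conf_level Two-sided confidence level.
#' @return A tibble, one row per subtype: `subtype`, `n`, `share_pct`,
#'   rate columns as in [outcome_rate()].
#' @export
subtype_share <- function(subtype_counts, total_infections, livebirths,
                          conf_level = 0.95) {
  counts <- unlist(subtype_counts)
  if (length(counts) != 3) stop("three subtype counts required", call. = FALSE)
  if (is.null(names(counts)) || !all(names(counts) %in% INFECTION_SUBTYPES)) {
    names(counts) <- INFECTION_SUBTYPES
  }
  if (sum(counts) > total_infections) {
    stop("subtype counts exceed `total_infections`", call. = FALSE)
  }
  share <- if (total_infections == 0) rep(NA_real_, 3) else {
    round_half_up(100 * counts / total_infections, 1)
  }
  rates <- outcome_rate(unname(counts), livebirths, "livebirths",
                        outcome = "neonatal_infection",
                        conf_level = conf_level)
  dplyr::bind_cols(tibble::tibble(subtype = names(counts),
                                  n = unname(counts),
                                  share_pct = unname(share)),
                   rates[, -(1:2)])
}

#' Site-by-outcome rate summary table
#'
#' Builds the network rate table: one row per site and outcome with the
#' event count, denominator, rate per 1,000 and exact confidence interval,
#' plus a `total` row per outcome whose counts are the column sums. Rows
#' with a zero denominator are kept with missing rates and raise a warning.
#' Output ordering is by outcome then site, invariant to input row order.
#'
#' @param counts A tibble with columns `site_id`, `outcome`, `numerator`,
#'   `denominator` and optionally `denominator_kind` (inferred from the
#'   outcome when absent); e.g. the `counts` element of [classify_cohort()].
#' @param conf_level Two-sided confidence level.
#' @return A tibble of rate estimates.
#' @export
site_summary <- function(counts, conf_level = 0.95) {
  stopifnot(all(c("site_id", "outcome", "numerator", "denominator") %in%
                  names(counts)))
  if (!"denominator_kind" %in% names(counts)) {
    counts$denominator_kind <- ifelse(counts$outcome == "stillbirth",
                                      "total_births", "livebirths")
  }
  counts <- counts[!is.na(counts$numerator), ]
  totals <- counts |>
    dplyr::group_by(.data$outcome, .data$denominator_kind) |>
    dplyr::summarise(site_id = "total",
                     numerator = sum(.data$numerator),
                     denominator = sum(.data$denominator),
                     .groups = "drop")
  all_counts <- dplyr::bind_rows(counts, totals) |>
    dplyr::arrange(factor(.data$outcome, levels = OUTCOMES),
                   .data$site_id != "total", .data$site_id)
  zero <- all_counts$denominator == 0
  if (any(zero)) {
    warning(sum(zero), " row(s) with zero denominator emitted without rates",
            call. = FALSE)
  }
  out <- dplyr::bind_rows(lapply(seq_len(nrow(all_counts)), function(i) {
    row <- all_counts[i, ]
    if (row$denominator == 0) {
      tibble::tibble(outcome = row$outcome, site_id = row$site_id,
                     numerator = row$numerator, denominator = 0,
                     denominator_kind = row$denominator_kind,
                     rate_per_1000 = NA_real_, ci_low_per_1000 = NA_real_,
                     ci_high_per_1000 = NA_real_, rate_display = NA_real_,
                     ci_low_display = NA_real_, ci_high_display = NA_real_)
    } else {
      outcome_rate(row$numerator, row$denominator, row$denominator_kind,
                   outcome = row$outcome, site_id = row$site_id,
                   conf_level = conf_level)
    }
  }))
  out
}
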