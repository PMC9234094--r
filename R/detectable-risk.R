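#' Design assumptions for minimum-detectable-risk planning
#'
#' Defaults reflect a standard planning scenario for facility-based
#' vaccine-safety studies: two-sided alpha 0.05, target power 0.80, a
#' two-year accrual, a 1:3 exposed-unexposed cohort, and a 1:1 case-control
#' design with 25% exposure (vaccination coverage) among controls.
#'
#' @param alpha Two-sided significance level.
#' @param target_power Required power at the detectable effect.
#' @param duration_years Accrual duration in years.
#' @param cohort_exposed_ratio `k` in a 1:k exposed:unexposed split.
#' @param cc_control_ratio `m` in a 1:m case:control split.
#' @param exposure_prevalence_controls Exposure probability among controls.
#' @return A list of class `design_assumptions`.
#' @export
design_assumptions <- function(alpha = 0.05, target_power = 0.80,
                               duration_years = 2, cohort_exposed_ratio = 3,
                               cc_control_ratio = 1,
                               exposure_prevalence_controls = 0.25) {
  stopifnot(alpha > 0, alpha < 1, target_power > 0, target_power < 1,
            duration_years > 0, cohort_exposed_ratio >= 1,
            cc_control_ratio >= 1, exposure_prevalence_controls > 0,
            exposure_prevalence_controls < 1)
  structure(list(alpha = alpha, target_power = target_power,
                 duration_years = duration_years,
                 cohort_exposed_ratio = cohort_exposed_ratio,
                 cc_control_ratio = cc_control_ratio,
                 exposure_prevalence_controls = exposure_prevalence_controls),
            class = "design_assumptions")
}

#' Power of the two-sample test for proportions
#'
#' Normal-approximation power of the two-sided two-proportion z-test with
#' pooled variance under the null and unpooled variance under the
#' alternative, no continuity correction:
#' `power = pnorm((|p1 - p0| - z * s0) / s1)` where
#' `s0 = sqrt(pbar (1 - pbar) (1/n1 + 1/n0))` with `pbar` the
#' size-weighted pooled proportion, and
#' `s1 = sqrt(p1(1-p1)/n1 + p0(1-p0)/n0)`. At `p1 = p0` this returns
#' `alpha / 2` (one tail of the two-sided test). Fractional group sizes are
#' allowed — the calculation is a planning approximation.
#'
#' @param p1,p0 Event probabilities in the two groups, strictly in (0, 1).
#' @param n1,n0 Group sizes (>= 1, fractional allowed).
#' @param alpha Two-sided significance level.
#' @return Power in (0, 1); vectorised over its arguments.
#' @export
power_two_proportions <- function(p1, n1, p0, n0, alpha = 0.05) {
  if (any(p1 <= 0 | p1 >= 1 | p0 <= 0 | p0 >= 1)) {
    stop("degenerate proportion: `p1`, `p0` must lie strictly in (0, 1)",
         call. = FALSE)
  }
  if (any(n1 < 1) || any(n0 < 1)) stop("group sizes must be >= 1",
                                       call. = FALSE)
  z <- qnorm(1 - alpha / 2)
  pbar <- (n1 * p1 + n0 * p0) / (n1 + n0)
  s0 <- sqrt(pbar * (1 - pbar) * (1 / n1 + 1 / n0))
  s1 <- sqrt(p1 * (1 - p1) / n1 + p0 * (1 - p0) / n0)
  pnorm((abs(p1 - p0) - z * s0) / s1)
}

# Smallest ratio in (1, cap] whose power reaches the target, by bisection.
# `power_fn(ratio)` must be nondecreasing. Returns the cap sentinel (Inf)
# when even the cap falls short.
invert_power <- function(power_fn, target_power, cap = 100, tol = 1e-6) {
  lo <- 1 + 1e-9
  hi <- cap
  if (power_fn(hi) < target_power) return(Inf)
  if (power_fn(lo) >= target_power) return(lo)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (power_fn(mid) >= target_power) hi <- mid else lo <- mid
  }
  hi
}

mdr_result <- function(measure, point, ci_low, ci_high, x, n,
                       annual_denominator, design) {
  tibble::tibble(measure = measure,
                 point = point, ci_low = ci_low, ci_high = ci_high,
                 point_display = round_half_up(point, 2),
                 ci_low_display = round_half_up(ci_low, 2),
                 ci_high_display = round_half_up(ci_high, 2),
                 x = x, n = n, annual_denominator = annual_denominator,
                 alpha = design$alpha, target_power = design$target_power,
                 duration_years = design$duration_years,
                 cohort_exposed_ratio = design$cohort_exposed_ratio,
                 cc_control_ratio = design$cc_control_ratio,
                 exposure_prevalence_controls =
                   design$exposure_prevalence_controls)
}

#' Minimum detectable relative risk for a cohort design
#'
#' Given a baseline outcome rate `x/n` observed over a surveillance year,
#' finds the smallest relative risk a future cohort study could detect at
#' the design's power and significance level. The cohort accrues
#' `annual_denominator * duration_years` births split 1:k
#' exposed:unexposed; the detectable point is the smallest RR > 1 whose
#' two-proportion power (see [power_two_proportions()]) reaches the target,
#' found by bisection on (1, 100] to 1e-6. Confidence bounds propagate the
#' exact Clopper-Pearson interval of `x/n`: the rate's upper bound gives
#' the lower MDR bound (more events, smaller detectable effect) and vice
#' versa. The search is capped at 100 with an `Inf` sentinel when no finite
#' ratio reaches the target.
#'
#' @param x Events observed (>= 1; an MDR is undefined at zero events).
#' @param n Denominator the events were observed in.
#' @param annual_denominator Expected denominators accrued per year at the
#'   site (defaults to `n`, the 12-month surveillance denominator).
#' @param design A [design_assumptions()].
#' @param conf_level Confidence level for the propagated rate interval.
#' @return A one-row tibble (measure `"relative_risk"`) with unrounded and
#'   two-decimal point and bounds plus the inputs and assumptions.
#' @export
#' @examples
#' min_detectable_rr_cohort(2421, 9808)$point_display   # 1.08
min_detectable_rr_cohort <- function(x, n, annual_denominator = n,
                                     design = design_assumptions(),
                                     conf_level = 0.95) {
  stopifnot(inherits(design, "design_assumptions"))
  if (x < 1) stop("no finite minimum detectable relative risk at x = 0",
                  call. = FALSE)
  if (n < x) stop("`n` must be >= `x`", call. = FALSE)
  k <- design$cohort_exposed_ratio
  total <- annual_denominator * design$duration_years
  n_exposed <- total / (1 + k)
  n_unexposed <- k * total / (1 + k)
  solve_at <- function(p0) {
    cap <- min(100, (1 - 1e-12) / p0)
    invert_power(function(rr) {
      power_two_proportions(rr * p0, n_exposed, p0, n_unexposed,
                            design$alpha)
    }, design$target_power, cap = cap)
  }
  rate <- clopper_pearson(x, n, conf_level)
  mdr_result("relative_risk",
             point = solve_at(rate$proportion),
             ci_low = solve_at(rate$ci_high),
             ci_high = solve_at(rate$ci_low),
             x = x, n = n, annual_denominator = annual_denominator,
             design = design)
}

# Exposure probability among cases implied by an odds ratio and the control
# exposure prevalence q0: odds are multiplied by OR.
case_exposure_prob <- function(or, q0) or * q0 / (1 + q0 * (or - 1))

#' Minimum detectable odds ratio for a case-control design
#'
#' The expected case series is `(x/n) * annual_denominator *
#' duration_years` (fractional sizes retained), with `m` controls per case
#' and exposure prevalence `q0` among controls. A candidate odds ratio
#' implies case exposure prevalence `q1 = OR q0 / (1 + q0 (OR - 1))`; the
#' detectable point is the smallest OR whose two-proportion power comparing
#' `q1` (cases) against `q0` (controls) reaches the target, by the same
#' bisection as [min_detectable_rr_cohort()]. Confidence bounds propagate
#' the Clopper-Pearson interval of `x/n` through the expected case count.
#'
#' @inheritParams min_detectable_rr_cohort
#' @return A one-row tibble (measure `"odds_ratio"`).
#' @export
#' @examples
#' min_detectable_or_case_control(2421, 9808)$point_display   # 1.14
min_detectable_or_case_control <- function(x, n, annual_denominator = n,
                                           design = design_assumptions(),
                                           conf_level = 0.95) {
  stopifnot(inherits(design, "design_assumptions"))
  if (x < 1) stop("no finite minimum detectable odds ratio at x = 0",
                  call. = FALSE)
  if (n < x) stop("`n` must be >= `x`", call. = FALSE)
  m <- design$cc_control_ratio
  q0 <- design$exposure_prevalence_controls
  solve_at <- function(p0) {
    n_cases <- p0 * annual_denominator * design$duration_years
    if (n_cases < 1) return(Inf)
    invert_power(function(or) {
      power_two_proportions(case_exposure_prob(or, q0), n_cases, q0,
                            m * n_cases, design$alpha)
    }, design$target_power, cap = 100)
  }
  rate <- clopper_pearson(x, n, conf_level)
  mdr_result("odds_ratio",
             point = solve_at(rate$proportion),
             ci_low = solve_at(rate$ci_high),
             ci_high = solve_at(rate$ci_low),
             x = x, n = n, annual_denominator = annual_denominator,
             design = design)
}

#' Scenario grid of minimum detectable risks
#'
#' Evaluates the minimum detectable relative risk and/or odds ratio over a
#' Cartesian grid of design scenarios — the computational backend of an
#' interactive planning dashboard. Cohort scenarios vary duration and the
#' exposed:unexposed ratio; case-control scenarios vary duration, the
#' case:control ratio and control exposure prevalence.
#'
#' @inheritParams min_detectable_rr_cohort
#' @param durations Grid of study durations in years.
#' @param exposed_ratios Grid of cohort `k` values (1:k exposed:unexposed).
#' @param control_ratios Grid of case-control `m` values (1:m).
#' @param coverages Grid of control exposure prevalences.
#' @param measures Which measures to evaluate.
#' @param design Baseline assumptions for parameters not on the grid.
#' @return A long tibble sorted by (measure, duration, ratio, prevalence).
#' @export
scenario_grid <- function(x, n, annual_denominator = n,
                          durations = c(1, 2, 3),
                          exposed_ratios = c(1, 3),
                          control_ratios = c(1, 2, 4),
                          coverages = c(0.1, 0.25, 0.5),
                          measures = c("relative_risk", "odds_ratio"),
                          design = design_assumptions(),
                          conf_level = 0.95) {
  measures <- match.arg(measures, several.ok = TRUE)
  if (length(durations) == 0 ||
      ("relative_risk" %in% measures && length(exposed_ratios) == 0) ||
      ("odds_ratio" %in% measures &&
         (length(control_ratios) == 0 || length(coverages) == 0))) {
    stop("scenario grids must be non-empty", call. = FALSE)
  }
  rows <- list()
  if ("relative_risk" %in% measures) {
    grid <- expand.grid(duration_years = sort(durations),
                        ratio = sort(exposed_ratios))
    rows <- c(rows, lapply(seq_len(nrow(grid)), function(i) {
      d <- design
      d$duration_years <- grid$duration_years[i]
      d$cohort_exposed_ratio <- grid$ratio[i]
      min_detectable_rr_cohort(x, n, annual_denominator, d, conf_level)
    }))
  }
  if ("odds_ratio" %in% measures) {
    grid <- expand.grid(duration_years = sort(durations),
                        ratio = sort(control_ratios),
                        coverage = sort(coverages))
    rows <- c(rows, lapply(seq_len(nrow(grid)), function(i) {
      d <- design
      d$duration_years <- grid$duration_years[i]
      d$cc_control_ratio <- grid$ratio[i]
      d$exposure_prevalence_controls <- grid$coverage[i]
      min_detectable_or_case_control(x, n, annual_denominator, d, conf_level)
    }))
  }
  out <- dplyr::bind_rows(rows)
  dplyr::arrange(out, .data$measure, .data$duration_years,
                 .data$cohort_exposed_ratio, .data$cc_control_ratio,
                 .data$exposure_prevalence_controls)
}
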