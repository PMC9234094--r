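#' Load the packaged network count tables
#'
#' Whole-period site-level counts for the 21-facility surveillance network:
#' births and livebirths with stillbirth, neonatal death and low-birthweight
#' counts (`"births"`); preterm, SGA, microcephaly and neonatal infection
#' counts per livebirths (`"livebirth_outcomes"`); infection subtype counts
#' (`"infection_subtypes"`); and post-amendment ascertainment counts per
#' site, outcome and week window (`"ascertainment"`).
#'
#' @param which Which table to load.
#' @return A tibble.
#' @export
load_network_counts <- function(which = c("births", "livebirth_outcomes",
                                          "infection_subtypes",
                                          "ascertainment")) {
  which <- match.arg(which)
  path <- system.file("extdata",
                      paste0("network_counts_", which, ".tsv"),
                      package = "perisurv", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

# Reshape the two packaged whole-period count tables into the long
# (site_id, outcome, numerator, denominator) form site_summary() expects.
network_counts_long <- function(births = load_network_counts("births"),
                                livebirth_outcomes =
                                  load_network_counts("livebirth_outcomes")) {
  long1 <- births |>
    tidyr::pivot_longer(dplyr::all_of(c("stillbirth", "neonatal_death",
                                        "low_birthweight")),
                        names_to = "outcome", values_to = "numerator") |>
    dplyr::mutate(
      denominator = ifelse(.data$outcome == "stillbirth",
                           .data$total_births, .data$livebirths),
      denominator_kind = ifelse(.data$outcome == "stillbirth",
                                "total_births", "livebirths"))
  long2 <- livebirth_outcomes |>
    tidyr::pivot_longer(dplyr::all_of(c("preterm", "sga", "microcephaly",
                                        "neonatal_infection")),
                        names_to = "outcome", values_to = "numerator") |>
    dplyr::mutate(denominator = .data$livebirths,
                  denominator_kind = "livebirths")
  cols <- c("site_id", "outcome", "numerator", "denominator",
            "denominator_kind")
  dplyr::bind_rows(long1[, cols], long2[, cols])
}

#' Configure an end-to-end surveillance analysis run
#'
#' @param profiles Named list of [site_profile()]s (simulation mode), or
#'   `NULL` to run in counts-only mode from pre-aggregated tables.
#' @param seed Integer master seed, recorded in every output's provenance.
#' @param classification A [classification_config()].
#' @param design A [design_assumptions()].
#' @param windows Post-amendment windows tibble (`site_id`, `weeks`);
#'   defaults to every site's full duration in simulation mode and to the
#'   packaged ascertainment windows in counts mode.
#' @param counts Counts-mode input: a list with `rates` (long tibble as in
#'   [site_summary()]) and optionally `ascertainment` (`site_id`, `outcome`,
#'   `n_total`, `n_site`). Defaults to the packaged network tables.
#' @param mdr_outcomes Outcomes for which minimum detectable risks are
#'   computed (defaults to those with internally valid site counts).
#' @param output_dir Directory for the report bundle; `NULL` keeps results
#'   in memory only.
#' @param verify Run the built-in double-programming pass: recompute every
#'   confidence interval by binomial tail-sum inversion and every
#'   detectable risk by grid search, and stop on any disagreement.
#' @return A list of class `run_config`.
#' @export
run_config <- function(profiles = NULL, seed = 1,
                       classification = classification_config(),
                       design = design_assumptions(),
                       windows = NULL, counts = NULL,
                       mdr_outcomes = c("low_birthweight", "preterm",
                                        "stillbirth"),
                       output_dir = NULL, verify = FALSE) {
  if (is.null(profiles) && is.null(counts)) {
    counts <- list(rates = network_counts_long(),
                   ascertainment = load_network_counts("ascertainment"))
  }
  structure(list(profiles = profiles, seed = seed,
                 classification = classification, design = design,
                 windows = windows, counts = counts,
                 mdr_outcomes = mdr_outcomes,
                 output_dir = output_dir, verify = isTRUE(verify)),
            class = "run_config")
}

#' Run the surveillance analysis pipeline
#'
#' Simulation mode: simulate every site's line list with imperfect
#' ascertainment, classify it with the standardized rules, estimate
#' per-site outcome rates with exact intervals, tabulate ascertainment
#' sensitivity over each site's post-amendment window, and compute
#' site-specific minimum detectable risks from the site-flagged counts.
#' Counts mode (no profiles): run the rate and detectable-risk stages
#' directly from pre-aggregated site count tables — the entry point for
#' sites that submit aggregated monthly data only. Deterministic given the
#' configuration and seed.
#'
#' @param config A [run_config()].
#' @return A list of class `surveillance_report`: `rates`,
#'   `ascertainment`, `detectable_risk`, `monthly` (simulation mode),
#'   `records` (simulation mode), and `provenance`. When
#'   `config$output_dir` is set, each table is also written as delimited
#'   text with a provenance header.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  reference <- load_growth_reference()
  simulate_mode <- !is.null(config$profiles)

  if (simulate_mode) {
    records <- simulate_network(config$profiles, config$seed,
                                config$classification, reference)
    classified <- classify_cohort(records, config$classification, reference)
    rates <- site_summary(classified$counts)
    windows <- config$windows %||% tibble::tibble(
      site_id = vapply(config$profiles, `[[`, character(1), "site_id"),
      weeks = vapply(config$profiles, `[[`, numeric(1), "duration_weeks"))
    ascertainment <- sensitivity_table(classified$records, windows,
                                       config$classification, reference)
    monthly <- aggregate_monthly(records)
    flagged <- classified$records
    site_flag_counts <- dplyr::bind_rows(lapply(config$mdr_outcomes,
                                                function(o) {
      flagged |>
        dplyr::group_by(.data$site_id) |>
        dplyr::summarise(
          outcome = o,
          numerator = sum(.data[[paste0("flag_", o)]]),
          denominator = if (o == "stillbirth") dplyr::n()
                        else sum(.data$delivery_outcome == "livebirth"),
          .groups = "drop")
    }))
    durations <- setNames(vapply(config$profiles, `[[`, numeric(1),
                                 "duration_weeks"),
                          vapply(config$profiles, `[[`, character(1),
                                 "site_id"))
    site_flag_counts$annual <- site_flag_counts$denominator * 52 /
      durations[site_flag_counts$site_id]
    mdr_input <- site_flag_counts
  } else {
    rates <- site_summary(config$counts$rates)
    ascertainment <- if (!is.null(config$counts$ascertainment)) {
      a <- config$counts$ascertainment
      ascertainment_proportion(a$n_site, a$n_total,
                               outcome = a$outcome, site_id = a$site_id)
    }
    monthly <- NULL
    records <- NULL
    mdr_input <- config$counts$rates |>
      dplyr::filter(.data$outcome %in% config$mdr_outcomes,
                    !is.na(.data$numerator)) |>
      dplyr::mutate(annual = .data$denominator)
  }

  mdr <- dplyr::bind_rows(lapply(seq_len(nrow(mdr_input)), function(i) {
    row <- mdr_input[i, ]
    if (row$numerator < 1 || row$denominator < 1) {
      warning("no finite detectable risk for ", row$site_id, "/",
              row$outcome, " (zero events)", call. = FALSE)
      return(NULL)
    }
    res <- dplyr::bind_rows(
      min_detectable_rr_cohort(row$numerator, row$denominator, row$annual,
                               config$design),
      min_detectable_or_case_control(row$numerator, row$denominator,
                                     row$annual, config$design))
    res$site_id <- row$site_id
    res$outcome <- row$outcome
    res
  }))

  report <- list(rates = rates, ascertainment = ascertainment,
                 detectable_risk = mdr, monthly = monthly,
                 records = records,
                 provenance = report_provenance(config))
  class(report) <- "surveillance_report"
  if (config$verify) verify_report(report, config)
  if (!is.null(config$output_dir)) write_report(report, config$output_dir)
  report
}

report_provenance <- function(config) {
  hashable <- config[setdiff(names(config), "output_dir")]
  tibble::tibble(package = "perisurv",
                 version = as.character(packageVersion("perisurv")),
                 seed = config$seed,
                 config_hash = rlang::hash(hashable),
                 mode = if (is.null(config$profiles)) "counts" else "simulate")
}

write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  prov <- report$provenance
  header <- sprintf("# perisurv %s | seed %s | config %s | mode %s",
                    prov$version, prov$seed, prov$config_hash, prov$mode)
  for (nm in c("rates", "ascertainment", "detectable_risk", "monthly")) {
    tab <- report[[nm]]
    if (is.null(tab)) next
    path <- file.path(dir, paste0(nm, ".tsv"))
    writeLines(header, path)
    suppressWarnings(
      write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                  na = "", append = TRUE))
  }
  if (!is.null(report$records)) {
    write_linelist(report$records, file.path(dir, "linelist.tsv"))
  }
  summary_path <- file.path(dir, "summary.txt")
  writeLines(c(header,
               sprintf("records: %s",
                       if (is.null(report$records)) "counts-only"
                       else nrow(report$records)),
               sprintf("rate rows: %d", nrow(report$rates)),
               sprintf("detectable-risk rows: %d",
                       nrow(report$detectable_risk))),
             summary_path)
  invisible(dir)
}

# ---- built-in double-programming oracles --------------------------------

# Clopper-Pearson bounds by direct root-finding on the binomial tail sums,
# independent of the beta-quantile route.
cp_tailsum <- function(x, n, conf_level = 0.95) {
  alpha <- 1 - conf_level
  lo <- if (x == 0) 0 else {
    uniroot(function(p) stats::pbinom(x - 1, n, p) - (1 - alpha / 2),
            c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  }
  hi <- if (x == n) 1 else {
    uniroot(function(p) stats::pbinom(x, n, p) - alpha / 2,
            c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  }
  c(lo, hi)
}

# Minimum detectable ratio by exhaustive grid walk at `step` resolution.
mdr_grid_search <- function(power_fn, target_power, step = 1e-3, cap = 100) {
  ratio <- 1 + step
  while (ratio <= cap) {
    if (power_fn(ratio) >= target_power) return(ratio)
    ratio <- ratio + step
  }
  Inf
}

verify_report <- function(report, config) {
  rates <- report$rates[!is.na(report$rates$rate_per_1000), ]
  for (i in seq_len(nrow(rates))) {
    row <- rates[i, ]
    oracle <- cp_tailsum(row$numerator, row$denominator)
    if (abs(row$ci_low_per_1000 / 1000 - oracle[1]) > 1e-8 ||
        abs(row$ci_high_per_1000 / 1000 - oracle[2]) > 1e-8) {
      stop("verification failed: exact interval mismatch for ",
           row$site_id, "/", row$outcome, call. = FALSE)
    }
  }
  mdr <- report$detectable_risk
  for (i in seq_len(nrow(mdr))) {
    row <- mdr[i, ]
    if (!is.finite(row$point)) next
    d <- config$design
    power_fn <- if (row$measure == "relative_risk") {
      p0 <- row$x / row$n
      total <- row$annual_denominator * d$duration_years
      function(rr) power_two_proportions(
        rr * p0, total / (1 + d$cohort_exposed_ratio), p0,
        d$cohort_exposed_ratio * total / (1 + d$cohort_exposed_ratio),
        d$alpha)
    } else {
      n_cases <- (row$x / row$n) * row$annual_denominator * d$duration_years
      function(or) power_two_proportions(
        case_exposure_prob(or, d$exposure_prevalence_controls), n_cases,
        d$exposure_prevalence_controls, d$cc_control_ratio * n_cases,
        d$alpha)
    }
    grid_point <- mdr_grid_search(power_fn, d$target_power)
    if (abs(grid_point - row$point) > 1e-3 + 1e-6) {
      stop("verification failed: detectable-risk mismatch for ",
           row$site_id, "/", row$outcome, " (", row$measure, ")",
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' @export
print.surveillance_report <- function(x, ...) {
  prov <- x$provenance
  cat("<surveillance_report> perisurv", prov$version, "| mode:", prov$mode,
      "| seed:", prov$seed, "\n")
  cat("  rates:", nrow(x$rates), "rows\n")
  if (!is.null(x$ascertainment)) {
    cat("  ascertainment:", nrow(x$ascertainment), "rows\n")
  }
  cat("  detectable risk:", nrow(x$detectable_risk), "rows\n")
  invisible(x)
}
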