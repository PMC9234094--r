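#' Load a sex- and gestational-age-specific growth reference table
#'
#' Reads a delimited reference giving, per sex and completed gestational week
#' (24-42), the 10th-percentile, median and SD of birthweight (g) and the
#' 3rd-percentile, median and SD of head circumference (cm). These anchor the
#' small-for-gestational-age and congenital-microcephaly definitions. The
#' packaged default is a synthetic table built from a smooth, published-style
#' median/SD grid with percentiles derived under a normal model; substitute
#' any chart (INTERGROWTH-21st, Fenton, a national standard) by pointing
#' `path` at a file with the same header.
#'
#' @param path Path to a tab- or comma-delimited file with columns
#'   `sex`, `ga_week`, `weight_p10_g`, `weight_median_g`, `weight_sd_g`,
#'   `hc_p3_cm`, `hc_median_cm`, `hc_sd_cm`. Defaults to the packaged
#'   synthetic reference.
#' @return A tibble of class `growth_reference`, one row per (sex, week).
#' @export
#' @examples
#' ref <- load_growth_reference()
#' lookup_reference(ref, "male", 280, "weight_p10")
load_growth_reference <- function(path = NULL) {
  path <- path %||% system.file("extdata", "growth_reference_synthetic.tsv",
                                package = "perisurv", mustWork = TRUE)
  ref <- readr::read_delim(path, delim = guess_delim(path),
                           show_col_types = FALSE, progress = FALSE)
  required <- c("sex", "ga_week", "weight_p10_g", "weight_median_g",
                "weight_sd_g", "hc_p3_cm", "hc_median_cm", "hc_sd_cm")
  missing_cols <- setdiff(required, names(ref))
  if (length(missing_cols) > 0) {
    stop("growth reference is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  ref <- dplyr::arrange(ref, .data$sex, .data$ga_week)
  if (any(ref$weight_p10_g >= ref$weight_median_g)) {
    stop("growth reference invalid: weight p10 must be below the median",
         call. = FALSE)
  }
  bad_order <- ref |>
    dplyr::group_by(.data$sex) |>
    dplyr::summarise(ok = all(diff(.data$weight_median_g) > 0) &&
                       all(diff(.data$hc_median_cm) > 0)) |>
    dplyr::filter(!.data$ok)
  if (nrow(bad_order) > 0) {
    stop("growth reference invalid: medians must increase with gestational week",
         call. = FALSE)
  }
  class(ref) <- c("growth_reference", class(ref))
  ref
}

guess_delim <- function(path) {
  first <- readLines(path, n = 1)
  if (grepl("\t", first)) "\t" else ","
}

REFERENCE_MEASURES <- c("weight_p10", "weight_median", "weight_sd",
                        "hc_p3", "hc_median", "hc_sd")

reference_column <- function(measure) {
  switch(measure,
         weight_p10 = "weight_p10_g", weight_median = "weight_median_g",
         weight_sd = "weight_sd_g", hc_p3 = "hc_p3_cm",
         hc_median = "hc_median_cm", hc_sd = "hc_sd_cm",
         stop("unknown reference measure: ", measure, call. = FALSE))
}

#' Interpolate a growth-reference value at an exact gestational age
#'
#' Linearly interpolates between adjacent whole-week reference rows; at a
#' whole week the row value is returned exactly. Gestational ages outside
#' the reference span are clamped to its endpoints by default, a pragmatic
#' policy for the extremely preterm tail where no chart row exists.
#'
#' @param reference A `growth_reference` from [load_growth_reference()].
#' @param sex `"male"` or `"female"` (vectorised; must contain no `NA`).
#' @param gestational_age_days Gestational age in days (vectorised).
#' @param measure One of `"weight_p10"`, `"weight_median"`, `"weight_sd"`,
#'   `"hc_p3"`, `"hc_median"`, `"hc_sd"`.
#' @param clamp If `TRUE` (default), gestational ages outside the reference
#'   span evaluate at the nearest endpoint; if `FALSE` they raise an error.
#' @return Numeric vector of reference values (grams or cm).
#' @export
lookup_reference <- function(reference, sex, gestational_age_days, measure,
                             clamp = TRUE) {
  measure <- match.arg(measure, REFERENCE_MEASURES)
  if (any(is.na(sex))) stop("`sex` must not contain NA", call. = FALSE)
  if (!all(sex %in% c("male", "female"))) {
    stop("`sex` must be 'male' or 'female'", call. = FALSE)
  }
  col <- reference_column(measure)
  ga_weeks <- gestational_age_days / 7
  out <- rep(NA_real_, length(ga_weeks))
  for (s in unique(sex)) {
    rows <- reference[reference$sex == s, ]
    idx <- which(sex == s)
    w <- ga_weeks[idx]
    lo <- min(rows$ga_week)
    hi <- max(rows$ga_week)
    if (!clamp && any(w < lo | w > hi, na.rm = TRUE)) {
      stop("gestational age outside reference span [", lo * 7, ", ", hi * 7,
           "] days and clamping is disabled", call. = FALSE)
    }
    w <- pmin(pmax(w, lo), hi)
    out[idx] <- approx(rows$ga_week, rows[[col]], xout = w,
                       method = "linear", ties = "ordered")$y
  }
  out
}
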