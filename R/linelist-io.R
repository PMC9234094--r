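LINELIST_COLUMNS <- c("site_id", "birth_date", "delivery_outcome", "sex",
                      "gestational_age_days", "birthweight_g",
                      "head_circumference_cm", "neonatal_death_day",
                      "infection_subtype")

#' Write a birth line list as delimited text
#'
#' Tab-delimited, one header row, ISO-8601 dates, empty field for missing.
#' Round-trips through [read_linelist()].
#'
#' @param records A line list tibble (flag columns, if present, are kept).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_linelist <- function(records, path) {
  out <- records
  out$birth_date <- format(out$birth_date, "%Y-%m-%d")
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' Read a birth line list from delimited text
#'
#' Parses and validates a line list written by [write_linelist()] (or
#' prepared externally with the same header). Malformed rows — negative or
#' zero birthweight, gestational age outside [140, 315] days, neonatal
#' death day outside [0, 27], stillbirths carrying a death day or an
#' infection, unknown category levels — are not silently dropped: they are
#' collected into a rejects report with their line numbers.
#'
#' @param path Input path; the header must contain exactly the line-list
#'   schema columns (plus optional `flag_<outcome>` columns).
#' @return A list: `records` (typed tibble of accepted rows) and `rejects`
#'   (tibble with `line`, `reason`).
#' @export
read_linelist <- function(path) {
  raw <- readr::read_delim(path, delim = guess_delim(path),
                           col_types = readr::cols(.default = "c"),
                           na = c("", "NA"), show_col_types = FALSE,
                           progress = FALSE)
  flag_cols <- grep("^flag_", names(raw), value = TRUE)
  bad_flags <- setdiff(flag_cols, paste0("flag_", OUTCOMES))
  unknown <- setdiff(names(raw), c(LINELIST_COLUMNS, flag_cols))
  if (length(unknown) > 0 || length(bad_flags) > 0) {
    stop("unknown line-list columns: ",
         paste(c(unknown, bad_flags), collapse = ", "), call. = FALSE)
  }
  missing_cols <- setdiff(LINELIST_COLUMNS, names(raw))
  if (length(missing_cols) > 0) {
    stop("line list is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(raw) == 0) {
    empty <- tibble::tibble(site_id = character(),
                            birth_date = as.Date(character()),
                            delivery_outcome = character(),
                            sex = character(),
                            gestational_age_days = integer(),
                            birthweight_g = numeric(),
                            head_circumference_cm = numeric(),
                            neonatal_death_day = integer(),
                            infection_subtype = character())
    return(list(records = empty,
                rejects = tibble::tibble(line = integer(),
                                         reason = character())))
  }
  rec <- tibble::tibble(
    site_id = raw$site_id,
    birth_date = as.Date(raw$birth_date, format = "%Y-%m-%d"),
    delivery_outcome = raw$delivery_outcome,
    sex = raw$sex,
    gestational_age_days = suppressWarnings(as.integer(raw$gestational_age_days)),
    birthweight_g = suppressWarnings(as.numeric(raw$birthweight_g)),
    head_circumference_cm = suppressWarnings(as.numeric(raw$head_circumference_cm)),
    neonatal_death_day = suppressWarnings(as.integer(raw$neonatal_death_day)),
    infection_subtype = raw$infection_subtype %||% "none")
  rec$infection_subtype[is.na(rec$infection_subtype)] <- "none"
  for (fc in flag_cols) rec[[fc]] <- as.logical(raw[[fc]])

  reason <- rep(NA_character_, nrow(rec))
  note <- function(bad, why) {
    bad <- which(bad & is.na(reason))
    reason[bad] <<- why
  }
  note(is.na(rec$site_id) | is.na(rec$birth_date), "missing site or date")
  note(!rec$delivery_outcome %in% c("livebirth", "stillbirth"),
       "unknown delivery outcome")
  note(!is.na(rec$sex) & !rec$sex %in% c("male", "female"), "unknown sex")
  note(!is.na(rec$birthweight_g) & rec$birthweight_g <= 0,
       "impossible birthweight")
  note(!is.na(rec$gestational_age_days) &
         (rec$gestational_age_days < 140 | rec$gestational_age_days > 315),
       "gestational age outside [140, 315] days")
  note(!is.na(rec$neonatal_death_day) &
         (rec$neonatal_death_day < 0 | rec$neonatal_death_day > 27),
       "neonatal death day outside [0, 27]")
  note(rec$delivery_outcome == "stillbirth" &
         (!is.na(rec$neonatal_death_day) | rec$infection_subtype != "none"),
       "stillbirth with neonatal event")
  note(!rec$infection_subtype %in% c("none", INFECTION_SUBTYPES),
       "unknown infection subtype")

  bad <- !is.na(reason)
  list(records = rec[!bad, ],
       rejects = tibble::tibble(line = which(bad) + 1L,  # +1 for header row
                                reason = reason[bad]))
}
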