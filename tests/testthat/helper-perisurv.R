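# Shared fixtures. The packaged growth reference is loaded once per run.
ref <- load_growth_reference()

# A small, fully measured facility for fast simulation tests.
demo_profile <- function(...) {
  args <- list(site_id = "demo", annual_births = 2000,
               facility_level = "secondary", stillbirth_prob = 0.02,
               preterm_prob = 0.12, neonatal_death_prob = 0.015,
               infection_prob = 0.02)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(site_profile, args)
}

# One-row birth record with sensible defaults, overridable per test.
birth_record <- function(delivery_outcome = "livebirth", sex = "male",
                         gestational_age_days = 280L, birthweight_g = 3300,
                         head_circumference_cm = 34.5,
                         neonatal_death_day = NA_integer_,
                         infection_subtype = "none", site_id = "t",
                         birth_date = as.Date("2020-01-15")) {
  tibble::tibble(site_id = site_id, birth_date = birth_date,
                 delivery_outcome = delivery_outcome, sex = sex,
                 gestational_age_days = gestational_age_days,
                 birthweight_g = birthweight_g,
                 head_circumference_cm = head_circumference_cm,
                 neonatal_death_day = neonatal_death_day,
                 infection_subtype = infection_subtype)
}

# Independent Clopper-Pearson oracle: root-finding on binomial tail sums,
# avoiding the beta-quantile identity the implementation uses.
cp_oracle <- function(x, n, conf_level = 0.95) {
  alpha <- 1 - conf_level
  lo <- if (x == 0) 0 else {
    uniroot(function(p) 1 - pbinom(x - 1, n, p) - alpha / 2,
            c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  }
  hi <- if (x == n) 1 else {
    uniroot(function(p) pbinom(x, n, p) - alpha / 2,
            c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  }
  c(lo, hi)
}
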