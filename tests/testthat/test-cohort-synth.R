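test_that("identical (profile, seed) yields byte-identical line lists", {
  prof <- demo_profile()
  a <- simulate_site(prof, 11, ref)
  b <- simulate_site(prof, 11, ref)
  expect_identical(a, b)
  expect_false(identical(a, simulate_site(prof, 12, ref)))
  # the local seeding must not disturb the caller's RNG stream
  set.seed(99); before <- runif(3)
  set.seed(99); invisible(simulate_site(prof, 11, ref)); after <- runif(3)
  expect_identical(before, after)
})

test_that("zero-rate profiles simulate no events of those outcomes", {
  prof <- demo_profile(stillbirth_prob = 0, neonatal_death_prob = 0,
                       infection_prob = 0)
  recs <- simulate_site(prof, 3, ref)
  expect_true(all(recs$delivery_outcome == "livebirth"))
  expect_true(all(is.na(recs$neonatal_death_day)))
  expect_true(all(recs$infection_subtype == "none"))
})

test_that("record count tracks the configured load", {
  p1 <- demo_profile()
  expect_equal(nrow(simulate_site(p1, 5, ref)), 2000)
  p_half <- site_profile("demo", annual_births = 2000, duration_weeks = 26)
  expect_equal(nrow(simulate_site(p_half, 5, ref)), 1000)
  p_double <- site_profile("demo", annual_births = 4000)
  expect_equal(nrow(simulate_site(p_double, 5, ref)), 4000)
  expect_error(simulate_site(site_profile("demo", 2000, duration_weeks = 0),
                             1, ref), "empty cohort")
})

test_that("simulated records respect structural invariants", {
  recs <- simulate_site(demo_profile(), 17, ref)
  still <- recs[recs$delivery_outcome == "stillbirth", ]
  expect_true(all(is.na(still$neonatal_death_day)))
  expect_true(all(still$infection_subtype == "none"))
  dd <- recs$neonatal_death_day
  expect_true(all(is.na(dd) | (dd >= 0 & dd <= 27)))
  ga <- recs$gestational_age_days
  expect_true(all(ga >= 154 & ga <= 294))
  # classifier/simulator coherence: any livebirth below the reference p10
  # weight is SGA (stillbirths never carry livebirth-only labels)
  lab <- classify_births(recs, reference = ref)
  p10 <- lookup_reference(ref, recs$sex, ga, "weight_p10")
  live <- recs$delivery_outcome == "livebirth"
  expect_identical(lab$label_sga[live], (recs$birthweight_g < p10)[live])
  expect_true(all(!lab$label_sga[!live]))
})

test_that("invalid profile probabilities are rejected", {
  expect_error(site_profile("x", 1000, stillbirth_prob = 1.2), "\\[0, 1\\]")
  expect_error(site_profile("x", 1000,
                            infection_subtype_mix = c(0.5, 0.2, 0.2)),
               "sum to 1")
  expect_error(site_profile("x", 0), "annual_births")
})

test_that("perfect and null ascertainment flag exactly the right records", {
  prof <- demo_profile(
    measurement_missingness = c(gestational_age = 0.05, birthweight = 0.02,
                                head_circumference = 0.05))
  recs <- simulate_site(prof, 21, ref)
  perfect <- apply_site_ascertainment(recs, prof, 22, reference = ref)
  lab <- classify_births(recs, reference = ref)
  for (o in OUTCOMES) {
    expect_identical(perfect[[paste0("flag_", o)]],
                     lab[[paste0("label_", o)]])
  }
  none <- demo_profile(ascertainment_sensitivity = as.list(
    setNames(rep(0, length(OUTCOMES)), OUTCOMES)))
  unflagged <- apply_site_ascertainment(recs, none, 22, reference = ref)
  expect_true(all(!unlist(unflagged[paste0("flag_", OUTCOMES)])))
  # measurements are never altered by ascertainment
  expect_identical(perfect[names(recs)], recs)
})

test_that("partial sensitivity recovers the configured flag fraction", {
  prof <- site_profile("big", annual_births = 5000, preterm_prob = 0.3,
                       ascertainment_sensitivity = list(sga = 0.15))
  recs <- simulate_site(prof, 31, ref)
  flagged <- apply_site_ascertainment(recs, prof, 32, reference = ref)
  lab <- classify_births(recs, reference = ref)
  n_true <- sum(lab$label_sga)
  n_flag <- sum(flagged$flag_sga & lab$label_sga)
  ci <- clopper_pearson(n_flag, n_true)
  expect_gt(n_true, 200)
  expect_true(ci$ci_low <= 0.15 && 0.15 <= ci$ci_high)
  # false flags never arise when false_flag_prob is zero
  expect_true(all(lab$label_sga[flagged$flag_sga]))
})

test_that("monthly aggregates partition the line list", {
  prof <- demo_profile()
  recs <- apply_site_ascertainment(simulate_site(prof, 41, ref), prof, 42,
                                   reference = ref)
  monthly <- aggregate_monthly(recs)
  expect_equal(sum(monthly$births), nrow(recs))
  expect_equal(sum(monthly$livebirths),
               sum(recs$delivery_outcome == "livebirth"))
  expect_equal(sum(monthly$flag_preterm), sum(recs$flag_preterm))
  expect_equal(nrow(monthly), 12)
})

test_that("aggregates are invariant to record order and split by site", {
  p1 <- demo_profile()
  p2 <- site_profile("other", annual_births = 1000)
  recs <- dplyr::bind_rows(simulate_site(p1, 51, ref),
                           simulate_site(p2, 52, ref))
  shuffled <- recs[sample(nrow(recs)), ]
  expect_equal(aggregate_monthly(recs), aggregate_monthly(shuffled))
  monthly <- aggregate_monthly(recs)
  expect_equal(sum(monthly$births[monthly$site_id == "other"]), 1000)
  expect_equal(nrow(aggregate_monthly(recs[0, ])), 0)
})
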