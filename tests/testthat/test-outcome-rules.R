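test_that("strict thresholds: a value exactly at the cut-off is never a case", {
  cases <- list(
    list(rec = birth_record(birthweight_g = 2499), lab = "low_birthweight",
         present = TRUE),
    list(rec = birth_record(birthweight_g = 2500), lab = "low_birthweight",
         present = FALSE),
    list(rec = birth_record(gestational_age_days = 258L), lab = "preterm",
         present = TRUE),
    list(rec = birth_record(gestational_age_days = 259L), lab = "preterm",
         present = FALSE))
  for (cs in cases) {
    labels <- classify_birth(cs$rec, reference = ref)
    expect_identical(cs$lab %in% labels, cs$present)
  }
})

test_that("SGA boundary sits exactly at the packaged 10th percentile", {
  p10 <- ref$weight_p10_g[ref$sex == "male" & ref$ga_week == 40]
  below <- classify_birth(birth_record(birthweight_g = p10 - 1), reference = ref)
  at <- classify_birth(birth_record(birthweight_g = p10), reference = ref)
  expect_true("sga" %in% below)
  expect_false("sga" %in% at)
})

test_that("microcephaly rules use the configured head-circumference cut-off", {
  p3 <- ref$hc_p3_cm[ref$sex == "male" & ref$ga_week == 40]
  labels <- classify_birth(birth_record(head_circumference_cm = p3 - 0.1),
                           reference = ref)
  expect_true("microcephaly" %in% labels)
  med <- ref$hc_median_cm[ref$sex == "male" & ref$ga_week == 40]
  sd <- ref$hc_sd_cm[ref$sex == "male" & ref$ga_week == 40]
  cfg <- classification_config(microcephaly_rule = "minus3sd")
  rec <- birth_record(head_circumference_cm = med - 2.5 * sd)
  expect_true("microcephaly" %in% classify_birth(rec, reference = ref))
  expect_false("microcephaly" %in% classify_birth(rec, cfg, ref))
})

test_that("stillbirths carry exactly the stillbirth label", {
  rec <- birth_record(delivery_outcome = "stillbirth", birthweight_g = 1000,
                      gestational_age_days = 220L)
  expect_identical(classify_birth(rec, reference = ref), "stillbirth")
  # below the gestational-age floor it is not a registered stillbirth
  early <- birth_record(delivery_outcome = "stillbirth",
                        gestational_age_days = 180L)
  expect_length(classify_birth(early, reference = ref), 0)
  # missing gestational age counts by default, not when disabled
  noga <- birth_record(delivery_outcome = "stillbirth",
                       gestational_age_days = NA_integer_)
  expect_identical(classify_birth(noga, reference = ref), "stillbirth")
  cfg <- classification_config(stillbirth_count_missing_ga = FALSE)
  expect_length(classify_birth(noga, cfg, ref), 0)
})

test_that("neonatal death and infection rules respect the neonatal period", {
  expect_true("neonatal_death" %in% classify_birth(
    birth_record(neonatal_death_day = 27L), reference = ref))
  expect_true("neonatal_infection" %in% classify_birth(
    birth_record(infection_subtype = "meningitis"), reference = ref))
})

test_that("missing inputs drop labels and are tallied as unassessable", {
  recs <- dplyr::bind_rows(
    birth_record(birthweight_g = NA_real_),
    birth_record(gestational_age_days = NA_integer_, birthweight_g = 2000),
    birth_record())
  out <- classify_cohort(recs, reference = ref)
  counts <- out$counts
  expect_equal(counts$unassessable[counts$outcome == "low_birthweight"], 1)
  expect_equal(counts$unassessable[counts$outcome == "sga"], 2)
  # record 2 is LBW by weight alone even with missing gestational age
  expect_equal(counts$numerator[counts$outcome == "low_birthweight"], 1)
  # all livebirths stay in the denominator
  expect_equal(unique(counts$denominator), 3)
})

test_that("lowering birthweight never removes the LBW or SGA label", {
  set.seed(7)
  for (i in 1:20) {
    ga <- sample(168:294, 1)
    bw <- runif(1, 500, 4000)
    rec_hi <- birth_record(gestational_age_days = as.integer(ga),
                           birthweight_g = bw)
    rec_lo <- birth_record(gestational_age_days = as.integer(ga),
                           birthweight_g = bw - runif(1, 0, 800))
    hi <- classify_birth(rec_hi, reference = ref)
    lo <- classify_birth(rec_lo, reference = ref)
    for (lab in c("low_birthweight", "sga")) {
      if (lab %in% hi) expect_true(lab %in% lo)
    }
  }
})

test_that("cohort counts use livebirth and total-birth denominators correctly", {
  recs <- dplyr::bind_rows(
    birth_record(delivery_outcome = "stillbirth",
                 gestational_age_days = 220L),
    birth_record())
  counts <- classify_cohort(recs, reference = ref)$counts
  sb <- counts[counts$outcome == "stillbirth", ]
  lb <- counts[counts$outcome == "low_birthweight", ]
  expect_equal(sb$denominator, 2)
  expect_identical(sb$denominator_kind, "total_births")
  expect_equal(lb$denominator, 1)
  expect_identical(lb$denominator_kind, "livebirths")

  all_live <- dplyr::bind_rows(birth_record(), birth_record(sex = "female"))
  counts2 <- classify_cohort(all_live, reference = ref)$counts
  expect_equal(counts2$numerator[counts2$outcome == "stillbirth"], 0)
  expect_equal(unique(counts2$denominator), 2)
})
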