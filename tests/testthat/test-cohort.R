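test_that("cohort generation is deterministic given config and seed", {
  cfg <- cohort_config(n = 60)
  a <- generate_cohort(cfg, seed = 9)
  b <- generate_cohort(cfg, seed = 9)
  expect_identical(a$data, b$data)
  expect_identical(a$items, b$items)
  c2 <- generate_cohort(cfg, seed = 10)
  expect_false(identical(a$data$edeq, c2$data$edeq))
  # missingness is equally reproducible
  am <- impose_missingness(a, seed = 3)
  bm <- impose_missingness(b, seed = 3)
  expect_identical(am$data, bm$data)
})

test_that("cohort structure matches the design: 3 timepoints, day-0 admission", {
  ch <- generate_cohort(cohort_config(n = 50), seed = 4)
  d <- ch$data
  expect_equal(nrow(d), 150)
  expect_equal(sort(unique(as.character(d$timepoint))),
               sort(c("admission", "stepdown", "discharge")))
  expect_true(all(d$time_days[d$timepoint == "admission"] == 0))
  wide <- tidyr::pivot_wider(d[c("participant_id", "timepoint", "time_days")],
                             names_from = "timepoint", values_from = "time_days")
  expect_true(all(wide$stepdown > 0 & wide$stepdown < wide$discharge))
  expect_true(all(d$los_total == d$time_days[match(paste(d$participant_id, "discharge"),
                                                   paste(d$participant_id, d$timepoint))]))
  # scored scales live in their legal ranges
  expect_true(all(d$edeq >= 0 & d$edeq <= 6))
  expect_true(all(d$phq9 >= 0 & d$phq9 <= 27))
  expect_true(all(d$gad7 >= 0 & d$gad7 <= 21))
})

test_that("mixtures and admission distributions hit their targets at n = 2000", {
  ch <- cached_cohort()
  adm <- ch$data[ch$data$timepoint == "admission", ]
  n <- nrow(adm)
  mix <- ch$config$diagnosis_mix
  prop <- table(adm$diagnosis)[names(mix)] / n
  for (lev in names(mix)) {
    se <- sqrt(mix[lev] * (1 - mix[lev]) / n)
    expect_lt(abs(prop[lev] - mix[lev]), 3 * se)
  }
  expect_lt(abs(mean(adm$comorbid) - .797), 3 * sqrt(.797 * .203 / n))
  # admission means approximate the configured targets; clipping/rounding at
  # the item range edges biases the observed mean by a few percent at most
  expect_lt(abs(mean(adm$edeq) - 3.62), 0.05 * 3.62)
  expect_lt(abs(mean(adm$phq9) - 14.87), 0.6)
  expect_lt(abs(mean(adm$gad7) - 12.93), 0.5)
  # %EBW for AN admissions centres on the configured clinical mean
  an <- adm[adm$an_flag, ]
  expect_lt(abs(mean(an$pct_ebw_true) - 87.46),
            3 * 10.48 / sqrt(nrow(an)) + 0.1)
})

test_that("near-zero variance components put trajectories on the fixed-effect surface", {
  cfg <- cohort_config(
    n = 30,
    outcomes = list(edeq = list(mean = 3.5, slope = -0.01, icc = 0.5,
                                alpha = 0.96, sd = 1e-6),
                    phq9 = list(mean = 14, slope = -0.05, icc = 0.5,
                                alpha = 0.89, sd = 7.08),
                    gad7 = list(mean = 12, slope = -0.03, icc = 0.5,
                                alpha = 0.90, sd = 5.74))
  )
  ch <- generate_cohort(cfg, seed = 12)
  d <- ch$data
  expect_lt(max(abs(d$edeq_latent - (3.5 - 0.01 * d$time_days))), 1e-4)
})

test_that("generated items recover the target reliability", {
  set.seed(55)
  reg <- default_scale_registry()
  true_scores <- rnorm(2000, 12.93, 5.74)
  items <- generate_items(true_scores, reg$gad7, target_alpha = 0.90, seed = 77)
  a <- cronbach_alpha(items)
  expect_gt(a, 0.88); expect_lt(a, 0.92)
  # zero noise makes items parallel copies: alpha at the ceiling
  items0 <- generate_items(true_scores, reg$gad7, target_alpha = 0.90,
                           seed = 77, noise_sd = 0)
  expect_gt(cronbach_alpha(items0), 0.999)
  expect_error(generate_items(true_scores, reg$gad7, target_alpha = 1.2, seed = 1),
               "target_alpha")
})

test_that("MAR missingness is calibrated, covariate-ordered, and optional", {
  ch <- cached_cohort()
  d <- ch$data
  for (tp in c("stepdown", "discharge")) {
    target <- ch$config$missingness[[paste0(tp, "_rate")]]
    emp <- mean(is.na(d$edeq[d$timepoint == tp]))
    se <- sqrt(target * (1 - target) / ch$config$n)
    expect_lt(abs(emp - target), 2 * se + 1e-9)
  }
  expect_false(anyNA(d$edeq[d$timepoint == "admission"]))
  # configured direction: comorbid participants more likely complete
  adm <- d[d$timepoint == "admission", ]
  miss_d <- tapply(adm$missing_discharge, adm$comorbid, mean)
  expect_lt(miss_d[["TRUE"]], miss_d[["FALSE"]])
  # rate 0 leaves the cohort intact
  cfg0 <- cohort_config(n = 40)
  cfg0$missingness$stepdown_rate <- 0
  cfg0$missingness$discharge_rate <- 0
  ch0 <- generate_cohort(cfg0, seed = 2)
  ch0m <- impose_missingness(ch0, seed = 3)
  expect_false(anyNA(ch0m$data$edeq))
})

test_that("strong covariate effects order the conditional missingness rates", {
  cfg <- cohort_config(n = 1500)
  cfg$missingness$coef <- c(pct_ebw_z = 0, cis_female = 0, an_r = 0,
                            comorbid = -2, routine = 0)
  ch <- impose_missingness(generate_cohort(cfg, seed = 8), seed = 9)
  adm <- ch$data[ch$data$timepoint == "admission", ]
  p <- tapply(adm$missing_discharge, adm$comorbid, mean)
  # analytic check: with a logit gap of 2, the two conditional rates differ a lot
  expect_gt(p[["FALSE"]] - p[["TRUE"]], 0.25)
  # marginal rate still calibrated by the intercept
  expect_lt(abs(mean(adm$missing_discharge) - .556), 2 * sqrt(.556 * .444 / 1500))
})

test_that("fixed effects are recovered from a cohort with MAR gaps", {
  ch <- cached_cohort()
  truth <- ch$truth$outcomes$edeq
  fit <- fit_lmm(ch$data, edeq_latent ~ time_days + age_admission + los_total)
  expect_lt(abs(fit$beta["time_days"] - truth$slope), 3 * fit$se["time_days"])
  expect_lt(abs(fit$beta["age_admission"]), 3 * fit$se["age_admission"])
  # variance components are in the right neighbourhood
  expect_lt(abs(fit$sigma2_b - truth$sigma2_b), 0.25 * truth$sigma2_b)
  expect_lt(abs(fit$sigma2_e - truth$sigma2_e), 0.25 * truth$sigma2_e)
})

test_that("a cohort with a strong true improvement is dominated by clinically significant change", {
  cfg <- cohort_config(n = 400)
  ch <- generate_cohort(cfg, seed = 31)
  scores <- tidyr::pivot_longer(
    ch$data[c("participant_id", "timepoint", "edeq", "phq9", "gad7")],
    c("edeq", "phq9", "gad7"), names_to = "scale", values_to = "value"
  )
  tab <- change_table(scores)
  ede_dis <- tab[tab$scale == "edeq" & tab$interval == "admit_to_discharge", ]
  expect_equal(as.character(ede_dis$category[which.max(ede_dis$n)]),
               "clinically_significant")
  # with a zero slope, unchanged + normative dominate
  cfg0 <- cohort_config(n = 400)
  cfg0$outcomes <- lapply(cfg0$outcomes, function(o) { o$slope <- 0; o })
  ch0 <- generate_cohort(cfg0, seed = 32)
  s0 <- tidyr::pivot_longer(
    ch0$data[c("participant_id", "timepoint", "edeq", "phq9", "gad7")],
    c("edeq", "phq9", "gad7"), names_to = "scale", values_to = "value"
  )
  t0 <- change_table(s0)
  e0 <- t0[t0$scale == "edeq" & t0$interval == "admit_to_discharge", ]
  share <- sum(e0$pct[e0$category %in% c("unchanged", "normative")])
  expect_gt(share, 50)
})

test_that("config validation rejects infeasible settings", {
  expect_error(cohort_config(n = 0), "n")
  expect_error(cohort_config(nope = 1), "unknown config")
  bad <- cohort_config(n = 10)
  bad$diagnosis_mix <- c("AN-R" = 0.9, "BN" = 0.4)
  expect_error(generate_cohort(bad, seed = 1), "sum to 1")
  bad2 <- cohort_config(n = 10)
  bad2$missingness$discharge_rate <- 1.2
  expect_error(generate_cohort(bad2, seed = 1), "rates")
  expect_error(generate_cohort(cohort_config(n = 5)), "seed")
})
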