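#' Configuration for the synthetic cohort generator
#'
#' Returns the full default configuration emulating the study cohort the
#' pipeline was built for: 1,971 adolescents admitted to higher levels of
#' care, assessed at admission, first stepdown and discharge. Defaults encode
#' the published descriptives: the diagnostic mixture (AN-R .464, AN-BP .141,
#' BN .057, BED .019, OSFED/UFED .319), comorbidity prevalence .797,
#' admitting level-of-care mixture (IP .153, RES .435, PHP .351, IOP .061),
#' admission score means/SDs per scale, total length of stay 79.97 (49.56)
#' days with level-of-care-specific stepdown timing, item-reliability targets
#' (alpha .96/.89/.90), %EBW for AN admissions 87.46 (10.48) with a mean gain
#' of 16.43 (10.87) by discharge, and covariate-dependent missingness
#' targeting 23.3% at stepdown and 55.6% at discharge. Time slopes default to
#' the scale of the published fixed effects (about -0.01 to -0.06 score units
#' per day, chosen so admission-to-discharge change over a mean stay matches
#' the printed descriptive means).
#'
#' @param n Number of participants.
#' @param ... Named overrides for any top-level config entry.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n = 1971, ...) {
  mean_los <- 79.97
  cfg <- list(
    n = n,
    diagnosis_mix = c("AN-R" = .464, "AN-BP" = .141, "BN" = .057,
                      "BED" = .019, "OSFED/UFED" = .319),
    comorbid_prev = .797,
    loc_mix = c(IP = .153, RES = .435, PHP = .351, IOP = .061),
    gender_mix = c(cis_female = .853, cis_male = .071, nonbinary = .049,
                   trans_ftm = .020, trans_mtf = .005, other = .002),
    sex_female_prob = .922,
    region_mix = c(South = .35, West = .30, Midwest = .20, Northeast = .15),
    discharge_reason_mix = c(routine = .667, patient_request = .190,
                             required_other_care = .048, administrative = .043,
                             other = .017, resource = .015, covid = .013,
                             ama = .009),
    age = list(mean = 14.84, sd = 1.64, min = 9, max = 18),
    los = list(mean = mean_los, sd = 49.56, min = 3, max = 386),
    stepdown_los = list(
      IP = c(mean = 25.93, sd = 20.76), RES = c(mean = 42.72, sd = 23.51),
      PHP = c(mean = 38.75, sd = 20.00), IOP = c(mean = 45.49, sd = 22.16)
    ),
    # per-scale latent trajectory: admission mean/SD from the descriptive
    # table; slope so that mean change over a mean-length stay matches the
    # printed admission-to-discharge difference; ICC 0.6 splits the admission
    # variance into intercept and residual components.
    outcomes = list(
      edeq = list(mean = 3.62, sd = 1.59, slope = (2.27 - 3.62) / mean_los,
                  icc = 0.6, alpha = 0.96),
      phq9 = list(mean = 14.87, sd = 7.08, slope = (10.33 - 14.87) / mean_los,
                  icc = 0.6, alpha = 0.89),
      gad7 = list(mean = 12.93, sd = 5.74, slope = (10.61 - 12.93) / mean_los,
                  icc = 0.6, alpha = 0.90)
    ),
    # count-model truth on the log scale; intercepts and per-day slopes echo
    # the magnitude of the published binge/vomit fixed effects
    nb = list(
      binge = list(diagnoses = c("AN-BP", "BN", "BED"), intercept = 1.44,
                   slope = -0.04, sigma2_b = 0.5, theta = 1.5),
      vomit = list(diagnoses = c("AN-BP", "BN"), intercept = 2.76,
                   slope = -0.08, sigma2_b = 0.5, theta = 1.5)
    ),
    ebw = list(
      an_admit = c(mean = 87.46, sd = 10.48),
      an_gain = c(mean = 16.43, sd = 10.87),
      # non-AN values are not printed; means chosen so the full-sample
      # admission/discharge %EBW means (99.10 / 111.80) are reproduced given
      # the AN share of the mixture.
      other_admit = c(mean = 117, sd = 25),
      other_gain = c(mean = 7, sd = 10),
      floor = 40,
      height_sd = 0.06
    ),
    missingness = list(
      stepdown_rate = 0.233, discharge_rate = 0.556,
      # positive = more likely MISSING; signs invert the reported
      # more-likely-complete associations (lower admission %EBW, cisgender
      # female, AN-R, comorbidity, routine discharge).
      coef = c(pct_ebw_z = 0.25, cis_female = -0.35, an_r = -0.30,
               comorbid = -0.30, routine = -0.40)
    )
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown config entries: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  cfg <- utils::modifyList(cfg, dots)
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  if (!(cfg$n >= 1)) stop("config: `n` must be >= 1", call. = FALSE)
  for (mix in c("diagnosis_mix", "loc_mix", "gender_mix", "region_mix",
                "discharge_reason_mix")) {
    if (abs(sum(cfg[[mix]]) - 1) > 0.01) {
      stop("config: `", mix, "` must sum to 1", call. = FALSE)
    }
    if (any(cfg[[mix]] < 0)) stop("config: `", mix, "` has negative entries",
                                  call. = FALSE)
  }
  for (oc in names(cfg$outcomes)) {
    o <- cfg$outcomes[[oc]]
    if (o$sd <= 0) stop("config: outcome '", oc, "' needs sd > 0", call. = FALSE)
    if (o$icc < 0 || o$icc > 1) stop("config: icc must be in [0,1]", call. = FALSE)
    if (o$alpha <= 0 || o$alpha >= 1) {
      stop("config: item-reliability target must be in (0,1)", call. = FALSE)
    }
  }
  rates <- cfg$missingness
  if (rates$stepdown_rate < 0 || rates$stepdown_rate >= 1 ||
      rates$discharge_rate < 0 || rates$discharge_rate >= 1) {
    stop("config: missingness rates must lie in [0, 1)", call. = FALSE)
  }
  invisible(cfg)
}

rtruncnorm1 <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  # inverse-CDF truncation: exact and cheap for the mild truncation used here
  u <- stats::runif(n)
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + u * (phi - plo), mean, sd)
}

# Calibrate the parallel-items noise SD so the population alpha of the
# *discretized* (rounded + clipped) items matches the target. Uses a fixed
# internal error matrix (independent of any user seed) and a two-stage grid
# search; rounding and clipping attenuate alpha, so the Spearman-Brown
# closed form only brackets the answer.
item_noise_sd <- function(latent, spec, target_alpha) {
  k <- spec$n_items
  n <- length(latent)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(104729L)
  E <- matrix(stats::rnorm(n * k), n, k)
  alpha_at <- function(sig) {
    items <- discretize_items(latent + sig * E, spec)
    tryCatch(cronbach_alpha(items), error = function(e) NA_real_)
  }
  var_lat <- stats::var(latent)
  if (var_lat <= 0) stop("latent scores have zero variance; cannot calibrate items",
                         call. = FALSE)
  r <- target_alpha / (k - target_alpha * (k - 1))
  sig0 <- sqrt(var_lat * (1 / r - 1))
  grid <- sig0 * exp(seq(log(0.05), log(20), length.out = 41))
  a <- vapply(grid, alpha_at, numeric(1))
  ok <- !is.na(a)
  if (!any(ok) || max(a[ok]) < target_alpha - 0.02) {
    stop("item-reliability target ", target_alpha, " infeasible for scale '",
         spec$name, "' given its discretization; widen the item range",
         call. = FALSE)
  }
  best <- grid[ok][which.min(abs(a[ok] - target_alpha))]
  fine <- best * exp(seq(-0.35, 0.35, length.out = 21))
  af <- vapply(fine, alpha_at, numeric(1))
  fine[which.min(abs(af - target_alpha))]
}

discretize_items <- function(latent_mat, spec) {
  items <- pmin(pmax(round(latent_mat), spec$item_min), spec$item_max)
  colnames(items) <- paste0("item_", seq_len(ncol(items)))
  items
}

#' Generate item-level responses for given true scores
#'
#' Parallel-items model: each item is the (per-item) true score plus
#' independent Gaussian noise, rounded to the item grid and clipped to the
#' response range. The noise SD is calibrated (on an internal, fixed error
#' matrix, so calibration is independent of `seed`) so that the population
#' Cronbach's alpha of the discretized items equals `target_alpha`; at
#' n = 2000 the empirical alpha lands within about +/-0.02 of the target.
#' For sum scales the per-item true score is `true_score / n_items`; for
#' subscale-mean scales it is the true score itself.
#'
#' @param true_score Numeric vector of true scale scores (one per respondent).
#' @param spec A [scale_spec()].
#' @param target_alpha Target reliability in (0, 1).
#' @param seed Seed for the response noise.
#' @param noise_sd Optional pre-calibrated noise SD (skips calibration).
#' @return A numeric matrix (respondents x items) with columns `item_1 ...`.
#' @export
generate_items <- function(true_score, spec, target_alpha, seed,
                           noise_sd = NULL) {
  stopifnot(inherits(spec, "scale_spec"))
  if (!is.null(target_alpha) &&
      (target_alpha <= 0 || target_alpha >= 1)) {
    stop("`target_alpha` must be in (0, 1)", call. = FALSE)
  }
  latent <- if (spec$scoring == "sum") true_score / spec$n_items else true_score
  if (is.null(noise_sd)) {
    noise_sd <- item_noise_sd(latent, spec, target_alpha)
  }
  set.seed(seed)
  E <- matrix(stats::rnorm(length(latent) * spec$n_items),
              length(latent), spec$n_items)
  discretize_items(latent + noise_sd * E, spec)
}

#' Generate a synthetic treatment cohort
#'
#' Draws a fully seeded cohort with the longitudinal structure the analysis
#' pipeline expects: demographics and diagnoses from the configured mixtures;
#' three assessment rows per participant (admission day 0, stepdown at the
#' admitting level of care's typical length of stay, discharge at the total
#' length of stay); latent symptom trajectories from a random-intercept
#' model, observed through calibrated item-level responses so scored scales
#' inherit realistic discreteness; negative-binomial binge/vomit counts for
#' the binge/purge diagnoses; and weights following %EBW trajectories through
#' a growth reference. The truth record retains every generating parameter
#' for parameter-recovery tests. Identical config + seed gives an identical
#' cohort.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed (mandatory).
#' @param growth_table A [growth_reference()] for the weight arm (default the
#'   synthetic fixture).
#' @return An object of class `synthetic_cohort`: a list with `data` (long
#'   tibble, one row per participant x timepoint), `items` (named list of
#'   item-level tibbles per scale), `truth` (generating parameters), `config`
#'   and `seed`. For each scale the data carry both the observed score
#'   (`edeq`, ...) and the model-scale latent trajectory (`edeq_latent`, ...):
#'   the latent column follows the generating random-intercept model exactly,
#'   while the observed score sees it through the bounded, discrete items and
#'   is therefore slightly attenuated at the range edges.
#' @export
generate_cohort <- function(config = cohort_config(), seed,
                            growth_table = synthetic_growth_reference()) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  validate_cohort_config(config)
  set.seed(seed)
  n <- config$n
  registry <- default_scale_registry()

  draw_mix <- function(mix) {
    factor(sample(names(mix), n, replace = TRUE, prob = mix / sum(mix)),
           levels = names(mix))
  }
  participants <- tibble::tibble(
    participant_id = sprintf("P%05d", seq_len(n)),
    diagnosis = draw_mix(config$diagnosis_mix),
    comorbid = stats::rbinom(n, 1, config$comorbid_prev) == 1,
    loc_admit = draw_mix(config$loc_mix),
    gender = draw_mix(config$gender_mix),
    sex = ifelse(stats::runif(n) < config$sex_female_prob, "female", "male"),
    region = draw_mix(config$region_mix),
    discharge_reason = draw_mix(config$discharge_reason_mix),
    age_admission = rtruncnorm1(n, config$age$mean, config$age$sd,
                                config$age$min, config$age$max)
  )
  participants$an_flag <- participants$diagnosis %in% c("AN-R", "AN-BP")
  participants$loc_group <- ifelse(participants$loc_admit %in% c("IP", "RES"),
                                   "IP/RES", "PHP/IOP")
  participants$los_total <- round(rtruncnorm1(n, config$los$mean, config$los$sd,
                                              config$los$min, config$los$max))
  sd_par <- do.call(rbind, config$stepdown_los[as.character(participants$loc_admit)])
  stepdown_raw <- round(rtruncnorm1(n, sd_par[, "mean"], sd_par[, "sd"],
                                    1, Inf))
  participants$stepdown_day <- pmin(stepdown_raw, participants$los_total - 1)

  long <- tidyr::crossing(participant_id = participants$participant_id,
                          timepoint = factor(c("admission", "stepdown", "discharge"),
                                             levels = c("admission", "stepdown",
                                                        "discharge"))) |>
    dplyr::left_join(participants, by = "participant_id") |>
    dplyr::mutate(time_days = dplyr::case_when(
      .data$timepoint == "admission" ~ 0,
      .data$timepoint == "stepdown" ~ as.numeric(.data$stepdown_day),
      TRUE ~ as.numeric(.data$los_total)
    )) |>
    dplyr::arrange(.data$participant_id, .data$timepoint)
  idx <- match(long$participant_id, participants$participant_id)

  # latent symptom trajectories and item-level observation
  truth <- list(seed = seed, outcomes = list(), nb = config$nb,
                ebw = config$ebw, missingness = NULL)
  items <- list()
  for (sc in names(config$outcomes)) {
    o <- config$outcomes[[sc]]
    spec <- registry[[sc]]
    s2b <- o$icc * o$sd^2
    s2e <- (1 - o$icc) * o$sd^2
    b <- stats::rnorm(n, 0, sqrt(s2b))
    # model-scale (latent) trajectory: exactly the random-intercept model;
    # the observed score below sees it through the discrete, bounded items
    true_long <- o$mean + o$slope * long$time_days + b[idx] +
      stats::rnorm(nrow(long), 0, sqrt(s2e))
    noise_sd <- item_noise_sd(
      if (spec$scoring == "sum") true_long[long$timepoint == "admission"] / spec$n_items
      else true_long[long$timepoint == "admission"],
      spec, o$alpha
    )
    latent <- if (spec$scoring == "sum") true_long / spec$n_items else true_long
    E <- matrix(stats::rnorm(length(latent) * spec$n_items),
                length(latent), spec$n_items)
    item_mat <- discretize_items(latent + noise_sd * E, spec)
    items[[sc]] <- dplyr::bind_cols(
      tibble::tibble(participant_id = long$participant_id,
                     timepoint = long$timepoint),
      tibble::as_tibble(item_mat)
    )
    long[[sc]] <- score_items(items[[sc]], spec)$value
    long[[paste0(sc, "_latent")]] <- true_long
    truth$outcomes[[sc]] <- list(mean = o$mean, slope = o$slope,
                                 sigma2_b = s2b, sigma2_e = s2e,
                                 alpha = o$alpha, item_noise_sd = noise_sd)
  }

  # negative-binomial counts for the binge/purge diagnoses
  for (ct in names(config$nb)) {
    nb <- config$nb[[ct]]
    col <- paste0(ct, "_count")
    applies <- participants$diagnosis %in% nb$diagnoses
    b <- stats::rnorm(n, 0, sqrt(nb$sigma2_b))
    mu <- exp(nb$intercept + nb$slope * long$time_days + b[idx])
    counts <- stats::rnbinom(nrow(long), size = nb$theta, mu = mu)
    counts[!applies[idx]] <- NA_integer_
    long[[col]] <- counts
  }

  # %EBW trajectories -> observed weights through the growth reference
  eb <- config$ebw
  a_frac <- participants$age_admission * 12 / 240
  mult <- ifelse(participants$sex == "male", 1.04, 1.0)
  h_mean <- (0.80 + 0.95 * a_frac - 0.18 * a_frac^2) * mult
  participants$height_m <- stats::rnorm(n, h_mean, eb$height_sd)
  adm_pct <- ifelse(participants$an_flag,
                    stats::rnorm(n, eb$an_admit["mean"], eb$an_admit["sd"]),
                    stats::rnorm(n, eb$other_admit["mean"], eb$other_admit["sd"]))
  gain <- ifelse(participants$an_flag,
                 stats::rnorm(n, eb$an_gain["mean"], eb$an_gain["sd"]),
                 stats::rnorm(n, eb$other_gain["mean"], eb$other_gain["sd"]))
  adm_pct <- pmax(adm_pct, eb$floor)
  pct_long <- pmax(adm_pct[idx] + gain[idx] * long$time_days /
                     pmax(long$los_total, 1), eb$floor)
  long$age_months <- participants$age_admission[idx] * 12 +
    long$time_days / 30.44
  ew <- expected_body_weight(sex = long$sex,
                             age_months = pmin(long$age_months, 240),
                             height_m = participants$height_m[idx],
                             table = growth_table)
  long$height_m <- participants$height_m[idx]
  long$weight_kg <- pct_long / 100 * ew
  long$pct_ebw_true <- pct_long

  # participant-level admission severity covariate for predictor models
  adm_edeq <- long$edeq[long$timepoint == "admission"]
  long$admission_edeq <- adm_edeq[idx]
  long$pct_ebw_admission <- adm_pct[idx]
  long$episode <- 1L

  truth$heights <- list(sd = eb$height_sd)
  structure(list(data = long, items = items, truth = truth,
                 config = config, seed = seed),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort> ", x$config$n, " participants x 3 timepoints, seed ",
      x$seed, "\n", sep = "")
  cat("  outcomes:", paste(names(x$config$outcomes), collapse = ", "),
      "+ binge/vomit counts + weight\n")
  miss <- x$truth$missingness
  if (is.null(miss)) cat("  missingness: none imposed\n")
  else cat("  missingness imposed: stepdown", round(100 * miss$stepdown_rate, 1),
           "%, discharge", round(100 * miss$discharge_rate, 1), "%\n")
  invisible(x)
}

# Solve the logit intercept so the cohort-average missingness probability
# hits the target rate; monotone, so plain bisection.
calibrate_logit_intercept <- function(eta_cov, target) {
  f <- function(a) mean(stats::plogis(a + eta_cov)) - target
  lo <- -30; hi <- 30
  if (f(lo) > 0 || f(hi) < 0) {
    stop("missingness target ", target, " unattainable given covariate effects",
         call. = FALSE)
  }
  stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
}

#' Impose covariate-dependent (MAR) missingness on a synthetic cohort
#'
#' A logistic model on *observed* admission covariates (admission %EBW,
#' gender, diagnosis, comorbidity, discharge reason) drives missingness of
#' the stepdown and discharge assessments; the logit intercept is calibrated
#' by bisection so the marginal rates hit the configured targets. Admission
#' data are never missing, so the mechanism is missing-at-random with respect
#' to the modelled covariates. Missing assessments have every outcome (scale
#' scores, items, counts, weight) set to `NA`; the rows remain.
#'
#' @param cohort A `synthetic_cohort`.
#' @param config Usually `cohort$config`; only the `missingness` entry is used.
#' @param seed Seed for the missingness draws.
#' @return The cohort with gaps, with columns `missing_stepdown` /
#'   `missing_discharge` added to `data` and calibration results recorded in
#'   `truth$missingness`.
#' @export
impose_missingness <- function(cohort, config = cohort$config, seed) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  mc <- config$missingness
  d <- cohort$data
  adm <- d[d$timepoint == "admission", ]
  z <- as.numeric(scale(adm$pct_ebw_admission))
  if (all(is.na(z)) || stats::sd(adm$pct_ebw_admission) == 0) z <- rep(0, nrow(adm))
  eta_cov <- mc$coef["pct_ebw_z"] * z +
    mc$coef["cis_female"] * (adm$gender == "cis_female") +
    mc$coef["an_r"] * (adm$diagnosis == "AN-R") +
    mc$coef["comorbid"] * adm$comorbid +
    mc$coef["routine"] * (adm$discharge_reason == "routine")
  eta_cov <- as.numeric(eta_cov)
  set.seed(seed)
  plan <- list()
  for (tp in c("stepdown", "discharge")) {
    target <- mc[[paste0(tp, "_rate")]]
    if (target == 0) {
      miss <- rep(FALSE, nrow(adm))
      a <- -Inf
    } else {
      a <- calibrate_logit_intercept(eta_cov, target)
      miss <- stats::runif(nrow(adm)) < stats::plogis(a + eta_cov)
    }
    plan[[tp]] <- list(intercept = a, missing = miss)
  }
  outcome_cols <- intersect(c("edeq", "phq9", "gad7",
                              "edeq_latent", "phq9_latent", "gad7_latent",
                              "binge_count", "vomit_count", "weight_kg"),
                            names(d))
  for (tp in c("stepdown", "discharge")) {
    miss_ids <- adm$participant_id[plan[[tp]]$missing]
    rows <- d$timepoint == tp & d$participant_id %in% miss_ids
    d[rows, outcome_cols] <- NA
    d[[paste0("missing_", tp)]] <- d$participant_id %in% miss_ids
    for (sc in names(cohort$items)) {
      it <- cohort$items[[sc]]
      irows <- it$timepoint == tp & it$participant_id %in% miss_ids
      it[irows, grep("^item_", names(it))] <- NA
      cohort$items[[sc]] <- it
    }
  }
  cohort$data <- d
  cohort$truth$missingness <- list(
    stepdown_rate = mc$stepdown_rate, discharge_rate = mc$discharge_rate,
    stepdown_intercept = plan$stepdown$intercept,
    discharge_intercept = plan$discharge$intercept,
    coef = mc$coef, seed = seed
  )
  cohort
}
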