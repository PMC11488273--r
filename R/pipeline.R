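#' Configuration for a full pipeline run
#'
#' @param input Either `"synthetic"` (generate a cohort from `cohort`) or the
#'   path to a long-format CSV with the columns described in [preprocess()].
#' @param cohort A [cohort_config()] used when `input = "synthetic"`.
#' @param seed Integer seed (mandatory; drives generation, missingness and
#'   bootstrap).
#' @param registry Scale registry (named list of [scale_spec()]s).
#' @param growth_table A [growth_reference()]; default the synthetic fixture.
#' @param z Confidence multiplier for reliable-change thresholds.
#' @param boot Bootstrap replicates for partial R-squared intervals (0 skips).
#' @param m_tests Family size for the Bonferroni threshold (default 17, the
#'   number of models in the default analysis family).
#' @param impose_missing Whether to impose the configured MAR missingness on
#'   a synthetic cohort before analysis.
#' @param output_dir Optional directory; when given, [run_pipeline()] writes
#'   the report bundle there as CSV/markdown.
#' @return A list of class `run_config`.
#' @export
run_config <- function(input = "synthetic", cohort = cohort_config(),
                       seed, registry = default_scale_registry(),
                       growth_table = synthetic_growth_reference(),
                       z = 1.96, boot = 0, m_tests = 17L,
                       impose_missing = TRUE, output_dir = NULL) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  structure(list(input = input, cohort = cohort, seed = seed,
                 registry = registry, growth_table = growth_table, z = z,
                 boot = boot, m_tests = m_tests,
                 impose_missing = impose_missing, output_dir = output_dir),
            class = "run_config")
}

descriptives_table <- function(data, vars) {
  purrr::map_dfr(vars, function(v) {
    x <- data[[v]]
    tibble::tibble(variable = v, mean = mean(x, na.rm = TRUE),
                   sd = stats::sd(x, na.rm = TRUE),
                   min = suppressWarnings(min(x, na.rm = TRUE)),
                   max = suppressWarnings(max(x, na.rm = TRUE)),
                   n = sum(!is.na(x)))
  })
}

model_report <- function(fit, outcome, subsample, threshold, boot, seed) {
  td <- tidy(fit)
  td$outcome <- outcome
  td$subsample <- subsample
  td$significant <- td$p.value < threshold
  if (inherits(fit, "lmm_fit")) {
    labels <- attr(fit$terms, "term.labels")
    r2 <- purrr::map_dfr(labels, function(tm) {
      partial_r2(fit, tm, boot = boot, seed = seed)
    })
    td <- dplyr::left_join(
      td,
      dplyr::select(r2, term = "term", partial_r2 = "partial_r2",
                    r2_conf.low = "conf.low", r2_conf.high = "conf.high"),
      by = "term"
    )
  }
  dplyr::select(td, "outcome", "subsample", dplyr::everything())
}

#' Run the end-to-end outcome analysis
#'
#' Executes the full pipeline: preprocess (first-stay rule, count-outlier
#' screen, time since admission) -> change thresholds -> five-category change
#' classification and change tables per admitting group -> %EBW -> models
#' (per-subsample symptom and weight trajectories, pooled predictor models
#' with simple-coded diagnosis, post-hoc region models with level-of-care
#' control, negative-binomial count models) -> missingness diagnostics. All
#' stochastic steps derive from `config$seed`, so a rerun is identical.
#'
#' @param config A [run_config()].
#' @return A list of class `report_bundle`: `descriptives`, `thresholds`,
#'   `change_tables`, `models` (tibble of coefficient rows across models),
#'   `missingness`, `exclusions`, and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (identical(config$input, "synthetic")) {
    if (config$cohort$n < 1) stop("config: n must be >= 1", call. = FALSE)
    cohort <- generate_cohort(config$cohort, seed = config$seed,
                              growth_table = config$growth_table)
    if (config$impose_missing) {
      cohort <- impose_missingness(cohort, seed = config$seed + 1L)
    }
    raw <- cohort$data
  } else {
    raw <- tibble::as_tibble(utils::read.csv(config$input,
                                             stringsAsFactors = FALSE))
    raw$timepoint <- factor(raw$timepoint,
                            levels = c("admission", "stepdown", "discharge"))
  }

  data <- preprocess(raw)
  if (!"an_flag" %in% names(data) && "diagnosis" %in% names(data)) {
    data$an_flag <- data$diagnosis %in% c("AN-R", "AN-BP")
  }
  if (!"loc_group" %in% names(data) && "loc_admit" %in% names(data)) {
    data$loc_group <- ifelse(data$loc_admit %in% c("IP", "RES"),
                             "IP/RES", "PHP/IOP")
  }
  scales <- intersect(names(config$registry), names(data))
  thresholds <- change_thresholds(config$registry, z = config$z)

  scores_long <- data |>
    dplyr::select(dplyr::all_of(c("participant_id", "timepoint", "loc_group",
                                  scales))) |>
    tidyr::pivot_longer(dplyr::all_of(scales), names_to = "scale",
                        values_to = "value")
  change_tables <- change_table(scores_long, thresholds, strata = "loc_group")

  if (!"percent_ebw" %in% names(data) &&
      all(c("sex", "age_months", "weight_kg", "height_m") %in% names(data))) {
    data <- add_percent_ebw(data, table = config$growth_table)
  }

  threshold <- bonferroni(0.05, config$m_tests)
  models <- list()
  seed_i <- config$seed + 100L

  # symptom and weight trajectories per admitting group
  for (grp in unique(data$loc_group)) {
    sub <- data[data$loc_group == grp, ]
    for (oc in scales) {
      fml <- stats::as.formula(paste(oc, "~ time_days + age_admission + los_total"))
      fit <- fit_lmm(sub, fml)
      models[[length(models) + 1L]] <-
        model_report(fit, oc, grp, threshold, config$boot, seed_i)
    }
    an <- if ("percent_ebw" %in% names(sub)) {
      sub[sub$an_flag & !sub$ebw_out_of_grid, ]
    } else sub[0, ]
    if (dplyr::n_distinct(an$participant_id) >= 10) {
      fit <- fit_lmm(an, percent_ebw ~ time_days + age_admission + los_total)
      models[[length(models) + 1L]] <-
        model_report(fit, "percent_ebw_an", grp, threshold, config$boot, seed_i)
    }
  }

  # negative-binomial count models (pooled; count-valid participants only)
  counts <- data[data$count_model_eligible, ]
  nb_sets <- list(binge_count = c("AN-BP", "BN", "BED"),
                  vomit_count = c("AN-BP", "BN"))
  for (cc in names(nb_sets)) {
    if (!cc %in% names(counts)) next
    sub <- counts[counts$diagnosis %in% nb_sets[[cc]], ]
    if (sum(!is.na(sub[[cc]])) >= 30 && any(sub[[cc]] > 0, na.rm = TRUE)) {
      fml <- stats::as.formula(paste(cc, "~ time_days + age_admission + los_total"))
      fit <- fit_nb_glmm(sub, fml)
      models[[length(models) + 1L]] <-
        model_report(fit, cc, "pooled", threshold, 0, seed_i)
    }
  }

  # pooled predictor models: time x predictor interactions
  pred <- data
  dx <- simple_code(ifelse(pred$an_flag, "AN", as.character(pred$diagnosis)),
                    reference = "AN")
  pred <- dplyr::bind_cols(pred, tibble::as_tibble(dx))
  dx_terms <- colnames(dx)
  predictors <- c(list(diagnosis = dx_terms),
                  list(age = "age_admission",
                       admission_severity = "admission_edeq",
                       comorbid = "comorbid"))
  for (oc in scales) {
    for (pn in names(predictors)) {
      tm <- predictors[[pn]]
      if (identical(tm, "age_admission")) {
        rhs <- "time_days * age_admission + los_total"
      } else {
        rhs <- paste("time_days +", paste(tm, collapse = " + "), "+",
                     paste(paste0("time_days:", tm), collapse = " + "),
                     "+ age_admission + los_total")
      }
      fml <- stats::as.formula(paste(oc, "~", rhs))
      fit <- fit_lmm(pred, fml)
      models[[length(models) + 1L]] <-
        model_report(fit, oc, paste0("pooled_predictor_", pn), threshold,
                     0, seed_i)
    }
  }

  # post-hoc region models with level-of-care control
  reg <- dplyr::bind_cols(
    data, tibble::as_tibble(region_dummies(as.character(data$region)))
  )
  reg$loc_php_iop <- as.numeric(reg$loc_group == "PHP/IOP")
  for (oc in scales) {
    fml <- stats::as.formula(paste(
      oc, "~ time_days + West + Midwest + Northeast + loc_php_iop",
      "+ age_admission + los_total"))
    fit <- fit_lmm(reg, fml)
    models[[length(models) + 1L]] <-
      model_report(fit, oc, "posthoc_region", threshold, 0, seed_i)
  }

  desc_vars <- c("age_admission", "los_total", scales, "percent_ebw")
  desc <- descriptives_table(data, intersect(desc_vars, names(data)))
  missingness <- missingness_diagnostics(
    data, baseline_vars = intersect(c("admission_edeq", "pct_ebw_admission",
                                      "age_admission"), names(data))
  )

  bundle <- structure(list(
    descriptives = desc,
    thresholds = thresholds,
    change_tables = change_tables,
    models = dplyr::bind_rows(models),
    missingness = missingness,
    exclusions = exclusion_log(data),
    manifest = list(
      seed = config$seed,
      bonferroni_threshold = threshold, m_tests = config$m_tests,
      n_participants = dplyr::n_distinct(data$participant_id),
      input = if (identical(config$input, "synthetic")) "synthetic" else config$input,
      config_hash = rlang::hash(config),
      package_version = as.character(utils::packageVersion("edoutcomes")),
      timestamp = format(Sys.time(), tz = "UTC")
    )
  ), class = "report_bundle")
  if (!is.null(config$output_dir)) write_report_bundle(bundle, config$output_dir)
  bundle
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("<report_bundle> seed", x$manifest$seed, "-",
      x$manifest$n_participants, "participants\n")
  cat("  models fitted:", dplyr::n_distinct(paste(x$models$outcome,
                                                  x$models$subsample)), "\n")
  cat("  Bonferroni threshold:", signif(x$manifest$bonferroni_threshold, 3), "\n")
  invisible(x)
}

#' Render a change table as aligned markdown
#'
#' Formats the output of [change_table()] with one row per scale x interval
#' and the five category columns, percentages to one decimal, and the
#' category-definition footnotes (a-e).
#'
#' @param tab A tibble from [change_table()].
#' @return A character vector of markdown lines.
#' @export
render_change_table <- function(tab) {
  strata <- setdiff(names(tab), c("scale", "interval", "category", "n", "pct",
                                  "n_reporting"))
  wide <- tab |>
    dplyr::mutate(pct = sprintf("%.1f%%", .data$pct)) |>
    dplyr::select(-"n") |>
    tidyr::pivot_wider(names_from = "category", values_from = "pct")
  header_cols <- c(strata, "scale", "interval",
                   "CSC %ᵃ", "Reliable %ᵇ", "Unchanged %ᶜ",
                   "Deteriorated %ᵈ", "Normative %ᵉ", "n")
  body <- wide[, c(strata, "scale", "interval", "clinically_significant",
                   "improved", "unchanged", "deteriorated", "normative",
                   "n_reporting")]
  fmt_row <- function(cells) paste0("| ", paste(cells, collapse = " | "), " |")
  lines <- c(
    fmt_row(header_cols),
    fmt_row(rep("---", length(header_cols))),
    vapply(seq_len(nrow(body)), function(i) {
      fmt_row(as.character(unlist(body[i, ], use.names = FALSE)))
    }, character(1)),
    "",
    paste0("ᵃ Among those in the clinical range at admission: reliable ",
           "improvement that crossed the clinical cutoff into the normative range."),
    paste0("ᵇ Among those in the clinical range: reliable improvement ",
           "that did not cross the cutoff."),
    "ᶜ Among those in the clinical range: change within the reliable-change threshold.",
    "ᵈ Reliable change in the direction of worsening.",
    "ᵉ Scores within the normative range at both timepoints.",
    "Percentages are of the reporting sample (both timepoints observed); rows sum to 100% up to rounding."
  )
  lines
}

#' Write a report bundle to disk
#'
#' Writes each table of the bundle as CSV, the change tables additionally as
#' footnoted markdown, and the manifest as JSON.
#'
#' @param bundle A `report_bundle` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(bundle$descriptives, file.path(dir, "descriptives.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$thresholds, file.path(dir, "thresholds.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$change_tables, file.path(dir, "change_tables.csv"),
                   row.names = FALSE)
  writeLines(render_change_table(bundle$change_tables),
             file.path(dir, "change_tables.md"))
  utils::write.csv(bundle$models, file.path(dir, "models.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$missingness, file.path(dir, "missingness.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$exclusions, file.path(dir, "exclusions.csv"),
                   row.names = FALSE)
  jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
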