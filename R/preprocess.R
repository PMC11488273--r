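#' Preprocess a longitudinal treatment dataset
#'
#' Applies the cohort filters used before modelling: keeps only each
#' participant's first treatment episode; flags participants whose
#' self-reported binge or vomit episode frequency exceeds `count_max`
#' (default 500) at any timepoint for exclusion from count models (they stay
#' in all other analyses); and derives `time_days` as days since admission if
#' an `assessment_day` column is present. Every exclusion is logged with the
#' participant id and rule; retrieve the log with [exclusion_log()].
#'
#' @param data Long-format data frame with columns `participant_id`,
#'   `timepoint`, optionally `episode` (integer, 1 = first stay),
#'   `assessment_day`, `binge_count`, `vomit_count`.
#' @param count_max Count ceiling above which self-reports are treated as
#'   invalid for count analyses.
#' @return A tibble with the first-episode rows, a logical column
#'   `count_model_eligible`, and an `exclusions` attribute (a tibble of
#'   participant_id x rule).
#' @export
preprocess <- function(data, count_max = 500) {
  data <- tibble::as_tibble(data)
  stopifnot(all(c("participant_id", "timepoint") %in% names(data)))
  exclusions <- tibble::tibble(participant_id = character(), rule = character())

  if ("episode" %in% names(data)) {
    multi <- data |>
      dplyr::group_by(.data$participant_id) |>
      dplyr::summarise(first = min(.data$episode), multi = dplyr::n_distinct(.data$episode) > 1,
                       .groups = "drop")
    data <- data |>
      dplyr::left_join(multi, by = "participant_id") |>
      dplyr::filter(.data$episode == .data$first) |>
      dplyr::select(-"first")
    exclusions <- dplyr::bind_rows(exclusions, tibble::tibble(
      participant_id = as.character(multi$participant_id[multi$multi]),
      rule = "later_episode_rows_dropped_first_stay_kept"
    ))
    data$multi <- NULL
  }

  dup <- data |>
    dplyr::count(.data$participant_id, .data$timepoint) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup) > 0L) {
    stop("duplicate (participant, timepoint) rows for: ",
         paste(utils::head(dup$participant_id, 10), collapse = ", "),
         call. = FALSE)
  }

  if ("assessment_day" %in% names(data) && !"time_days" %in% names(data)) {
    data <- data |>
      dplyr::group_by(.data$participant_id) |>
      dplyr::mutate(time_days = .data$assessment_day -
                      min(.data$assessment_day[.data$timepoint == "admission"])) |>
      dplyr::ungroup()
  }

  count_cols <- intersect(c("binge_count", "vomit_count"), names(data))
  data$count_model_eligible <- TRUE
  if (length(count_cols)) {
    over_ids <- unique(unlist(lapply(count_cols, function(cc) {
      data$participant_id[!is.na(data[[cc]]) & data[[cc]] > count_max]
    })))
    data$count_model_eligible <- !(data$participant_id %in% over_ids)
    exclusions <- dplyr::bind_rows(exclusions, tibble::tibble(
      participant_id = as.character(over_ids),
      rule = paste0("count_over_", count_max, "_excluded_from_count_models")
    ))
  }
  attr(data, "exclusions") <- exclusions
  data
}

#' Retrieve the exclusion log attached by [preprocess()]
#'
#' @param data A tibble returned by [preprocess()].
#' @return A tibble with columns `participant_id`, `rule`.
#' @export
exclusion_log <- function(data) {
  attr(data, "exclusions") %||%
    tibble::tibble(participant_id = character(), rule = character())
}

#' Simple-coded contrasts for diagnosis (or any factor)
#'
#' Simple coding compares each level with the reference while keeping the
#' intercept at the unweighted grand mean of level means: the column for
#' level `j` takes value \eqn{(k-1)/k} for observations at level `j` and
#' \eqn{-1/k} otherwise.
#'
#' @param x A factor or character vector with `k >= 2` levels.
#' @param reference Reference level (default the first level).
#' @return A numeric matrix with `k - 1` named columns
#'   (`<level>_vs_<reference>`).
#' @export
#' @examples
#' head(simple_code(c("AN", "BN", "BED", "AN"), reference = "AN"))
simple_code <- function(x, reference = NULL) {
  f <- if (is.factor(x)) x else factor(x)
  if (anyNA(f) && !anyNA(x)) stop("unknown factor level in `x`", call. = FALSE)
  lev <- levels(f)
  k <- length(lev)
  if (k < 2L) stop("need at least 2 levels", call. = FALSE)
  reference <- reference %||% lev[1L]
  if (!reference %in% lev) stop("reference level '", reference, "' not found",
                                call. = FALSE)
  others <- setdiff(lev, reference)
  out <- vapply(others, function(l) {
    ifelse(f == l, (k - 1) / k, -1 / k)
  }, numeric(length(f)))
  nm <- make.names(paste0(others, "_vs_", reference))
  out <- matrix(out, nrow = length(f),
                dimnames = list(NULL, gsub("\\.", "_", nm)))
  if (anyNA(f)) out[is.na(f), ] <- NA_real_
  out
}

#' Dummy (treatment) coding for U.S. Census region
#'
#' Standard 0/1 indicators with South as the reference, used by the post-hoc
#' site-region models.
#'
#' @param region Character or factor vector with levels among South, West,
#'   Midwest, Northeast.
#' @param reference Reference region (default `"South"`).
#' @return A numeric indicator matrix with one column per non-reference region.
#' @export
region_dummies <- function(region, reference = "South") {
  levels_known <- c("South", "West", "Midwest", "Northeast")
  bad <- setdiff(unique(stats::na.omit(as.character(region))), levels_known)
  if (length(bad)) stop("unknown region(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  if (!reference %in% levels_known) stop("unknown reference region", call. = FALSE)
  others <- setdiff(levels_known, reference)
  out <- vapply(others, function(l) as.numeric(region == l),
                numeric(length(region)))
  matrix(out, nrow = length(region), dimnames = list(NULL, others))
}

#' Bonferroni-corrected per-test significance threshold
#'
#' @param alpha_family Family-wise error rate (default 0.05).
#' @param m_tests Number of tests in the family (>= 1).
#' @return `alpha_family / m_tests` at full precision (reports round to 3
#'   decimals; comparisons should use the full-precision value).
#' @export
#' @examples
#' round(bonferroni(0.05, 17), 3)  # 0.003
bonferroni <- function(alpha_family = 0.05, m_tests = 1L) {
  if (any(m_tests < 1)) stop("`m_tests` must be >= 1", call. = FALSE)
  alpha_family / m_tests
}

#' Baseline comparisons by follow-up completion status
#'
#' For each baseline variable, compares participants with and without data at
#' each follow-up timepoint: standardized mean difference (difference in
#' means over the pooled SD) for continuous variables, the chi-square
#' statistic for categorical ones, plus per-timepoint completion rates.
#' Used to examine whether missingness relates to baseline severity.
#'
#' @param data Long-format data frame with `participant_id`, `timepoint`, and
#'   per-timepoint outcome columns; completion at a timepoint means a
#'   non-missing value in `complete_col` at that timepoint.
#' @param baseline_vars Character vector of participant-level baseline columns
#'   to compare (measured at admission).
#' @param complete_col Column whose non-missingness defines completion
#'   (default `"edeq"`).
#' @return A tibble: `timepoint`, `variable`, `type`, `statistic`
#'   (SMD or chi-square), `completion_rate`, `n_complete`, `n_missing`.
#' @export
missingness_diagnostics <- function(data, baseline_vars,
                                    complete_col = "edeq") {
  stopifnot(complete_col %in% names(data))
  base <- data |>
    dplyr::filter(.data$timepoint == "admission") |>
    dplyr::distinct(.data$participant_id, .keep_all = TRUE)
  out <- list()
  for (tp in c("stepdown", "discharge")) {
    comp_ids <- data$participant_id[data$timepoint == tp &
                                      !is.na(data[[complete_col]])]
    base$complete <- base$participant_id %in% comp_ids
    rate <- mean(base$complete)
    for (v in baseline_vars) {
      x <- base[[v]]
      if (is.numeric(x)) {
        x1 <- x[base$complete]; x0 <- x[!base$complete]
        sp <- sqrt((stats::var(x1, na.rm = TRUE) + stats::var(x0, na.rm = TRUE)) / 2)
        stat <- if (is.na(sp) || sp == 0) 0 else
          (mean(x1, na.rm = TRUE) - mean(x0, na.rm = TRUE)) / sp
        type <- "smd"
      } else {
        tab <- table(x, base$complete)
        stat <- if (nrow(tab) < 2L || ncol(tab) < 2L) 0 else
          suppressWarnings(unname(stats::chisq.test(tab, correct = FALSE)$statistic))
        type <- "chisq"
      }
      out[[length(out) + 1L]] <- tibble::tibble(
        timepoint = tp, variable = v, type = type, statistic = stat,
        completion_rate = rate,
        n_complete = sum(base$complete), n_missing = sum(!base$complete)
      )
    }
  }
  dplyr::bind_rows(out)
}
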