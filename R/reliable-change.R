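#' Jacobson-Truax reliable-change threshold
#'
#' The reliable change index marks individual change larger than measurement
#' error alone would produce. With admission standard deviation \eqn{s} and
#' reliability \eqn{\alpha}, the standard error of measurement is
#' \eqn{SE_m = s\sqrt{1-\alpha}}, the standard error of a difference is
#' \eqn{S_{diff} = \sqrt{2}\,SE_m}, and the threshold is \eqn{z \cdot S_{diff}}
#' (z = 1.96 for 95% confidence). The value is returned at full precision;
#' reports round to 2 decimals.
#'
#' @param admission_sd Admission-timepoint standard deviation (> 0).
#' @param alpha Reliability in `[0, 1]`.
#' @param z Confidence multiplier (> 0), default 1.96.
#' @return The threshold in score units (0 when `alpha == 1`).
#' @export
#' @examples
#' round(rci_threshold(1.59, 0.96), 2)  # 0.88, the EDE-Q global threshold
rci_threshold <- function(admission_sd, alpha, z = 1.96) {
  if (any(admission_sd <= 0)) stop("`admission_sd` must be > 0", call. = FALSE)
  if (any(alpha < 0 | alpha > 1)) stop("`alpha` must lie in [0, 1]", call. = FALSE)
  if (any(z <= 0)) stop("`z` must be > 0", call. = FALSE)
  z * sqrt(2) * admission_sd * sqrt(1 - alpha)
}

#' Clinical-significance cutoff (Jacobson-Truax criterion "c")
#'
#' The point between the clinical and normative population means, weighted by
#' the opposite standard deviations:
#' \eqn{c = (s_{norm} m_{clin} + s_{clin} m_{norm}) / (s_{norm} + s_{clin})}.
#' Crossing c marks movement into the normative range.
#'
#' @param m_clinical,sd_clinical Mean and SD of the clinical population.
#' @param m_norm,sd_norm Mean and SD of the normative population.
#' @return The cutoff in score units.
#' @export
criterion_c_cutoff <- function(m_clinical, sd_clinical, m_norm, sd_norm) {
  if (any(sd_clinical < 0) || any(sd_norm < 0)) {
    stop("standard deviations must be >= 0", call. = FALSE)
  }
  if (any(sd_clinical + sd_norm == 0)) {
    stop("`sd_clinical` and `sd_norm` cannot both be 0", call. = FALSE)
  }
  (sd_norm * m_clinical + sd_clinical * m_norm) / (sd_norm + sd_clinical)
}

#' Change thresholds for a set of scales
#'
#' Builds the per-scale table of reliable-change thresholds and
#' clinical-significance cutoffs used by [classify_change()] and
#' [change_table()]. Thresholds are computed from each scale's admission SD
#' and reliability; cutoffs default to the configured `clinical_cutoff` of
#' each `scale_spec` (the community-norm means/SDs behind criterion "c" live
#' in external references, so the cutoffs are configured constants — use
#' [criterion_c_cutoff()] directly when norms are available).
#'
#' @param registry A named list of [scale_spec()]s.
#' @param z Confidence multiplier for the RCI (default 1.96).
#' @return A tibble with columns `scale`, `rci_threshold`, `cs_cutoff`,
#'   `confidence_z`, `provenance`.
#' @export
#' @examples
#' change_thresholds()
change_thresholds <- function(registry = default_scale_registry(), z = 1.96) {
  purrr::map_dfr(registry, function(sp) {
    tibble::tibble(
      scale = sp$name,
      rci_threshold = rci_threshold(sp$admission_sd, sp$reliability_alpha, z),
      cs_cutoff = sp$clinical_cutoff,
      confidence_z = z,
      provenance = "computed"
    )
  })
}

change_categories <- function() {
  c("clinically_significant", "improved", "unchanged", "deteriorated", "normative")
}

#' Classify individual change into the five-category taxonomy
#'
#' For higher-is-worse scales with admission score `admit`, follow-up score
#' `followup`, reliable-change threshold `rci` and clinical cutoff `cutoff`:
#' among those in the clinical range at admission (`admit > cutoff`),
#' improvement beyond the RCI that also crosses below the cutoff is
#' *clinically significant*; improvement beyond the RCI that stays at or above
#' the cutoff is *improved*; worsening beyond the RCI is *deteriorated*;
#' anything else is *unchanged*. Participants in the normative range at both
#' timepoints are *normative*; a participant who starts normative and worsens
#' beyond the RCI into the clinical range is classified *deteriorated*.
#' All comparisons are strict (ties at the threshold or cutoff do not count
#' as change or crossing).
#'
#' @param admit,followup Numeric vectors of scores (recycled to a common
#'   length). Pairs with either score missing return `NA`.
#' @param rci Reliable-change threshold in score units.
#' @param cutoff Clinical-significance cutoff in score units.
#' @return A factor with levels `clinically_significant`, `improved`,
#'   `unchanged`, `deteriorated`, `normative`.
#' @export
#' @examples
#' classify_change(3.62, 2.27, rci = 0.88, cutoff = 2.71)  # clinically_significant
classify_change <- function(admit, followup, rci, cutoff) {
  n <- max(length(admit), length(followup))
  admit <- rep_len(admit, n); followup <- rep_len(followup, n)
  rci <- rep_len(rci, n); cutoff <- rep_len(cutoff, n)
  improvement <- admit - followup
  out <- rep(NA_character_, n)
  clin <- !is.na(admit) & !is.na(followup) & admit > cutoff
  norm <- !is.na(admit) & !is.na(followup) & admit <= cutoff
  out[clin] <- dplyr::case_when(
    improvement[clin] > rci[clin] & followup[clin] < cutoff[clin] ~ "clinically_significant",
    improvement[clin] > rci[clin] ~ "improved",
    -improvement[clin] > rci[clin] ~ "deteriorated",
    TRUE ~ "unchanged"
  )
  out[norm] <- dplyr::if_else(
    followup[norm] > cutoff[norm] & -improvement[norm] > rci[norm],
    "deteriorated", "normative"
  )
  factor(out, levels = change_categories())
}

#' Cohort change table
#'
#' Counts and percentages of the five change categories for each scale and
#' interval (admission to stepdown, admission to discharge), computed among
#' participants with both scores present (the "reporting sample"), optionally
#' stratified (e.g. by admitting level-of-care group).
#'
#' @param scores A data frame of scored data in long format with columns
#'   `participant_id`, `timepoint` (`admission`/`stepdown`/`discharge`),
#'   `scale`, `value`, plus any stratification columns.
#' @param thresholds A tibble as returned by [change_thresholds()].
#' @param strata Optional character vector of participant-level columns in
#'   `scores` to stratify by.
#' @return A tibble with one row per scale x interval (x stratum) x category:
#'   `n`, `pct` (percentage of the reporting sample) and `n_reporting`.
#' @export
change_table <- function(scores, thresholds = change_thresholds(),
                         strata = NULL) {
  needed <- c("participant_id", "timepoint", "scale", "value")
  stopifnot(all(needed %in% names(scores)))
  wide <- scores |>
    dplyr::select(dplyr::all_of(c(needed, strata))) |>
    tidyr::pivot_wider(names_from = "timepoint", values_from = "value")
  for (tp in c("admission", "stepdown", "discharge")) {
    if (!tp %in% names(wide)) wide[[tp]] <- NA_real_
  }
  long <- dplyr::bind_rows(
    dplyr::mutate(wide, interval = "admit_to_stepdown", followup = .data$stepdown),
    dplyr::mutate(wide, interval = "admit_to_discharge", followup = .data$discharge)
  ) |>
    dplyr::filter(!is.na(.data$admission), !is.na(.data$followup)) |>
    dplyr::left_join(thresholds, by = "scale")
  if (nrow(long) == 0L) stop("empty reporting sample", call. = FALSE)
  long$category <- classify_change(long$admission, long$followup,
                                   long$rci_threshold, long$cs_cutoff)
  grp <- c(strata, "scale", "interval")
  long |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::group_modify(function(d, key) {
      cnt <- table(d$category)  # factor table: all five categories, zeros kept
      tibble::tibble(
        category = factor(names(cnt), levels = change_categories()),
        n = as.integer(cnt),
        pct = 100 * as.integer(cnt) / nrow(d),
        n_reporting = nrow(d)
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(dplyr::across(dplyr::all_of(grp)), .data$category)
}

#' Plot a change table
#'
#' Stacked-bar view of the five-category percentages per scale and interval.
#'
#' @param tab A tibble from [change_table()].
#' @return A ggplot object.
#' @export
plot_change_table <- function(tab) {
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$interval, y = .data$pct,
                                    fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~scale) +
    ggplot2::labs(x = NULL, y = "% of reporting sample", fill = "category") +
    ggplot2::theme_minimal()
}
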