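#' Define a self-report scale
#'
#' A `scale_spec` bundles everything the pipeline needs to know about one
#' instrument: its items and response range, how items combine into a score,
#' the internal-consistency reliability and admission-timepoint standard
#' deviation used for reliable-change thresholds, and the clinical cutoff
#' used for clinical-significance classification.
#'
#' @param name Scale identifier (e.g. `"edeq"`).
#' @param n_items Number of items (> 1).
#' @param item_min,item_max Bounds of the item response scale.
#' @param scoring Either `"sum"` (total score) or `"subscale_mean"`
#'   (mean of subscale means, as for the EDE-Q global).
#' @param subscales For `scoring = "subscale_mean"`, an integer vector of
#'   length `n_items` mapping each item to its subscale (or a character
#'   vector of subscale labels). Ignored for sum scales.
#' @param reliability_alpha Cronbach's alpha in `[0, 1]` used for the
#'   reliable-change threshold.
#' @param admission_sd Admission-timepoint standard deviation of the score
#'   (score units, > 0).
#' @param admission_mean Admission-timepoint mean (score units); used by the
#'   synthetic-cohort generator.
#' @param clinical_cutoff Clinical-significance cutoff (criterion "c") in
#'   score units; must lie in the legal score range.
#' @param direction Only `"higher_is_worse"` is supported.
#'
#' @return An object of class `scale_spec`.
#' @export
#' @examples
#' scale_spec("phq9", n_items = 9, item_min = 0, item_max = 3,
#'            scoring = "sum", reliability_alpha = 0.89,
#'            admission_sd = 7.08, clinical_cutoff = 9.48)
scale_spec <- function(name, n_items, item_min, item_max,
                       scoring = c("sum", "subscale_mean"),
                       subscales = NULL,
                       reliability_alpha,
                       admission_sd,
                       admission_mean = NA_real_,
                       clinical_cutoff,
                       direction = "higher_is_worse") {
  scoring <- match.arg(scoring)
  stopifnot(is.character(name), length(name) == 1L)
  if (!(n_items > 1)) stop("`n_items` must be > 1", call. = FALSE)
  if (!(item_min < item_max)) stop("`item_min` must be < `item_max`", call. = FALSE)
  if (!(reliability_alpha >= 0 && reliability_alpha <= 1)) {
    stop("`reliability_alpha` must lie in [0, 1]", call. = FALSE)
  }
  if (!(admission_sd > 0)) stop("`admission_sd` must be > 0", call. = FALSE)
  rng <- score_range(scoring, n_items, item_min, item_max)
  if (clinical_cutoff < rng[1] || clinical_cutoff > rng[2]) {
    stop("`clinical_cutoff` outside the legal score range [",
         rng[1], ", ", rng[2], "]", call. = FALSE)
  }
  if (scoring == "subscale_mean") {
    if (is.null(subscales) || length(subscales) != n_items) {
      stop("`subscales` must map each of the ", n_items, " items to a subscale",
           call. = FALSE)
    }
    subscales <- as.factor(subscales)
  }
  structure(
    list(name = name, n_items = as.integer(n_items),
         item_min = item_min, item_max = item_max,
         scoring = scoring, subscales = subscales,
         reliability_alpha = reliability_alpha,
         admission_sd = admission_sd,
         admission_mean = admission_mean,
         clinical_cutoff = clinical_cutoff,
         direction = direction,
         score_min = rng[1], score_max = rng[2]),
    class = "scale_spec"
  )
}

score_range <- function(scoring, n_items, item_min, item_max) {
  if (scoring == "sum") c(n_items * item_min, n_items * item_max)
  else c(item_min, item_max)
}

#' @export
print.scale_spec <- function(x, ...) {
  cat("<scale_spec> ", x$name, ": ", x$n_items, " items in [",
      x$item_min, ", ", x$item_max, "], scoring = ", x$scoring,
      "\n  alpha = ", x$reliability_alpha, ", admission SD = ", x$admission_sd,
      ", clinical cutoff = ", x$clinical_cutoff, "\n", sep = "")
  invisible(x)
}

#' Default scale registry
#'
#' The three instruments of the outcome battery with their default
#' psychometric constants: the EDE-Q global (22 attitudinal items scored as
#' the mean of four subscale means, range 0-6), the PHQ-9 (9 items, summed,
#' 0-27) and the GAD-7 (7 items, summed, 0-21). Reliabilities are the
#' admission-timepoint values (0.96 / 0.89 / 0.90) and admission means/SDs
#' are 3.62 (1.59), 14.87 (7.08) and 12.93 (5.74); clinical cutoffs from
#' adolescent community norms are 2.71 / 9.48 / 7.97. All of these are
#' configurable by building your own `scale_spec`s, and a registry can also
#' be read from a YAML/JSON file via [read_scale_registry()].
#'
#' The default EDE-Q subscale map assigns items 1-5 to restraint, 6-10 to
#' eating concern, 11-18 to shape concern and 19-22 to weight concern;
#' alternative maps are data, not code — supply your own via `scale_spec()`.
#'
#' @return A named list of `scale_spec` objects (`edeq`, `phq9`, `gad7`).
#' @export
default_scale_registry <- function() {
  edeq_map <- rep(c("restraint", "eating_concern", "shape_concern", "weight_concern"),
                  times = c(5L, 5L, 8L, 4L))
  list(
    edeq = scale_spec("edeq", n_items = 22, item_min = 0, item_max = 6,
                      scoring = "subscale_mean", subscales = edeq_map,
                      reliability_alpha = 0.96, admission_sd = 1.59,
                      admission_mean = 3.62, clinical_cutoff = 2.71),
    phq9 = scale_spec("phq9", n_items = 9, item_min = 0, item_max = 3,
                      scoring = "sum", reliability_alpha = 0.89,
                      admission_sd = 7.08, admission_mean = 14.87,
                      clinical_cutoff = 9.48),
    gad7 = scale_spec("gad7", n_items = 7, item_min = 0, item_max = 3,
                      scoring = "sum", reliability_alpha = 0.90,
                      admission_sd = 5.74, admission_mean = 12.93,
                      clinical_cutoff = 7.97)
  )
}

#' Read a scale registry from a YAML or JSON file
#'
#' The file must contain a mapping from scale name to the fields of
#' [scale_spec()].
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A named list of `scale_spec` objects.
#' @export
read_scale_registry <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML registries requires the 'yaml' package", call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  out <- lapply(names(raw), function(nm) {
    fields <- raw[[nm]]
    fields$name <- fields$name %||% nm
    do.call(scale_spec, fields)
  })
  stats::setNames(out, names(raw))
}

check_items <- function(items, n_items, item_min, item_max, what) {
  if (length(items) != n_items) {
    stop(what, " expects ", n_items, " item responses, got ", length(items),
         call. = FALSE)
  }
  ok <- is.na(items) | (items >= item_min & items <= item_max)
  if (!all(ok)) {
    stop(what, ": responses outside [", item_min, ", ", item_max, "]: ",
         paste(items[!ok], collapse = ", "), call. = FALSE)
  }
  invisible(items)
}

score_sum_scale <- function(items, n_items, item_min, item_max,
                            proration_max_missing, what) {
  check_items(items, n_items, item_min, item_max, what)
  n_miss <- sum(is.na(items))
  if (n_miss == 0L) return(sum(items))
  if (n_miss > proration_max_missing) return(NA_real_)
  round(mean(items, na.rm = TRUE) * n_items)
}

#' Score the PHQ-9 depression screen
#'
#' Sum of nine items rated 0-3 (range 0-27). By default no missing items are
#' tolerated; with `proration_max_missing > 0`, up to that many missing items
#' are prorated as `round(mean(present) * 9)`.
#'
#' @param items Numeric vector of 9 responses in 0-3 (`NA` allowed).
#' @param proration_max_missing Maximum number of missing items to prorate.
#' @return The total score, or `NA` when too many items are missing.
#' @export
#' @examples
#' score_phq9(c(3, 2, 2, 1, 1, 1, 0, 0, 0))  # 10
score_phq9 <- function(items, proration_max_missing = 0L) {
  score_sum_scale(items, 9L, 0, 3, proration_max_missing, "score_phq9")
}

#' Score the GAD-7 anxiety screen
#'
#' Sum of seven items rated 0-3 (range 0-21); proration as in [score_phq9()].
#'
#' @inheritParams score_phq9
#' @param items Numeric vector of 7 responses in 0-3 (`NA` allowed).
#' @return The total score, or `NA` when too many items are missing.
#' @export
score_gad7 <- function(items, proration_max_missing = 0L) {
  score_sum_scale(items, 7L, 0, 3, proration_max_missing, "score_gad7")
}

#' Score the EDE-Q global
#'
#' Each attitudinal subscale is scored as the mean of its present items,
#' provided at least `min_present_prop` of the subscale's items are present;
#' the global score is the unweighted mean of the four subscale scores. If
#' any subscale falls below the presence threshold the global is `NA`.
#'
#' @param items Numeric vector of attitudinal responses in 0-6 (`NA` allowed),
#'   in the item order of `spec$subscales`.
#' @param spec A `scale_spec` with `scoring = "subscale_mean"`.
#' @param min_present_prop Minimum proportion of items per subscale that must
#'   be present (default 0.5).
#' @return The global score in 0-6, or `NA`.
#' @export
score_edeq_global <- function(items, spec = default_scale_registry()$edeq,
                              min_present_prop = 0.5) {
  stopifnot(inherits(spec, "scale_spec"), spec$scoring == "subscale_mean")
  check_items(items, spec$n_items, spec$item_min, spec$item_max, "score_edeq_global")
  by_sub <- split(items, spec$subscales)
  means <- vapply(by_sub, function(v) {
    if (mean(!is.na(v)) < min_present_prop) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
  if (anyNA(means)) return(NA_real_)
  mean(means)
}

#' Score item-level data for one scale
#'
#' Data-frame-first scorer: takes long-per-participant wide-per-item data and
#' returns one scored row per participant x timepoint.
#'
#' @param data A data frame with columns `participant_id`, `timepoint` and
#'   item columns named `item_1 ... item_k`.
#' @param spec A [scale_spec()].
#' @param proration_max_missing For sum scales, see [score_phq9()].
#' @param min_present_prop For subscale-mean scales, see [score_edeq_global()].
#' @return A tibble with columns `participant_id`, `timepoint`, `scale`,
#'   `value`.
#' @export
score_items <- function(data, spec, proration_max_missing = 0L,
                        min_present_prop = 0.5) {
  stopifnot(inherits(spec, "scale_spec"))
  item_cols <- paste0("item_", seq_len(spec$n_items))
  missing_cols <- setdiff(item_cols, names(data))
  if (length(missing_cols)) {
    stop("missing item columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  mat <- as.matrix(data[item_cols])
  value <- apply(mat, 1L, function(items) {
    if (spec$scoring == "sum") {
      score_sum_scale(items, spec$n_items, spec$item_min, spec$item_max,
                      proration_max_missing, spec$name)
    } else {
      score_edeq_global(items, spec, min_present_prop)
    }
  })
  tibble::tibble(
    participant_id = data$participant_id,
    timepoint = data$timepoint,
    scale = spec$name,
    value = as.numeric(value)
  )
}

#' Cronbach's alpha
#'
#' Internal-consistency reliability
#' \eqn{\alpha = k/(k-1)\,(1 - \sum_i \mathrm{var}_i / \mathrm{var}_{total})}.
#' Incomplete rows are dropped listwise; variances use the population (1/n)
#' denominator throughout, which cancels in the ratio but is kept consistent.
#'
#' @param x A numeric matrix or data frame, rows = respondents, columns =
#'   items (at least 2 items and 3 complete rows).
#' @return Alpha, a scalar in \eqn{(-\infty, 1]}.
#' @export
cronbach_alpha <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2L) stop("cronbach_alpha needs at least 2 items", call. = FALSE)
  x <- x[stats::complete.cases(x), , drop = FALSE]
  n <- nrow(x)
  if (n < 3L) stop("cronbach_alpha needs at least 3 complete rows", call. = FALSE)
  pvar <- function(v) mean((v - mean(v))^2)
  total <- pvar(rowSums(x))
  if (total <= 0) stop("total score has zero variance: degenerate item data",
                       call. = FALSE)
  k <- ncol(x)
  k / (k - 1) * (1 - sum(apply(x, 2L, pvar)) / total)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
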