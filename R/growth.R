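#' Evaluate an LMS growth reference at a z-score
#'
#' The LMS parameterization describes a reference distribution by a Box-Cox
#' power `L`, median `M` and coefficient of variation `S`; the measurement at
#' standard-normal deviate `z` is \eqn{M(1 + LSz)^{1/L}} for `L` away from 0
#' and \eqn{M e^{Sz}} in the limit `L -> 0`.
#'
#' @param L,M,S LMS parameters (`M > 0`, `S > 0`); vectors are recycled.
#' @param z Standard-normal deviate (default 0, the median).
#' @return The measurement value in the units of `M`.
#' @export
#' @examples
#' lms_value(L = -1.5, M = 16.4, S = 0.08, z = 0)  # the median, 16.4
lms_value <- function(L, M, S, z = 0) {
  if (any(M <= 0) || any(S <= 0)) stop("`M` and `S` must be > 0", call. = FALSE)
  n <- max(length(L), length(M), length(S), length(z))
  L <- rep_len(L, n); M <- rep_len(M, n); S <- rep_len(S, n); z <- rep_len(z, n)
  out <- numeric(n)
  small <- abs(L) <= 1e-8
  out[small] <- M[small] * exp(S[small] * z[small])
  base <- 1 + L[!small] * S[!small] * z[!small]
  if (any(base <= 0)) {
    stop("z outside the support of the LMS distribution (1 + L*S*z <= 0)",
         call. = FALSE)
  }
  out[!small] <- M[!small] * base^(1 / L[!small])
  out
}

#' Build a growth-reference table
#'
#' Validates and classes a data frame of LMS rows. Expected columns:
#' `measure` (`"bmi_for_age"` or `"weight_for_age"`), `sex` (`"female"` /
#' `"male"`), `age_months`, `L`, `M`, `S`. Within each (measure, sex) the age
#' grid must be strictly increasing.
#'
#' @param df A data frame with the columns above.
#' @return A tibble of class `growth_reference`.
#' @export
growth_reference <- function(df) {
  needed <- c("measure", "sex", "age_months", "L", "M", "S")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop("growth reference lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (any(df$M <= 0) || any(df$S <= 0)) {
    stop("growth reference requires M > 0 and S > 0", call. = FALSE)
  }
  df <- dplyr::arrange(tibble::as_tibble(df), .data$measure, .data$sex,
                       .data$age_months)
  bad <- df |>
    dplyr::group_by(.data$measure, .data$sex) |>
    dplyr::summarise(ok = !anyDuplicated(.data$age_months), .groups = "drop")
  if (any(!bad$ok)) stop("duplicate ages in the growth reference grid", call. = FALSE)
  class(df) <- c("growth_reference", class(df))
  df
}

#' Read a growth reference from CSV
#'
#' The CSV must carry columns `measure, sex, age_months, L, M, S` (see
#' [growth_reference()]).
#'
#' @param path Path to the CSV file.
#' @return A `growth_reference` tibble.
#' @export
read_growth_reference <- function(path) {
  growth_reference(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Synthetic LMS growth reference
#'
#' A smooth parametric stand-in for real growth-chart LMS tables, covering
#' ages 24-240 months for both sexes and both measures (BMI-for-age and
#' weight-for-age). The curves are plausible in shape and magnitude
#' (median BMI rising from ~15.5 to ~21-22 kg/m2 across adolescence; median
#' weight from ~12 to ~57-65 kg) but are *synthetic*: they are for testing
#' and simulation, not clinical use. Real LMS CSVs are read through the same
#' [read_growth_reference()] interface.
#'
#' @param age_step Grid spacing in months (default 6).
#' @return A `growth_reference` tibble.
#' @export
synthetic_growth_reference <- function(age_step = 6) {
  ages <- seq(24, 240, by = age_step)
  a <- ages / 240  # 0..1 over the grid
  build <- function(sex) {
    mult <- if (sex == "male") 1.04 else 1.0
    bmi_m <- 15.5 - 1.2 * a + 8.0 * a^2  # dip then adolescent rise, kg/m2
    hgt_m <- (0.80 + 0.95 * a - 0.18 * a^2) * mult  # metres, levels off late
    wfa_m <- bmi_m * hgt_m^2 * mult
    dplyr::bind_rows(
      tibble::tibble(measure = "bmi_for_age", sex = sex, age_months = ages,
                     L = -1.8 + 0.8 * a, M = bmi_m, S = 0.08 + 0.05 * a),
      tibble::tibble(measure = "weight_for_age", sex = sex, age_months = ages,
                     L = -1.2 + 0.7 * a, M = wfa_m, S = 0.11 + 0.06 * a)
    )
  }
  growth_reference(dplyr::bind_rows(build("female"), build("male")))
}

#' Interpolate LMS parameters at an age
#'
#' Linear interpolation of L, M and S between the bracketing grid ages for
#' the requested measure and sex; exact at grid points. Ages outside the grid
#' are a range error — no extrapolation.
#'
#' @param table A [growth_reference()] tibble.
#' @param sex `"female"` or `"male"` (vectorized).
#' @param age_months Age in months (vectorized).
#' @param measure `"bmi_for_age"` or `"weight_for_age"`.
#' @return A tibble with columns `L`, `M`, `S` (one row per query).
#' @export
interpolate_reference <- function(table, sex, age_months,
                                  measure = c("bmi_for_age", "weight_for_age")) {
  measure <- match.arg(measure)
  n <- max(length(sex), length(age_months))
  sex <- rep_len(sex, n); age_months <- rep_len(age_months, n)
  out <- matrix(NA_real_, n, 3, dimnames = list(NULL, c("L", "M", "S")))
  for (sx in unique(sex)) {
    sub <- table[table$measure == measure & table$sex == sx, ]
    if (nrow(sub) == 0L) stop("no reference rows for sex '", sx, "'", call. = FALSE)
    idx <- which(sex == sx)
    ages <- age_months[idx]
    if (any(ages < min(sub$age_months) | ages > max(sub$age_months))) {
      stop("age outside the growth-reference grid [", min(sub$age_months),
           ", ", max(sub$age_months), "] months; no extrapolation", call. = FALSE)
    }
    for (col in c("L", "M", "S")) {
      out[idx, col] <- stats::approx(sub$age_months, sub[[col]], xout = ages,
                                     method = "linear", ties = "ordered")$y
    }
  }
  tibble::as_tibble(out)
}

#' Expected body weight for sex and age
#'
#' The default method multiplies the reference *median* BMI for sex and age
#' by height squared (`median_bmi`); the alternative uses the reference
#' median weight-for-age directly (`weight_for_age`), for participants
#' without a height measurement.
#'
#' @param sex,age_months Vectors of sex (`"female"`/`"male"`) and age in months.
#' @param height_m Height in metres; required for `method = "median_bmi"`
#'   unless `fallback = TRUE`.
#' @param table A [growth_reference()] tibble.
#' @param method `"median_bmi"` (default) or `"weight_for_age"`.
#' @param fallback If `TRUE`, queries with missing height fall back to
#'   weight-for-age instead of erroring.
#' @return Expected weight in kg.
#' @export
expected_body_weight <- function(sex, age_months, height_m = NULL,
                                 table = synthetic_growth_reference(),
                                 method = c("median_bmi", "weight_for_age"),
                                 fallback = FALSE) {
  method <- match.arg(method)
  n <- max(length(sex), length(age_months),
           if (is.null(height_m)) 0L else length(height_m))
  sex <- rep_len(sex, n); age_months <- rep_len(age_months, n)
  if (method == "weight_for_age") {
    return(interpolate_reference(table, sex, age_months, "weight_for_age")$M)
  }
  if (is.null(height_m)) height_m <- rep(NA_real_, n)
  height_m <- rep_len(height_m, n)
  no_height <- is.na(height_m)
  if (any(no_height) && !fallback) {
    stop("height is required for method = 'median_bmi'; set `fallback = TRUE` ",
         "to use weight-for-age for participants without height", call. = FALSE)
  }
  out <- numeric(n)
  if (any(!no_height)) {
    m_bmi <- interpolate_reference(table, sex[!no_height],
                                   age_months[!no_height], "bmi_for_age")$M
    out[!no_height] <- m_bmi * height_m[!no_height]^2
  }
  if (any(no_height)) {
    out[no_height] <- interpolate_reference(table, sex[no_height],
                                            age_months[no_height],
                                            "weight_for_age")$M
  }
  out
}

#' Percent of expected body weight
#'
#' \eqn{\%EBW = 100 \cdot observed / expected}. Equals 100 exactly when the
#' observed weight sits at the reference expectation, and is invariant to
#' rescaling both weights.
#'
#' @param observed_kg,expected_kg Observed and expected weight in kg (> 0).
#' @return Percent of expected body weight.
#' @export
#' @examples
#' percent_ebw(45, 50)  # 90
percent_ebw <- function(observed_kg, expected_kg) {
  if (any(observed_kg <= 0, na.rm = TRUE) || any(expected_kg <= 0, na.rm = TRUE)) {
    stop("weights must be > 0", call. = FALSE)
  }
  100 * observed_kg / expected_kg
}

#' Add %EBW columns to a longitudinal dataset
#'
#' Data-frame-first wrapper: computes expected weight and percent of expected
#' body weight for every row with the needed inputs. Rows whose age falls
#' outside the reference grid are flagged (`ebw_out_of_grid`) and left `NA`
#' rather than extrapolated.
#'
#' @param data A data frame with columns `sex`, `age_months`, `weight_kg` and
#'   (for the default method) `height_m`.
#' @param table A [growth_reference()] tibble.
#' @param method See [expected_body_weight()].
#' @param fallback See [expected_body_weight()].
#' @return `data` with columns `expected_weight_kg`, `percent_ebw`,
#'   `ebw_method`, `ebw_out_of_grid` appended.
#' @export
add_percent_ebw <- function(data, table = synthetic_growth_reference(),
                            method = c("median_bmi", "weight_for_age"),
                            fallback = FALSE) {
  method <- match.arg(method)
  stopifnot(all(c("sex", "age_months", "weight_kg") %in% names(data)))
  rng <- table |>
    dplyr::group_by(.data$sex) |>
    dplyr::summarise(lo = min(.data$age_months), hi = max(.data$age_months),
                     .groups = "drop")
  data <- dplyr::left_join(tibble::as_tibble(data), rng, by = "sex")
  out_of_grid <- is.na(data$age_months) | data$age_months < data$lo |
    data$age_months > data$hi
  usable <- !out_of_grid & !is.na(data$weight_kg)
  expected <- rep(NA_real_, nrow(data))
  if (any(usable)) {
    expected[usable] <- expected_body_weight(
      sex = data$sex[usable], age_months = data$age_months[usable],
      height_m = if ("height_m" %in% names(data)) data$height_m[usable],
      table = table, method = method, fallback = fallback
    )
  }
  data |>
    dplyr::select(-"lo", -"hi") |>
    dplyr::mutate(
      expected_weight_kg = expected,
      percent_ebw = dplyr::if_else(usable, 100 * .data$weight_kg / expected,
                                   NA_real_),
      ebw_method = method,
      ebw_out_of_grid = out_of_grid
    )
}
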