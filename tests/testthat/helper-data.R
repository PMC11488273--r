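# Shared fixtures, built in code.

# One n = 2000 cohort (with MAR gaps) reused across tests that only read it.
.fixture_cache <- new.env(parent = emptyenv())

cached_cohort <- function() {
  if (is.null(.fixture_cache$cohort)) {
    ch <- generate_cohort(cohort_config(n = 2000), seed = 360001)
    .fixture_cache$cohort <- impose_missingness(ch, seed = 360002)
  }
  .fixture_cache$cohort
}

# Ten admission/followup EDE-Q pairs whose five-category classification is
# enumerable by hand (rci 0.88, cutoff 2.71):
#   1 (3.62, 2.27) CS        2 (4.00, 3.50) unchanged  3 (4.00, 3.00) improved
#   4 (3.00, 4.00) deteriorated 5 (2.00, 1.00) normative 6 (5.00, 1.00) CS
#   7 (2.75, 2.74) unchanged (change 0.01)  8 (2.00, 2.00) normative
#   9 (2.00, 3.50) deteriorated (worsens 1.5 from normative range)
#  10 (3.00, 2.80) unchanged
toy_pairs <- function() {
  tibble::tibble(
    participant_id = sprintf("T%02d", 1:10),
    admission = c(3.62, 4.00, 4.00, 3.00, 2.00, 5.00, 2.75, 2.00, 2.00, 3.00),
    followup  = c(2.27, 3.50, 3.00, 4.00, 1.00, 1.00, 2.74, 2.00, 3.50, 2.80)
  )
}

toy_pairs_expected <- c(
  "clinically_significant", "unchanged", "improved", "deteriorated",
  "normative", "clinically_significant", "unchanged", "normative",
  "deteriorated", "unchanged"
)

# Two-row LMS toy table for hand-checked interpolation.
toy_growth <- function() {
  growth_reference(data.frame(
    measure = "bmi_for_age", sex = "female",
    age_months = c(120, 160), L = c(-1.0, -2.0), M = c(17, 21),
    S = c(0.08, 0.12)
  ))
}
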