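test_that("reliable-change thresholds reproduce the published constants", {
  expect_equal(round(rci_threshold(1.59, 0.96), 2), 0.88)
  expect_equal(round(rci_threshold(7.08, 0.89), 2), 6.51)
  expect_equal(round(rci_threshold(5.74, 0.90), 2), 5.03)
  expect_equal(rci_threshold(2.5, 1), 0)       # perfectly reliable scale
  expect_error(rci_threshold(-1, 0.9), "admission_sd")
  expect_error(rci_threshold(1, 1.1), "alpha")
})

test_that("rci_threshold is increasing in sd, decreasing in alpha, linear in z", {
  sds <- seq(0.5, 8, by = 0.5)
  expect_true(all(diff(rci_threshold(sds, 0.9)) > 0))
  alphas <- seq(0, 0.99, by = 0.01)
  expect_true(all(diff(rci_threshold(2, alphas)) < 0))
  expect_equal(rci_threshold(2, 0.9, z = 3), 3 / 1.96 * rci_threshold(2, 0.9))
})

test_that("criterion-c cutoff is the SD-weighted mean of the two population means", {
  expect_equal(criterion_c_cutoff(10, 2, 4, 2), 7)        # equal SDs -> midpoint
  expect_equal(criterion_c_cutoff(10, 2, 4, 0), 4)        # tight norms -> norm mean
  # direct evaluation: (1 * 3.62 + 1.59 * 1) / (1 + 1.59)
  expect_equal(criterion_c_cutoff(3.62, 1.59, 1.0, 1.0),
               (1 * 3.62 + 1.59 * 1) / 2.59, tolerance = 1e-12)
  expect_error(criterion_c_cutoff(3, 0, 1, 0), "both")
})

test_that("change_thresholds builds the default per-scale table", {
  th <- change_thresholds()
  expect_equal(th$scale, c("edeq", "phq9", "gad7"))
  expect_equal(round(th$rci_threshold, 2), c(0.88, 6.51, 5.03))
  expect_equal(th$cs_cutoff, c(2.71, 9.48, 7.97))
})

test_that("classify_change applies the five-category taxonomy", {
  cls <- function(a, f) as.character(classify_change(a, f, rci = 0.88, cutoff = 2.71))
  expect_equal(cls(3.62, 2.27), "clinically_significant")
  expect_equal(cls(4.00, 3.50), "unchanged")
  expect_equal(cls(4.00, 3.00), "improved")
  expect_equal(cls(3.00, 4.00), "deteriorated")
  expect_equal(cls(2.00, 1.00), "normative")
  # strict inequalities: ties at the threshold/cutoff do not count
  expect_equal(cls(4.00, 4.00 - 0.88), "unchanged")
  expect_equal(cls(3.62, 2.71), "improved")     # lands exactly on the cutoff
  expect_true(is.na(classify_change(NA, 2, 0.88, 2.71)))
})

test_that("classification partitions all complete pairs and is monotone", {
  grid <- expand.grid(a = seq(0, 6, by = 0.25), f = seq(0, 6, by = 0.25))
  cat5 <- classify_change(grid$a, grid$f, rci = 0.88, cutoff = 2.71)
  expect_false(anyNA(cat5))                                # exhaustive partition
  expect_setequal(levels(cat5),
                  c("clinically_significant", "improved", "unchanged",
                    "deteriorated", "normative"))
  # fixing admission above the cutoff, decreasing follow-up moves the category
  # only along unchanged -> improved -> clinically_significant
  rank_map <- c(unchanged = 0, improved = 1, clinically_significant = 2)
  for (a in c(2.72, 3.0, 3.62, 5.0, 6.0)) {
    f <- seq(a, 0, by = -0.01)
    cats <- as.character(classify_change(rep(a, length(f)), f, 0.88, 2.71))
    expect_true(all(cats %in% names(rank_map)))
    expect_true(all(diff(rank_map[cats]) >= 0))
  }
  # invariance to a common shift of scores and cutoff
  set.seed(3)
  a <- runif(200, 0, 6); f <- runif(200, 0, 6)
  expect_equal(classify_change(a, f, 0.88, 2.71),
               classify_change(a + 5, f + 5, 0.88, 2.71 + 5))
})

test_that("change_table matches hand enumeration and partitions the cohort", {
  pairs <- toy_pairs()
  scores <- dplyr::bind_rows(
    tibble::tibble(participant_id = pairs$participant_id, timepoint = "admission",
                   scale = "edeq", value = pairs$admission),
    tibble::tibble(participant_id = pairs$participant_id, timepoint = "stepdown",
                   scale = "edeq", value = pairs$followup)
  )
  tab <- change_table(scores)
  sd_tab <- tab[tab$interval == "admit_to_stepdown", ]
  counts <- table(factor(toy_pairs_expected, levels = levels(sd_tab$category)))
  expect_equal(sd_tab$n, as.integer(counts))
  expect_equal(sum(sd_tab$n), 10)
  expect_equal(sum(sd_tab$pct), 100)
  expect_equal(unique(sd_tab$n_reporting), 10)
  # the discharge interval has no data -> only stepdown rows present
  expect_false("admit_to_discharge" %in% tab$interval)
})

test_that("uniform large improvements are all clinically significant", {
  scores <- dplyr::bind_rows(
    tibble::tibble(participant_id = sprintf("p%d", 1:8), timepoint = "admission",
                   scale = "edeq", value = 3.62),
    tibble::tibble(participant_id = sprintf("p%d", 1:8), timepoint = "discharge",
                   scale = "edeq", value = 2.27)
  )
  tab <- change_table(scores)
  expect_equal(tab$pct[tab$category == "clinically_significant"], 100)
})

test_that("with no score change, above-cutoff pairs are unchanged", {
  scores <- dplyr::bind_rows(
    tibble::tibble(participant_id = sprintf("p%d", 1:6), timepoint = "admission",
                   scale = "edeq", value = c(4, 4, 5, 3, 1, 2)),
    tibble::tibble(participant_id = sprintf("p%d", 1:6), timepoint = "discharge",
                   scale = "edeq", value = c(4, 4, 5, 3, 1, 2))
  )
  tab <- change_table(scores)
  expect_equal(tab$n[tab$category == "unchanged"], 4L)
  expect_equal(tab$n[tab$category == "normative"], 2L)
  expect_equal(tab$n[tab$category %in% c("improved", "deteriorated")], c(0L, 0L))
})

test_that("incomplete pairs are excluded from the reporting denominator", {
  scores <- dplyr::bind_rows(
    tibble::tibble(participant_id = c("a", "b", "c"), timepoint = "admission",
                   scale = "edeq", value = c(3.62, 4, 4)),
    tibble::tibble(participant_id = c("a", "b"), timepoint = "discharge",
                   scale = "edeq", value = c(2.27, NA))
  )
  tab <- change_table(scores)
  expect_equal(unique(tab$n_reporting), 1L)
  expect_error(change_table(scores[scores$timepoint == "admission", ]), "empty")
})
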