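fake_result_row <- function(intron, fraction, q, delta, sig, tested = TRUE,
                            tp = 14L) {
  data.table(intron_id = intron, fraction = fraction, timepoint = tp,
             pir_control = 10, pir_mutant = 10 + delta, delta_pir = delta,
             p = q / 2, q = q,
             direction = ifelse(delta > 0, "included", "skipped"),
             n_lines_consistent = 12L, n_line_pairs = 12L,
             coverage_ok = tested, significant = sig)
}

test_that("the classification rule maps significance patterns to categories", {
  res <- rbind(
    fake_result_row("i1", "nuclear", 0.01, 20, TRUE),
    fake_result_row("i1", "cytoplasmic", 0.9, 2, FALSE),
    fake_result_row("i2", "nuclear", 0.01, 20, TRUE),
    fake_result_row("i2", "cytoplasmic", 0.01, 20, TRUE),
    fake_result_row("i3", "nuclear", 0.8, 1, FALSE),
    fake_result_row("i3", "cytoplasmic", 0.02, 15, TRUE),
    fake_result_row("i4", "nuclear", 0.01, -20, TRUE),   # skipped direction
    fake_result_row("i4", "cytoplasmic", 0.9, 0, FALSE)
  )
  calls <- classify_compartment(res, timepoint = 14L)
  expect_equal(calls[intron_id == "i1", category], "nuclear_predominant")
  expect_equal(calls[intron_id == "i2", category], "both_compartments")
  expect_equal(calls[intron_id == "i3", category], "cytoplasmic_predominant")
  expect_false("i4" %in% calls$intron_id)
  expect_false(any(calls$low_confidence))
})

test_that("an event untested in the other fraction is flagged low confidence", {
  res <- rbind(
    fake_result_row("i1", "nuclear", 0.01, 20, TRUE),
    fake_result_row("i1", "cytoplasmic", NA_real_, 5, FALSE, tested = FALSE)
  )
  calls <- classify_compartment(res, timepoint = 14L)
  expect_equal(calls$category, "nuclear_predominant")
  expect_true(calls$low_confidence)
})

test_that("categories partition the classified set and swapping fractions swaps calls", {
  cfg <- small_config(seed = 13L)
  sim <- simulate_fraction_counts(cfg)
  res <- differential_ir_scan(sim$counts, sim$samples)
  calls <- classify_compartment(res, timepoint = 14L)
  expect_false(anyDuplicated(calls$intron_id) > 0)
  swapped <- data.table::copy(res)
  swapped[, fraction := ifelse(fraction == "nuclear", "cytoplasmic", "nuclear")]
  calls2 <- classify_compartment(swapped, timepoint = 14L)
  m <- merge(calls[, .(intron_id, category)], calls2[, .(intron_id, category)],
             by = "intron_id")
  expect_equal(nrow(m), nrow(calls))
  flip <- c(nuclear_predominant = "cytoplasmic_predominant",
            both_compartments = "both_compartments",
            cytoplasmic_predominant = "nuclear_predominant")
  expect_equal(m$category.y, unname(flip[m$category.x]))
  # pure function of its inputs
  expect_identical(calls, classify_compartment(res, timepoint = 14L))
})

test_that("curation overrides can exclude and re-label events", {
  res <- rbind(
    fake_result_row("i1", "nuclear", 0.01, 20, TRUE),
    fake_result_row("i1", "cytoplasmic", 0.9, 2, FALSE),
    fake_result_row("i2", "nuclear", 0.01, 20, TRUE),
    fake_result_row("i2", "cytoplasmic", 0.9, 2, FALSE)
  )
  ov <- data.table(intron_id = c("i1", "i2"),
                   category = c(NA_character_, "both_compartments"))
  calls <- classify_compartment(res, timepoint = 14L, overrides = ov)
  expect_false("i1" %in% calls$intron_id)
  expect_equal(calls[intron_id == "i2", category], "both_compartments")
})

test_that("peak timepoint selection picks the stratum with most events", {
  res <- rbind(fake_result_row("i1", "nuclear", 0.01, 20, TRUE, tp = 7L),
               fake_result_row("i2", "nuclear", 0.01, 20, TRUE, tp = 14L),
               fake_result_row("i3", "cytoplasmic", 0.01, 20, TRUE, tp = 14L))
  expect_equal(pick_peak_timepoint(res), 14L)
})

test_that("external retention profile is null-calibrated and localizes a planted shift", {
  set.seed(7)
  calls <- data.table(
    intron_id = sprintf("i%02d", 1:30),
    category = rep(c("nuclear_predominant", "both_compartments",
                     "cytoplasmic_predominant"), each = 10)
  )
  lines <- data.table(line_id = sprintf("L%d", 1:6),
                      genotype = rep(c("control", "mutant"), each = 3))
  design <- data.table(sample_id = sprintf("s%d", 1:6),
                       line_id = lines$line_id, genotype = lines$genotype)
  base <- CJ(intron_id = calls$intron_id, sample_id = design$sample_id)
  base[, pir := 20 + rnorm(.N, 0, 3)]
  null_prof <- category_retention_profile(base, calls, design)
  expect_true(all(null_prof$perm_p > 0.05))
  expect_lt(abs(null_prof[category == "all", median_paired_diff]), 3)

  shifted <- data.table::copy(base)
  mut_samples <- design[genotype == "mutant", sample_id]
  cyto_ids <- calls[category == "cytoplasmic_predominant", intron_id]
  shifted[intron_id %in% cyto_ids & sample_id %in% mut_samples, pir := pir + 15]
  prof <- category_retention_profile(shifted, calls, design)
  cp <- prof[category == "cytoplasmic_predominant"]
  expect_equal(cp$perm_p, min(prof$perm_p))
  expect_gt(cp$median_paired_diff, 10)
})

test_that("exhaustive line permutation matches direct enumeration on 3+3 lines", {
  m <- c(10, 12, 11, 18, 19, 21)
  line_means <- data.table(line_id = sprintf("L%d", 1:6),
                           genotype = rep(c("control", "mutant"), each = 3),
                           m = m)
  # oracle: all C(6,3)=20 assignments of the mutant label
  combs <- utils::combn(6, 3)
  obs <- mean(m[4:6]) - mean(m[1:3])
  perm <- apply(combs, 2, function(i) mean(m[i]) - mean(m[-i]))
  p_oracle <- mean(abs(perm) >= abs(obs) - 1e-12)

  design <- data.table(sample_id = sprintf("s%d", 1:6),
                       line_id = line_means$line_id,
                       genotype = line_means$genotype)
  calls <- data.table(intron_id = "i1", category = "cytoplasmic_predominant")
  pir <- data.table(intron_id = "i1", sample_id = design$sample_id, pir = m)
  prof <- category_retention_profile(pir, calls, design)
  expect_true(all(prof$exact))
  expect_equal(prof[category == "cytoplasmic_predominant", perm_p], p_oracle)
})

test_that("a mostly unmatched external table demands an ID mapping", {
  calls <- data.table(intron_id = sprintf("i%d", 1:10),
                      category = "nuclear_predominant")
  pir <- data.table(intron_id = c("i1", "x2"), sample_id = "s1", pir = 10)
  design <- data.table(sample_id = "s1", line_id = "L1", genotype = "control")
  expect_error(category_retention_profile(pir, calls, design), "ID mapping")
})
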