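#' Pick the peak timepoint of the aberrant-retention programme
#'
#' The stratum (timepoint) with the most significant IR events across both
#' fractions; ties resolve to the earliest timepoint.
#'
#' @param results Output of [differential_ir_scan()].
#' @return Integer timepoint.
#' @export
pick_peak_timepoint <- function(results) {
  res <- data.table::as.data.table(results)
  tab <- res[significant == TRUE, .N, by = timepoint]
  if (nrow(tab) == 0L) return(sort(unique(res$timepoint))[1])
  data.table::setorder(tab, -N, timepoint)
  tab$timepoint[1]
}

#' Classify aberrant IR events by nucleocytoplasmic distribution
#'
#' At one timepoint, every intron significant with direction `included` in at
#' least one fraction is assigned to exactly one category: significant in the
#' nuclear fraction only -> `nuclear_predominant`; cytoplasmic only ->
#' `cytoplasmic_predominant`; both -> `both_compartments`. Skipped-direction
#' events are excluded. An intron wholly untested (failed coverage) in the
#' other fraction is classified from the tested fraction and flagged
#' `low_confidence`. An optional override table reproduces manual curation:
#' rows with a `category` force that call, rows with `category = NA` exclude
#' the intron.
#'
#' @param results Output of [differential_ir_scan()] covering both fractions.
#' @param timepoint Timepoint to classify at; default
#'   [pick_peak_timepoint()].
#' @param overrides Optional `data.frame(intron_id, category)`.
#' @return `data.table`: `intron_id`, `category`, `nuclear_delta_pir`,
#'   `cytoplasmic_delta_pir`, `nuclear_q`, `cytoplasmic_q`,
#'   `low_confidence`.
#' @export
classify_compartment <- function(results, timepoint = NULL, overrides = NULL) {
  res <- data.table::as.data.table(results)
  tp <- timepoint %||% pick_peak_timepoint(res)
  res <- res[timepoint == tp]
  if (data.table::uniqueN(res$fraction) < 2L)
    stopf("results at timepoint %s do not cover both fractions", tp)
  nuc <- res[fraction == "nuclear"]
  cyt <- res[fraction == "cytoplasmic"]
  ids <- union(nuc$intron_id, cyt$intron_id)
  ni <- match(ids, nuc$intron_id); ci <- match(ids, cyt$intron_id)
  sig_n <- !is.na(ni) & nuc$significant[ni] & nuc$direction[ni] == "included"
  sig_c <- !is.na(ci) & cyt$significant[ci] & cyt$direction[ci] == "included"
  sig_n[is.na(sig_n)] <- FALSE; sig_c[is.na(sig_c)] <- FALSE
  tested_n <- !is.na(ni) & nuc$coverage_ok[ni]
  tested_c <- !is.na(ci) & cyt$coverage_ok[ci]
  keep <- sig_n | sig_c
  category <- ifelse(sig_n & sig_c, "both_compartments",
                     ifelse(sig_n, "nuclear_predominant", "cytoplasmic_predominant"))
  calls <- data.table::data.table(
    intron_id = ids,
    category = category,
    nuclear_delta_pir = nuc$delta_pir[ni],
    cytoplasmic_delta_pir = cyt$delta_pir[ci],
    nuclear_q = nuc$q[ni],
    cytoplasmic_q = cyt$q[ci],
    low_confidence = (sig_n & !tested_c) | (sig_c & !tested_n)
  )[keep]
  if (!is.null(overrides)) {
    ov <- data.table::as.data.table(overrides)
    drop <- ov[is.na(category), intron_id]
    calls <- calls[!intron_id %in% drop]
    force <- ov[!is.na(category)]
    hit <- match(force$intron_id, calls$intron_id)
    calls$category[hit[!is.na(hit)]] <- force$category[!is.na(hit)]
  }
  data.table::setorder(calls, category, intron_id)
  attr(calls, "timepoint") <- tp
  calls[]
}

#' Category-wise retention profile in an external PIR dataset
#'
#' Summarizes percent retention per genotype for each taxonomy category (and
#' for the pooled call set) in any external PIR-like table, and tests the
#' genotype effect with a line-stratified permutation test: the per-line mean
#' retention over the category's introns is the experimental unit, the
#' statistic is the difference of genotype means over lines, and genotype
#' labels are permuted across lines (exhaustively when there are at most
#' `max_exact` assignments, otherwise by Monte Carlo with `n_perm` draws).
#' The effect size is the median over introns of the paired difference of
#' genotype medians.
#'
#' @param external_pir Long table (`intron_id`, `sample_id`, `pir`).
#' @param calls Output of [classify_compartment()] (or a mapping thereof
#'   onto the external dataset's intron ids).
#' @param design Sample sheet for the external dataset (`sample_id`,
#'   `line_id`, `genotype`).
#' @param max_exact,n_perm,seed Permutation controls.
#' @return `data.table`: category (including `"all"`), per-genotype medians,
#'   median paired difference, permutation p, numbers of lines and introns.
#' @export
category_retention_profile <- function(external_pir, calls, design,
                                       max_exact = 20000L, n_perm = 10000L,
                                       seed = 1L) {
  pir <- data.table::as.data.table(external_pir)
  design <- data.table::as.data.table(design)
  calls <- data.table::as.data.table(calls)
  found <- mean(calls$intron_id %in% unique(pir$intron_id))
  if (found < 0.5)
    stopf("only %.0f%% of classified introns found in the external table; supply an intron ID mapping",
          100 * found)
  pir <- merge(pir, design[, .(sample_id, line_id, genotype)], by = "sample_id")
  groups <- c(list(all = calls$intron_id),
              split(calls$intron_id, calls$category))
  out <- lapply(names(groups), function(g) {
    sub <- pir[intron_id %in% groups[[g]] & !is.na(pir)]
    if (nrow(sub) == 0L) return(NULL)
    line_means <- sub[, .(m = mean(pir)), by = .(line_id, genotype)]
    pm <- line_permutation_p(line_means, max_exact, n_perm, seed)
    med <- sub[, .(med = median(pir)), by = .(intron_id, genotype)]
    wide <- data.table::dcast(med, intron_id ~ genotype, value.var = "med")
    paired <- if (all(c("mutant", "control") %in% names(wide)))
      median(wide$mutant - wide$control, na.rm = TRUE) else NA_real_
    data.table::data.table(
      category = g,
      median_control = median(sub[genotype == "control", pir]),
      median_mutant = median(sub[genotype == "mutant", pir]),
      median_paired_diff = paired,
      perm_p = pm$p, exact = pm$exact,
      n_lines = nrow(line_means), n_introns = data.table::uniqueN(sub$intron_id)
    )
  })
  data.table::rbindlist(out)
}

line_permutation_p <- function(line_means, max_exact, n_perm, seed) {
  m <- line_means$m
  is_mut <- line_means$genotype == "mutant"
  k <- sum(is_mut); n <- length(m)
  if (k == 0L || k == n) return(list(p = NA_real_, exact = NA))
  stat <- function(idx) mean(m[idx]) - mean(m[-idx])
  obs <- stat(which(is_mut))
  n_comb <- choose(n, k)
  if (n_comb <= max_exact) {
    combs <- utils::combn(n, k)
    perm <- apply(combs, 2, stat)
    list(p = mean(abs(perm) >= abs(obs) - 1e-12), exact = TRUE)
  } else {
    perm <- with_seed(seed, vapply(seq_len(n_perm), function(i)
      stat(sample.int(n, k)), numeric(1)))
    list(p = (1 + sum(abs(perm) >= abs(obs) - 1e-12)) / (1 + n_perm), exact = FALSE)
  }
}
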