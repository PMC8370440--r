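#' Scan for differential intron retention between genotypes
#'
#' For every fraction x timepoint stratum, junction counts are pooled within
#' genotype across lines; pooled PIR, ΔPIR (mutant - control, percentage
#' points) and a two-sided Fisher count test are computed per intron, with
#' Benjamini-Hochberg correction within the stratum. The Fisher table opposes
#' the retention arm (EI + IE) to the splicing arm (`ee_weight * EE`,
#' default 2: one retained molecule presents two boundary junctions where one
#' spliced molecule presents a single exon-exon junction). An event is
#' significant when q < `q_threshold`, |ΔPIR| >= `delta_threshold`, pooled
#' junction coverage reaches `min_coverage` in both genotypes, and the sign
#' of the per-line PIR difference agrees with ΔPIR in at least
#' ceil(`consistency` * pairs) of the control x mutant line pairs with
#' defined per-line PIR.
#'
#' @param counts Junction-count table (`sample_id`, `intron_id`, EI, IE, EE).
#' @param design Sample sheet (`sample_id`, `line_id`, `genotype`, `DIV`,
#'   `fraction`); genotypes must be `control` / `mutant`.
#' @param q_threshold,delta_threshold,min_coverage Significance thresholds.
#' @param ee_weight Weight on EE in the Fisher splicing arm (2 or 1).
#' @param consistency Required fraction of sign-consistent line pairs.
#' @param min_line_reads Junction reads required for a per-line PIR.
#' @return `data.table`, one row per intron x fraction x timepoint:
#'   `pir_control`, `pir_mutant`, `delta_pir`, `p`, `q`, `direction`
#'   (`included`/`skipped`), `n_lines_consistent`, `n_line_pairs`,
#'   `coverage_ok`, `significant`. Strata missing one genotype entirely are
#'   skipped with a warning.
#' @export
differential_ir_scan <- function(counts, design,
                                 q_threshold = 0.05, delta_threshold = 10,
                                 min_coverage = 20L, ee_weight = 2,
                                 consistency = 2 / 3, min_line_reads = 10L) {
  counts <- data.table::as.data.table(counts)
  design <- data.table::as.data.table(design)
  stopifnot(all(c("control", "mutant") %in% unique(design$genotype)))
  dt <- merge(counts[, .(sample_id, intron_id, EI, IE, EE)],
              design[, .(sample_id, line_id, genotype, DIV, fraction)],
              by = "sample_id")

  res_list <- list()
  for (fr in unique(design$fraction)) {
    for (tp in sort(unique(design$DIV))) {
      sub <- dt[fraction == fr & DIV == tp]
      if (nrow(sub) == 0L) next
      if (data.table::uniqueN(sub$genotype) < 2L) {
        warnf("stratum %s / DIV %s lacks one genotype entirely; skipped", fr, tp)
        next
      }
      pooled <- sub[, .(EI = sum(EI), IE = sum(IE), EE = sum(EE)),
                    by = .(intron_id, genotype)]
      wide <- data.table::dcast(pooled, intron_id ~ genotype,
                                value.var = c("EI", "IE", "EE"), fill = 0L)
      ret_c <- wide$EI_control + wide$IE_control
      ret_m <- wide$EI_mutant + wide$IE_mutant
      pir_c <- 100 * (ret_c / 2) / (ret_c / 2 + wide$EE_control)
      pir_m <- 100 * (ret_m / 2) / (ret_m / 2 + wide$EE_mutant)
      cov_ok <- (ret_c + wide$EE_control) >= min_coverage &
        (ret_m + wide$EE_mutant) >= min_coverage
      spl_c <- as.integer(round(ee_weight * wide$EE_control))
      spl_m <- as.integer(round(ee_weight * wide$EE_mutant))
      p <- fisher_p_vec(ret_c, spl_c, ret_m, spl_m)
      q <- rep(NA_real_, length(p))
      q[cov_ok] <- p.adjust(p[cov_ok], method = "BH")

      cons <- line_sign_consistency(sub, wide$intron_id, pir_m - pir_c,
                                    min_line_reads)
      delta <- pir_m - pir_c
      need <- ceiling(consistency * cons$n_pairs)
      res <- data.table::data.table(
        intron_id = wide$intron_id, fraction = fr, timepoint = tp,
        pir_control = pir_c, pir_mutant = pir_m, delta_pir = delta,
        p = p, q = q,
        direction = ifelse(delta > 0, "included", "skipped"),
        n_lines_consistent = cons$n_consistent, n_line_pairs = cons$n_pairs,
        coverage_ok = cov_ok
      )
      res[, significant := !is.na(q) & q < q_threshold &
            abs(delta_pir) >= delta_threshold & coverage_ok &
            n_line_pairs > 0L & n_lines_consistent >= need]
      res_list[[length(res_list) + 1L]] <- res
    }
  }
  out <- data.table::rbindlist(res_list)
  if (nrow(out) == 0L)
    return(data.table::data.table(
      intron_id = character(), fraction = character(), timepoint = integer(),
      pir_control = numeric(), pir_mutant = numeric(), delta_pir = numeric(),
      p = numeric(), q = numeric(), direction = character(),
      n_lines_consistent = integer(), n_line_pairs = integer(),
      coverage_ok = logical(), significant = logical()))
  data.table::setorder(out, fraction, timepoint, intron_id)
  out[]
}

fisher_p_vec <- function(ret_c, spl_c, ret_m, spl_m) {
  n <- length(ret_c)
  p <- rep(1, n)
  rs <- ret_c + ret_m; ss <- spl_c + spl_m
  gc_ <- ret_c + spl_c; gm <- ret_m + spl_m
  live <- rs > 0L & ss > 0L & gc_ > 0L & gm > 0L
  for (i in which(live)) {
    p[i] <- stats::fisher.test(matrix(c(ret_c[i], spl_c[i], ret_m[i], spl_m[i]),
                                      nrow = 2, byrow = TRUE))$p.value
  }
  p
}

line_sign_consistency <- function(sub, intron_ids, delta, min_line_reads) {
  per_line <- sub[, .(EI = sum(EI), IE = sum(IE), EE = sum(EE)),
                  by = .(intron_id, line_id, genotype)]
  per_line[, pir := 100 * ((EI + IE) / 2) / ((EI + IE) / 2 + EE)]
  per_line[(EI + IE + EE) < min_line_reads, pir := NA_real_]
  ctrl <- per_line[genotype == "control"]
  mut <- per_line[genotype == "mutant"]
  cw <- data.table::dcast(ctrl, intron_id ~ line_id, value.var = "pir")
  mw <- data.table::dcast(mut, intron_id ~ line_id, value.var = "pir")
  cm <- as.matrix(cw[match(intron_ids, cw$intron_id), -1, drop = FALSE])
  mm <- as.matrix(mw[match(intron_ids, mw$intron_id), -1, drop = FALSE])
  n_cons <- integer(length(intron_ids))
  n_pairs <- integer(length(intron_ids))
  sgn <- sign(delta)
  for (a in seq_len(ncol(mm))) {
    for (b in seq_len(ncol(cm))) {
      d <- mm[, a] - cm[, b]
      ok <- !is.na(d)
      n_pairs <- n_pairs + ok
      n_cons <- n_cons + (ok & sign(d) == sgn & sgn != 0)
    }
  }
  list(n_consistent = n_cons, n_pairs = n_pairs)
}

#' Union of significant IR events across timepoints
#'
#' @param results Output of [differential_ir_scan()].
#' @return `data.table` of unique (fraction, intron_id, direction) triples
#'   significant in at least one timepoint, with the best (smallest) q and
#'   the timepoint achieving it.
#' @export
ir_event_union <- function(results) {
  sig <- data.table::as.data.table(results)[significant == TRUE]
  if (nrow(sig) == 0L) return(sig[, .(fraction, intron_id, direction, q, timepoint)])
  sig[order(q), .(direction = direction[1], q = q[1], timepoint = timepoint[1],
                  n_timepoints = .N),
      by = .(fraction, intron_id)]
}

#' Tally a splicing census by event class and direction
#'
#' IR events come from the differential scan; other event classes (AltEx,
#' Alt5, Alt3, MIC) are tallied from an optional pre-classified table — they
#' are counted, never re-quantified.
#'
#' @param results Output of [differential_ir_scan()].
#' @param events Optional pre-classified table with columns `event_id`,
#'   `class` (AltEx/Alt5/Alt3/MIC), `direction`, `fraction`, `timepoint`.
#' @return `data.table`: fraction, timepoint, class, direction, n,
#'   proportion (within fraction x timepoint).
#' @export
splicing_event_census <- function(results, events = NULL) {
  classes <- c("IR", "AltEx", "Alt5", "Alt3", "MIC")
  sig <- data.table::as.data.table(results)[significant == TRUE]
  ir <- sig[, .(n = .N), by = .(fraction, timepoint, direction)]
  ir[, class := "IR"]
  tallies <- ir
  if (!is.null(events) && nrow(events) > 0L) {
    ev <- data.table::as.data.table(events)
    bad <- setdiff(unique(ev$class), classes)
    if (length(bad) > 0L) stopf("unknown splicing class label: %s", bad[1])
    extra <- ev[, .(n = .N), by = .(fraction, timepoint, class, direction)]
    tallies <- data.table::rbindlist(list(ir, extra), use.names = TRUE)
  }
  if (nrow(tallies) == 0L)
    return(data.table::data.table(fraction = character(), timepoint = integer(),
                                  class = character(), direction = character(),
                                  n = integer(), proportion = numeric()))
  tallies[, proportion := n / sum(n), by = .(fraction, timepoint)]
  data.table::setcolorder(tallies, c("fraction", "timepoint", "class",
                                     "direction", "n", "proportion"))
  data.table::setorder(tallies, fraction, timepoint, class, direction)
  tallies[]
}

#' Cytoplasmic expression shift of splicing-factor genes
#'
#' Per timepoint, the cytoplasmic log2 fold-change (mutant vs control) of
#' each factor gene is computed from genotype-mean CPM (pseudocount 1), and
#' the distribution is summarized with a one-sided sign test for a downward
#' median shift.
#'
#' @param expr Result of [compute_expression()].
#' @param factor_genes Character vector of gene ids (non-empty).
#' @param design Sample sheet.
#' @return List: `shifts` (per timepoint x gene log2FC), `summary` (per
#'   timepoint median/quartiles and sign-test p), `missing` (factor genes
#'   absent from the expression table).
#' @export
splicing_factor_shift <- function(expr, factor_genes, design) {
  if (length(factor_genes) == 0L) stopf("empty splicing-factor gene list")
  design <- data.table::as.data.table(design)
  missing <- setdiff(factor_genes, rownames(expr$cpm))
  present <- intersect(factor_genes, rownames(expr$cpm))
  if (length(present) == 0L) stopf("no factor gene found in expression table")
  cyto <- design[fraction == "cytoplasmic"]
  rows <- list()
  for (tp in sort(unique(cyto$DIV))) {
    cs <- cyto[DIV == tp & genotype == "control", sample_id]
    ms <- cyto[DIV == tp & genotype == "mutant", sample_id]
    if (length(cs) == 0L || length(ms) == 0L) next
    mc <- rowMeans(expr$cpm[present, cs, drop = FALSE])
    mm <- rowMeans(expr$cpm[present, ms, drop = FALSE])
    rows[[length(rows) + 1L]] <- data.table::data.table(
      timepoint = tp, gene_id = present, log2fc = log2((mm + 1) / (mc + 1))
    )
  }
  shifts <- data.table::rbindlist(rows)
  summary <- shifts[, {
    nz <- log2fc[log2fc != 0]
    pv <- if (length(nz) > 0)
      binom.test(sum(nz < 0), length(nz), alternative = "greater")$p.value else 1
    list(median = median(log2fc), q25 = quantile(log2fc, 0.25),
         q75 = quantile(log2fc, 0.75), n = .N, sign_test_p = pv)
  }, by = timepoint]
  list(shifts = shifts, summary = summary, missing = missing)
}
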