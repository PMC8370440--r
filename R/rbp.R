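#' Crosslink-event enrichment scores for one RBP track
#'
#' An event counts for an intron when its interval midpoint lies inside the
#' intron (point-like crosslinks; no double counting at boundaries) and its
#' strand matches the intron's (strandless events match both strands).
#' Densities are weighted events per kb; the enrichment score is
#' `log2((density + pseudocount) / (background_density + pseudocount))`
#' where the background density is the median density over
#' `background_introns`.
#'
#' @param track `GRanges` of crosslink events (optional `score` column as
#'   count weight, default 1), or a BED path.
#' @param introns Intron table to score.
#' @param background_introns Intron table of the background set (non-empty).
#' @param pseudocount Density pseudocount, events/kb.
#' @return `data.table`: `intron_id`, `density`, `score`, with the
#'   background density as an attribute.
#' @export
score_crosslink_enrichment <- function(track, introns, background_introns,
                                       pseudocount = 0.1) {
  if (is.character(track)) track <- rtracklayer::import(track, format = "BED")
  if (nrow(background_introns) == 0L) stopf("background intron set is empty")
  dens <- crosslink_density(track, introns)
  bg <- median(crosslink_density(track, background_introns))
  score <- log2((dens + pseudocount) / (bg + pseudocount))
  out <- data.table::data.table(intron_id = introns$intron_id,
                                density = dens, score = score)
  attr(out, "background_density") <- bg
  out
}

crosslink_density <- function(track, introns) {
  w <- track$score
  if (is.null(w)) w <- rep(1, length(track))
  w[is.na(w)] <- 1
  mid <- GenomicRanges::resize(track, width = 1L, fix = "center")
  igr <- introns_to_granges(introns)
  stranded <- as.character(GenomicRanges::strand(mid)) != "*"
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(mid, igr, ignore.strand = TRUE))
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  same <- !stranded[qh] |
    as.character(GenomicRanges::strand(mid))[qh] == introns$strand[sh]
  dt <- data.table::data.table(i = sh[same], w = w[qh][same])
  agg <- dt[, .(total = sum(w)), by = i]
  counts <- rep(0, nrow(introns))
  counts[agg$i] <- agg$total
  1000 * counts / (introns$end - introns$start)
}

#' Intron x RBP enrichment-score matrix
#'
#' @param tracks Named list of crosslink `GRanges` (or BED paths), one per
#'   RBP.
#' @param introns Intron table (rows of the matrix).
#' @param background_introns Background intron table.
#' @param pseudocount Density pseudocount, events/kb.
#' @return List: `scores` (matrix intron x RBP, log2 scale),
#'   `background_density` (per RBP).
#' @export
crosslink_enrichment_matrix <- function(tracks, introns, background_introns,
                                        pseudocount = 0.1) {
  stopifnot(length(names(tracks)) == length(tracks))
  if (nrow(background_introns) == 0L) stopf("background intron set is empty")
  # one density pass per RBP over the combined intron set
  combined <- data.table::rbindlist(list(
    data.table::as.data.table(introns)[, .(intron_id, chrom, start, end, strand)],
    data.table::as.data.table(background_introns)[, .(intron_id, chrom, start, end, strand)]
  ))
  fg <- seq_len(nrow(introns))
  bgi <- nrow(introns) + seq_len(nrow(background_introns))
  m <- matrix(NA_real_, nrow = nrow(introns), ncol = length(tracks),
              dimnames = list(introns$intron_id, names(tracks)))
  bg <- setNames(numeric(length(tracks)), names(tracks))
  for (r in names(tracks)) {
    tr <- tracks[[r]]
    if (is.character(tr)) tr <- rtracklayer::import(tr, format = "BED")
    dens <- crosslink_density(tr, combined)
    bg[[r]] <- median(dens[bgi])
    m[, r] <- log2((dens[fg] + pseudocount) / (bg[[r]] + pseudocount))
  }
  list(scores = m, background_density = bg)
}

#' Rank RBPs by differential binding to cytoplasmic- vs nuclear-predominant
#' introns
#'
#' Per RBP: two-sided Mann-Whitney test of enrichment scores in
#' cytoplasmic-predominant vs nuclear-predominant introns (and secondarily
#' vs both-compartments), BH correction across RBPs; an RBP is flagged
#' enriched when q < `q_threshold` and its cytoplasmic median exceeds its
#' nuclear median. The ranking orders by effect size (difference of
#' medians), then p, then name — deterministic under ties.
#'
#' @param matrix_scores Result of [crosslink_enrichment_matrix()] (or a bare
#'   score matrix).
#' @param calls Output of [classify_compartment()].
#' @param q_threshold FDR cutoff.
#' @return `data.table`, one row per RBP, sorted: medians per category,
#'   `effect` (cyt - nuc median), `p`, `p_vs_both`, `q`, `enriched`.
#' @export
rank_rbps_by_category <- function(matrix_scores, calls, q_threshold = 0.05) {
  m <- if (is.list(matrix_scores)) matrix_scores$scores else matrix_scores
  calls <- data.table::as.data.table(calls)
  idx <- function(cat) intersect(calls[category == cat, intron_id], rownames(m))
  nuc <- idx("nuclear_predominant"); cyt <- idx("cytoplasmic_predominant")
  both <- idx("both_compartments")
  if (length(nuc) < 3L || length(cyt) < 3L)
    stopf("need at least 3 introns in the nuclear and cytoplasmic categories (got %d / %d)",
          length(nuc), length(cyt))
  rows <- lapply(colnames(m), function(r) {
    xc <- m[cyt, r]; xn <- m[nuc, r]
    mw <- mann_whitney_test(xc, xn)
    pb <- if (length(both) >= 3L) mann_whitney_test(xc, m[both, r])$p else NA_real_
    data.table::data.table(
      rbp = r, median_cytoplasmic = median(xc), median_nuclear = median(xn),
      median_both = if (length(both) > 0L) median(m[both, r]) else NA_real_,
      effect = median(xc) - median(xn), U = mw$U, p = mw$p, p_vs_both = pb)
  })
  out <- data.table::rbindlist(rows)
  out[, q := p.adjust(p, method = "BH")]
  out[, enriched := q < q_threshold & median_cytoplasmic > median_nuclear]
  data.table::setorder(out, -effect, p, rbp)
  out[]
}

#' Per-category enrichment profile of a single RBP
#'
#' @param matrix_scores Result of [crosslink_enrichment_matrix()] (or a bare
#'   score matrix).
#' @param calls Output of [classify_compartment()].
#' @param rbp_name Column of the matrix to profile.
#' @return List: `summary` (per-category median/quartiles/n) and `tests`
#'   (pairwise Mann-Whitney p per category pair).
#' @export
per_category_rbp_profile <- function(matrix_scores, calls, rbp_name) {
  m <- if (is.list(matrix_scores)) matrix_scores$scores else matrix_scores
  if (!rbp_name %in% colnames(m))
    stopf("unknown RBP '%s'; available: %s", rbp_name,
          paste(utils::head(colnames(m), 20), collapse = ", "))
  calls <- data.table::as.data.table(calls)
  cats <- c("nuclear_predominant", "both_compartments", "cytoplasmic_predominant")
  vals <- lapply(cats, function(cat) {
    ids <- intersect(calls[category == cat, intron_id], rownames(m))
    m[ids, rbp_name]
  })
  names(vals) <- cats
  if (any(vapply(vals, length, 1L) == 0L))
    stopf("category with no introns in the matrix for %s", rbp_name)
  summary <- data.table::rbindlist(lapply(cats, function(cat) {
    v <- vals[[cat]]
    data.table::data.table(category = cat, n = length(v), median = median(v),
                           q25 = quantile(v, 0.25), q75 = quantile(v, 0.75))
  }))
  pairs <- utils::combn(cats, 2)
  tests <- data.table::rbindlist(lapply(seq_len(ncol(pairs)), function(j) {
    mw <- mann_whitney_test(vals[[pairs[1, j]]], vals[[pairs[2, j]]])
    data.table::data.table(group1 = pairs[1, j], group2 = pairs[2, j],
                           U = mw$U, p = mw$p)
  }))
  list(summary = summary, tests = tests)
}
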