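#' GC fraction of a nucleotide sequence
#'
#' (G + C) / (A + C + G + T); N bases are excluded from numerator and
#' denominator. Empty effective length yields `NA`. Non-ACGTN characters are
#' an error.
#'
#' @param sequence Character scalar over {A, C, G, T, N} (case-insensitive).
#' @return GC fraction in [0, 1], or `NA`.
#' @export
compute_gc <- function(sequence) {
  s <- Biostrings::DNAString(toupper(sequence))  # errors on non-IUPAC input
  f <- Biostrings::letterFrequency(s, c("A", "C", "G", "T", "N"))
  if (sum(f) != length(s))  # rejects IUPAC ambiguity codes other than N
    stopf("sequence contains characters outside {A,C,G,T,N}")
  denom <- sum(f[c("A", "C", "G", "T")])
  if (denom == 0) return(NA_real_)
  unname((f[["G"]] + f[["C"]]) / denom)
}

#' Mean conservation score over intervals
#'
#' Length-weighted arithmetic mean of per-base scores over the bases of each
#' interval covered by the track; the mean is `NA` when less than
#' `min_coverage` of the interval's bases are covered. Invariant to how the
#' track is segmented.
#'
#' @param track `GRanges` with a `score` column (e.g. from
#'   `rtracklayer::import(..., format = "bedGraph")`), or a bedGraph path.
#' @param introns Intron table (`intron_id`, `chrom`, `start`, `end`).
#' @param min_coverage Minimum covered fraction for a defined mean.
#' @return `data.table`: `intron_id`, `conservation`, `coverage`.
#' @export
compute_conservation <- function(track, introns, min_coverage = 0.5) {
  if (is.character(track)) track <- rtracklayer::import(track, format = "bedGraph")
  igr <- introns_to_granges(introns)
  hits <- suppressWarnings(GenomicRanges::findOverlaps(igr, track, ignore.strand = TRUE))
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  inter <- suppressWarnings(
    GenomicRanges::pintersect(igr[qh], track[sh], ignore.strand = TRUE))
  w <- GenomicRanges::width(inter)
  sc <- track$score[sh]
  dt <- data.table::data.table(i = qh, w = w, ws = w * sc)
  agg <- dt[, .(covered = sum(w), total = sum(ws)), by = i]
  len <- introns$end - introns$start
  conservation <- rep(NA_real_, nrow(introns))
  coverage <- rep(0, nrow(introns))
  coverage[agg$i] <- agg$covered / len[agg$i]
  conservation[agg$i] <- agg$total / agg$covered
  miss_chrom <- !introns$chrom %in% as.character(unique(GenomeInfoDb::seqnames(track)))
  if (any(miss_chrom))
    warnf("%d intron(s) on chromosomes absent from the conservation track", sum(miss_chrom))
  conservation[coverage < min_coverage] <- NA_real_
  data.table::data.table(intron_id = introns$intron_id,
                         conservation = conservation, coverage = coverage)
}

#' Per-intron cis-feature table (length, GC, conservation)
#'
#' @param introns Intron table.
#' @param genome Optional `DNAStringSet` for GC (forward-strand GC; GC is
#'   strand-invariant).
#' @param track Optional conservation track for [compute_conservation()].
#' @return `data.table`: `intron_id`, `length`, `gc`, `conservation`.
#' @export
cis_feature_table <- function(introns, genome = NULL, track = NULL) {
  out <- data.table::data.table(
    intron_id = introns$intron_id,
    length = introns$end - introns$start,
    gc = NA_real_, conservation = NA_real_
  )
  if (!is.null(genome)) {
    seqs <- Biostrings::subseq(genome[introns$chrom],
                               start = introns$start + 1L, end = introns$end)
    f <- Biostrings::letterFrequency(seqs, c("G", "C", "A", "T"))
    out$gc <- (f[, "G"] + f[, "C"]) / rowSums(f)
  }
  if (!is.null(track)) {
    out$conservation <- compute_conservation(track, introns)$conservation
  }
  out[]
}

#' Compare cis features among taxonomy categories and background
#'
#' For each feature (length, gc, conservation) and each pair of groups
#' (the three categories plus the background intron set), a two-sided
#' Mann-Whitney test with BH correction across all comparisons. Groups with
#' fewer than 3 members are skipped with a flag.
#'
#' @param features Output of [cis_feature_table()].
#' @param calls Output of [classify_compartment()].
#' @param background_introns Character vector of background intron ids
#'   (see [background_intron_set()]).
#' @return `data.table`: feature, group1, group2, n1, n2, U, p, q, medians,
#'   direction, skipped.
#' @export
compare_categories <- function(features, calls, background_introns) {
  features <- data.table::as.data.table(features)
  calls <- data.table::as.data.table(calls)
  groups <- list(
    nuclear = calls[category == "nuclear_predominant", intron_id],
    both = calls[category == "both_compartments", intron_id],
    cytoplasmic = calls[category == "cytoplasmic_predominant", intron_id],
    background = setdiff(background_introns, calls$intron_id)
  )
  pairs <- utils::combn(names(groups), 2)
  rows <- list()
  for (feat in c("length", "gc", "conservation")) {
    if (all(is.na(features[[feat]]))) next
    for (j in seq_len(ncol(pairs))) {
      g1 <- pairs[1, j]; g2 <- pairs[2, j]
      x <- features[intron_id %in% groups[[g1]]][[feat]]
      y <- features[intron_id %in% groups[[g2]]][[feat]]
      x <- x[!is.na(x)]; y <- y[!is.na(y)]
      if (length(x) < 3L || length(y) < 3L) {
        rows[[length(rows) + 1L]] <- data.table::data.table(
          feature = feat, group1 = g1, group2 = g2,
          n1 = length(x), n2 = length(y), U = NA_real_, p = NA_real_,
          median1 = NA_real_, median2 = NA_real_,
          direction = NA_character_, skipped = TRUE)
        next
      }
      mw <- mann_whitney_test(x, y)
      rows[[length(rows) + 1L]] <- data.table::data.table(
        feature = feat, group1 = g1, group2 = g2,
        n1 = length(x), n2 = length(y), U = mw$U, p = mw$p,
        median1 = median(x), median2 = median(y),
        direction = if (median(x) > median(y)) g1
                    else if (median(y) > median(x)) g2 else "none",
        skipped = FALSE)
    }
  }
  out <- data.table::rbindlist(rows)
  out[, q := NA_real_]
  out[skipped == FALSE, q := p.adjust(p, method = "BH")]
  out[]
}

#' Background intron set: all introns of genes hosting an aberrant IR event
#'
#' @param introns Intron table.
#' @param calls Output of [classify_compartment()].
#' @return Character vector of intron ids.
#' @export
background_intron_set <- function(introns, calls) {
  introns <- data.table::as.data.table(introns)
  genes <- unique(introns[intron_id %in% calls$intron_id, gene_id])
  introns[gene_id %in% genes, intron_id]
}

#' Couple taxonomy categories to host-gene expression changes
#'
#' Per category and fraction at one timepoint: the distribution of host-gene
#' log2 fold-changes (mutant vs control genotype-mean CPM, pseudocount 1),
#' a two-sided sign test against zero (skipped below 3 informative genes),
#' and BH correction across the category x fraction cells.
#'
#' @param expr Result of [compute_expression()].
#' @param calls Output of [classify_compartment()].
#' @param design Sample sheet.
#' @param host_map `data.frame(intron_id, gene_id)` mapping events to host
#'   genes (e.g. the intron table).
#' @param timepoint Timepoint of the comparison; default the calls'
#'   timepoint attribute.
#' @return `data.table`: category, fraction, n_genes, n_missing,
#'   median_log2fc, sign_test_p, q.
#' @export
expression_coupling <- function(expr, calls, design, host_map, timepoint = NULL) {
  design <- data.table::as.data.table(design)
  host_map <- data.table::as.data.table(host_map)
  tp <- timepoint %||% attr(calls, "timepoint") %||% sort(unique(design$DIV))[1]
  rows <- list()
  for (cat in unique(calls$category)) {
    genes <- unique(host_map[intron_id %in% calls[category == cat, intron_id], gene_id])
    present <- intersect(genes, rownames(expr$cpm))
    for (fr in c("nuclear", "cytoplasmic")) {
      cs <- design[DIV == tp & fraction == fr & genotype == "control", sample_id]
      ms <- design[DIV == tp & fraction == fr & genotype == "mutant", sample_id]
      if (length(present) == 0L || length(cs) == 0L || length(ms) == 0L) {
        rows[[length(rows) + 1L]] <- data.table::data.table(
          category = cat, fraction = fr, n_genes = length(present),
          n_missing = length(genes) - length(present),
          median_log2fc = NA_real_, sign_test_p = NA_real_)
        next
      }
      l2fc <- log2((rowMeans(expr$cpm[present, ms, drop = FALSE]) + 1) /
                     (rowMeans(expr$cpm[present, cs, drop = FALSE]) + 1))
      nz <- l2fc[l2fc != 0]
      pv <- if (length(nz) >= 3L)
        binom.test(sum(nz < 0), length(nz))$p.value else NA_real_
      rows[[length(rows) + 1L]] <- data.table::data.table(
        category = cat, fraction = fr, n_genes = length(present),
        n_missing = length(genes) - length(present),
        median_log2fc = median(l2fc), sign_test_p = pv)
    }
  }
  out <- data.table::rbindlist(rows)
  out[, q := p.adjust(sign_test_p, method = "BH")]
  out[]
}
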