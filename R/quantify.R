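#' Count junction-informative reads for a set of introns
#'
#' Classifies alignments from one sample against each intron:
#' \describe{
#'   \item{EE}{a split read whose skipped (N) segment equals the intron
#'     exactly — unambiguous evidence of splicing;}
#'   \item{EI / IE}{a contiguous (junction-free) read crossing the intron's
#'     transcription-order 5' / 3' boundary with at least `min_overhang`
#'     aligned bases on each side;}
#'   \item{body}{a contiguous read fully inside the intron.}
#' }
#' A read counts for at most one class per intron, with priority
#' EE > EI/IE > body; a contiguous read crossing both boundaries (possible
#' only for introns shorter than the read) is counted as EI. Split reads may
#' count EE for several introns. Reads on chromosomes absent from the intron
#' set are skipped with a warning; unmapped reads are ignored.
#'
#' @param sam_path Path to a SAM or BAM file (SAM is converted on the fly).
#' @param introns Intron table from [derive_introns()].
#' @param min_overhang Minimum aligned bases on each side of a boundary.
#' @param sample_id Sample label for the output table.
#' @param exons Optional exon table; when given, `gene_exonic` counts
#'   junction-free reads fully contained in an exon of the intron's host
#'   gene, otherwise `gene_exonic` is `NA`.
#' @return `data.table` with one row per intron: `sample_id`, `intron_id`,
#'   `EI`, `IE`, `EE`, `body`, `gene_exonic`.
#' @export
count_junction_reads <- function(sam_path, introns, min_overhang = 8L,
                                 sample_id = basename(sam_path), exons = NULL) {
  ov <- as.integer(min_overhang)
  bam <- sam_path
  if (grepl("\\.sam$", sam_path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- suppressMessages(Rsamtools::asBam(sam_path, destination = dest,
                                             indexDestination = FALSE))
  }
  gal <- GenomicAlignments::readGAlignments(bam)

  known <- unique(introns$chrom)
  on_known <- as.character(GenomeInfoDb::seqnames(gal)) %in% known
  if (any(!on_known)) {
    warnf("%d read(s) on chromosomes absent from the intron set skipped",
          sum(!on_known))
    gal <- gal[on_known]
  }

  out <- data.table::data.table(
    sample_id = sample_id, intron_id = introns$intron_id,
    EI = 0L, IE = 0L, EE = 0L, body = 0L, gene_exonic = NA_integer_
  )
  if (length(gal) == 0L) return(out)

  intron_key <- interval_key(introns$chrom, introns$start, introns$end, "*")

  # EE: skipped segments matching an intron exactly
  jn <- GenomicAlignments::junctions(gal)
  jn_flat <- unlist(jn, use.names = FALSE)
  if (length(jn_flat) > 0L) {
    jk <- interval_key(as.character(GenomeInfoDb::seqnames(jn_flat)),
                       GenomicRanges::start(jn_flat) - 1L,
                       GenomicRanges::end(jn_flat), "*")
    hits <- match(jk, intron_key)
    ee_tab <- table(hits[!is.na(hits)])
    out$EE[as.integer(names(ee_tab))] <- as.integer(ee_tab)
  }

  # contiguous reads only, as genomic spans (1-based closed from GRanges)
  contig <- gal[GenomicAlignments::njunc(gal) == 0L]
  if (length(contig) == 0L) return(out)
  spans <- GenomicRanges::granges(contig)
  GenomicRanges::strand(spans) <- "*"

  igr <- introns_to_granges(introns)
  win <- function(boundary0) {
    # 0-based window [b-ov, b+ov) -> 1-based closed (b-ov+1, b+ov)
    GenomicRanges::GRanges(introns$chrom,
                           IRanges::IRanges(start = boundary0 - ov + 1L,
                                            end = boundary0 + ov))
  }
  cross_start <- suppressWarnings(GenomicRanges::findOverlaps(win(introns$start), spans, type = "within"))
  cross_end <- suppressWarnings(GenomicRanges::findOverlaps(win(introns$end), spans, type = "within"))
  body_hits <- suppressWarnings(GenomicRanges::findOverlaps(spans, igr, type = "within",
                                           ignore.strand = TRUE))

  pair <- data.table::rbindlist(list(
    data.table::data.table(intron = S4Vectors::queryHits(cross_start),
                           read = S4Vectors::subjectHits(cross_start), kind = "s"),
    data.table::data.table(intron = S4Vectors::queryHits(cross_end),
                           read = S4Vectors::subjectHits(cross_end), kind = "e"),
    data.table::data.table(intron = S4Vectors::subjectHits(body_hits),
                           read = S4Vectors::queryHits(body_hits), kind = "b")
  ))
  if (nrow(pair) > 0L) {
    pair[, strand := introns$strand[intron]]
    # class per (read, intron): boundary crossings beat body; if both
    # boundaries are crossed the read is counted as EI (transcription 5')
    cls <- pair[, {
      k <- kind
      if (any(k != "b")) {
        first_cross <- if (any(k == "s") && any(k == "e")) {
          if (strand[1] == "+") "s" else "e"
        } else k[k != "b"][1]
        is_ei <- (strand[1] == "+" && first_cross == "s") ||
          (strand[1] == "-" && first_cross == "e")
        list(cls = if (is_ei) "EI" else "IE")
      } else list(cls = "body")
    }, by = .(intron, read)]
    agg <- cls[, .N, by = .(intron, cls)]
    for (cl in c("EI", "IE", "body")) {
      sub <- agg[cls == cl]
      if (nrow(sub) > 0L)
        data.table::set(out, i = sub$intron, j = cl, value = sub$N)
    }
  }

  if (!is.null(exons)) {
    exons <- data.table::as.data.table(exons)
    ex <- unique(exons[, .(gene_id, chrom, start, end)])
    egr <- GenomicRanges::GRanges(ex$chrom,
                                  IRanges::IRanges(ex$start + 1L, ex$end))
    eh <- suppressWarnings(GenomicRanges::findOverlaps(spans, egr, type = "within",
                                      ignore.strand = TRUE))
    per_gene <- data.table::data.table(
      read = S4Vectors::queryHits(eh),
      gene_id = ex$gene_id[S4Vectors::subjectHits(eh)]
    )
    per_gene <- unique(per_gene)[, .N, by = gene_id]
    gx <- per_gene$N[match(introns$gene_id, per_gene$gene_id)]
    gx[is.na(gx)] <- 0L
    out$gene_exonic <- gx
  }
  out
}

#' Compute percent intron retention from junction counts
#'
#' PIR = 100 * mean(EI, IE) / (mean(EI, IE) + EE). A cell is missing
#' (`NA`, `coverage_ok = FALSE`) when EI + IE + EE falls below
#' `min_junction_reads`.
#'
#' @param counts Junction-count table (`sample_id`, `intron_id`, `EI`, `IE`,
#'   `EE`, ...).
#' @param min_junction_reads Minimum junction-informative reads per cell.
#' @return `data.table` with `sample_id`, `intron_id`, `pir` (percent, `NA`
#'   when coverage fails) and `coverage_ok`.
#' @export
compute_pir <- function(counts, min_junction_reads = 10L) {
  counts <- data.table::as.data.table(counts)
  if (any(counts$EI < 0 | counts$IE < 0 | counts$EE < 0))
    stopf("negative junction counts")
  out <- counts[, .(sample_id, intron_id)]
  ret <- (counts$EI + counts$IE) / 2
  out[, pir := 100 * ret / (ret + counts$EE)]
  out[, coverage_ok := (counts$EI + counts$IE + counts$EE) >= min_junction_reads]
  out[coverage_ok == FALSE, pir := NA_real_]
  out[is.nan(pir), `:=`(pir = NA_real_, coverage_ok = FALSE)]
  out[]
}

#' Cast a long PIR table to an intron x sample matrix
#'
#' @param pir Output of [compute_pir()].
#' @return Numeric matrix, rows = introns, columns = samples.
#' @export
pir_matrix <- function(pir) {
  wide <- data.table::dcast(data.table::as.data.table(pir),
                            intron_id ~ sample_id, value.var = "pir")
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$intron_id
  m
}

#' Normalize gene counts to log2 counts-per-million
#'
#' CPM per sample (summing to 1e6 before the log transform), then
#' log2(CPM + 1). A gene is flagged reliably expressed when its CPM is at
#' least `cpm_threshold` in every sample of at least one
#' timepoint-by-fraction group.
#'
#' @param gene_counts Long table (`sample_id`, `gene_id`, `exonic`).
#' @param design Sample sheet with `sample_id`, `DIV`, `fraction`.
#' @param cpm_threshold Reliable-expression CPM cutoff.
#' @return List: `counts`, `cpm`, `logcpm` (gene x sample matrices) and
#'   `reliable` (named logical).
#' @export
compute_expression <- function(gene_counts, design, cpm_threshold = 1) {
  gc <- data.table::as.data.table(gene_counts)
  wide <- data.table::dcast(gc, gene_id ~ sample_id, value.var = "exonic", fill = 0)
  m <- as.matrix(wide[, -1]); rownames(m) <- wide$gene_id
  libs <- colSums(m)
  if (any(libs == 0))
    stopf("sample %s has zero total counts", colnames(m)[which(libs == 0)[1]])
  cpm <- sweep(m, 2, libs, "/") * 1e6
  logcpm <- log2(cpm + 1)
  design <- data.table::as.data.table(design)
  grp <- design[match(colnames(m), sample_id), paste(DIV, fraction)]
  reliable <- rep(FALSE, nrow(m))
  for (g in unique(grp)) {
    cols <- which(grp == g)
    reliable <- reliable | matrixStats_rowAll(cpm[, cols, drop = FALSE] >= cpm_threshold)
  }
  names(reliable) <- rownames(m)
  list(counts = m, cpm = cpm, logcpm = logcpm, reliable = reliable)
}

matrixStats_rowAll <- function(x) rowSums(x) == ncol(x)

#' Cytoplasmic intron-retaining-transcript share per genotype
#'
#' For each intron and cytoplasmic sample, the IRT share is
#' mean(EI, IE) / (mean(EI, IE) + EE) — the PIR on the 0-1 scale, i.e. the
#' fraction of the gene's junction evidence carried by the retained form.
#' Shares are pooled over the intron set and summarized per genotype by
#' median and interquartile range.
#'
#' @param counts Junction-count table.
#' @param intron_ids Introns of interest (non-empty).
#' @param design Sample sheet (`sample_id`, `genotype`, `fraction`, `DIV`).
#' @param timepoint Optional DIV filter.
#' @param min_junction_reads Coverage filter per cell.
#' @return `data.table` with `genotype`, `median_share`, `q25`, `q75`, `n`.
#' @export
compute_irt_fraction <- function(counts, intron_ids, design, timepoint = NULL,
                                 min_junction_reads = 10L) {
  if (length(intron_ids) == 0L) stopf("empty intron set")
  design <- data.table::as.data.table(design)
  keep <- design[fraction == "cytoplasmic"]
  if (!is.null(timepoint)) keep <- keep[DIV %in% timepoint]
  cnt <- data.table::as.data.table(counts)[intron_id %in% intron_ids &
                                             sample_id %in% keep$sample_id]
  cnt[, genotype := keep$genotype[match(sample_id, keep$sample_id)]]
  ret <- (cnt$EI + cnt$IE) / 2
  cnt[, share := ret / (ret + EE)]
  cnt <- cnt[(EI + IE + EE) >= min_junction_reads]
  cnt[, .(median_share = median(share), q25 = quantile(share, 0.25),
          q75 = quantile(share, 0.75), n = .N), by = genotype]
}
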