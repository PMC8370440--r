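#' Fractionation-leakage metric from intron-body vs exonic signal
#'
#' For each housekeeping gene, line and timepoint: intronic signal = summed
#' intron-body reads over the gene's introns divided by total intron length;
#' exonic signal = gene exonic reads divided by total exon length; the
#' intron/exon ratio is reported per fraction, and the normalized leakage is
#' the cytoplasmic ratio divided by the nuclear ratio (defined only when the
#' nuclear ratio is positive). Mirrors the qPCR logic of comparing intronic
#' and exonic amplicons of a cytosolic marker gene in both fractions.
#'
#' @param counts Junction-count table with `body` and `gene_exonic` columns.
#' @param introns,exons Annotation tables.
#' @param housekeeping_genes Gene ids to profile (must have introns).
#' @param design Sample sheet.
#' @return `data.table`: gene_id, line_id, DIV, nuclear/cytoplasmic
#'   intron-exon ratios, `normalized_leakage`.
#' @export
fractionation_leakage <- function(counts, introns, exons, housekeeping_genes,
                                  design) {
  counts <- data.table::as.data.table(counts)
  introns <- data.table::as.data.table(introns)
  exons <- data.table::as.data.table(exons)
  design <- data.table::as.data.table(design)
  for (g in housekeeping_genes)
    if (nrow(introns[gene_id == g]) == 0L)
      stopf("housekeeping gene %s has no introns", g)
  ilen <- introns[gene_id %in% housekeeping_genes,
                  .(intron_len = sum(end - start)), by = gene_id]
  elen <- unique(exons[gene_id %in% housekeeping_genes,
                       .(gene_id, start, end)])[, .(exon_len = sum(end - start)),
                                                by = gene_id]
  sub <- counts[intron_id %in% introns[gene_id %in% housekeeping_genes, intron_id]]
  sub[, gene_id := introns$gene_id[match(intron_id, introns$intron_id)]]
  per <- sub[, .(body = sum(body), gene_exonic = gene_exonic[1]),
             by = .(sample_id, gene_id)]
  per <- merge(merge(per, ilen, by = "gene_id"), elen, by = "gene_id")
  per <- merge(per, design[, .(sample_id, line_id, DIV, fraction)], by = "sample_id")
  per[, ratio := (body / intron_len) / (gene_exonic / exon_len)]
  wide <- data.table::dcast(per, gene_id + line_id + DIV ~ fraction,
                            value.var = "ratio")
  wide[, normalized_leakage := ifelse(nuclear > 0, cytoplasmic / nuclear, NA_real_)]
  data.table::setnames(wide, c("nuclear", "cytoplasmic"),
                       c("nuclear_ratio", "cytoplasmic_ratio"))
  wide[]
}

#' Global expression structure by singular value decomposition
#'
#' Genes (rows) are centered; optionally scaled to unit variance. The SVD of
#' the centered matrix gives variance fractions (squared singular values
#' over their total) and per-sample coordinates (V diag(d)), annotated with
#' the design for plotting.
#'
#' @param logcpm Gene x sample matrix (e.g. `compute_expression()$logcpm`);
#'   must be complete (no missing values).
#' @param design Sample sheet.
#' @param scale. Scale rows to unit variance (constant rows are dropped with
#'   a warning when scaling).
#' @return List: `variance_fraction`, `coords` (`data.table` with sample
#'   annotations and PC columns), `svd` (the raw decomposition).
#' @export
svd_structure <- function(logcpm, design, scale. = FALSE) {
  if (anyNA(logcpm)) stopf("expression matrix contains missing values")
  design <- data.table::as.data.table(design)
  x <- logcpm - rowMeans(logcpm)
  if (scale.) {
    sds <- apply(x, 1, sd)
    if (any(sds == 0)) {
      warnf("%d constant gene(s) dropped before scaling", sum(sds == 0))
      x <- x[sds > 0, , drop = FALSE]; sds <- sds[sds > 0]
    }
    x <- x / sds
  }
  dec <- svd(x)
  vf <- dec$d^2 / sum(dec$d^2)
  k <- min(10L, length(dec$d))
  coords <- dec$v[, seq_len(k), drop = FALSE] %*% diag(dec$d[seq_len(k)], k)
  colnames(coords) <- paste0("PC", seq_len(k))
  cdt <- data.table::data.table(sample_id = colnames(logcpm), coords)
  cdt <- merge(cdt, design, by = "sample_id", sort = FALSE)
  list(variance_fraction = vf, coords = cdt, svd = dec)
}

#' Hierarchical sample clustering on Spearman correlation distance
#'
#' Distance = 1 - Spearman rank correlation between sample expression
#' vectors; complete-linkage agglomeration; the dendrogram is serialized as
#' a Newick string.
#'
#' @param logcpm Gene x sample matrix.
#' @return List: `dist` (matrix), `hclust`, `newick`.
#' @export
sample_clustering <- function(logcpm) {
  const <- apply(logcpm, 2, function(v) sd(v) == 0)
  if (any(const))
    stopf("sample %s has a constant expression vector; correlation undefined",
          colnames(logcpm)[which(const)[1]])
  d <- 1 - cor(logcpm, method = "spearman")
  hc <- stats::hclust(stats::as.dist(d), method = "complete")
  newick <- ape::write.tree(ape::as.phylo(hc))
  list(dist = d, hclust = hc, newick = newick)
}
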