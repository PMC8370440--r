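#' Simulate gene/intron architecture with planted ground truth
#'
#' Draws the gene models (one contig per gene, alternating fixed-length exons
#' and variable introns), assigns the planted aberrant-retention categories
#' (at most one planted intron per gene), designates splicing-factor and
#' housekeeping genes among the unplanted genes, marks the enriched RBPs, and
#' draws every intron's baseline retention level per fraction. This is the
#' counts-first core of the generator: everything downstream
#' ([simulate_fraction_counts()], [simulate_crosslink_tracks()],
#' [simulate_conservation_track()]) consumes this structure, and sequence
#' generation ([simulate_annotation_and_genome()]) is layered on top, so count
#' tables are reproducible without ever materializing a genome.
#'
#' @param config A [sim_config()].
#' @return A list with elements `exons`, `introns` (as from
#'   [derive_introns()]), `truth` (per-intron category, planted per-fraction
#'   ΔPIR at the peak, baseline PIR per fraction, length and GC targets),
#'   `genes` (per-gene role), `rbps` (per-RBP enriched flag) and
#'   `contig_lengths`.
#' @export
simulate_structure <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    ng <- config$n_genes
    gene_id <- sprintf("g%04d", seq_len(ng))
    strand <- sample(c("+", "-"), ng, replace = TRUE)
    ipg <- seq(config$introns_per_gene[1], config$introns_per_gene[2])
    n_introns <- if (length(ipg) == 1L) rep(ipg, ng) else sample(ipg, ng, replace = TRUE)

    cc <- config$category_counts[c("nuclear", "both", "cytoplasmic")]
    planted_genes <- sample(gene_id, sum(cc))
    category_of_gene <- setNames(rep("none", ng), gene_id)
    category_of_gene[planted_genes] <- rep(c("nuclear", "both", "cytoplasmic"), times = cc)

    free <- setdiff(gene_id, planted_genes)
    sf_genes <- sample(free, config$n_splicing_factors)
    hk_genes <- sample(setdiff(free, sf_genes), config$n_housekeeping)
    role <- setNames(rep("none", ng), gene_id)
    role[sf_genes] <- "splicing_factor"
    role[hk_genes] <- "housekeeping"

    draw_len <- function(cat, n) {
      d <- config$length_dist[[cat]]
      len <- if (d$sdlog == 0) rep(exp(d$meanlog), n) else
        exp(rnorm(n, d$meanlog, d$sdlog))
      pmax(60L, as.integer(round(len)))
    }

    exon_rows <- vector("list", ng)
    intron_meta <- vector("list", ng)
    contig_len <- integer(ng)
    for (i in seq_len(ng)) {
      g <- gene_id[i]
      k <- n_introns[i]
      cat_g <- category_of_gene[g]
      planted_idx <- if (cat_g != "none") sample.int(k, 1L) else NA_integer_
      icat <- rep("background", k)
      if (!is.na(planted_idx)) icat[planted_idx] <- cat_g
      ilen <- integer(k)
      for (cat in unique(icat)) {
        w <- which(icat == cat)
        ilen[w] <- draw_len(cat, length(w))
      }
      el <- config$exon_length
      starts <- integer(k + 1L); ends <- integer(k + 1L)
      pos <- 100L
      for (j in seq_len(k + 1L)) {
        starts[j] <- pos; ends[j] <- pos + el; pos <- pos + el
        if (j <= k) pos <- pos + ilen[j]
      }
      contig_len[i] <- pos + 100L
      exon_rows[[i]] <- data.table::data.table(
        gene_id = g, gene_name = g, transcript_id = paste0(g, ".t1"),
        chrom = g, start = starts, end = ends, strand = strand[i]
      )
      # genomic order of introns; ordinal assigned later by derive_introns
      intron_meta[[i]] <- data.table::data.table(
        gene_id = g, chrom = g,
        start = ends[seq_len(k)], end = starts[seq_len(k) + 1L],
        strand = strand[i], category = icat,
        gc_target = unname(config$gc_target[icat]), length = ilen
      )
    }
    exons <- data.table::rbindlist(exon_rows)
    data.table::setorder(exons, gene_id, transcript_id, start)
    meta <- data.table::rbindlist(intron_meta)
    meta[, intron_id := intron_identifier(gene_id, chrom, start, end, strand)]

    introns <- derive_introns(exons)
    meta <- meta[match(introns$intron_id, meta$intron_id)]
    stopifnot(identical(meta$intron_id, introns$intron_id))

    ni <- nrow(meta)
    bn <- config$baseline_pir_nuclear
    bc <- config$baseline_pir_cytoplasmic
    rbeta_mean <- function(n, m, conc) {
      if (is.infinite(conc)) rep(m, n) else rbeta(n, m * conc, (1 - m) * conc)
    }
    baseline_nuc <- rbeta_mean(ni, bn$mean, bn$conc)
    baseline_cyt <- rbeta_mean(ni, bc$mean, bc$conc)
    hk <- meta$gene_id %in% hk_genes
    baseline_nuc[hk] <- 0.05   # housekeeping: efficiently spliced, nuclear residual only
    baseline_cyt[hk] <- 0.005  # near-zero cytoplasmic intronic signal absent leakage

    truth <- data.table::data.table(
      intron_id = meta$intron_id, gene_id = meta$gene_id,
      category = meta$category, length = meta$length,
      gc_target = meta$gc_target,
      delta_pir_nuclear = ifelse(meta$category %in% c("nuclear", "both"), config$delta_pir, 0),
      delta_pir_cytoplasmic = ifelse(meta$category %in% c("cytoplasmic", "both"), config$delta_pir, 0),
      baseline_pir_nuclear = baseline_nuc,
      baseline_pir_cytoplasmic = baseline_cyt,
      conservation_mean = config$conservation_mean +
        ifelse(meta$category == "cytoplasmic", config$conservation_shift, 0)
    )

    rbps <- data.table::data.table(
      rbp = sprintf("rbp%03d", seq_len(config$n_rbps)),
      enriched = FALSE
    )
    rbps$enriched[sample.int(config$n_rbps, config$n_enriched_rbps)] <- TRUE

    genes <- data.table::data.table(
      gene_id = gene_id, chrom = gene_id, strand = strand,
      n_introns = n_introns, category = unname(category_of_gene),
      role = unname(role)
    )

    list(exons = exons, introns = introns, truth = truth, genes = genes,
         rbps = rbps, contig_lengths = setNames(contig_len, gene_id),
         config = config)
  })
}

#' Simulate the toy genome and annotation files
#'
#' Generates per-base sequence realizing each intron's category GC target
#' (exons and intergenic spacers at background GC) and, when `dir` is given,
#' writes `genome.fa` and `annotation.gtf`. Deterministic given the config
#' seed; the structure is identical to [simulate_structure()] under the same
#' config, so counts simulated with or without a genome agree.
#'
#' @param config A [sim_config()].
#' @param dir Optional output directory for FASTA/GTF.
#' @param structure Optional pre-computed [simulate_structure()] result.
#' @return The structure list, extended with `genome` (a `DNAStringSet`) and,
#'   if written, `fasta_path` / `gtf_path`.
#' @export
simulate_annotation_and_genome <- function(config, dir = NULL, structure = NULL) {
  st <- structure %||% simulate_structure(config)
  st$genome <- with_seed(config$seed + 1L, simulate_genome_sequences(st, config))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    st$fasta_path <- file.path(dir, "genome.fa")
    Biostrings::writeXStringSet(st$genome, st$fasta_path, width = 70L)
    st$gtf_path <- file.path(dir, "annotation.gtf")
    write_gtf(st$exons, st$gtf_path)
  }
  st
}

simulate_genome_sequences <- function(st, config) {
  bg_gc <- config$gc_target[["background"]]
  seqs <- character(nrow(st$genes))
  base_probs <- function(gc) c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  meta <- st$truth[match(st$introns$intron_id, st$truth$intron_id)]
  intr_by_gene <- split(seq_len(nrow(st$introns)), st$introns$gene_id)
  for (i in seq_len(nrow(st$genes))) {
    g <- st$genes$gene_id[i]
    L <- st$contig_lengths[[g]]
    p <- base_probs(bg_gc)
    chars <- sample(names(p), L, replace = TRUE, prob = p)
    idx <- intr_by_gene[[g]]
    for (j in idx) {
      s <- st$introns$start[j]; e <- st$introns$end[j]
      pj <- base_probs(meta$gc_target[j])
      chars[(s + 1L):e] <- sample(names(pj), e - s, replace = TRUE, prob = pj)
    }
    seqs[i] <- paste(chars, collapse = "")
  }
  Biostrings::DNAStringSet(setNames(seqs, st$genes$gene_id))
}

# GTF writer for simulated annotation (gene/transcript/exon rows, 1-based closed)
write_gtf <- function(exons, path) {
  exons <- data.table::as.data.table(exons)
  tx <- exons[, .(start = min(start), end = max(end)),
              by = .(gene_id, gene_name, transcript_id, chrom, strand)]
  gene_attr <- sprintf('gene_id "%s"; gene_name "%s";', tx$gene_id, tx$gene_name)
  tx_attr <- sprintf('gene_id "%s"; transcript_id "%s"; gene_name "%s";',
                     tx$gene_id, tx$transcript_id, tx$gene_name)
  ex_attr <- sprintf('gene_id "%s"; transcript_id "%s"; gene_name "%s";',
                     exons$gene_id, exons$transcript_id, exons$gene_name)
  rows <- c(
    sprintf("%s\tfracir\tgene\t%d\t%d\t.\t%s\t.\t%s",
            tx$chrom, tx$start + 1L, tx$end, tx$strand, gene_attr),
    sprintf("%s\tfracir\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
            tx$chrom, tx$start + 1L, tx$end, tx$strand, tx_attr),
    sprintf("%s\tfracir\texon\t%d\t%d\t.\t%s\t.\t%s",
            exons$chrom, exons$start + 1L, exons$end, exons$strand, ex_attr)
  )
  writeLines(rows, path)
  invisible(path)
}
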