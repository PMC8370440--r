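#' Run the full compartment-aware intron-retention pipeline
#'
#' Synthetic mode (the default): simulate annotation, genome, fractionated
#' junction counts, crosslink and conservation tracks with planted truth;
#' then quantify (PIR, expression), scan for differential retention,
#' classify the nucleocytoplasmic taxonomy at the peak timepoint, profile
#' cis features and RBP enrichment, and produce fractionation/structure QC.
#' All tables are written as TSV plus a JSON run manifest recording the seed
#' and every threshold; outputs carry no timestamps, so a fixed seed yields
#' byte-identical files across runs.
#'
#' Real-data mode: supply `real_data` with paths to a junction-count TSV and
#' sample sheet (and optionally GTF/FASTA/crosslink BEDs/conservation
#' bedGraph); the simulate stage is skipped and truth-dependent outputs are
#' omitted.
#'
#' @param config A [sim_config()] (synthetic mode), or `NULL` with
#'   `real_data` set.
#' @param outdir Output directory (created).
#' @param seed Overrides `config$seed` when given.
#' @param thresholds Named list overriding defaults of
#'   [differential_ir_scan()] (`q_threshold`, `delta_threshold`,
#'   `min_coverage`, `ee_weight`, `consistency`), [compute_pir()]
#'   (`min_junction_reads`) and [score_crosslink_enrichment()]
#'   (`pseudocount`).
#' @param real_data Optional list of paths: `counts`, `sample_sheet`, and
#'   optionally `gtf`, `genome`, `crosslink_dir`, `conservation`.
#' @return Invisibly, the bundle of in-memory results.
#' @export
run_pipeline <- function(config = sim_config(), outdir, seed = NULL,
                         thresholds = list(), real_data = NULL) {
  th <- utils::modifyList(list(
    q_threshold = 0.05, delta_threshold = 10, min_coverage = 20L,
    ee_weight = 2, consistency = 2 / 3, min_junction_reads = 10L,
    pseudocount = 0.1
  ), thresholds)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(x, name) data.table::fwrite(x, file.path(outdir, name), sep = "\t")

  synthetic <- is.null(real_data)
  tracks <- NULL; cons <- NULL; genome <- NULL; st <- NULL
  if (synthetic) {
    if (!is.null(seed)) config$seed <- as.integer(seed)
    validate_sim_config(config)
    st <- simulate_annotation_and_genome(config, dir = outdir)
    genome <- st$genome
    introns <- st$introns; exons <- st$exons
    sim <- simulate_fraction_counts(config, st)
    counts <- sim$counts; gene_counts <- sim$gene_counts; design <- sim$samples
    tracks <- simulate_crosslink_tracks(config, st,
                                        dir = file.path(outdir, "crosslinks"))
    cons <- simulate_conservation_track(config, st,
                                        path = file.path(outdir, "conservation.bedGraph"))
    write_introns_bed(introns, file.path(outdir, "introns.bed"))
    tsv(design, "sample_sheet.tsv")
    tsv(counts, "junction_counts.tsv")
    tsv(gene_counts, "gene_counts.tsv")
    tsv(st$truth, "truth_introns.tsv")
    tsv(st$genes, "truth_genes.tsv")
    tsv(st$rbps, "truth_rbps.tsv")
  } else {
    for (need in c("counts", "sample_sheet"))
      if (is.null(real_data[[need]])) stopf("real_data mode requires '%s'", need)
    counts <- data.table::fread(real_data$counts)
    design <- data.table::fread(real_data$sample_sheet)
    gene_counts <- unique(counts[, .(sample_id, gene_id =
      sub(":.*$", "", intron_id), exonic = gene_exonic)])
    if (!is.null(real_data$gtf)) {
      exons <- read_gene_annotation(real_data$gtf)
      introns <- derive_introns(exons)
    } else {
      introns <- unique(counts[, .(intron_id)])
      introns[, c("gene_id", "chrom", "range", "strand") :=
                data.table::tstrsplit(intron_id, ":")]
      introns[, c("start", "end") := lapply(data.table::tstrsplit(range, "-"), as.integer)]
      introns[, range := NULL]
      introns[, gene_name := gene_id]
      exons <- NULL
    }
    if (!is.null(real_data$genome)) genome <- read_genome(real_data$genome)
    if (!is.null(real_data$conservation))
      cons <- rtracklayer::import(real_data$conservation, format = "bedGraph")
    if (!is.null(real_data$crosslink_dir)) {
      beds <- list.files(real_data$crosslink_dir, pattern = "\\.bed$",
                         full.names = TRUE)
      tracks <- lapply(beds, rtracklayer::import, format = "BED")
      names(tracks) <- sub("\\.bed$", "", basename(beds))
    }
  }

  # --- quantify
  pir <- compute_pir(counts, min_junction_reads = th$min_junction_reads)
  expr <- compute_expression(gene_counts, design)
  tsv(pir, "pir.tsv")

  # --- differential scan + census + factor shift
  scan <- differential_ir_scan(counts, design,
                               q_threshold = th$q_threshold,
                               delta_threshold = th$delta_threshold,
                               min_coverage = th$min_coverage,
                               ee_weight = th$ee_weight,
                               consistency = th$consistency)
  tsv(scan, "differential_ir.tsv")
  tsv(ir_event_union(scan), "ir_event_union.tsv")
  census <- splicing_event_census(scan)
  tsv(census, "census.tsv")
  sf_shift <- NULL
  if (synthetic) {
    sf_genes <- st$genes[role == "splicing_factor", gene_id]
    sf_shift <- splicing_factor_shift(expr, sf_genes, design)
    tsv(sf_shift$summary, "splicing_factor_shift.tsv")
  }

  # --- taxonomy
  peak <- pick_peak_timepoint(scan)
  calls <- classify_compartment(scan, timepoint = peak)
  tsv(calls, "taxonomy.tsv")

  irt <- NULL
  if (nrow(calls) > 0L) {
    irt <- compute_irt_fraction(counts, calls$intron_id, design, timepoint = peak,
                                min_junction_reads = th$min_junction_reads)
    tsv(irt, "irt_share.tsv")
  }

  # --- cis features + RBP enrichment
  feats <- NULL; comps <- NULL; coupling <- NULL; emat <- NULL; ranking <- NULL
  if (nrow(calls) > 0L) {
    background_ids <- background_intron_set(introns, calls)
    feats <- cis_feature_table(introns[introns$intron_id %in% background_ids, ],
                               genome = genome, track = cons)
    tsv(feats, "cis_features.tsv")
    comps <- compare_categories(feats, calls, background_ids)
    tsv(comps, "feature_comparisons.tsv")
    coupling <- expression_coupling(expr, calls, design, introns, timepoint = peak)
    tsv(coupling, "expression_coupling.tsv")
    if (!is.null(tracks)) {
      call_introns <- introns[introns$intron_id %in% calls$intron_id, ]
      bg_introns <- introns[introns$intron_id %in%
                              setdiff(background_ids, calls$intron_id), ]
      emat <- crosslink_enrichment_matrix(tracks, call_introns, bg_introns,
                                          pseudocount = th$pseudocount)
      em_dt <- data.table::data.table(intron_id = rownames(emat$scores),
                                      emat$scores)
      tsv(em_dt, "enrichment_matrix.tsv")
      ranking <- rank_rbps_by_category(emat, calls, q_threshold = th$q_threshold)
      tsv(ranking, "rbp_ranking.tsv")
    }
  }

  # --- QC
  leakage <- NULL
  if (synthetic) {
    hk <- st$genes[role == "housekeeping", gene_id]
    if (length(hk) > 0L) {
      leakage <- fractionation_leakage(counts, introns, exons, hk, design)
      tsv(leakage, "fractionation_leakage.tsv")
    }
  }
  svd_res <- svd_structure(expr$logcpm[expr$reliable, , drop = FALSE], design)
  tsv(data.table::data.table(component = seq_along(svd_res$variance_fraction),
                             variance_fraction = svd_res$variance_fraction),
      "svd_variance.tsv")
  tsv(svd_res$coords[, c("sample_id", "PC1", "PC2", "line_id", "genotype",
                         "DIV", "fraction"), with = FALSE], "svd_coords.tsv")
  clust <- sample_clustering(expr$logcpm[expr$reliable, , drop = FALSE])
  writeLines(clust$newick, file.path(outdir, "sample_clustering.nwk"))

  manifest <- list(
    package = "fracir",
    version = as.character(utils::packageVersion("fracir")),
    mode = if (synthetic) "synthetic" else "real",
    seed = if (synthetic) config$seed else NA,
    thresholds = th,
    peak_timepoint = peak,
    n_introns = nrow(introns),
    n_samples = nrow(design),
    n_taxonomy_calls = nrow(calls)
  )
  if (synthetic) manifest$config <- unclass(config)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(config = if (synthetic) config else NULL, structure = st,
                 counts = counts, gene_counts = gene_counts, design = design,
                 pir = pir, expr = expr, scan = scan, census = census,
                 splicing_factor_shift = sf_shift, peak_timepoint = peak,
                 calls = calls, irt_share = irt, features = feats,
                 comparisons = comps, coupling = coupling,
                 enrichment = emat, rbp_ranking = ranking,
                 leakage = leakage, svd = svd_res, clustering = clust,
                 manifest = manifest))
}
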