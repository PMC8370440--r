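#' Simulation configuration for the fractionated RNA-seq generator
#'
#' Defaults encode the emulated study design: 4 control and 3 mutant iPSC
#' lines sampled at six differentiation timepoints (days in vitro 0, 3, 7, 14,
#' 22, 35) in nuclear and cytoplasmic fractions, with aberrant intron
#' retention planted in three nucleocytoplasmic categories
#' (237 nuclear-predominant, 63 both-compartments, 49
#' cytoplasmic-predominant) that peaks at DIV 14. Category-specific intron
#' architecture follows the observed contrasts: nuclear-category introns are
#' short and GC-rich, cytoplasmic/both-category introns long and AT-rich, and
#' only the cytoplasmic-only category carries a conservation shift and extra
#' crosslink density for the designated subset of RBPs.
#'
#' @param n_genes Number of simulated genes (one contig per gene).
#' @param introns_per_gene Integer range `c(min, max)` of introns per gene.
#' @param n_lines_control,n_lines_mutant Number of cell lines per genotype.
#' @param timepoints DIV labels.
#' @param peak_timepoint Timepoint at which planted effects peak.
#' @param category_counts Named counts of planted events
#'   (`nuclear`, `both`, `cytoplasmic`); at most one planted intron per gene.
#' @param delta_pir Planted retention increase at the peak, percentage points.
#' @param baseline_pir_nuclear,baseline_pir_cytoplasmic Beta-distribution
#'   parameters `list(mean, conc)` for per-intron baseline PIR (fractions);
#'   `conc = Inf` gives a constant baseline.
#' @param library_size Expected junction reads per intron per sample.
#' @param gene_mean_expression Expected exonic reads per gene per sample.
#' @param nb_dispersion Negative-binomial dispersion of sequencing depth.
#' @param leakage Fraction of nuclear signal contaminating cytoplasmic
#'   samples, in `[0, 1)`; expected nuclear counts are mixed additively into
#'   the cytoplasmic expectation before sampling.
#' @param n_rbps,n_enriched_rbps Number of simulated RBP crosslink tracks and
#'   how many of them are enriched in cytoplasmic-category introns.
#' @param crosslink_rate Background crosslink density, events per kb.
#' @param crosslink_fold Density fold-increase inside cytoplasmic-category
#'   introns for enriched RBPs.
#' @param conservation_mean Background mean per-base conservation score.
#' @param conservation_shift Mean score increase inside cytoplasmic-only
#'   category introns.
#' @param conservation_conc Beta concentration of per-bin conservation scores.
#' @param conservation_bin Bin width (nt) of the emitted bedGraph.
#' @param length_dist Per-category intron length log-normal parameters,
#'   named lists `list(meanlog, sdlog)`; `sdlog = 0` gives constant lengths.
#' @param gc_target Per-category intron GC fraction targets.
#' @param exon_length Constant exon length (nt).
#' @param n_splicing_factors Number of designated splicing-factor genes.
#' @param splicing_factor_downshift Cytoplasmic log2 fold-change applied to
#'   splicing-factor genes in mutant samples at the peak timepoint.
#' @param n_housekeeping Number of housekeeping genes (stable expression,
#'   near-zero cytoplasmic baseline retention) used for leakage QC.
#' @param timepoint_expression_sd,fraction_expression_sd,line_expression_sd
#'   Standard deviations (log2 scale) of per-gene timepoint trajectories,
#'   fraction offsets and per-line offsets.
#' @param body_factor Expected intron-body reads per retained unit:
#'   `library_size * PIR * (length/1000) * body_factor`.
#' @param seed Integer seed; fully determines every generated artifact.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_genes = 450L,
                       introns_per_gene = c(3L, 7L),
                       n_lines_control = 4L,
                       n_lines_mutant = 3L,
                       timepoints = c(0L, 3L, 7L, 14L, 22L, 35L),
                       peak_timepoint = 14L,
                       category_counts = c(nuclear = 237L, both = 63L, cytoplasmic = 49L),
                       delta_pir = 25,
                       baseline_pir_nuclear = list(mean = 0.22, conc = 40),
                       baseline_pir_cytoplasmic = list(mean = 0.10, conc = 40),
                       library_size = 100,
                       gene_mean_expression = 500,
                       nb_dispersion = 0.15,
                       leakage = 0.05,
                       n_rbps = 100L,
                       n_enriched_rbps = 27L,
                       crosslink_rate = 10,
                       crosslink_fold = 4,
                       conservation_mean = 0.5,
                       conservation_shift = 0.2,
                       conservation_conc = 20,
                       conservation_bin = 25L,
                       length_dist = list(
                         nuclear = list(meanlog = log(200), sdlog = 0.25),
                         both = list(meanlog = log(2000), sdlog = 0.25),
                         cytoplasmic = list(meanlog = log(2000), sdlog = 0.25),
                         background = list(meanlog = log(600), sdlog = 0.6)
                       ),
                       gc_target = c(nuclear = 0.7, both = 0.4,
                                     cytoplasmic = 0.4, background = 0.5),
                       exon_length = 150L,
                       n_splicing_factors = 72L,
                       splicing_factor_downshift = -1,
                       n_housekeeping = 3L,
                       timepoint_expression_sd = 1.0,
                       fraction_expression_sd = 0.8,
                       line_expression_sd = 0.1,
                       body_factor = 0.5,
                       seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes), introns_per_gene = as.integer(introns_per_gene),
    n_lines_control = as.integer(n_lines_control),
    n_lines_mutant = as.integer(n_lines_mutant),
    timepoints = as.integer(timepoints), peak_timepoint = as.integer(peak_timepoint),
    category_counts = category_counts, delta_pir = delta_pir,
    baseline_pir_nuclear = baseline_pir_nuclear,
    baseline_pir_cytoplasmic = baseline_pir_cytoplasmic,
    library_size = library_size, gene_mean_expression = gene_mean_expression,
    nb_dispersion = nb_dispersion, leakage = leakage,
    n_rbps = as.integer(n_rbps), n_enriched_rbps = as.integer(n_enriched_rbps),
    crosslink_rate = crosslink_rate, crosslink_fold = crosslink_fold,
    conservation_mean = conservation_mean, conservation_shift = conservation_shift,
    conservation_conc = conservation_conc, conservation_bin = as.integer(conservation_bin),
    length_dist = length_dist, gc_target = gc_target,
    exon_length = as.integer(exon_length),
    n_splicing_factors = as.integer(n_splicing_factors),
    splicing_factor_downshift = splicing_factor_downshift,
    n_housekeeping = as.integer(n_housekeeping),
    timepoint_expression_sd = timepoint_expression_sd,
    fraction_expression_sd = fraction_expression_sd,
    line_expression_sd = line_expression_sd,
    body_factor = body_factor,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_genes > 0, length(cfg$introns_per_gene) == 2,
            cfg$introns_per_gene[1] >= 1,
            cfg$introns_per_gene[2] >= cfg$introns_per_gene[1],
            cfg$n_lines_control >= 1, cfg$n_lines_mutant >= 1,
            cfg$peak_timepoint %in% cfg$timepoints,
            all(cfg$category_counts >= 0),
            cfg$leakage >= 0, cfg$leakage < 1,
            cfg$library_size > 0, cfg$nb_dispersion >= 0,
            cfg$n_enriched_rbps <= cfg$n_rbps,
            cfg$crosslink_rate > 0, cfg$crosslink_fold > 0,
            cfg$conservation_mean >= 0, cfg$conservation_mean <= 1,
            cfg$conservation_mean + cfg$conservation_shift <= 1,
            cfg$delta_pir >= 0, cfg$delta_pir <= 100)
  for (b in list(cfg$baseline_pir_nuclear, cfg$baseline_pir_cytoplasmic))
    stopifnot(b$mean > 0, b$mean < 1, b$conc > 0)
  stopifnot(all(c("nuclear", "both", "cytoplasmic") %in% names(cfg$category_counts)))
  stopifnot(all(c("nuclear", "both", "cytoplasmic", "background") %in% names(cfg$length_dist)))
  stopifnot(all(cfg$gc_target > 0 & cfg$gc_target < 1))
  if (sum(cfg$category_counts) > cfg$n_genes)
    stopf("category_counts total (%d) exceeds n_genes (%d); at most one planted intron per gene",
          sum(cfg$category_counts), cfg$n_genes)
  if (cfg$n_splicing_factors + cfg$n_housekeeping >
      cfg$n_genes - sum(cfg$category_counts))
    stopf("not enough unplanted genes for %d splicing factors + %d housekeeping genes",
          cfg$n_splicing_factors, cfg$n_housekeeping)
  invisible(cfg)
}

#' Read / write a simulation config as YAML-like key/value text
#'
#' @param path File path.
#' @return For `read_sim_config`, a `sim_config`.
#' @export
write_sim_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "sim_config"))
  x <- unclass(cfg)
  x$category_counts <- as.list(x$category_counts)
  x$gc_target <- as.list(x$gc_target)
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, pretty = TRUE), path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- jsonlite::fromJSON(paste(readLines(path, warn = FALSE), collapse = "\n"),
                          simplifyVector = TRUE)
  x$category_counts <- unlist(x$category_counts)
  x$gc_target <- unlist(x$gc_target)
  do.call(sim_config, x)
}
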