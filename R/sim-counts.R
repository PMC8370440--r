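#' Simulate fractionated junction-count and gene-expression tables
#'
#' Per sample and intron, junction depth is negative-binomial around
#' `library_size`; reads are then allocated between the retention arm
#' (split between the exon-intron and intron-exon boundaries with a
#' Binomial(0.5)) and the spliced exon-exon arm so that the expected percent
#' intron retention equals that sample's true PIR. Mutant samples receive the
#' planted ΔPIR in the category-appropriate fraction(s), scaled by a
#' triangular timepoint ramp that peaks at `peak_timepoint` and vanishes at
#' the first and last timepoints. Cytoplasmic samples receive an additive
#' `leakage` admixture of the expected nuclear signal before sampling.
#' Designated splicing-factor genes receive the configured cytoplasmic log2
#' fold-change in mutant samples at the peak timepoint.
#'
#' An intron's true PIR is a fixed property of (intron, fraction, genotype,
#' timepoint): all variability across lines comes from sequencing-depth and
#' allocation sampling, which keeps the pooled Fisher count test exactly
#' calibrated under the null.
#'
#' @param config A [sim_config()].
#' @param structure A [simulate_structure()] result for the same config.
#' @return A list: `counts` (sample_id, intron_id, EI, IE, EE, body,
#'   gene_exonic), `gene_counts` (sample_id, gene_id, exonic), `samples`
#'   (sample sheet: sample_id, line_id, genotype, DIV, fraction) and
#'   `true_pir` (the planted per-stratum PIR, percent).
#' @export
simulate_fraction_counts <- function(config, structure = NULL) {
  st <- structure %||% simulate_structure(config)
  with_seed(config$seed + 2L, {
    samples <- simulated_sample_sheet(config)
    truth <- st$truth
    ni <- nrow(truth)

    ramp <- timepoint_ramp(config$timepoints, config$peak_timepoint)

    # true PIR per intron x fraction x genotype x timepoint (fractions 0..1)
    strata <- data.table::CJ(timepoint = config$timepoints,
                             genotype = c("control", "mutant"),
                             fraction = c("nuclear", "cytoplasmic"))
    pir_tab <- strata[, {
      base <- if (fraction == "nuclear") truth$baseline_pir_nuclear else truth$baseline_pir_cytoplasmic
      delta <- if (fraction == "nuclear") truth$delta_pir_nuclear else truth$delta_pir_cytoplasmic
      eff <- if (genotype == "mutant") delta / 100 * ramp[as.character(timepoint)] else 0
      list(intron_id = truth$intron_id, pir = pmin(base + eff, 0.98))
    }, by = .(timepoint, genotype, fraction)]

    # gene-level expected expression (log2 scale effects)
    genes <- st$genes
    ng <- nrow(genes)
    a_g <- rnorm(ng, 0, config$timepoint_expression_sd)
    b_g <- rnorm(ng, 0, config$fraction_expression_sd)
    stable <- genes$role == "housekeeping"
    a_g[stable] <- 0; b_g[stable] <- 0
    f_t <- setNames(seq(-1, 1, length.out = length(config$timepoints)),
                    as.character(sort(config$timepoints)))
    c_l <- setNames(rnorm(nrow(samples_lines(config)), 0, config$line_expression_sd),
                    samples_lines(config)$line_id)

    gene_mu <- function(smp) {
      # expected exonic depth for every gene in one sample (before leakage)
      sf <- genes$role == "splicing_factor" & smp$genotype == "mutant" &
        smp$fraction == "cytoplasmic" & smp$DIV == config$peak_timepoint
      log2mu <- log2(config$gene_mean_expression) +
        a_g * f_t[[as.character(smp$DIV)]] +
        b_g * (smp$fraction == "nuclear") +
        c_l[[smp$line_id]] +
        ifelse(sf, config$splicing_factor_downshift, 0)
      2^log2mu
    }

    size <- if (config$nb_dispersion > 0) 1 / config$nb_dispersion else Inf
    rnb <- function(n, mu) {
      if (is.infinite(size)) rpois(n, mu) else rnbinom(n, mu = mu, size = size)
    }

    lam <- config$leakage
    gene_of <- match(truth$gene_id, genes$gene_id)
    count_rows <- vector("list", nrow(samples))
    gene_rows <- vector("list", nrow(samples))
    for (k in seq_len(nrow(samples))) {
      smp <- as.list(samples[k])
      key <- pir_tab[timepoint == smp$DIV & genotype == smp$genotype]
      p_own <- key[fraction == smp$fraction][match(truth$intron_id, intron_id), pir]
      q_own <- 2 * p_own / (1 + p_own)  # retention-read share yielding E[PIR] = p
      mu_jx <- config$library_size
      body_mu_own <- config$body_factor * config$library_size * p_own * truth$length / 1000
      mu_g_own <- gene_mu(smp)
      if (smp$fraction == "cytoplasmic" && lam > 0) {
        p_nuc <- key[fraction == "nuclear"][match(truth$intron_id, intron_id), pir]
        q_nuc <- 2 * p_nuc / (1 + p_nuc)
        smp_nuc <- smp; smp_nuc$fraction <- "nuclear"
        mu_g <- mu_g_own + lam * gene_mu(smp_nuc)
        q_eff <- (q_own + lam * q_nuc) / (1 + lam)
        mu_jx <- config$library_size * (1 + lam)
        body_mu <- body_mu_own + lam * config$body_factor * config$library_size *
          p_nuc * truth$length / 1000
      } else {
        mu_g <- mu_g_own
        q_eff <- q_own
        body_mu <- body_mu_own
      }
      n_jx <- rnb(ni, mu_jx)
      R <- rbinom(ni, n_jx, q_eff)
      EI <- rbinom(ni, R, 0.5)
      exonic <- rnb(ng, mu_g)
      count_rows[[k]] <- data.table::data.table(
        sample_id = smp$sample_id, intron_id = truth$intron_id,
        EI = EI, IE = R - EI, EE = n_jx - R,
        body = rpois(ni, body_mu),
        gene_exonic = exonic[gene_of]
      )
      gene_rows[[k]] <- data.table::data.table(
        sample_id = smp$sample_id, gene_id = genes$gene_id, exonic = exonic
      )
    }
    pir_tab[, pir := 100 * pir]
    list(counts = data.table::rbindlist(count_rows),
         gene_counts = data.table::rbindlist(gene_rows),
         samples = samples,
         true_pir = pir_tab)
  })
}

samples_lines <- function(config) {
  data.table::data.table(
    line_id = c(sprintf("ctrl%d", seq_len(config$n_lines_control)),
                sprintf("vcp%d", seq_len(config$n_lines_mutant))),
    genotype = c(rep("control", config$n_lines_control),
                 rep("mutant", config$n_lines_mutant))
  )
}

#' Sample sheet for the simulated design
#'
#' @param config A [sim_config()].
#' @return `data.table` with sample_id, line_id, genotype, DIV, fraction.
#' @export
simulated_sample_sheet <- function(config) {
  lines <- samples_lines(config)
  sheet <- data.table::CJ(line_id = lines$line_id, DIV = config$timepoints,
                          fraction = c("nuclear", "cytoplasmic"))
  sheet <- merge(sheet, lines, by = "line_id")
  sheet[, sample_id := sprintf("%s_DIV%02d_%s", line_id, DIV, substr(fraction, 1, 3))]
  data.table::setcolorder(sheet, c("sample_id", "line_id", "genotype", "DIV", "fraction"))
  data.table::setorder(sheet, line_id, DIV, fraction)
  sheet[]
}

# triangular effect ramp: 0 at the first and last timepoints, 1 at the peak
timepoint_ramp <- function(timepoints, peak) {
  tp <- sort(unique(timepoints))
  lo <- min(tp); hi <- max(tp)
  r <- ifelse(tp <= peak,
              if (peak > lo) (tp - lo) / (peak - lo) else 1,
              if (hi > peak) (hi - tp) / (hi - peak) else 1)
  setNames(r, as.character(tp))
}
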