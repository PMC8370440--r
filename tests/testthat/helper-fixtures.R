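library(data.table)

# small, fast simulation config used across module tests
small_config <- function(seed = 3L, ...) {
  defaults <- list(
    n_genes = 40L, introns_per_gene = c(2L, 4L),
    category_counts = c(nuclear = 6L, both = 4L, cytoplasmic = 4L),
    n_rbps = 12L, n_enriched_rbps = 4L,
    n_splicing_factors = 8L, n_housekeeping = 2L,
    seed = seed
  )
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# taxonomy calls built straight from planted truth (bypasses the scan);
# used where a test needs category groupings independent of detection
truth_calls <- function(st) {
  map <- c(nuclear = "nuclear_predominant", both = "both_compartments",
           cytoplasmic = "cytoplasmic_predominant")
  tr <- st$truth[st$truth$category != "background", ]
  data.table(intron_id = tr$intron_id, category = unname(map[tr$category]))
}

write_toy_gtf <- function(path, rows) {
  writeLines(rows, path)
  path
}

gtf_row <- function(chrom, type, start1, end1, strand, gene, tx = NULL,
                    name = gene) {
  attrs <- if (is.null(tx))
    sprintf('gene_id "%s"; gene_name "%s";', gene, name)
  else
    sprintf('gene_id "%s"; transcript_id "%s"; gene_name "%s";', gene, tx, name)
  sprintf("%s\ttoy\t%s\t%d\t%d\t.\t%s\t.\t%s", chrom, type, start1, end1, strand, attrs)
}

# --- independent oracles -------------------------------------------------

# Fisher two-sided p by direct hypergeometric enumeration over the support,
# using the same "probabilities <= observed (1 + eps)" two-sided rule
fisher_oracle_p <- function(a, b, c_, d) {
  r1 <- a + b; r2 <- c_ + d; c1 <- a + c_; n <- r1 + r2
  lo <- max(0L, c1 - r2); hi <- min(r1, c1)
  xs <- lo:hi
  logp <- lchoose(r1, xs) + lchoose(r2, c1 - xs) - lchoose(n, c1)
  p <- exp(logp)
  obs <- p[xs == a]
  sum(p[p <= obs * (1 + 1e-7)])
}

# Mann-Whitney U by explicit pairwise comparison
mw_u_oracle <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}

# exact two-sided Mann-Whitney p by full enumeration of group assignments
mw_p_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  vals <- c(x, y)
  u_obs <- mw_u_oracle(x, y)
  combs <- utils::combn(n1 + n2, n1)
  us <- apply(combs, 2, function(idx) mw_u_oracle(vals[idx], vals[-idx]))
  p_le <- mean(us <= u_obs + 1e-9)
  p_ge <- mean(us >= u_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# AUROC of a score against binary labels, via the rank-sum identity
auroc <- function(score, label) {
  r <- rank(score)
  n1 <- sum(label); n0 <- sum(!label)
  (sum(r[label]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

random_count_table <- function(introns, seed, lambda = c(3, 3, 5, 2)) {
  set.seed(seed)
  n <- nrow(introns)
  data.table(intron_id = introns$intron_id,
             EI = rpois(n, lambda[1]), IE = rpois(n, lambda[2]),
             EE = rpois(n, lambda[3]), body = rpois(n, lambda[4]))
}
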