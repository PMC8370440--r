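test_that("GC computation handles N exclusion and rejects bad characters", {
  expect_equal(compute_gc("GGCC"), 1)
  expect_equal(compute_gc("ATAT"), 0)
  expect_equal(compute_gc("GANC"), 2 / 3)  # hand count excluding N
  expect_true(is.na(compute_gc("NNNN")))
  expect_error(compute_gc("ACGR"), "outside|IUPAC|invalid")
  # strand invariance on random sequences
  set.seed(5)
  for (k in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T", "N"), 50, replace = TRUE), collapse = "")
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    expect_equal(compute_gc(s), compute_gc(rc))
  }
})

toy_track <- function(segs) {
  GenomicRanges::GRanges(segs$chrom, IRanges::IRanges(segs$start + 1L, segs$end),
                         score = segs$score)
}

test_that("conservation mean is length-weighted and respects the coverage rule", {
  introns <- data.table(intron_id = c("a", "b", "c"), chrom = "chr1",
                        start = c(0L, 100L, 300L), end = c(100L, 200L, 400L),
                        strand = "+")
  segs <- data.table(chrom = "chr1",
                     start = c(0L, 50L, 100L, 150L),
                     end = c(50L, 100L, 150L, 160L),
                     score = c(1, 0, 0.8, 0.4))
  cons <- compute_conservation(toy_track(segs), introns)
  expect_equal(cons[intron_id == "a", conservation], 0.5)
  # hand computation: (50*0.8 + 10*0.4) / 60, coverage 60%
  expect_equal(cons[intron_id == "b", conservation], (50 * 0.8 + 10 * 0.4) / 60)
  expect_equal(cons[intron_id == "b", coverage], 0.6)
  expect_true(is.na(cons[intron_id == "c", conservation]))
})

test_that("conservation mean is invariant to track segmentation", {
  introns <- data.table(intron_id = "a", chrom = "chr1",
                        start = 0L, end = 90L, strand = "+")
  coarse <- data.table(chrom = "chr1", start = c(0L, 30L), end = c(30L, 90L),
                       score = c(0.9, 0.3))
  fine <- data.table(chrom = "chr1", start = seq(0L, 80L, 10L),
                     end = seq(10L, 90L, 10L),
                     score = c(rep(0.9, 3), rep(0.3, 6)))
  expect_equal(compute_conservation(toy_track(coarse), introns)$conservation,
               compute_conservation(toy_track(fine), introns)$conservation)
})

test_that("a track on other chromosomes yields missing values with a warning", {
  introns <- data.table(intron_id = "a", chrom = "chrZ", start = 0L, end = 100L,
                        strand = "+")
  segs <- data.table(chrom = "chr1", start = 0L, end = 100L, score = 0.5)
  expect_warning(cons <- compute_conservation(toy_track(segs), introns), "absent")
  expect_true(is.na(cons$conservation))
})

test_that("category comparisons separate planted length and GC contrasts", {
  cfg <- small_config(seed = 37L)
  st <- simulate_annotation_and_genome(cfg)
  calls <- truth_calls(st)
  feats <- cis_feature_table(st$introns, genome = st$genome)
  bg <- background_intron_set(st$introns, calls)
  comps <- compare_categories(feats, calls, bg)
  # groups of 6 vs 4: the smallest attainable two-sided exact p is
  # 2 / choose(10, 4); a full separation must attain it
  p_floor <- 2 / choose(10, 4)
  len <- comps[feature == "length" & group1 == "nuclear" & group2 == "cytoplasmic"]
  expect_lte(len$p, p_floor + 1e-12)
  expect_equal(len$direction, "cytoplasmic")
  gc <- comps[feature == "gc" & group1 == "nuclear" & group2 == "cytoplasmic"]
  expect_lte(gc$p, p_floor + 1e-12)
  expect_equal(gc$direction, "nuclear")
  expect_true(all(comps[skipped == FALSE, q] >= comps[skipped == FALSE, p] - 1e-12))
})

test_that("groups below three members are skipped with a flag", {
  feats <- data.table(intron_id = sprintf("i%d", 1:10), length = 1:10,
                      gc = NA_real_, conservation = NA_real_)
  calls <- data.table(intron_id = c("i1", "i2"),
                      category = c("nuclear_predominant", "cytoplasmic_predominant"))
  comps <- compare_categories(feats, calls, sprintf("i%d", 1:10))
  expect_true(all(comps[group1 != "background" & group2 != "background", skipped]))
})

test_that("U statistic in comparisons equals the brute-force pairwise count", {
  feats <- data.table(intron_id = sprintf("i%d", 1:9),
                      length = c(5, 9, 2, 7, 7, 3, 8, 1, 6),
                      gc = NA_real_, conservation = NA_real_)
  calls <- data.table(intron_id = sprintf("i%d", 1:5),
                      category = rep("nuclear_predominant", 5))
  comps <- compare_categories(feats, calls, sprintf("i%d", 1:9))
  got <- comps[feature == "length" & group1 == "nuclear" & group2 == "background"]
  expect_equal(got$U, mw_u_oracle(feats$length[1:5], feats$length[6:9]))
})

test_that("expression coupling recovers a planted cytoplasmic downshift of host genes", {
  set.seed(11)
  n_genes <- 120
  genes <- sprintf("g%03d", 1:n_genes)
  design <- data.table(
    sample_id = sprintf("s%d", 1:8),
    line_id = rep(sprintf("L%d", 1:4), 2),
    genotype = rep(c("control", "control", "mutant", "mutant"), 2),
    DIV = 14L,
    fraction = rep(c("nuclear", "cytoplasmic"), each = 4)
  )
  mu <- matrix(1000, n_genes, 8, dimnames = list(genes, design$sample_id))
  nuc_hosts <- genes[1:40]
  cyto_cols <- design[fraction == "cytoplasmic" & genotype == "mutant", sample_id]
  mu[nuc_hosts, cyto_cols] <- 1000 * 2^(-0.5)
  counts <- data.table(
    sample_id = rep(design$sample_id, each = n_genes),
    gene_id = rep(genes, 8),
    exonic = rpois(n_genes * 8, as.vector(mu))
  )
  expr <- compute_expression(counts, design)
  calls <- data.table(intron_id = paste0(genes[1:60], ":i"),
                      category = rep(c("nuclear_predominant", "cytoplasmic_predominant"),
                                     each = 30))
  host_map <- data.table(intron_id = paste0(genes[1:60], ":i"), gene_id = genes[1:60])
  cpl <- expression_coupling(expr, calls, design, host_map, timepoint = 14L)
  nuc_cyto <- cpl[category == "nuclear_predominant" & fraction == "cytoplasmic"]
  expect_lt(nuc_cyto$median_log2fc, -0.3)
  expect_lt(nuc_cyto$sign_test_p, 0.01)
  ctrl_cell <- cpl[category == "cytoplasmic_predominant" & fraction == "nuclear"]
  expect_lt(abs(ctrl_cell$median_log2fc), 0.15)
})
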