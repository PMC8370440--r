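test_that("planted truth covers every intron once with disjoint categories", {
  st <- simulate_structure(small_config())
  expect_equal(sort(st$truth$intron_id), sort(st$introns$intron_id))
  expect_false(anyDuplicated(st$truth$intron_id) > 0)
  cc <- small_config()$category_counts
  tab <- st$truth[, .N, by = category]
  for (cat in names(cc))
    expect_equal(tab[category == cat, N], unname(cc[cat]))
})

test_that("degenerate length distributions are honored exactly", {
  cfg <- small_config(length_dist = list(
    nuclear = list(meanlog = log(200), sdlog = 0),
    both = list(meanlog = log(1000), sdlog = 0),
    cytoplasmic = list(meanlog = log(2000), sdlog = 0),
    background = list(meanlog = log(400), sdlog = 0.5)
  ))
  st <- simulate_structure(cfg)
  expect_true(all(st$truth[category == "nuclear", length] == 200L))
  expect_true(all(st$truth[category == "cytoplasmic", length] == 2000L))
})

test_that("realized intron GC is close to its target at moderate length", {
  cfg <- small_config(length_dist = list(
    nuclear = list(meanlog = log(5000), sdlog = 0),
    both = list(meanlog = log(5000), sdlog = 0),
    cytoplasmic = list(meanlog = log(5000), sdlog = 0),
    background = list(meanlog = log(500), sdlog = 0.3)
  ))
  st <- simulate_annotation_and_genome(cfg)
  feats <- cis_feature_table(st$introns, genome = st$genome)
  m <- merge(feats, st$truth[, .(intron_id, category, gc_target)], by = "intron_id")
  planted <- m[category != "background"]
  # binomial sampling bound: at length 5000, 4 sd ~ 0.028
  expect_true(all(abs(planted$gc - planted$gc_target) < 0.03))
})

test_that("the generator is deterministic under a fixed seed", {
  cfg <- small_config(seed = 17L)
  d1 <- tempfile(); d2 <- tempfile()
  simulate_annotation_and_genome(cfg, dir = d1)
  simulate_annotation_and_genome(cfg, dir = d2)
  expect_identical(readLines(file.path(d1, "genome.fa")),
                   readLines(file.path(d2, "genome.fa")))
  expect_identical(readLines(file.path(d1, "annotation.gtf")),
                   readLines(file.path(d2, "annotation.gtf")))
  s1 <- simulate_fraction_counts(cfg)
  s2 <- simulate_fraction_counts(cfg)
  expect_identical(s1$counts, s2$counts)
  t1 <- simulate_crosslink_tracks(cfg)
  t2 <- simulate_crosslink_tracks(cfg)
  expect_identical(lapply(t1, GenomicRanges::start), lapply(t2, GenomicRanges::start))
  c1 <- simulate_conservation_track(cfg)
  c2 <- simulate_conservation_track(cfg)
  expect_identical(c1$score, c2$score)
})

test_that("the written GTF round-trips through the annotation reader", {
  cfg <- small_config(seed = 9L)
  dir <- tempfile()
  st <- simulate_annotation_and_genome(cfg, dir = dir)
  ex <- read_gene_annotation(file.path(dir, "annotation.gtf"))
  introns <- derive_introns(ex)
  expect_setequal(introns$intron_id, st$introns$intron_id)
})

test_that("planted ΔPIR is recovered empirically at deep counts", {
  cfg <- small_config(library_size = 600, delta_pir = 25, leakage = 0)
  sim <- simulate_fraction_counts(cfg)
  st <- simulate_structure(cfg)
  cyto_ids <- st$truth[category == "cytoplasmic", intron_id]
  peak <- cfg$peak_timepoint
  sheet <- sim$samples
  cnt <- merge(sim$counts, sheet, by = "sample_id")
  pooled <- cnt[intron_id %in% cyto_ids & DIV == peak & fraction == "cytoplasmic",
                .(EI = sum(EI), IE = sum(IE), EE = sum(EE)), by = .(intron_id, genotype)]
  pooled[, pir := 100 * ((EI + IE) / 2) / ((EI + IE) / 2 + EE)]
  wide <- data.table::dcast(pooled, intron_id ~ genotype, value.var = "pir")
  expect_true(all(abs((wide$mutant - wide$control) - 25) < 5))
})

test_that("expected junction depth matches the configured library size", {
  # law of total expectation: E[EI+IE+EE] = library_size (nuclear samples)
  cfg <- small_config(nb_dispersion = 0.05)
  sim <- simulate_fraction_counts(cfg)
  nuc <- sim$samples[fraction == "nuclear", sample_id]
  tot <- sim$counts[sample_id %in% nuc, EI + IE + EE]
  se <- sd(tot) / sqrt(length(tot))
  expect_lt(abs(mean(tot) - cfg$library_size), 4 * se + 1)
})

test_that("with no planted effects control and mutant PIR are exchangeable", {
  cfg <- small_config(delta_pir = 0, leakage = 0, seed = 23L)
  sim <- simulate_fraction_counts(cfg)
  scan <- differential_ir_scan(sim$counts, sim$samples)
  expect_equal(sum(scan$significant), 0L)
  # raw Fisher p approximately uniform: ~5% below 0.05
  expect_lt(mean(scan[coverage_ok == TRUE, p] < 0.05), 0.1)
})

test_that("crosslink fold multiplier applies only to enriched RBPs in cytoplasmic introns", {
  cfg <- small_config(crosslink_rate = 20, crosslink_fold = 4, length_dist = list(
    nuclear = list(meanlog = log(3000), sdlog = 0),
    both = list(meanlog = log(3000), sdlog = 0),
    cytoplasmic = list(meanlog = log(3000), sdlog = 0),
    background = list(meanlog = log(3000), sdlog = 0)
  ))
  st <- simulate_structure(cfg)
  tracks <- simulate_crosslink_tracks(cfg, st)
  cyto <- st$introns[st$introns$intron_id %in%
                       st$truth[category == "cytoplasmic", intron_id], ]
  other <- st$introns[st$introns$intron_id %in%
                        st$truth[category == "background", intron_id], ]
  dens_ratio <- function(rbp) {
    gr <- tracks[[rbp]]
    n_in <- function(introns) {
      igr <- GenomicRanges::GRanges(introns$chrom,
                                    IRanges::IRanges(introns$start + 1L, introns$end))
      sum(IRanges::overlapsAny(gr, igr)) / sum(introns$end - introns$start)
    }
    n_in(cyto) / n_in(other)
  }
  enr <- st$rbps[enriched == TRUE, rbp][1]
  non <- st$rbps[enriched == FALSE, rbp][1]
  expect_gt(dens_ratio(enr), 2.5)           # Poisson rate estimate of fold 4
  expect_lt(abs(dens_ratio(non) - 1), 0.5)  # no fold for non-enriched RBPs
})

test_that("conservation shift raises cytoplasmic-category intron scores only", {
  cfg <- small_config(conservation_shift = 0.3)
  st <- simulate_structure(cfg)
  track <- simulate_conservation_track(cfg, st)
  cons <- compute_conservation(track, st$introns)
  m <- merge(cons, st$truth[, .(intron_id, category)], by = "intron_id")
  expect_gt(m[category == "cytoplasmic", mean(conservation)],
            m[category == "background", mean(conservation)] + 0.2)
  expect_lt(abs(m[category == "nuclear", mean(conservation)] -
                  m[category == "background", mean(conservation)]), 0.05)
})

test_that("config validation rejects impossible designs and round-trips via file", {
  expect_error(sim_config(n_genes = 10, category_counts = c(nuclear = 9, both = 9, cytoplasmic = 9)),
               "category_counts")
  expect_error(sim_config(leakage = 1.2))
  cfg <- small_config(seed = 5L)
  f <- tempfile(fileext = ".json")
  write_sim_config(cfg, f)
  cfg2 <- read_sim_config(f)
  expect_equal(cfg2$category_counts, cfg$category_counts)
  expect_equal(cfg2$seed, cfg$seed)
  expect_equal(cfg2$length_dist$nuclear$meanlog, cfg$length_dist$nuclear$meanlog)
})
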