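test_that("PIR follows the boundary-mean formula", {
  tab <- data.table(sample_id = "s", intron_id = c("a", "b", "c"),
                    EI = c(10L, 0L, 30L), IE = c(10L, 0L, 10L),
                    EE = c(10L, 50L, 20L))
  pir <- compute_pir(tab)
  expect_equal(pir$pir, c(50, 0, 100 * 20 / 40))  # hand evaluation
  expect_error(compute_pir(data.table(sample_id = "s", intron_id = "a",
                                      EI = -1L, IE = 0L, EE = 0L)), "negative")
})

test_that("PIR coverage filter and scale invariance hold", {
  base <- data.table(sample_id = "s", intron_id = "a", EI = 3L, IE = 2L, EE = 4L)
  expect_true(is.na(compute_pir(base, min_junction_reads = 10)$pir))
  p1 <- compute_pir(base, min_junction_reads = 1)$pir
  for (k in c(2L, 7L, 40L)) {
    scaled <- data.table(sample_id = "s", intron_id = "a",
                         EI = 3L * k, IE = 2L * k, EE = 4L * k)
    expect_equal(compute_pir(scaled, min_junction_reads = 1)$pir, p1)
  }
  # monotone: more retention reads raise PIR, more EE lowers it
  up <- compute_pir(data.table(sample_id = "s", intron_id = "a",
                               EI = 4L, IE = 2L, EE = 4L), 1)$pir
  dn <- compute_pir(data.table(sample_id = "s", intron_id = "a",
                               EI = 3L, IE = 2L, EE = 5L), 1)$pir
  expect_gt(up, p1); expect_lt(dn, p1)
})

test_that("junction counter applies overhang, exact-skip and containment rules", {
  introns <- data.table(intron_id = "gX:chr1:100-200:+", gene_id = "gX",
                        gene_name = "gX", chrom = "chr1", start = 100L,
                        end = 200L, strand = "+", ordinal = 1L)
  sam <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:unsorted",
    "@SQ\tSN:chr1\tLN:1000",
    # [95,120): only 5 bases on the exon side -> not counted
    "r1\t0\tchr1\t96\t255\t25M\t*\t0\t0\t*\t*",
    # [90,110): 10 bases each side -> EI
    "r2\t0\tchr1\t91\t255\t20M\t*\t0\t0\t*\t*",
    # split read skipping [100,200) exactly -> EE
    "r3\t0\tchr1\t91\t255\t10M100N10M\t*\t0\t0\t*\t*",
    # split read with a different skip -> nothing
    "r4\t0\tchr1\t91\t255\t10M90N10M\t*\t0\t0\t*\t*",
    # fully inside the intron -> body
    "r5\t0\tchr1\t121\t255\t30M\t*\t0\t0\t*\t*",
    # crossing the 3' boundary -> IE
    "r6\t0\tchr1\t191\t255\t20M\t*\t0\t0\t*\t*"
  ), sam)
  cnt <- count_junction_reads(sam, introns, min_overhang = 8)
  expect_equal(cnt$EI, 1L)
  expect_equal(cnt$IE, 1L)
  expect_equal(cnt$EE, 1L)
  expect_equal(cnt$body, 1L)
})

test_that("EI/IE labels are strand-aware (EI is transcription-order 5')", {
  introns <- data.table(intron_id = "gY:chr1:100-200:-", gene_id = "gY",
                        gene_name = "gY", chrom = "chr1", start = 100L,
                        end = 200L, strand = "-", ordinal = 1L)
  sam <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:unsorted", "@SQ\tSN:chr1\tLN:1000",
    "r1\t0\tchr1\t91\t255\t20M\t*\t0\t0\t*\t*",   # genomic start boundary
    "r2\t0\tchr1\t191\t255\t20M\t*\t0\t0\t*\t*"   # genomic end boundary
  ), sam)
  cnt <- count_junction_reads(sam, introns, min_overhang = 8)
  # on the minus strand the genomic end is the transcription-order 5' boundary
  expect_equal(cnt$EI, 1L)
  expect_equal(cnt$IE, 1L)
})

test_that("emitted alignments round-trip exactly through the counter", {
  st <- simulate_structure(small_config(seed = 31L))
  for (s in 1:3) {
    tab <- random_count_table(st$introns, seed = 100 + s)
    sam <- tempfile(fileext = ".sam")
    emit_alignments(tab, st$introns, st$contig_lengths, sam)
    cnt <- count_junction_reads(sam, st$introns, exons = st$exons)
    m <- merge(tab, cnt, by = "intron_id", suffixes = c(".t", ""))
    expect_identical(m$EI, m$EI.t)
    expect_identical(m$IE, m$IE.t)
    expect_identical(m$EE, m$EE.t)
    expect_identical(m$body, m$body.t)
  }
})

test_that("counter matches a per-read brute-force reimplementation of the rules", {
  st <- simulate_structure(small_config(seed = 41L))
  introns <- st$introns
  tab <- random_count_table(introns, seed = 77)
  sam <- tempfile(fileext = ".sam")
  emit_alignments(tab, introns, st$contig_lengths, sam)
  cnt <- count_junction_reads(sam, introns)

  # independent oracle: parse SAM text and apply the three rules per read
  lines <- grep("^@", readLines(sam), invert = TRUE, value = TRUE)
  fields <- data.table::tstrsplit(lines, "\t")
  chrom <- fields[[3]]; pos1 <- as.integer(fields[[4]]); cig <- fields[[6]]
  ov <- 8L
  oracle <- data.table(intron_id = introns$intron_id, EI = 0L, IE = 0L,
                       EE = 0L, body = 0L)
  for (k in seq_along(lines)) {
    st0 <- pos1[k] - 1L
    ops <- regmatches(cig[k], gregexpr("[0-9]+[MN]", cig[k]))[[1]]
    lens <- as.integer(sub("[MN]", "", ops))
    types <- sub("[0-9]+", "", ops)
    if ("N" %in% types) {
      skip_start <- st0 + lens[1]
      skip_end <- skip_start + lens[types == "N"]
      hit <- which(introns$chrom == chrom[k] & introns$start == skip_start &
                     introns$end == skip_end)
      if (length(hit)) oracle$EE[hit] <- oracle$EE[hit] + 1L
    } else {
      en0 <- st0 + lens[1]
      for (i in which(introns$chrom == chrom[k])) {
        s <- introns$start[i]; e <- introns$end[i]
        cs <- st0 <= s - ov && en0 >= s + ov
        ce <- st0 <= e - ov && en0 >= e + ov
        if (cs || ce) {
          # crossing the transcription-order 5' boundary (or both) -> EI
          ei <- (introns$strand[i] == "+" && cs) || (introns$strand[i] == "-" && ce)
          if (ei) oracle$EI[i] <- oracle$EI[i] + 1L else oracle$IE[i] <- oracle$IE[i] + 1L
        } else if (st0 >= s && en0 <= e) {
          oracle$body[i] <- oracle$body[i] + 1L
        }
      }
    }
  }
  m <- merge(cnt, oracle, by = "intron_id", suffixes = c("", ".o"))
  expect_identical(m$EI, m$EI.o)
  expect_identical(m$IE, m$IE.o)
  expect_identical(m$EE, m$EE.o)
  expect_identical(m$body, m$body.o)
})

test_that("emit_alignments rejects impossible requests and handles empty tables", {
  introns <- data.table(intron_id = "g:c:100-110:+", gene_id = "g",
                        gene_name = "g", chrom = "c", start = 100L,
                        end = 110L, strand = "+", ordinal = 1L)
  tab <- data.table(intron_id = "g:c:100-110:+", EI = 1L, IE = 0L, EE = 0L, body = 0L)
  expect_error(emit_alignments(tab, introns, c(c = 1000L), tempfile(), min_overhang = 8),
               "shorter")
  sam <- tempfile(fileext = ".sam")
  emit_alignments(tab[0], introns, c(c = 1000L), sam)
  txt <- readLines(sam)
  expect_true(all(startsWith(txt, "@")))
  cnt <- count_junction_reads(sam, introns)
  expect_equal(sum(cnt$EI + cnt$IE + cnt$EE + cnt$body), 0L)
})

test_that("CPM normalization sums to one million and flags reliable genes", {
  gcounts <- data.table(
    sample_id = rep(c("s1", "s2"), each = 3),
    gene_id = rep(c("g1", "g2", "g3"), 2),
    exonic = c(500000, 500000, 0, 10, 999990, 0)
  )
  design <- data.table(sample_id = c("s1", "s2"), DIV = 0L,
                       fraction = "nuclear", genotype = "control",
                       line_id = c("l1", "l2"))
  expr <- compute_expression(gcounts, design)
  expect_equal(colSums(expr$cpm), c(s1 = 1e6, s2 = 1e6))
  expect_equal(expr$logcpm["g1", "s1"], log2(5e5 + 1))
  # brute-force threshold check: reliable = CPM >= 1 in all samples of a group
  expect_equal(unname(expr$reliable), c(TRUE, TRUE, FALSE))
  bad <- data.table(sample_id = "s1", gene_id = "g1", exonic = 0)
  expect_error(compute_expression(bad, design), "zero total")
})

test_that("IRT share summarizes retention on the 0-1 scale per genotype", {
  design <- data.table(sample_id = c("m1", "c1"), line_id = c("v1", "l1"),
                       genotype = c("mutant", "control"), DIV = 14L,
                       fraction = "cytoplasmic")
  counts <- data.table(
    sample_id = rep(c("m1", "c1"), each = 2),
    intron_id = rep(c("i1", "i2"), 2),
    EI = c(40L, 40L, 20L, 20L), IE = c(40L, 40L, 20L, 20L),
    EE = c(60L, 60L, 80L, 80L)
  )
  out <- compute_irt_fraction(counts, c("i1", "i2"), design)
  expect_equal(out[genotype == "mutant", median_share], 0.4)
  expect_equal(out[genotype == "control", median_share], 0.2)
  # zero EE -> share 1
  z <- compute_irt_fraction(data.table(sample_id = "m1", intron_id = "i1",
                                       EI = 10L, IE = 10L, EE = 0L),
                            "i1", design)
  expect_equal(z$median_share, 1)
  expect_error(compute_irt_fraction(counts, character(0), design), "empty")
})
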