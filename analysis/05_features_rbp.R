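#!/usr/bin/env Rscript
# Characterize each taxonomy category by cis attributes (intron length, GC
# content, conservation) against the background of all introns of
# IR-targeted genes, couple categories to host-gene expression changes, and
# rank RBPs by crosslink enrichment in cytoplasmic- vs nuclear-predominant
# retained introns.

suppressMessages({library(fracir); library(data.table)})

datadir <- "results/data"
design <- fread(file.path(datadir, "sample_sheet.tsv"))
gene_counts <- fread(file.path(datadir, "gene_counts.tsv"))
truth_rbps <- fread(file.path(datadir, "truth_rbps.tsv"))
gtf <- file.path(datadir, "annotation.gtf")

exons <- read_gene_annotation(gtf)
introns <- derive_introns(exons)
genome <- read_genome(file.path(datadir, "genome.fa"))
calls <- fread("results/taxonomy.tsv")
peak <- pick_peak_timepoint(fread("results/differential_ir.tsv"))

bg_ids <- background_intron_set(introns, calls)
feats <- cis_feature_table(introns[introns$intron_id %in% bg_ids, ],
                           genome = genome,
                           track = file.path(datadir, "conservation.bedGraph"))
fwrite(feats, "results/cis_features.tsv", sep = "\t")
comps <- compare_categories(feats, calls, bg_ids)
fwrite(comps, "results/feature_comparisons.tsv", sep = "\t")
message("nuclear vs cytoplasmic category contrasts:")
print(comps[group1 == "nuclear" & group2 == "cytoplasmic",
            .(feature, median_nuclear = signif(median1, 3),
              median_cytoplasmic = signif(median2, 3), p = signif(p, 2))])

expr <- compute_expression(gene_counts, design)
coupling <- expression_coupling(expr, calls, design, introns, timepoint = peak)
fwrite(coupling, "results/expression_coupling.tsv", sep = "\t")

beds <- list.files(file.path(datadir, "crosslinks"), pattern = "\\.bed$",
                   full.names = TRUE)
tracks <- setNames(as.list(beds), sub("\\.bed$", "", basename(beds)))
call_introns <- introns[introns$intron_id %in% calls$intron_id, ]
bg_introns <- introns[introns$intron_id %in% setdiff(bg_ids, calls$intron_id), ]
emat <- crosslink_enrichment_matrix(tracks, call_introns, bg_introns)
fwrite(data.table(intron_id = rownames(emat$scores), emat$scores),
       "results/enrichment_matrix.tsv", sep = "\t")
rk <- rank_rbps_by_category(emat, calls)
fwrite(rk, "results/rbp_ranking.tsv", sep = "\t")
tp <- merge(rk, truth_rbps, by = "rbp", suffixes = c("", "_truth"))
message(sprintf("%d RBPs enriched in cytoplasmic-predominant introns (%d planted; precision %.2f)",
                sum(rk$enriched), sum(truth_rbps$enriched),
                tp[enriched == TRUE, mean(enriched_truth)]))
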