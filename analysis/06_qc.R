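#!/usr/bin/env Rscript
# Quality control: fractionation leakage from housekeeping-gene intron-body
# vs exonic signal, global expression structure by SVD (which axes carry
# developmental stage and cellular fraction), and unsupervised hierarchical
# clustering of samples on Spearman correlation distance.

suppressMessages({library(fracir); library(data.table)})

datadir <- "results/data"
counts <- fread(file.path(datadir, "junction_counts.tsv"))
gene_counts <- fread(file.path(datadir, "gene_counts.tsv"))
design <- fread(file.path(datadir, "sample_sheet.tsv"))
genes <- fread(file.path(datadir, "truth_genes.tsv"))
exons <- read_gene_annotation(file.path(datadir, "annotation.gtf"))
introns <- derive_introns(exons)

hk <- genes[role == "housekeeping", gene_id]
leak <- fractionation_leakage(counts, introns, exons, hk, design)
fwrite(leak, "results/fractionation_leakage.tsv", sep = "\t")
message(sprintf("median normalized leakage (cytoplasmic/nuclear intron signal): %.3f",
                median(leak$normalized_leakage, na.rm = TRUE)))

expr <- compute_expression(gene_counts, design)
m <- expr$logcpm[expr$reliable, , drop = FALSE]
dec <- svd_structure(m, design)
fwrite(data.table(component = seq_along(dec$variance_fraction),
                  variance_fraction = dec$variance_fraction),
       "results/svd_variance.tsv", sep = "\t")
fwrite(dec$coords[, .(sample_id, PC1, PC2, line_id, genotype, DIV, fraction)],
       "results/svd_coords.tsv", sep = "\t")
message(sprintf("PC1 %.0f%% of variance (developmental stage), PC2 %.0f%% (fraction)",
                100 * dec$variance_fraction[1], 100 * dec$variance_fraction[2]))

cl <- sample_clustering(m)
writeLines(cl$newick, "results/sample_clustering.nwk")
message("wrote sample dendrogram (Newick) to results/sample_clustering.nwk")
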