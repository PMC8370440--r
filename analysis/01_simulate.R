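#!/usr/bin/env Rscript
# Generate the synthetic fractionated RNA-seq study: 4 control + 3 VCP-mutant
# lines, six timepoints (DIV 0-35), nuclear and cytoplasmic fractions, with
# 237/63/49 aberrant intron-retention events planted in the three
# nucleocytoplasmic categories, matched crosslink and conservation tracks,
# and full ground truth. All downstream scripts read from results/data/.

suppressMessages(library(fracir))

outdir <- "results/data"
cfg <- sim_config(seed = 1L)

st <- simulate_annotation_and_genome(cfg, dir = outdir)
sim <- simulate_fraction_counts(cfg, st)
tracks <- simulate_crosslink_tracks(cfg, st, dir = file.path(outdir, "crosslinks"))
cons <- simulate_conservation_track(cfg, st, path = file.path(outdir, "conservation.bedGraph"))

write_introns_bed(st$introns, file.path(outdir, "introns.bed"))
data.table::fwrite(sim$samples, file.path(outdir, "sample_sheet.tsv"), sep = "\t")
data.table::fwrite(sim$counts, file.path(outdir, "junction_counts.tsv"), sep = "\t")
data.table::fwrite(sim$gene_counts, file.path(outdir, "gene_counts.tsv"), sep = "\t")
data.table::fwrite(st$truth, file.path(outdir, "truth_introns.tsv"), sep = "\t")
data.table::fwrite(st$genes, file.path(outdir, "truth_genes.tsv"), sep = "\t")
data.table::fwrite(st$rbps, file.path(outdir, "truth_rbps.tsv"), sep = "\t")
write_sim_config(cfg, file.path(outdir, "config.json"))

message(sprintf("simulated %d genes / %d introns across %d samples (%d planted events)",
                nrow(st$genes), nrow(st$introns), nrow(sim$samples),
                sum(st$truth$category != "background")))
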