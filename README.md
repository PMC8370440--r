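# fracir — compartment-aware intron retention for fractionated RNA-seq

Bulk RNA-seq of separately sequenced **nuclear and cytoplasmic fractions**
makes it possible to ask not just *whether* an intron is aberrantly
retained in a disease genotype, but *where* the retained transcript lives.
`fracir` implements that analysis end to end for a time-resolved,
two-genotype fractionation design (the motivating setting is iPSC-derived
motor neurogenesis with ALS-causing mutations, sampled at six
differentiation timepoints in 4 control and 3 mutant lines):

1. **Quantification.** Percent intron retention per intron and sample from
   junction reads:
   `PIR = 100 · mean(EI, IE) / (mean(EI, IE) + EE)`,
   where EI/IE are reads crossing the exon–intron / intron–exon boundary
   (transcription order, ≥ 8 nt overhang) and EE are split reads skipping
   the intron exactly. Gene expression as log2 CPM.
2. **Differential retention.** Per fraction × timepoint, counts pooled
   within genotype and tested with a two-sided **Fisher count test** on
   `[[EI+IE, 2·EE]]` (control vs mutant), BH-corrected within stratum,
   with |ΔPIR| ≥ 10, coverage, and per-line sign-consistency filters.
3. **Nucleocytoplasmic taxonomy.** Significant included events at the peak
   timepoint are partitioned into *nuclear-predominant* /
   *both-compartments* / *cytoplasmic-predominant* by where they reach
   significance; external PIR datasets are profiled per category with a
   line-stratified permutation test.
4. **Cis features & RBP binding.** Intron length, GC, mean conservation
   per category vs the background of IR-targeted genes (tie-aware exact
   Mann-Whitney), and per-RBP crosslink enrichment
   `log2((density + 0.1) / (background median density + 0.1))`
   with a ranking of RBPs preferentially bound to cytoplasmic-predominant
   introns.
5. **QC.** Fractionation leakage from housekeeping-gene intron-body vs
   exonic signal, SVD of expression (variance per axis, sample
   coordinates), Spearman/complete-linkage sample clustering (Newick).

Because the deposited study data are not redistributable at desk scale,
the package ships a first-class **synthetic generator**
(`simulate_*`) that plants every one of these effects with known ground
truth — 237/63/49 events in the three categories peaking at DIV 14,
fraction leakage, category-specific intron architecture, enriched RBP
crosslink tracks, a conservation shift — and the test suite validates the
pipeline by recovery and calibration against that truth.

## Worked example

The `analysis/` directory is a numbered workflow over the package. From
the repository root:

```sh
Rscript analysis/01_simulate.R      # synthetic study -> results/data/
Rscript analysis/02_quantify.R      # PIR, expression, IRT shares
Rscript analysis/03_differential.R  # per-stratum scan, census, factor shift
Rscript analysis/04_taxonomy.R      # three-way classification at the peak
Rscript analysis/05_features_rbp.R  # cis features + RBP ranking
Rscript analysis/06_qc.R            # leakage, SVD, clustering
```

Selected output (seed 1):

```
simulated 450 genes / 2279 introns across 84 samples (349 planted events)

cytoplasmic IRT share at the peak (median [IQR]):
  control: 0.10 [0.06-0.14]
  mutant: 0.35 [0.31-0.40]

significant IR events per stratum:
      fraction     0     3     7    14    22
1: cytoplasmic     0     2    94   112   108
2:     nuclear     1    16   224   303   290

peak timepoint: DIV 14
taxonomy calls:
                  category     N
1:       both_compartments    63
2: cytoplasmic_predominant    49
3:     nuclear_predominant   238
recall 1.000, category accuracy 1.000

nuclear vs cytoplasmic category contrasts:
        feature median_nuclear median_cytoplasmic     p
1:       length        199.000           1960.000 3e-28
2:           gc          0.698              0.401 3e-28
3: conservation          0.503              0.701 3e-28

28 RBPs enriched in cytoplasmic-predominant introns (27 planted; precision 0.96)
median normalized leakage (cytoplasmic/nuclear intron signal): 0.064
PC1 49% of variance (developmental stage), PC2 16% (fraction)
```

Reading this: the differential scan recovers all 349 planted events at the
DIV-14 peak and assigns every recovered planted event to its true
compartment category (238 nuclear-predominant calls = 237 planted plus one
background false positive). The mutant cytoplasm carries ~35% of the
junction evidence for affected introns in retained form vs ~10% in
controls; nuclear-category introns are short/GC-rich while
cytoplasmic-category introns are long/AT-rich and more conserved; and the
RBP ranking recovers the planted cytoplasmically-binding RBP set almost
exactly. Expression structure is dominated by developmental stage (PC1)
with cellular fraction second (PC2).

Equivalently, `run_pipeline(sim_config(seed = 1), outdir = "out")` runs
all stages in one call and writes every table plus a JSON manifest of
seeds and thresholds; outputs are byte-identical across runs at a fixed
seed.

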