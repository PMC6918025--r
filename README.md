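# barseqfit

Functional-genomics toolkit for discovering carbon-catabolism genes by
combining **barcoded mutant-pool fitness profiling (BarSeq / RB-TDNA-seq)**
with **bulk RNA-seq differential expression**, modeled on the analysis that
identified the d-galacturonic acid (d-galUA) catabolism pathway of the
oleaginous yeast *Rhodosporidium toruloides*. The package is aimed at
microbial functional genomicists running pooled-insertion fitness screens
alongside transcriptomics.

## What it computes

**Strain and gene fitness.** For barcode *b*, the strain fitness score is
the depth-scaled, pseudocounted log2 ratio of condition versus time-zero
counts,

    s_b = log2((n_b · N0/N + 1) / (n0_b + 1)),

normalized to zero mean per sample. Gene fitness is the weighted mean of
all observations (barcodes × replicates) of a gene with weights
`w_i = 2 / (1/(n0_i+1) + 1/(n_i+1))` (harmonic mean of the observation's
depths), and significance is a variance-floor T-statistic
`t = f / sqrt(max(V_count, V_emp))` combining the Poisson count-noise floor
with the empirical between-barcode/between-replicate variance; `|t| > 3`
marks significant fitness effects.

**Expression.** FPKM (`counts · 1e9 / (libsize · length)`), one-way ANOVA
on `log2(FPKM + 1)` across conditions with Benjamini–Hochberg adjustment,
and hierarchical clustering of expression profiles (distance `1 − Pearson r`,
average linkage, cut at *k* = 3).

**Integration (quadrant filter).** A gene is a pathway candidate iff it is
significantly induced on the target carbon source (q < 0.05, FPKM > 5,
≥ 2-fold over every reference condition) *and* its mutants show a specific
fitness defect (relative fitness < −1 and relative T < −3 against every
reference).

**Kinetics.** Conversion of NADPH-depletion absorbance slopes to specific
activities (nkat/mg) and direct nonlinear Michaelis–Menten fits
(`v = Vmax·S/(Km+S)`).

**Synthetic data.** Generators for pools, BarSeq counts under competitive
selection (`abundance × 2^(g(1+f))`, multinomial sequencing), NB RNA-seq
counts, barcode-amplicon FASTQ, and enzyme-assay rate tables — all with
known ground truth, so the full pipeline is testable without any external
accession.

## Worked example

The scripted analysis under `analysis/` simulates a 500-gene study with a
four-gene planted pathway (50-fold induction and a −0.8 per-generation
fitness defect on d-galUA) and runs every stage:

```sh
Rscript analysis/01_simulate.R   # pool + BarSeq + RNA-seq counts -> results/
Rscript analysis/02_fitness.R    # strain/gene fitness + relative fitness
Rscript analysis/03_expression.R # FPKM, ANOVA/BH, prefilter, clustering
Rscript analysis/04_integrate.R  # quadrant filter -> candidate table
Rscript analysis/05_kinetics.R   # Michaelis-Menten round trips
```

Output from a run (seed 20260926 inside `01_simulate.R`):

```
dgalua: 500 genes scored; 12 with |T| > 3; fitness range [-4.96, 0.23]
gly:    500 genes scored;  2 with |T| > 3; fitness range [-0.32, 0.45]
d-galUA vs gly: 4 genes below the (-1, -3) relative cutoffs:
  gene_0011, gene_0101, gene_0257, gene_0404
4 candidate gene(s): gene_0011, gene_0101, gene_0257, gene_0404
planted genes recovered: 4 / 4; false calls: 0
published worked example: 7 / 7 genes pass the induction rule
RTO4_11882 (d-galUA reductase): Km 7 -> refit 7 mM; Vmax 553 -> refit 553 nkat/mg
```

Reading: the planted pathway genes carry strongly negative fitness on
d-galUA (≈ g·f = −4.8 before noise) but are neutral on glycerol and d-glc,
so they — and only they — fall in the induced-and-required quadrant. The
seven-gene table bundled in `inst/extdata/` (the curated published FPKM and
fitness summary for the d-galUA-induced *R. toruloides* genes, exposed via
`dgalua_candidate_reference()`) all pass the ≥ 2-fold induction rule, and
the Michaelis–Menten fitter exactly recovers the reported kinetic
parameters of the purified pathway enzymes from noiseless assay curves.

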