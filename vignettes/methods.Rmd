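---
title: "Methods: pooled-fitness and expression integration for carbon-catabolism gene discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pooled-fitness and expression integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barseqfit)
```

# The problem

*Rhodosporidium toruloides* grows efficiently on d-galacturonic acid
(d-galUA), the backbone sugar of pectin, but the basidiomycete pathway for
its catabolism had to be identified functionally. `barseqfit` implements the
two genome-wide screens used for that identification and their integration:

1. **Fitness profiling (BarSeq / RB-TDNA-seq).** A pooled library of
   sequence-barcoded random T-DNA insertion mutants is grown competitively
   on a carbon source; insertions in genes required for growth deplete
   their barcodes relative to a time-zero sample of the same pool.
2. **Expression profiling.** Bulk RNA-seq on the three carbon sources
   (d-galUA, d-glc, glycerol) identifies genes transcriptionally induced by
   d-galUA.
3. **Quadrant integration.** Genes both specifically induced on d-galUA and
   required for fitness on it are called pathway candidates.

A small kinetics module covers the downstream enzymology (specific
activities from NADPH-depletion slopes, Michaelis–Menten fits).

# Fitness model

For barcode $b$ with time-zero count $n_{0b}$ and condition count $n_b$,
the strain fitness score is

$$ s_b = \log_2 \frac{n_b \cdot N_0/N + \psi}{n_{0b} + \psi} $$

where $N_0/N$ rescales the condition sample to the time-zero library size
and $\psi = 1$ is a pseudocount bounding the score for barcodes drifting to
zero counts. Because most insertions are phenotypically neutral, scores are
normalized to mean zero within each sample; the package asserts the
post-normalization mean to $10^{-12}$.

Gene fitness aggregates all observations of a gene — each barcode in each
replicate — by a weighted mean whose weights are the harmonic means of the
pseudocounted depths,

$$ w_i = \frac{2}{1/(n_{0i}+\psi) + 1/(n_i+\psi)}, \qquad
   f_g = \frac{\sum_i w_i s_i}{\sum_i w_i}. $$

A design note on the weighting: the aggregation is sometimes described as a
"weighted harmonic mean of scores", but a literal harmonic mean of signed
log-ratios is undefined whenever scores cross zero. We therefore read the
phrase as *harmonic-mean-depth weighting*: the score itself enters a
weighted arithmetic mean, and the harmonic mean acts on the two depths of
an observation, so an observation is only as informative as the shallower
of its two counts. This keeps the estimator defined everywhere and gives
deeply sequenced strains the dominant vote, which is the stated intent of
depth-proportional weighting.

Significance uses a variance-floor T-statistic $t_g = f_g / \sqrt{V_g}$
with

$$ V_g = \max(V_{\mathrm{count}}, V_{\mathrm{emp}}), \qquad
   V_{\mathrm{count}} = \frac{1}{\ln^2 2}
     \frac{\sum_i w_i^2\,(1/(n_{0i}+\psi) + 1/(n_i+\psi))}{(\sum_i w_i)^2},
$$
$$ V_{\mathrm{emp}} = \frac{\sum_i w_i (s_i - f_g)^2}{(\sum_i w_i)(m-1)}
   \quad (m \ge 2 \text{ observations, else } 0). $$

$V_{\mathrm{count}}$ is the delta-method variance of the weighted-mean log
ratio under Poisson counting noise — the floor below which no agreement
between barcodes can push the variance; $V_{\mathrm{emp}}$ measures the
realized consistency between barcodes and between biological replicates.
Taking the max makes $|t| > 3$ demand both adequate depth and internal
agreement. $|t| > 3$ is the conventional significance cutoff and is a
configurable threshold, not a hard-coded constant. Fitness scores are
deliberately *not* scaled by the number of generations, so they are
comparable across conditions grown for different times but are not
absolute growth rates.

Relative fitness between conditions $A$ and $B$ is
$f_A - f_B$ with $t_{rel} = (f_A - f_B)/\sqrt{V_A + V_B}$.

# Expression model

FPKM is computed exactly as
$\mathrm{FPKM}_{gs} = 10^9 \, c_{gs} / (L_s \, \ell_g)$ with $\ell_g$ the
transcript length and $L_s$ the library size; the package tests the
algebraic identity that FPKM converts back to counts.

The differential test is a one-way ANOVA F-test on $\log_2(\mathrm{FPKM}+1)$
across conditions with Benjamini–Hochberg adjustment. This is an explicit
stand-in: the original analysis used a transcript-assembly DE package, but
the downstream quadrant filter consumes only fold changes and an adjusted
p value, so a simple, well-calibrated test suffices; equivalence with any
particular DE package is not claimed. The $+1$ offset bounds the transform
at zero counts. Zero-variance genes get $p = 1$ by convention; genes with
zero within-group but nonzero between-group variance get $p = 0$.

Genes retained for clustering must have $q < 0.05$, a maximal
condition-mean FPKM $\ge 5$, and a maximal pairwise condition fold change
$\ge 2$. Clustering is agglomerative with distance $1 - r$ (Pearson
correlation between gene profiles) and average linkage, cut at a fixed
$k = 3$ — matching the three carbon sources, each of which induces one
expression program; cutting by height is possible via `stats::cutree` on
the same tree but is not the default. Genes are sorted lexicographically
before clustering so tied merges resolve reproducibly, and labels are
renumbered by decreasing cluster size.

# The quadrant filter

A gene is a candidate for the target condition (d-galUA) against reference
conditions (glycerol, d-glc) iff, for **every** reference:

* expression arm: $q < 0.05$, target FPKM $> 5$, and target FPKM
  $\ge 2 \times$ reference FPKM;
* fitness arm: relative fitness $< -1$ and relative $t < -3$.

The "$\ge 2$-fold decrease in mutant abundance" phrasing and the
"relative fitness $< -1$" cutoff are treated as the same rule on the log2
scale. Genes lacking fitness data (essential genes are absent from an
insertion library) are reported as not evaluable rather than silently
dropped. One known edge of the published seven-gene table: the GaaD homolog
RTO4_9774 is listed as a pathway gene although its printed relative fitness
(−0.8 against both references) misses the −1 cutoff — rounding or the
additional low-carbon conditions of the original screen may explain its
inclusion. The package applies the stated rule as-is and does not
special-case it; with the default thresholds RTO4_9774 passes the
expression arm but not the fitness arm.

# Synthetic data: what it emulates and what it does not

The generators define the study conditions for all calibration and
recovery tests:

* **Pool.** Genes tiled on one scaffold (1.5 kb genes, 0.5 kb gaps);
  `max(1, Poisson(3))` barcodes per gene; 20% of the pool intergenic so the
  zero-mean normalization has a genuine neutral anchor; time-zero
  abundances log-normal with $\sigma = 1$, emulating the strongly skewed
  strain abundances of a transformed library.
* **Selection.** A strain's abundance multiplies by $2^{g(1+f)}$ over
  $g = 6$ generations (the midpoint of the 5–7 generations of the actual
  competitions), so a rare strain's expected raw score is $\approx g f$ —
  consistent with observed score magnitudes of −4 to −5 for pathway genes.
  Sequencing is multinomial at $10^6$ reads per sample, three replicates.
* **RNA-seq.** Log-normal baselines, condition mean = baseline × induced
  fold, negative-binomial counts with a single global dispersion (0.05),
  three conditions × three replicates.
* **Amplicons.** Reads are 5′ flank + 20-nt barcode + 3′ flank with
  constant quality; the default flank sequences are synthetic, as the real
  amplicon architecture is a property of the library construction protocol
  and is configuration here, not a constant.

Not emulated: PCR chimeras and sequencing errors inside the barcode (the
counter matches barcodes exactly, so real data would need the upstream
error-tolerant collapse step of the library-characterization tooling),
chromosomal-position effects, replicate-specific library quality, gene
length–dependent RNA-seq biases, and condition-correlated dispersion.
Passing the recovery tests therefore shows the *statistics* behave as
designed under the stated generative model, not that the pipeline is
robust to every artifact of real sequencing data.

# Numerical choices

* Pseudocount $\psi = 1$ throughout the fitness math.
* Condition samples are rescaled to the time-zero library size before
  ratios; scores are then invariant to uniform depth changes up to
  pseudocount effects that vanish as counts grow.
* Michaelis–Menten fits use direct Levenberg–Marquardt nonlinear least
  squares on $v = V_{max} S/(K_m + S)$ (never a Lineweaver–Burk
  linearization, which biases estimates under additive noise), with the
  deterministic initializer $V_{max,0} = \max v$, $K_{m,0} = S$ at the
  observation nearest $V_{max,0}/2$, and box constraints
  $K_m, V_{max} > 0$.
* The NADPH molar absorptivity at 340 nm defaults to
  6.22 mM⁻¹ cm⁻¹; plate path length, reaction volume and protein mass are
  explicit inputs because well path depends on fill volume.
* Insertions are assigned to genes by containment in the full annotated
  span (strand-agnostic; a T-DNA insertion disrupts both strands);
  a central-fraction window is available (`central_fraction`) but off by
  default, since there is no stated rule for boundary insertions.
  Insertions inside overlapping genes count toward each gene rather than
  being discarded.

# Problem sizes and determinism

Calibration and recovery suites run at 500 genes, ~2,000 barcodes,
$10^6$ reads per sample and three replicates — small enough for quick
desk-scale iteration, large enough that the multinomial noise floor sits
well below the planted effects (a $f = -0.5$ gene at $g = 6$ shifts its
barcodes by −3 log2 units, ~25 times the per-observation count-noise sd at
mean coverage ~500). Every generator is a pure function of its seed;
identical seeds give bit-identical outputs and distinct seeds decorrelate
the draws.

# Known limitations

* The ANOVA stand-in has less power than dispersion-modeling DE tests at
  low counts; at the simulated depths this is immaterial, on real shallow
  data it would not be.
* Exact barcode matching undercounts samples with high sequencing error.
* The T-statistic's count-noise floor assumes Poisson (multinomial)
  counting; overdispersed amplicon PCR would make $|t|$ anticonservative,
  which the empirical-variance branch only partly absorbs with few
  barcodes.
* The quadrant filter inherits the published thresholds; they are
  conventions, not optimized quantities, and are exposed as configuration.
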