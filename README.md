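# recscreen

An R package implementing a gene-expression-reversal drug repositioning
screen and its downstream characterisation stages, exercised end to end on
synthetic data with planted effects.

## The problem

Tumors that overexpress replication-licensing factors (here the
minichromosome-maintenance genes **MCM2** and **MCM10**) have poor
prognosis, so compounds that recurrently *reverse* that overexpression
across many cancer cell lines are repositioning candidates. The screen
combines two orthogonal lines of evidence per compound:

1. **Recurrence (REC) scoring** of perturbation signatures. For compound
   *c*, gene *g*, timepoint *t* and z-scores *z* over cell lines *l*:

   REC = ( #{l : z ≥ 2} − #{l : z ≤ −2} ) / n_measured ∈ [−1, 1]

   with an exact permutation p-value (gene labels resampled within each
   cell line; the null enumerated in closed form by convolution) and
   Benjamini–Hochberg FDR across compounds per (gene, timepoint) slice.
2. **Basal expression vs drug sensitivity**: Pearson correlation of a
   gene's basal log2 expression with the compound's sensitivity AUC
   (lower AUC = more sensitive) across cell lines.

A compound is **nominated** iff REC < 0 with FDR ≤ 1e-3 and top-30
negative-REC membership for *both* target genes at *both* timepoints, and
r < 0 with p ≤ 0.05 for both genes. Downstream stages: preranked GSEA on a
compound's REC gene list, a Kaplan–Meier expression-cutoff scan with
Bonferroni correction, mitochondrial fusion/fission morphometry from
16-bit TIFF micrographs, and 4PL IC50 fitting.

No external data are downloaded; a synthetic-data module generates every
input format (tall signature TSV, expression/sensitivity matrices, survival
CSV, GMT, TIFF pairs, dose–response CSV) with known planted structure, so
every stage is tested against a recoverable truth. See
`vignettes/expression-reversal-screen.Rmd` for the methods.

## Worked example

The analysis is organised as numbered drivers under `analysis/`, each a
thin script over the package functions, writing tables under `results/`
(regenerated from scratch; nothing large is committed):

```sh
Rscript analysis/01_simulate_inputs.R   # all inputs, one seed
Rscript analysis/02_rec_scoring.R       # rec_scores.tsv
Rscript analysis/03_nominate.R          # candidates.tsv, nominated.txt
Rscript analysis/04_gsea.R              # gsea_results.tsv
Rscript analysis/05_survival_scan.R     # scan_MCM2.tsv, KM tables
Rscript analysis/06_mito_morphology.R   # mito_objects.tsv, comparison
Rscript analysis/07_dose_response.R     # ic50.tsv
```

Stage 02 on the default world (201 compounds, one planted dual-target
reversal compound "BI-2536") prints:

```
Most negative REC for MCM2 at 6h :
 compound  rec        p      fdr
  BI-2536 -1.0 4.62e-16 9.29e-14
  CPD0140 -0.2 2.66e-02 6.10e-01
  CPD0086 -0.2 2.99e-02 6.10e-01
```

The planted compound downregulates MCM2 beyond |z| ≥ 2 in all 10 cell
lines (REC = −1); the exact permutation tail is ~5e-16 and survives the
FDR ≤ 1e-3 filter, while the best null compound sits at REC = −0.2,
FDR 0.61. Stage 03 then intersects with the sensitivity arm:

```
Nominated compounds: BI-2536
 compound rec_MCM2_6h fdr_MCM2_6h rec_MCM10_24h fdr_MCM10_24h r_MCM2 p_MCM2 r_MCM10 p_MCM10
  BI-2536          -1    9.29e-14            -1      1.21e-12 -0.752  0.012  -0.819 0.00376
```

exactly the planted compound: negative correlation (high expression → low
AUC → sensitive) for both target genes. Stage 05, on a 498-patient cohort
with a planted hazard ratio of 4 above the median of MCM2:

```
<scan_result> MCM2: best cutoff 21.06 (241 high / 257 low), raw p = 7.21e-40,
              Bonferroni p = 3.24e-37 over 449 cutoffs
High-expression arm median survival 3.5 vs 13.8 months (low)
```

the scan recovers a near-median cutoff with high expression markedly worse
— the prognostic direction that motivates targeting these genes. Stage 07
recovers IC50 = 19.8 nM (4PL) from a table simulated at 20 nM with 5%
noise on the 0/1/3/10/30/100 nM gradient.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

re-runs the full screen from scratch at the given seed (simulation → REC
scoring with exact permutation p-values → correlation → nomination) and
writes the reported quantities as JSON. The underlying study's headline
numbers all depend on unpublished measurements or external databases, so
no numeric targets are defined and the JSON object is empty; the
package-level guarantees are instead property-based and live in
`tests/testthat/test-acceptance.R` (oracle equivalence, null calibration,
planted-signal recovery for every stage).
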