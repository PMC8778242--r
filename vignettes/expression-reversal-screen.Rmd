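---
title: "Methods: an expression-reversal drug nomination screen and its downstream assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an expression-reversal drug nomination screen and its downstream assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Tumors that overexpress replication-licensing factors such as MCM2 and MCM10
tend to have poor prognosis, which makes compounds that *reverse* that
overexpression attractive repositioning candidates. `recscreen` implements
such a screen end to end: perturbation signatures over a panel of cancer
cell lines are summarised per compound into a recurrence score for each
target gene, compounds whose recurrent downregulation survives a stringent
FDR filter are intersected with basal-expression/drug-sensitivity
correlations, and the surviving candidates are carried into downstream
characterisation stages -- preranked gene set enrichment, survival
stratification of tumor cohorts, mitochondrial morphometry, and
dose-response IC50 estimation.

Because the public resources this style of screen consumes (perturbation
signature compendia, sensitivity portals, tumor cohort browsers) cannot be
bundled, the package carries a first-class synthetic-data module that
emulates every input with planted effects. Every stage is therefore
testable offline, and every "green" below means *the machinery recovers a
known planted truth*, not that any particular biological claim is
reproduced.

# The REC score

For compound $c$, gene $g$, timepoint $t$, and differential-expression
z-scores $z_{cgl t}$ over cell lines $l$, the recurrence score is

$$\mathrm{REC} = \frac{\#\{l : z \ge \theta\} - \#\{l: z \le -\theta\}}{n_{\text{measured}}}, \qquad \theta = 2,$$

a bounded, signed statistic: $+1$ means the compound upregulates the gene
beyond $|z| \ge 2$ in every measured line, $-1$ means recurrent
downregulation everywhere, and it is antisymmetric under $z \to -z$. Only
*measured* cell lines enter the denominator; the tensor container
distinguishes absent cells from zeros precisely so that ragged coverage
(e.g. eight lines at one timepoint, ten at another) never biases the score.

## Permutation null and exact enumeration

The null resamples the gene label independently within each cell line of
the compound's signature, preserving each line's signature distribution.
The test statistic is $|\mathrm{REC}|$ (two-sided: the screen reads both
reversal and mimicry). Because the per-line draws are independent, the null
law of the indicator sum is the convolution of per-line three-point
distributions ($+1$ with the line's fraction of up-calls, $-1$ with its
fraction of down-calls). That convolution *is* the full enumeration of all
$n_{\text{genes}}^{\,n_{\text{lines}}}$ label assignments, computed in
$O(n_{\text{lines}}^2)$, and it is the default p-value.

The exact default matters quantitatively: a Monte-Carlo estimate with
$B = 999$ draws has add-one floor $p \ge 10^{-3}$, and after
Benjamini--Hochberg across $\sim 200$ compounds no compound could ever
reach the screen's FDR $\le 10^{-3}$ filter. Exact tail probabilities for a
strong reversal compound are of order $10^{-13}$, which survives the
correction comfortably. Monte-Carlo (with the add-one estimator, never
zero) is retained for calibration studies and as the spec'd interface.

## Discreteness and calibrated p-values

With ten cell lines the REC statistic takes eleven values, so its
permutation p-value is *sub*-uniform with large atoms (under a pure null,
$\mathrm{REC} = 0$ -- hence $p = 1$ -- for roughly 63% of compounds). A
Kolmogorov--Smirnov test of those raw p-values against the continuous
uniform rejects regardless of how well-calibrated the test is. The
well-posed uniformity statement for a discrete statistic uses the
tie-randomized p-value -- the observation's rank among the null draws with
ties broken uniformly at random -- which is exactly uniform on the
permutation grid under exchangeability. `rec_table(randomized_ties = TRUE)`
reports it as `p_rand` for diagnostics; all screening decisions use the
conservative `p`.

## Multiplicity family

BH-FDR is applied across compounds within each (gene, timepoint) slice:
the screening question is "which compounds recurrently move *this* gene",
asked once per slice. Ranks (`rank_neg`, 1 = most negative REC) are
likewise per slice, with ties broken by smaller p then compound id, and
"top $k$" membership is evaluated within the slice. Whether top-$k$ should
instead pool timepoints is not determined by the screen's description; the
per-slice choice is the stricter one under the conjunctive filter below.

# Nomination

A compound is nominated iff

* for **every** target gene and **every** timepoint: $\mathrm{REC} < 0$,
  $\mathrm{FDR} \le 10^{-3}$, and membership in the top 30 most negative
  REC scores; and
* for **every** target gene: Pearson $r < 0$ with $p \le 0.05$ between
  basal (log2) expression and sensitivity AUC across shared cell lines.

Sensitivity is stored as AUC with **lower = more sensitive** (the
convention of the major sensitivity portals), so "high expression goes with
sensitivity" is a *negative* r against AUC; the sign test is applied to
that r. Pearson is the default because the screen's description names no
statistic; Spearman is one keyword away. The filters combine by
conjunction, which makes nomination monotone: relaxing any threshold can
only add nominees (property-tested).

# The synthetic world

The generator's defaults are the screen's stated operating conditions; they
are fixed once and not tuned against test outcomes.

| parameter | default | rationale |
|---|---|---|
| cell lines | the 10-line panel (`LINCS_CELL_LINES`) | the panel the screen scores over |
| timepoints | 6h, 24h | the two perturbation durations scored |
| compounds | 201 (200 null + 1 planted) | "one true positive among a few hundred screened" |
| genes | 200 | large enough for stable per-line null fractions |
| background z | $\mathcal{N}(0, 1)$ | signatures are consumed downstream of any platform processing, so bead-level realism buys nothing |
| planted effect | $-4$ z units, all lines, both timepoints | a strong, unambiguous reversal |
| planted correlation | $0.9$ | strong expression/sensitivity coupling |
| survival baseline hazard | 0.05 / month | median null survival ~14 months, a plausible cohort scale |
| censoring | exponential, hazard = `censor_rate` x baseline | `censor_rate = 0` means none |
| tube width / PSF | 6 px / 1.2 px | tubes several PSF widths across, as in a well-sampled confocal field |

The expression/sensitivity correlation is planted through a shared latent
factor per cell line: with $a = \sqrt{|r|}$, target-gene expression is
$aF + \sqrt{1-a^2}\,\varepsilon_g$ and the planted compound's AUC is
$-(aF + \sqrt{1-a^2}\,\varepsilon_c)$ (then affinely mapped to log2- and
AUC-like units), giving pairwise correlation $-|r|$ against *every* target
gene simultaneously and an exactly degenerate $r = -1$ at $|r| = 1$.

What the generator does **not** emulate: platform batch structure,
compound-compound correlation, dose dependence of signatures,
heavy-tailed expression noise, segmentation confounders such as
out-of-focus haze (a three-class thresholding fallback exists for that),
or 3-D image stacks (fields are generated flat, as after a z-projection).
A green end-to-end test therefore establishes that the pipeline's
*inference machinery* is correct and calibrated on its stated model -- not
that the model captures everything real data would throw at it.

# Preranked GSEA

The ranked list is a compound's per-gene REC slice, descending, ties broken
stably by gene id. The enrichment score is the classic weighted
Kolmogorov--Smirnov running sum (weight 1 by default): hits increment by
$|s|^w$ normalised over hits, misses decrement by $1/(N - N_h)$, and ES is
the signed maximum deviation. The implementation evaluates the running sum
only at hit-adjacent positions ($O(|S|\log|S|)$ after sorting); it is
tested to $10^{-12}$ against a full $O(N)$ walk.

The null permutes gene labels, i.e. draws random hit positions of the same
size -- for a *preranked* list there are no sample labels to permute, so a
"sample-level" null is not definable here; the gene-label null is the
standard preranked substitute and is shared across sets of equal size for
speed. NES divides ES by the mean magnitude of sign-matched null ES; p is
the sign-matched add-one tail; the FDR q is the usual pooled-NES ratio
(fraction of null NES at least as extreme over fraction of observed NES at
least as extreme), clipped to $[0,1]$. Sets are filtered to intersection
sizes in $[10, 500]$; 1000 permutations and the $q < 0.25$ reading
threshold are the operating defaults.

# Survival cutoff scan

Kaplan--Meier estimation delegates to the `survival` package; the log-rank
statistic is implemented in-package (observed minus expected over the
hypergeometric variance), cross-checked against `survival::survdiff`, and
vectorised so the scan can afford one test per admissible cutoff. A cutoff
is admissible when both arms keep at least `min_group` patients, with
default $\max(8, \lceil 0.05 n \rceil)$ -- a floor that prevents the
near-degenerate splits where the log-rank approximation is worst. Ties at
the cutoff go to the low arm (high means strictly greater), a deterministic
documented choice. The reported p is the *minimum* raw p over cutoffs --
deliberately anti-conservative -- times the number of cutoffs actually
tested (Bonferroni), capped at 1. Since the multiplier counts tested
cutoffs, the scan is invariant to monotone transforms of expression, and
the Bonferroni bound restores Type-I control (null calibration is
property-tested; the cost is conservatism, since neighbouring cutoffs are
highly correlated). Stage-wise expression summaries (group means, one-way
ANOVA) are provided as a descriptive helper only.

# Mitochondrial morphometry

The analysis mirrors a standard confocal recipe: Gaussian blur (sigma 1.2
px), automatic threshold, object detection with a 3-pixel minimum size,
per-object area/perimeter/shape. Thresholding is 1-D k-means with k = 2 and
deterministic initialisation at the intensity extremes, taking the brighter
cluster; it is scale-invariant by construction and errors on constant
images. A k = 3 variant with the two brightest clusters merged is available
for images with a diffuse haze class. An optional polygon ROI restricts
analysis to one cell. The "3-pixel detection parameter" of the original
acquisition software is interpreted as the minimum object size in pixels.

Perimeter estimation is the one genuinely open numerical choice. The
4-direction Crofton estimator is excellent on discs but carries a known
anisotropy bias of about $-6\%$ on axis-aligned boundaries, which breaks a
5%-accuracy expectation on rectangles; the boundary-configuration weighted
estimator (weights 1 for isothetic steps, $\sqrt2$ for diagonal steps,
$(1+\sqrt2)/2$ for corner pixels) is exact on large axis-aligned rectangles
and within ~5% on discs (circularity 0.95). The weighted estimator is
therefore the default and Crofton the option; both are exposed and
cross-checked in tests. Per-object circularity $4\pi A/P^2$ may slightly
exceed 1 on tiny objects through discretisation. Condition comparison is a
two-sided **Welch** t-test per metric (pooled-variance Student optional):
with object counts and variances differing between fission and fusion
states, the unequal-variance default is the defensible one. Statistics are
per-object; per-image aggregation is a one-liner on the object table. Note
that a single field pair yields few objects -- the demo prints the
direction but is underpowered; the test suite pools three fields per
condition, the scale at which such experiments are actually quantified.

# Dose-response IC50

The four-parameter logistic
$v(d) = b + (t - b) / (1 + (d/\mathrm{IC}_{50})^h)$ is fitted by least
squares on log-dose with top and bottom free. The dose-0 control is
excluded from the fit (log 0 is undefined) and serves only as the 100%
anchor. The optimiser is deterministic: three fixed starts (IC50 at the
lower quartile, median, and upper quartile of log-doses), BFGS then a
Nelder--Mead polish, best residual wins; an increasing fit is re-expressed
in decreasing form by swapping asymptotes. Estimates outside
[min positive dose / 10, max dose x 10] are flagged extrapolated. The
fallback is log-linear interpolation of mean viability between the doses
bracketing 50%. Noiseless round-trips recover IC50 to $10^{-6}$; at 5%
viability noise on the 0/1/3/10/30/100 nM gradient the median absolute
log2 error stays below 0.3 (both property-tested).

# Reproducibility machinery

All randomness flows from one master seed through named substreams
(`derive_seed`), so re-running any stage with the same configuration is
byte-identical and adding a stage never perturbs another's draws. Every
output table carries a header comment with a 32-bit FNV-1a hash of the full
configuration. File formats are deliberately plain: tall TSV for
signatures (absent cells simply omitted -- never written as zeros), GMT for
gene sets, CSV for cohorts and viability, and a minimal uncompressed 16-bit
grayscale TIFF reader/writer (no R TIFF package is assumed; the dialect
covers what confocal exports and the generator produce, not compressed or
tiled files).

# Degenerate inputs, in one place

* tensor slices with fewer than two measured lines, single-gene tensors,
  and duplicate signature keys: errors naming the offender;
* zero control MAD in `robust_z`: gene flagged absent with a warning;
* constant images, empty masks, all-censored cohorts, no admissible
  cutoff, flat viability, sets outside the size window: each handled per
  its contract (error, empty result, warning, or logged skip -- see the
  function documentation).

# Known limitations

* The REC formula and its permutation null are this package's own
  concretization of a recurrence-scoring idea whose published ancestor is
  not restated here; results should be read under this definition.
* Bonferroni over scanned cutoffs is conservative; a permutation-based
  minimum-p null would be sharper but far costlier.
* The GSEA FDR q is the standard heuristic estimator, not a proven FDR
  bound, and small collections make it noisy.
* Morphometry has no network/skeleton topology metrics and no 3-D
  reconstruction; touching tubes merge into single objects, which is
  visible in the fused condition's object counts.
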