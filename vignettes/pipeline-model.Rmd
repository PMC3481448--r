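---
title: "The pipesim pipeline model: assumptions, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The pipesim pipeline model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

pipesim simulates a label-free LC-MS proteomics experiment end to end, from
ground-truth protein concentrations to the numbers a biomarker study actually
reports: how many peptides and proteins were observed, how accurately proteins
were quantified, how many true markers the differential test recovered, and
how well classifiers trained on the observed data perform relative to
classifiers trained on the uncorrupted ground truth. Because the truth is
known by construction, every loss along the pipeline is measurable. This
vignette records the model itself, the assumptions behind it, and the design
decisions we made where the model left choices open.

```{r, eval = FALSE}
library(pipesim)
cfg <- sim_config(M = 50, n_markers = 20, n_background = 100)
res <- run_once(cfg, seed = 1)
glance(res)
```

## The protein mixture

Two sample classes (say control and treatment) share a panel of
`n_markers + n_background` protein species. Control mean concentrations are
i.i.d. Gamma with shape `t = 2` and scale `theta = 1000`, spanning roughly
four orders of magnitude, which is typical of in-solution protein abundance.
Each marker receives a fold change: a magnitude `a ~ Unif(1.5, 2)` applied
upward or downward with a fair coin; non-markers keep fold 1.

Sample-to-sample variation is multivariate Gaussian around the class means.
The covariance is block-diagonal: proteins are grouped into blocks of size
`D = 2` (a minimal stand-in for co-regulated pathway members) with
correlation `rho = 0.6` inside a block and independence across blocks. The
per-protein standard deviation is `phi * eta`, i.e. a constant coefficient
of variation; the model names a per-protein CV but gives it no value, so we
use a single scalar `phi = 0.1` for all proteins (configurable). One scalar
keeps the CV from becoming a second confounder in the sweeps.

Three further choices were open:

* **Negative draws.** The Gaussian tail can produce negative concentrations;
  we clamp them at zero. At `phi = 0.1` the event is a 10-sigma excursion,
  so clamping touches well under 1% of entries (asserted in the tests).
* **Marker placement.** Markers occupy the first slot of each of the first
  `n_markers` correlation blocks, so each marker is co-blocked with
  background proteins rather than with another marker. This is the more
  interesting case for the classifier, which can then exploit
  marker-background correlation. Marker identities are carried explicitly,
  so no downstream code depends on row positions.
* **Sampling.** `draw_samples()` never forms the dense covariance; it draws
  block by block through the block Cholesky factor, which is exact for this
  structure and lets the null-calibration study use 10^4 proteins. The dense
  constructor `build_covariance()` exists for inspection, and the test suite
  checks that the empirical covariance of the factored sampler converges to
  the dense matrix.

## From proteins to peptide signals

Proteins are digested in silico by the trypsin rule (cleave C-terminal to K
or R, not before P). The model does not fix digestion settings; we default
to 0 missed cleavages and peptide length 6-40 residues, typical tryptic
search settings. Identical peptide sequences from different proteins are
merged into one species whose parent set is the union — the membership map
that later defines "unique" peptides.

Each peptide species gets:

* a **monoisotopic mass** (sum of residue masses plus water);
* a **retention time**: our stand-in maps the mean Kyte-Doolittle hydropathy
  of the sequence through a logistic onto the scan axis (`n_scans = 1000`).
  Only relative RT proximity enters the model (through signal overlap), so
  any deterministic monotone predictor preserves the behaviour being
  studied;
* an **efficiency** `e ~ Unif(0.1, 1)`, fixed per species across samples. In
  reality LC transmission and ionization efficiency depend on the whole
  analyte mixture and are not predictable peptide by peptide, which is
  exactly why the model treats efficiency as a dispersed random factor and
  sweeps its lower bound.

The peptide concentration in a sample is the sum over its parent proteins.
Expected ion abundance is `mu = min(c * e * kappa, sat)`: `kappa` is the
instrument response factor (calibration-curve slope) and `sat` the detector
ceiling, so the linear dynamic range of a peptide ends at `sat / (e kappa)`.
Observed abundance adds Gaussian noise with variance `alpha mu^2 + beta mu`
(`alpha = 0.03`, `beta = 3.6`, values estimated from replicate serum runs in
the literature the model builds on), clamped at zero. Saturation is applied
to the expected abundance before noise, per the calibration-curve reading.

## Detection, identification, linking

**MS1 detection.** The signal-to-noise ratio follows from the noise law:
`SNR = E[v]^2 / Var(v) = mu / (alpha mu + beta)`, which rises with signal
strength and plateaus at `1/alpha`. The probability that a detection
algorithm reports a truly present feature is a polynomial in SNR,
`TPR = k SNR^p + b` (defaults `k = 0.0016`, `p = 2`, `b = 0`), clamped to
\[0, 1\]. Algorithms differ in their handling of convoluted signals: an
overlap-aware algorithm keeps the base TPR, an overlap-sensitive one has its
TPR divided by the number of peptides sharing a mass/RT neighbourhood
(masses closer than `1/mass_resolution` relative — we use the smaller mass
as denominator for symmetry — and RTs closer than 0.5% of the run). The
overlap count includes the peptide itself, so an isolated peptide is
unpenalized. Overlap is computed once per catalog since masses and RTs are
sample-independent here.

**MS2 identification.** Whether a detected species is also identified by
database search is a Bernoulli trial with a species-level success rate
(identifiability), re-drawn independently per sample, which is the standard
picture of MS2 under-sampling. Trained sequence-based identifiability
predictors exist but require external model weights; our stand-in draws the
identifiability once per species from Beta(2, 8) — mean 0.2, heterogeneous
across species, near reported average identification rates — with a
deterministic logistic(length, hydropathy) alternative and a constant
("fixed") model for idealized settings. With `r` replicate MS2 assays the
per-sample success rate becomes `1 - (1 - p)^r`.

**Linking.** A feature counts as observed only when reported by both MS1
detection and MS2 identification. Both algorithms have their own false
positives; requiring agreement of the two orthogonal evidence streams is how
the modeled workflow suppresses them, and it is the strictest reading of
which cells count as missing downstream.

## Roll-up and evaluation

Protein estimates are built from observed peptides through three filters:
(1) only peptides unique to one protein; (2) missing-value rate at most 0.7;
(3) Pearson correlation above 0.6 with at least one sibling peptide of the
same protein, over samples where both are observed. "At least one sibling"
(the max, not the mean) keeps a good peptide from being dragged down by one
bad sibling; correlations are computed pairwise-complete with a minimum of
three common samples, since a two-point correlation is always ±1. A protein
with fewer than two surviving peptides is not quantified (all-zero row);
otherwise its abundance per sample is the mean of the survivors observed in
that sample (zero when none is), and concentration is abundance over
`kappa`.

One behaviour of the correlation filter is worth knowing about. Sibling
peptides of the same protein correlate because they share the parent's
biological variation; at `phi = 0.1` that shared variance is modest relative
to the measurement noise (`alpha = 0.03` alone contributes a CV of about
0.17), so a non-differential protein's sibling correlation sits *below* the
0.6 threshold in expectation and such proteins are quantified mainly when
the finite-sample correlation estimate fluctuates upward. Markers are
different: their fold change adds between-class variance shared by all
siblings, lifting the correlation above the threshold. Two consequences
show up in the sweeps: differential proteins are quantified at a higher rate
than background proteins, and the overall quantification rate *decreases*
with sample size (more samples concentrate the correlation estimate around
its sub-threshold expectation). Raising `phi` or lowering `min_corr` moves
this regime.

Quantification error is the mean over all proteins and samples of
`|c - c_hat| / c`, including unquantified proteins (each contributing 1 per
entry — excluding them would reward dropping proteins). Entries with a true
concentration of exactly zero (possible only through clamping) are excluded
with a warning.

Differential expression uses the equal-sample-size, equal-variance
two-sample t statistic per protein at the raw 0.05 level, with no multiple
testing correction — the model's reported "percentage of detected markers"
is defined at the raw level, and correction would change the measurand.
Classification selects the 20 largest-|t| features on training data (ties to
the smaller index), then trains 3-nearest-neighbour (Euclidean, majority
vote, distance ties to the smaller training index) and LDA (pooled
covariance, equal priors, ridge 1e-6 so constant features cannot break the
solve) classifiers. Errors are measured on an independent test set of 1000
samples per class drawn from the same abundance model and pushed through the
*same pipeline realization* — same efficiencies, identifiabilities and
survivor sets, fresh noise and detection draws — because train and test
feature spaces must match. The same classifiers trained on the uncorrupted
concentrations give the benchmark error, and the gap between the two is the
price of the pipeline. When a configuration is harsh enough that nothing is
quantified, there is no feature space and the classification error is
reported at chance (0.5).

A useful closed form falls out of the identification model: if a protein has
`n` peptides each identified independently with probability `q`, the
probability it can be quantified (at least two peptides identified) is at
most `1 - (1-q)^n - n q (1-q)^(n-1)`; at `q = 0.17`, `n = 20` this is 0.88.
The roll-up filters only lower it, hence an upper bound.

## Reproducibility and numerics

Every stochastic stage draws under its own seed derived from the run seed
(`stage_seed()`), so a run is bit-reproducible and stages stay decoupled:
adding draws in one stage cannot shift another stage's stream. A committed
golden snapshot of a toy run guards against silent numeric drift.

Sizes used by the shipped test suite are chosen to make Monte-Carlo
assertions sharp at desk scale: moment checks use 10^5 draws, correlation
recovery 5x10^3 samples, null calibration 10^4 proteins at M = 50, and the
trend studies run 10 replicates per grid point on a 120-protein panel (20
markers + 100 background) subsampled from a 480-protein synthetic proteome,
with coarse 3-5 point grids. Trends are asserted as orderings and interior
extrema, not as figure values: the quantitative figure-level numbers depend
on the specific proteome and on a trained identifiability predictor, neither
of which is shipped.

## What the synthetic proteome does and does not emulate

The generator draws residue sequences i.i.d. at Swiss-Prot background
frequencies with lengths from a truncated normal (mean 450, sd 150, minimum
50), matching real proteomes in tryptic peptide count per protein (around
15-20 after length filtering) and in amino-acid composition, hence in mass
and hydropathy distributions. It does not emulate homology: real proteomes
contain families with long shared subsequences, so shared (non-unique)
peptides are rarer here than in a real database. Passing tests therefore
validate the pipeline mechanics and parameter effects, not the absolute
uniqueness rate of any particular organism. Feeding a real FASTA through
`read_fasta()` recovers that realism where it matters.

## Known limitations

* No post-translational modifications, charge-state distributions, isotope
  envelopes or raw spectra; the model deliberately stays above the physics
  of the instrument.
* Two classes only; efficiencies and identifiabilities are
  sample-independent; no decoy/FDR machinery (false positives enter only
  through the AND-linking suppression).
* Plain averaging roll-up; median-polish or pairwise-ratio schemes are out
  of scope.
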