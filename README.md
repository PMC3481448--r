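# pipesim

Ground-truthed simulation of the label-free LC-MS proteomics pipeline.

Biomarker discovery by mass spectrometry fails in ways that are hard to
diagnose on real data: every stage — digestion, ionization, detection,
identification, roll-up — loses or distorts signal, the losses compound, and
with real samples there is no ground truth to measure them against. pipesim
treats the whole workflow as a noisy channel and simulates it end to end
with known truth, so that the effect of any single parameter (peptide
efficiency, instrument response, saturation ceiling, noise level, detection
algorithm, mass resolution, sample size, MS2 replication) on the *end
results* — quantification error, recovered markers, classification error —
can be isolated and measured. It is aimed at people designing proteomics
experiments or detection/quantification algorithms who want to know where
the bottleneck in their pipeline actually is.

## The model in brief

* **Protein truth.** Two classes, M samples each. Control means
  η<sub>l</sub> ~ Gamma(t = 2, θ = 1000); markers get fold changes
  f<sub>l</sub> = a or 1/a with a ~ Unif(1.5, 2); samples are multivariate
  Gaussian with block-diagonal covariance (blocks of D = 2 at correlation
  ρ = 0.6, per-protein sd = φη<sub>l</sub>).
* **Peptide signal.** Tryptic digestion; peptide concentration
  c<sup>pep</sup><sub>ij</sub> = Σ<sub>k∈Ω<sub>i</sub></sub>
  c<sup>pro</sup><sub>kj</sub> over parent proteins; expected abundance
  μ<sub>ij</sub> = min(c<sup>pep</sup><sub>ij</sub> e<sub>i</sub> κ, sat)
  with e<sub>i</sub> ~ Unif(0.1, 1), response κ = 5; observed abundance
  v = max(0, μ + ε), ε ~ N(0, αμ² + βμ), α = 0.03, β = 3.6.
* **Detection and identification.** SNR = μ/(αμ + β);
  MS1 TPR = (k·SNR<sup>p</sup> + b)·o with k = 0.0016, p = 2, b = 0 and an
  overlap factor o = 1 (overlap-aware algorithms) or 1/(number of peptides
  within 1/resolution in mass and 0.5% of the run in RT); MS2
  identification is Bernoulli per sample with species identifiability
  p<sub>i</sub> (r replicates give rate 1 − (1 − p<sub>i</sub>)<sup>r</sup>);
  a feature is observed only if reported by both.
* **Roll-up and evaluation.** Unique peptides, missing rate ≤ 0.7,
  sibling correlation > 0.6; proteins with ≥ 2 survivors are averaged and
  divided by κ. Outputs: mean relative quantification error, missing-value
  rates, % markers significant at 0.05, and KNN(3)/LDA test error on
  observed vs. original data.

## A worked example

```r
library(pipesim)

cfg <- sim_config(M = 50, n_markers = 20, n_background = 100)
res <- run_once(cfg, seed = 1)
res
#> <run_result> seed 1
#>      peptide_id_rate   protein_quant_rate peptide_missing_rate
#>               0.9937               0.6500               0.7989
#> protein_missing_rate                 qerr pct_markers_detected
#>               0.4768               0.7156              90.0000
#>     err_knn_observed     err_lda_observed     err_knn_original
#>               0.0285               0.0070               0.0000
#>     err_lda_original
#>               0.0000
```

Reading: with the default instrument settings, 80% of (peptide, sample)
cells are missing after linking MS1 and MS2 evidence, yet 65% of proteins
still clear the two-surviving-peptides bar; the mean relative quantification
error is 0.72; 90% of the true markers are recovered at the 0.05 level; and
the pipeline costs real classification accuracy — LDA error 0.007 on the
observed data versus 0.000 on the uncorrupted concentrations. (Absolute
levels depend on the proteome and the identifiability model; the package
ships a synthetic proteome generator, and `read_fasta()` accepts any real
FASTA.)

Parameter sweeps and plots:

```r
sw <- run_sweep(cfg, "kappa", c(0.1, 1, 10, 100, 1e4), n_runs = 10,
                seed_base = 100)
tidy(sw)        # per-value median/mean/sd of every index
autoplot(sw, indices = c("qerr", "protein_missing_rate"), log_x = TRUE)
```

A thin command-line wrapper with `run`, `sweep` and `report` subcommands is
installed at `inst/scripts/pipesim.R`.

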