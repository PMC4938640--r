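---
title: "Models and methods behind degronscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind degronscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(degronscreen)
library(dplyr)
```

degronscreen analyzes screens in which short peptides (degrons) are fused
to the C-terminus of a Ura3-HA reporter in budding yeast. A degron that
routes the reporter into the ubiquitin–proteasome system lowers its
steady-state level, which shows up as poor growth on medium lacking
uracil; deleting the responsible E3 ligase restores growth. The package
covers the four quantitative stages of such a screen — peptide sequence
features, plate-based growth analysis, cycloheximide-chase decay kinetics,
and per-degron E3-dependence calls — plus a synthetic-screen generator
with known ground truth that makes every stage testable end to end.

## Sequence features

Each library member is a peptide translated from a random genomic fragment
in the reporter's reading frame, continuing into the vector until the
first stop codon (`translate_fusion()`; the vector tail carries stops in
all three frames, so termination is guaranteed). Two features are
computed per peptide:

* **GRAVY** (grand average of hydropathy): the arithmetic mean of
  Kyte–Doolittle hydropathy values over the residues, dimensionless,
  bounded in [−4.5, 4.5]. The scale is injectable; the default reproduces
  the published values for the bundled 14-peptide tester set to three
  decimals.
* **Maximal hydrophobic run**: the longest contiguous stretch of residues
  from a configurable hydrophobic set. The default set
  {A, C, F, I, L, M, V, W} is the positive-hydropathy residues minus
  glycine; the literature motivates the feature (exposure of at least five
  contiguous hydrophobic residues is a reported recognition rule for the
  nuclear quality-control ligase San1) but does not pin down the set, so
  it is an argument, not a constant.

Nonstandard residues (B, J, O, U, X, Z) are rejected with a position-naming
error rather than imputed: the library construction can only produce
standard residues, so anything else is a data defect.

```{r features}
tester_set() |> select(id, length, gravy, max_hydrophobic_run) |> head(5)
```

## The synthetic screen

`sim_params()` collects every generator knob with defaults chosen once to
mirror the screen the analysis was designed for:

* **Library**: fragments of 50–400 bp drawn uniformly from a random
  100 kb genome (fragment placement is uniform, so only the alphabet
  statistics of the genome matter, not its full 12 Mb scale), inserted in
  random orientation and translated in the fusion frame; empty peptides
  (immediate stop) are discarded.
* **Kinetics**: wild-type decay constants follow
  $\log\lambda_i = a + b\,\mathrm{gravy}_i + c\,\mathbf{1}[\mathrm{run}_i \ge 5] + \varepsilon_i$,
  $\varepsilon_i \sim N(0, \sigma_\lambda)$, with defaults
  $a = \log 0.25$, $b = 0.25$, $c = 0.4$, $\sigma_\lambda = 0.4$
  (min⁻¹ units). These center half-lives in the 1–10 min range with a
  hydrophobicity trend, matching the observation that most isolated
  degrons confer half-lives under a few minutes.
* **Strain panel**: each degron is dependent on a mutant's E3 with
  probability $\pi_m$ and, when dependent, its rate is divided by the
  stabilization factor $f_m$. Defaults — doa10 ($\pi = 0.5$, $f = 8$),
  ltn1 (0.3, 4), san1 (0.05, 2), ubr1 (0.05, 1.5) — reflect the reported
  pattern: Doa10 acts on about half the library and nearly fully
  stabilizes its substrates, Ltn1 on fewer and more weakly, San1/Ubr1 on
  very few and modestly.
* **Plates**: steady-state reporter level follows synthesis/turnover
  balance $S = 1/(\lambda + \mu)$ with dilution $\mu = 0.006$ min⁻¹
  (≈2 h doubling). Colony area is
  $\mathrm{baseline} + (A_{max} - \mathrm{baseline})\,S/(S+K)$ times a
  per-plate lognormal effect (sdlog 0.05) and per-well lognormal noise
  (sdlog 0.1). The saturating form is a modeling assumption — the
  quantitative mapping from Ura3 level to colony size is not known — but
  it has the two properties the analysis needs: a strong degron converges
  to the no-Ura3 baseline, and stabilization restores growth. The
  per-plate effect is what justifies within-plate normalization.
  Quadruplicate pinning is the default; each pinned copy is one physical
  plate with its own controls.
* **Chase/blots**: substrate signal $I_0 e^{-\lambda t}$ and a constant
  loading channel, both with multiplicative lognormal noise.
  `blot_sigma` (default 0.1) parameterizes the noise of the *derived*
  percent-remaining point: that observation combines four independent
  log-noise terms (two channels at $t$ and at 0), so each channel draws
  with sdlog `blot_sigma/2`. Default timepoints 0, 2, 4, 8, 15, 30 min
  span half-lives from under 2 min to ~30 min; fast degrons need the
  early points. All stages are deterministic under a fixed seed, with
  per-stage child seeds derived from one master seed.

What the generator does **not** emulate: colony morphology and image
segmentation artifacts, position effects within a plate beyond a single
multiplicative factor, mRNA-level or ribosome-stalling effects, and
saturation/nonlinearity of blot densitometry. Passing tests on synthetic
screens therefore demonstrate that the statistics recover the generative
model they assume, not that real plates meet those assumptions.

## Plate growth analysis

Areas are normalized within each physical plate by anchoring to the two
control roles,
$(\mathrm{area} - \overline{\mathrm{noUra}}) / (\overline{\mathrm{Ura3HA}} - \overline{\mathrm{noUra}})$,
clipped below at zero (a zero colony is a real Ura⁻ phenotype, kept as 0,
not missing). Min–max anchoring was chosen because both control roles are
present on every plate by design; it removes any plate-wide multiplicative
effect exactly. Corner wells are excluded from analysis. A plate whose
reference mean does not exceed its floor mean is rejected as degenerate.

For each degron, the mutant effect is the log2 ratio of mean normalized
sizes, tested with a Mann-Whitney test (exact when the smaller arm has
≤ 8 observations and no ties, tie-corrected normal approximation
otherwise). Two-sided is the default; a one-sided option exists because
stabilization is directional. P-values are adjusted across degrons within
a mutant (Benjamini–Hochberg by default, `"none"` reproduces per-test
masking).

**Discreteness matters at quadruplicate scale.** With 4 vs 4 observations
the exact two-sided Mann-Whitney p can never go below 2/70 ≈ 0.0286.
Two practical consequences, both visible in the package's tests:

* Type-I calibration of the growth test is checked at 10 replicates per
  arm, where the null distribution is nearly continuous and the nominal
  0.05 level is attainable; at n = 4 the test is simply conservative.
* Adjusting across ~200 degrons when every true positive sits exactly at
  the 2/70 floor can push *all* adjusted p-values above 0.05, no matter
  how large the effect. End-to-end dependence recovery on quadruplicate
  screens therefore uses per-test masking (`correction = "none"`), which
  is also how the original heatmaps appear to have been thresholded.
  With more replicates, BH behaves normally and is the better default.

## Decay kinetics

Percent remaining is
$P(t) = 100\,\frac{\mathrm{sub}(t)/\mathrm{load}(t)}{\mathrm{sub}(0)/\mathrm{load}(0)}$,
so $P(0) = 100$ exactly and rescaling both channels cancels. The model
$P = 100\,e^{-\lambda t}$ is fitted by unweighted nonlinear least squares
over $\lambda \ge 0$ with the amplitude fixed at 100 — the model as
stated; a free amplitude is available behind `free_amplitude = TRUE`.
The solver starts from a log-linear regression of $\ln(P/100)$ on $t$
(through the origin, over points with $P > 0$), refines with `nls`
(`port`, lower bound 0), and falls back to a bounded one-dimensional
search if `nls` fails; there are no random restarts, so fits are
deterministic. Points with $P > 100$ are retained as noise, not clipped.
On noiseless exponential data the fit is exact to machine precision. The
headline estimate pools all replicate points; per-replicate fits supply
the SD of the half-life, matching the mean-and-SD presentation of
triplicate chases. $\lambda \le 0$ maps to the stable sentinel
(`t_half = Inf`), reported as "longer than the chase window", never as an
extrapolated number.

Curves are compared with the extra-sum-of-squares F-test (shared-λ
reduced model vs separate-λ full model, $F$ with $(1, n_A + n_B - 2)$
degrees of freedom). Multiple-comparison adjustment defaults to Holm's
step-down procedure (the specific method behind published "adjusted"
p-values is not always recoverable, so the method is injectable:
Holm, Bonferroni, BH, none).

```{r chase, fig.width = 5, fig.height = 3.5}
params <- sim_params(timepoints = c(0, 1, 2, 4, 8), blot_sigma = 0.1)
chase <- simulate_chase(0.43, params, seed = 7, degron_id = "CL1")
fit <- fit_decay(percent_remaining(chase))
fit
autoplot(fit)
```

**A known limitation of the F-test on self-normalized chases.** Because
every point of a replicate is divided by that replicate's own noisy 0-min
ratio, all its points share the $t=0$ noise term. Under multiplicative
noise this within-series correlation makes the F-test anticonservative:
in simulations at the default noise, the null rejection rate at
$\alpha = 0.05$ is roughly 0.2 rather than 0.05 (the implementation
itself is exactly calibrated when errors are independent and
homoscedastic, which the unit tests verify). The same caveat applies to
any analysis that F-tests percent-remaining curves, including the
published procedure this package implements; treat chase F-test p-values
as a ranking, not as calibrated error rates, or increase the number of
independent replicates.

## Dependence calls and reporting

A degron is called **dependent** on an E3 when the growth rescue in the
corresponding deletion mutant is significant and positive
(`adjusted_p < alpha` and `relative_growth > 0`), **independent**
otherwise, and **indeterminate** when normalization was degenerate.
Growth is the calling readout — it is the screen's primary measurement —
with the chase-derived half-life ratio (mutant/WT) carried as
confirmatory annotation. `detection_threshold()` reports the smallest
half-life fold change among growth-detected degrons, i.e. the empirical
sensitivity limit of the growth assay; it is computed from the data,
never hard-coded. `library_report()` assembles one row per degron
(features, per-mutant relative growth, half-lives, labels) with a
per-mutant dependent-fraction summary.

```{r screen}
p <- sim_params(n_fragments = 80L,
                strains = tibble::tibble(strain = "doa10", pi = 0.5, f = 8))
scr <- simulate_screen(p, seed = 11)
res <- analyze_screen(scr$plates, correction = "none")
attr(library_report(scr$degrons, growth = res$growth, calls = res$calls),
     "summary")
```

## Numerical and testing choices

* Problem sizes in the test suite — 200 simulated chase fits per recovery
  setting, a ~1000-degron null screen for calibration, a 200-degron
  screen for end-to-end recovery — were chosen as the smallest sizes at
  which the binomial/Monte-Carlo tolerances being asserted are
  meaningful.
* Mann-Whitney, Holm, F-distribution and translation results are checked
  against brute-force oracles (full rank-split enumeration, the
  step-down definition, numerical integration of the F density, an
  independently written codon table) rather than against the library
  calls that implement them.
* Fragment coordinates in provenance are 0-based half-open with a strand
  flag. Ties in rank tests use mid-ranks. Seeds below 2³¹ everywhere.

## Limitations

Beyond the F-test caveat above: the colony-size model is qualitative
(any monotone saturating map would do); dependence calls inherit the
granularity of the exact test at low replication; half-lives longer than
the chase window are censored, not estimated; and the package does not
model secondary structure, aggregation propensity, or degron
transferability to other reporters.
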