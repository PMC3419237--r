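---
title: "Models and methods behind rnrkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind rnrkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnrkit)
```

## The scientific setting

Class Ia ribonucleotide reductase (RNR) supplies every vertebrate cell with
deoxyribonucleotides. Its small subunits (R2 and p53R2) carry a di-iron
centre that reacts with molecular oxygen to generate a stable tyrosyl
radical — the species that ultimately drives catalysis. Because radical
generation needs O~2~, RNR is a natural focus when asking how an
anoxia-tolerant vertebrate such as the crucian carp can keep dividing cells
without oxygen. The experimental programme around that question combines
four quantitative strands, and `rnrkit` implements the computational core
of each:

1. **EPR spectroscopy** of the tyrosyl radical and of the one-electron
   reduced, mixed-valent Fe(II)Fe(III) di-iron centre: powder spectra at
   X-band (~9.67 GHz) and high field (285 GHz), g-tensor and hyperfine
   analysis, spin quantification against a Cu(II)-EDTA standard.
2. **Radical-stability kinetics**: first-order decay of the EPR signal over
   hours of anoxic incubation.
3. **qPCR expression profiling** of RNR subunits and cell-division markers
   across six oxygen regimes, normalised to an exogenous mRNA standard
   (mw2060) with per-primer amplification efficiencies, followed by
   one-way ANOVA with Dunnett's many-to-one post-test.
4. **Protein-sequence analysis**: translation, pairwise identity,
   distance-based neighbor-joining trees with bootstrap supports, and
   KEN-box motif scanning.

A seeded synthetic-data module generates inputs with the statistical
structure each stage assumes, so the full pipeline runs and is tested with
no external data.

## Powder EPR simulation

`powder_spectrum()` models an S = 1/2 spin system with an anisotropic
g-tensor, optional nuclear hyperfine couplings and an orientation-dependent
Gaussian linewidth. The design choices:

* **Resonance condition.** For a molecular orientation with unit vector
  $n$ in the g principal frame, $g(n) = \sqrt{\sum_k g_k^2 n_k^2}$ and the
  Zeeman resonance field is $B_0(n) = h\nu / (g(n)\,\mu_B)$ (CODATA
  constants; internal unit mT, all user-facing couplings and widths in
  Gauss because that is how the EPR literature prints them; 1 G = 0.1 mT).
* **First-order hyperfine.** Each nucleus $i$ with spin $I_i$ and principal
  couplings $A_{i,k}$ (assumed collinear with the g frame — the published
  parameter sets give principal values only, no Euler angles) contributes
  an effective splitting $a_i(n) = \sqrt{\sum_k (A_{i,k} n_k)^2}$, and the
  $\prod_i (2I_i+1)$ transitions sit at
  $B_0(n) + \sum_i m_i\,a_i(n)$, $m_i \in \{-I_i \dots I_i\}$, with equal
  weights. For couplings of at most ~22 G at fields of 0.34 T and above,
  second-order corrections are below 0.1 G and are omitted.
* **Lineshape.** Gaussian, parameterised by peak-to-peak derivative widths
  per axis and interpolated as $\Delta B(n)^2 = \sum_k n_k^2 \Delta B_k^2$.
  Frozen-solution tyrosyl radicals are dominated by unresolved proton
  couplings, for which Gaussian shapes are the standard choice; the source
  parameter sets print widths (4.5/3.5/4.4 G) without naming a shape.
* **Orientation average.** A deterministic equal-area grid over one octant:
  the solid-angle element is $d(\cos\theta)\,d\varphi$, so a uniform
  midpoint grid in $\cos\theta \in [0,1]$ and $\varphi \in [0,\pi/2]$
  carries exactly equal weights. The default 2000 orientations keep
  extracted g-values stable to within a field-grid step; the grid is
  reproducible across runs by construction, which a random sampler would
  not be.
* **Field grid.** 4096 points by default; when no window is given the grid
  auto-ranges to the extreme stick positions ± 10 linewidths (floored at
  a positive field).
* Modulation amplitude and microwave power are treated as metadata only:
  the simulated quantity is the ideal first derivative of the absorption
  under non-saturating conditions.

Mixed-valent Fe(II)Fe(III) centres are simulated with no hyperfine
structure and a default 100 G (10 mT) per-axis width. Published tables for
these species give only g-values; the width is our documented stand-in for
their broad envelopes, and the turning-point extraction tolerance (±0.01
in g) is set accordingly. The Cu(II)-EDTA concentration standard is
likewise modelled as a broad featureless S = 1/2 envelope (g ≈ 2.31, 2.07,
2.07; 400 G widths): only its double integral enters any calculation.

### Parameter refinement

`fit_spin_system()` refines selected parameter blocks (g-tensor, a named
hyperfine tensor, linewidths) by least squares against an observed
spectrum, both normalised to unit maximum amplitude. A plain residual is
badly multimodal here: a uniform g offset of 0.001 displaces a 285 GHz
tyrosyl pattern by ~5 mT, more than ten linewidths, so a naive
Levenberg–Marquardt run locks onto side minima. The implemented scheme is

1. a global pre-search on a heavily smoothed objective (both spectra
   convolved with a Gaussian kernel, 10% of the field span): a scan over a
   common multiplicative g factor (pattern translation), then one
   coordinate-descent sweep over each free scalar across the documented
   basin (±0.0006 per g component around the translation-corrected start,
   ±4 G per hyperfine component);
2. Levenberg–Marquardt stages at kernel widths of 10%, 3%, 1% of the span,
   each warm-starting the next;
3. a final unsmoothed stage at the full orientation count, so the returned
   parameters minimise the exact residual.

Simulations during fitting run on a field grid padded by 25% on each side
and are cropped back to the observed axis; without this, lines sliding off
the observed window during optimisation distort the objective. Failure to
converge is flagged on the returned object, never silent. On noiseless
self-simulated spectra the scheme recovers g to ~10^-6^ and hyperfine
components to well under 0.1 G from starts of +0.001 in g or +3 G in A.

### g-value extraction and quantification

`extract_g()` reads g1 from the low-field derivative maximum, g2 from the
steepest central zero crossing and g3 from the high-field minimum
(parabolic sub-grid refinement), converting field to g through the
resonance condition. When a known spin system is supplied, two low-field
extrema closer than 1.5× the largest coupling are averaged as a hyperfine
doublet. Turning points are reliable for broad, hyperfine-free spectra
(the mixed-valent centres); for hyperfine-structured tyrosyl spectra the
`"fit"` method is the accurate route and is what the g-recovery checks use.

`double_integral()` integrates the first-derivative spectrum twice
(trapezoidal). With the default `linear_endpoints` baseline, the
derivative has the line through its endpoint levels removed (each level
the mean of the outer 2% of points, so point noise cannot tilt the line),
and the absorption from the first integration is endpoint-corrected to
zero — the standard stabilisation, without which a residual derivative
offset grows quadratically in the sweep width. `quantify_spins()` forms
`standard_conc × DI_sample / DI_standard` and refuses spectra recorded at
different frequencies, mirroring the identical-conditions requirement of
the laboratory procedure. A g-dependent intensity factor (taken as the
squared mean principal g-value, an Aasa–Vänngård-type correction) is
available but off by default: the reference procedure compares raw double
integrals, and whether the original analysis applied any such correction
is not documented. Protein arithmetic uses ε₂₈₀ = 124 000 M⁻¹cm⁻¹ per
dimer.

### Radical decay

`fit_decay()` fits $I(t) = I_0 e^{-kt}$; two points are solved in closed
form, longer series by nonlinear least squares started from the log-linear
regression, with $k \ge 0$ enforced (an apparent negative decay clamps to
zero with a warning — radical regeneration is outside the model). The
single-exponential form is fixed by design: the reference observations are
fractional losses (e.g. 31% over 24 h ⇒ t½ ≈ 44.8 h; 40% over 10 min ⇒
t½ ≈ 13.6 min), which determine one rate constant.

## qPCR quantification

The amplification-curve model throughout the synthetic module is a
four-parameter logistic plus flat baseline whose exponential phase grows by
the efficiency E per cycle. Its second-derivative maximum has the closed
form $c_0 - \ln(2+\sqrt{3})/\ln E$, which makes every Cp computation
testable against an analytic oracle.

* **Cp calling** (`call_cp()`): Savitzky–Golay smoothing (window 5, order
  2) and curvature localisation, then sub-cycle refinement by fitting a
  logistic around the transition and taking its analytic
  second-derivative maximum. A sampled curvature maximum at unit cycle
  spacing carries a 0.2–0.5-cycle discretisation bias; the model-based
  refinement removes it (verified to 0.05 cycles against the closed form).
  Curves without a 3-fold rise over baseline raise a no-amplification
  error.
* **Efficiency** (`estimate_efficiency()`): best-R² sliding window of 4–6
  consecutive cycles on log10 fluorescence, E = 10^slope^, after baseline
  subtraction. When the curve has plateaued, the regression uses
  plateau-corrected values $W/(1 - W/\text{plateau})$ — exactly
  exponential for a logistic — because otherwise the window selector
  drifts into the plateau bend under noise and biases E downwards by up to
  0.1. Estimates outside (1, 2.1] are flagged and excluded from
  `mean_efficiency()`.
* **Relative level**: $E_{std}^{Cp_{std}} / E_{tar}^{Cp_{tar}}$ with
  tissue-matched per-primer mean efficiencies and duplicate-mean Cp
  values; duplicates differing by ≥ 1 cycle are flagged, not dropped.
  Normalisation is to the exogenous standard mw2060 spiked at a fixed
  amount per mg tissue, which sidesteps unstable endogenous reference
  genes under anoxia.
* **Statistics** (`dunnett_vs_control()`): one-way ANOVA, then two-sided
  many-to-one comparisons against the normoxic control under homogeneous
  variance. Critical values come from a seeded Monte Carlo of the null
  max-|t| statistic (10^5^ draws by default) rather than printed tables:
  the tables are edition-dependent, while the Monte Carlo is reproducible,
  testable (it matches the multivariate-t quantile to ~0.002 and holds the
  familywise error at 0.05 ± 0.01 in calibration runs) and extends to
  unbalanced designs. Two-sided comparisons are assumed; the original
  report does not state sidedness.

## Protein-sequence phylogenetics

* **Distances**: p-distance with pairwise gap deletion (robust for
  partial-length paralogs), Poisson correction $-\ln(1-p)$ and Kimura's
  protein correction $-\ln(1-p-0.2p^2)$; Kimura is the default stand-in
  for a PHYLIP-era Protdist run whose exact model is version-dependent.
  Saturated pairs are capped at 10 substitutions/site with a warning.
* **Neighbor joining**: Saitou–Nei with the standard Q criterion.
  Negative branch lengths are clamped to zero with the deficit moved to
  the sibling branch (path lengths through the join are preserved), and
  ties in Q break deterministically in input label order. On additive
  matrices the implementation is exact (verified against direct tree
  construction and a brute-force least-squares search over all 5-taxon
  topologies).
* **Bootstrap**: columns resampled with replacement, distances and NJ
  rebuilt per replicate, and each reference-tree bipartition's recovery
  counted (supports as counts out of n, default 300). Supports are mapped
  onto the full-data tree — matching how such figures are annotated — and
  nodes above half the replicate count are flagged (the conventional
  "over 150 of 300" display rule). Consensus-tree construction is out of
  scope.
* **Identity**: global Needleman–Wunsch alignment with BLOSUM62 and affine
  gaps (open 10, extend 0.5), identity counted over alignment columns
  excluding dual-gap columns. The reference identity table does not state
  its alignment method; this standard scoring is the package's documented
  contract.
* **KEN box**: the minimal K-E-N tripeptide by default; any regular
  expression can be supplied, since the consensus actually applied to the
  13-residue span reported for p53R2ii is not documented.

## The synthetic-data module

`scenario_config()` encodes the study design as defaults: six exposure
groups (normoxia, hypoxia, anoxia 1/3/5 d, reoxygenation), n = 8 per group
(within the reported 6–10), brain and heart tissues, the measured
per-primer efficiencies including mw2060, and a 10-fold Ki67 induction in
anoxic brain as the planted effect. Generators are pure functions of
(config, seed).

* EPR spectra are rescaled so the double integral equals the spin
  concentration, then Gaussian noise (default 2% of the maximum
  amplitude) is added; noise ≥ 50% is refused as unusable.
* Decay series sample the stability-assay design points (0 h control,
  24 h anoxic, +1 h normoxic).
* qPCR plates encode fold-changes as Cp shifts through the assigned
  efficiency, with lognormal biological variation (σ = 0.25 on the log
  scale, a ~25% CV typical of mRNA levels across individual fish) and
  technical duplicate noise (σ = 0.1 cycles). Target base Cp values are
  chosen so a fold-change of 1 maps to a relative level of exactly 1.
* Protein families evolve by independent-site substitutions under an
  equal-rates 20-state model (the amino-acid analogue of Jukes–Cantor),
  no indels. This is deliberately non-empirical: sufficient for
  topology-recovery and calibration tests, not for simulating real
  protein evolution.

What the generators do **not** emulate — and hence what green tests do not
demonstrate about real data: correlated instrument baselines and g/A-strain
in EPR spectra, non-logistic amplification artefacts (inhibition, primer
dimers), plate effects, indels and among-site rate variation, and any
wet-lab variability upstream of the measured signals.

## Problem sizes and numerical choices

The test-suite and acceptance runs use the conditions above at full scale:
285 GHz refits at 4096 field points × 2000 orientations, the X-band
hyperfine refit likewise, 300 bootstrap replicates, 10^5^ Monte Carlo
draws for Dunnett critical values and 2000 null datasets for the
calibration check. Unit tests use reduced grids (≥ 400 orientations, 1024–
2048 points) where the property under test is grid-independent. Seeds are
fixed everywhere randomness enters; tolerance choices (±0.0002 on refitted
g, ±0.5 G on hyperfine, ±0.01 on turning-point g of broad signals, 0.05
cycles on Cp, 15% on spin quantification, 20% on qPCR fold recovery)
reflect the measurement precision of each quantity, not the optimiser's.

## Known limitations

* Hyperfine frames are assumed collinear with the g frame; non-collinear
  sets would need Euler angles the published parameters do not provide.
* No second-order hyperfine, S > 1/2 manifolds, g/A-strain, saturation or
  temperature effects; no full spin-Hamiltonian diagonalisation.
* Turning-point g extraction is biased by ~0.0005 on hyperfine-structured
  spectra (use the fit method there).
* The efficiency estimator assumes a logistic plateau when correcting the
  window regression; strongly non-logistic plateaus fall back to the
  uncorrected fit and may under-estimate E slightly.
* Multiple sequence alignment is consumed, never produced; ML/Bayesian
  tree inference and codon models are out of scope.
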