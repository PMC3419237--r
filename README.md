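# rnrkit

Simulation and analysis toolkit for characterising class Ia ribonucleotide
reductase (RNR) small subunits and their expression — the kind of
multi-technique dataset collected when asking how an anoxia-tolerant fish
such as the crucian carp keeps producing deoxyribonucleotides, and hence
dividing cells, with little or no oxygen.

RNR's R2/p53R2 subunits carry a di-iron centre that reacts with O₂ to form
a stable tyrosyl radical. `rnrkit` covers the four computational strands of
such a study:

* **Powder EPR simulation** of S = 1/2 species — tyrosyl radicals with an
  anisotropic g-tensor (g₁ ≥ g₂ ≥ g₃), first-order proton hyperfine
  couplings `a_i(n)² = Σ_k (A_ik n_k)²` and orientation-interpolated
  Gaussian linewidths, and mixed-valent Fe(II)Fe(III) centres — at any
  microwave frequency (X-band 9.67 GHz, high-field 285 GHz). Resonance
  condition `B = hν/(g(n)μ_B)` with `g(n) = sqrt(Σ g_k² n_k²)`, averaged
  over a deterministic equal-area orientation grid.
* **EPR analysis**: least-squares spin-Hamiltonian refinement
  (coarse-to-fine Levenberg–Marquardt), turning-point g extraction, spin
  quantification by double integration against a Cu(II)-EDTA standard
  (`c = c_std · DI_sample/DI_std`), radicals per dimer, and first-order
  radical decay `I(t) = I₀e^(−kt)`, `t½ = ln2/k`.
* **qPCR quantification**: second-derivative-maximum Cp calling, LinReg-style
  per-reaction efficiencies, relative levels
  `E_std^Cp_std / E_tar^Cp_tar` against the exogenous mw2060 standard, and
  one-way ANOVA with a seeded Monte Carlo Dunnett many-to-one post-test.
* **Protein phylogenetics**: CDS translation, BLOSUM62 global-alignment
  identity, p/Poisson/Kimura distances, Saitou–Nei neighbor joining,
  column-bootstrap supports (counts out of n replicates) and KEN-box
  scanning.

A seeded synthetic-data module (`scenario_config()`, `make_epr_dataset()`,
`make_decay_series()`, `make_qpcr_plate()`, `simulate_protein_family()`)
generates inputs with the statistical structure each stage assumes — six
exposure groups (normoxia, hypoxia, anoxia 1/3/5 d, reoxygenation) at
n = 8, measured primer efficiencies, known spin systems and guide trees —
so the whole pipeline runs and is tested without any download.

## Worked example

Simulate the mixed-valent form of crucian carp R2ii at X-band from its
published g-values, read the g-tensor back off the spectrum, fit the
radical-stability observation, and compute a relative mRNA level:

```r
library(rnrkit)

sp <- powder_spectrum(preset_spin_system("mv_carp_R2ii"), frequency_GHz = 9.67)
extract_g(sp, method = "turning_points")
#> g-values (turning_points): g1 = 1.9192, g2 = 1.7319, g3 = 1.6121
#>   field positions (mT): 359.99, 398.93, 428.56

fit_decay(c(0, 24), c(1.00, 0.69))   # a 31% signal loss over 24 h at 0 degC
#> First-order radical decay fit
#>   k = 0.01546 per hour; half-life = 44.8 h
#>   I0 = 1

relative_level(E_std = 1.82, Cp_std = 26.0, E_tar = 1.78, Cp_tar = 24.7)
#> [1] 3.771
```

The extracted g-values land on the generating tensor (1.92, 1.73, 1.61) to
within 0.002 — broad mixed-valent envelopes blur the turning points by a
few tenths of a mT. The decay fit turns the observed fractional loss into
a rate constant and half-life; the relative level says this sample carries
~3.8× as much target mRNA per unit of spiked standard as a sample with
equal Cp values would.

A command-line launcher wrapping the same functions ships at
`system.file("cli", "rnrkit.R", package = "rnrkit")` with subcommands
`simulate-epr`, `analyze-epr`, `qpcr`, `phylo`, `identity`, `translate`
and `synth`.

See `vignettes/rnrkit-methods.Rmd` for the models, assumptions, parameter
choices and limitations.

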