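---
title: "Models and methods: ensemble networks, landscapes, and folding fits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: ensemble networks, landscapes, and folding fits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caspensemble)
```

caspensemble analyzes protein conformational ensembles of the caspase family
along three coupled axes: residue-interaction networks with centrality
metrics, essential-dynamics free-energy landscapes, and equilibrium-unfolding
thermodynamics. Because full-length molecular-dynamics trajectories and
wet-lab denaturation data are expensive, every stage is driven — and
validated — by a synthetic-data generator with known ground truth, so the
whole pipeline is testable by parameter recovery. This vignette records the
models, the tunable parameters and their defaults, the numerical choices, and
what the synthetic conditions do and do not tell you about real data.

## Residue-interaction networks

A contact is any heavy-atom pair within a distance cutoff (default 4.0 Å,
the value used throughout structural network analysis of caspase ensembles)
whose residues are at least two apart in the chain; cross-chain pairs are
always eligible. Chain-adjacent residues (|i−j| ≤ 1) are excluded so covalent
geometry never counts as a non-covalent interaction, and hydrogens are
ignored because their treatment varies between crystallographic and NMR
models.

Contacts are typed by operational rules that `typing_rules()` exposes for
override:

* **electrostatic** — the atoms belong to oppositely charged sidechain
  groups (Asp/Glu carboxylate oxygens vs Lys/Arg/His sidechain nitrogens);
* **hydrophobic** — both atoms are sidechain carbons of apolar residues
  (Ala, Val, Leu, Ile, Pro, Phe, Met, Trp);
* **vdw** — everything else within the cutoff.

Published network analyses of MD ensembles typically delegate these
definitions to the analysis plugin; the rules above are this package's
explicit, testable definitions.

Per frame and residue pair, the edge weight is the *count* of atom-pair
contacts (the "sum" convention); `mean_weight` averages those counts over all
frames, and `occupancy` records the fraction of frames with at least one
contact. Degree centrality DC(v) is the sum of incident `mean_weight`s with
interaction types pooled — the average number of non-covalent contacts the
residue makes — and an unweighted per-neighbor variant sits behind
`weighted = FALSE`, since external tools are not always explicit about which
convention they report. Betweenness centrality uses edge length
1/`mean_weight` (stronger contact, shorter path) and is *unnormalized*,
because the conventional hub threshold (BC > 1000 alongside DC > 20) is only
meaningful for raw path counts. Computation is delegated to igraph's Brandes
implementation; the test suite checks it against an exhaustive
path-enumeration oracle on hundreds of small random graphs.

Conservation grades (ConSurf-style, 1–9) are consumed, never computed, and
binned as high (8–9), intermediate (6–7), and variable (1–5). The published
binning leaves grade 5 unassigned ("below 5" is variable); we group 5 with
variable, the conservative choice for a "variable" call. Structural-region
classes (helix, beta, top_loop, bottom_loop, short_beta) are likewise
consumed from an annotation file: the distinction between active-site top
loops and basal bottom loops is caspase anatomy, not derivable from geometry.

Family averaging maps each protein's residues onto a master alignment and
takes per-column arithmetic means over non-gapped proteins only; gap
positions contribute to neither numerator nor denominator, and sequence
mismatches are rejected naming the offending protein.

**Toy-geometry caveat.** The synthetic base geometry is an idealized α-helix
trace (1.5 Å rise, 100° turn) with one pseudo-sidechain atom per residue. At
that coarse-grained resolution no heavy-atom pair at |i−j| ≥ 2 falls within
4 Å, so the analysis scripts and demo configuration use a 6 Å cutoff for toy
ensembles. The 4 Å default is unchanged and is what you should use with
all-atom ensembles.

## Essential dynamics and free-energy landscapes

Frames are superposed onto a reference by least-squares rotation/translation
(Kabsch, via SVD), fitting on Cα atoms by default while the covariance is
computed over all heavy atoms; both selections are arguments, since fitting
selections are rarely reported. PCA eigenvalues are the variances (Å²) along
orthonormal collective modes; signs are fixed by making each mode's
largest-magnitude component positive (signs are arbitrary, determinism is
not). Mass weighting is available behind a flag and off by default — the
unweighted covariance is the cleaner object to test against planted modes.

Note one subtlety the test suite encodes: superposition on a subset
(Cα) re-introduces the subset's rigid-body component of any internal motion,
so eigenvalues of a superposed ensemble differ slightly from those of the
raw aligned ensemble. Rigid-body *invariance* — jittering every frame by a
random rotation/translation and superposing — is exact and is asserted to
1e−8.

The free-energy landscape over PC1/PC2 is G = −RT ln(P/P_max) on a 32×32
histogram (bin count is an argument), with T = 298.15 K (RT ≈ 0.593
kcal/mol); the source analyses do not state their FEL temperature, and all
package energies are kcal/mol. Empty bins are masked rather than assigned
the maximum G (a known artifact of some tooling), so landscapes are bounded
by sampling, as in published plots.

Metastable basins are local minima of the occupied 8-neighborhood grid,
extracted by a topological-persistence sweep: bins are processed in order of
increasing G (ties by lowest row, then column, which collapses flat plateaus
deterministically), components are merged union-find style, and a minimum's
persistence is the barrier height at which its component merges into a
deeper one. A minimum counts as a basin only if its persistence is at least
`min_prominence` (default 1.0 kcal/mol ≈ 1.7 kT) *and* it lies that far
below the shallowest occupied bin. The second condition matters: on a −RT
log scale, isolated single-count rim bins are spurious "minima" by
construction, and Poisson noise between low-count neighbors easily exceeds
1 kT. A dip shallower than ~1.7 kT is sampling noise, not a metastable
state. Basins closer than `min_separation` bins (default 2, Chebyshev) merge
into the deeper one. Each basin's representative frame is the one whose
projection is nearest its minimum-bin center (ties to the lowest index).

Landscape breadth — occupied bins × bin area, plus the PC1 span — supports
the water-vs-urea and monomer-vs-dimer comparisons: broader planted
fluctuations must, and in the paired tests do, enlarge the occupied area.

## Equilibrium unfolding thermodynamics

Both folding models use the linear extrapolation method,
ΔG(urea) = ΔG°(H₂O) − m·[urea] and K = exp(−ΔG/RT) with
R = 1.9872×10⁻³ kcal mol⁻¹ K⁻¹ and T = 298.15 K (buffer pH is reported in
the source work, temperature is not). Positive ΔG° means the folded species
is stable in water. Two-state: fU = K₁/(1+K₁). Three-state monomer
N↔I↔U: fN = 1/(1+K₁+K₁K₂), fI = K₁fN, fU = K₁K₂fN — fractions sum to one
identically, and a three-state model with a very large ΔG°₂ reproduces the
two-state model exactly (a nested-model identity the tests assert at
1e−6).

The observed signal is the population-weighted sum of species baselines,
linear in urea for N and U; the intermediate contributes a urea-independent
constant, the standard identifiability choice for three-state fits (a slope
is available behind a flag). Signals are fit in raw units with per-probe
baselines rather than pre-normalized, so normalization error never
propagates into ΔG°.

`global_fit()` shares the thermodynamic parameters across all datasets
(probes × concentrations × directions pooled — the folding reactions are
reversible) and shares baselines per probe. For fixed thermodynamic
parameters the baselines enter linearly, so they are profiled out exactly by
per-probe linear least squares; the nonlinear search then runs over only 2
(two-state) or 4 (three-state) parameters, by L-BFGS-B from 25
Latin-hypercube starts (bounds ΔG° ∈ [0, 15] kcal/mol, m ∈ (0, 3]
kcal mol⁻¹ M⁻¹), followed by a tight polish from the best start. Standard
errors come from the Gauss-Newton curvature of the profiled objective; model
choice combines AIC with the concentration-dependence screen.

The concentration-dependence statistic is the maximum, over urea bins and
probes, of the across-concentration range of min-max-normalized
replicate-averaged curves. Its null distribution is that of a maximum of
~75 ranges, so a fixed small multiple of the noise sd misfires; the
threshold is instead the level-α family-wise bound
√2·σ·z(1 − α/(2·n_pairs·n_bins)) with α = 0.01 and σ estimated by the
second-difference estimator. On synthetic data this classifies 15/15 monomer
datasets as independent and 15/15 midpoint-shifted (oligomer-like) fixtures
as dependent.

Limited-proteolysis band intensities are fit to I(t) = A·e^(−kt) + C by
Levenberg-Marquardt with k ≥ 0; non-decaying input returns k = 0 with a
degenerate flag rather than an error.

## The synthetic-data generator as the study design

The generator defines the conditions under which every recovery claim is
made:

* **Ensembles** fluctuate along a small number of orthonormal planted modes
  (rigid-body components projected out, so superposition is a no-op up to a
  global transform) with strictly decreasing amplitudes, plus isotropic
  Gaussian noise (default 0.05 Å) and optional rigid jitter. Denaturant
  conditions are emulated *only* as broader mode amplitudes — there is no
  force field, solvent, or urea chemistry.
* **Unfolding experiments** follow the published design: three probes
  (280 nm and 295 nm fluorescence, far-UV CD), protein concentrations 2, 6
  and 8 μM, urea 0–9 M in 25 steps, unfolding and refolding directions, with
  homoscedastic Gaussian noise of sd = 2% of each probe's N→U signal range.
* **Presets.** `"21M"` generates from the published three-state free
  energies ΔG°₁ = 1.0 and ΔG°₂ = 2.7 kcal/mol; `"hub_mutant"` from the
  published two-state ΔG° = 2.3 kcal/mol. The m-values and baselines are not
  in the available text and are this package's stand-ins: m₂ = 0.7
  kcal mol⁻¹ M⁻¹ places the second midpoint at 3.9 M urea, matching the
  observed change of slope near 4 M, and m = 0.575 gives the two-state
  preset its 4 M midpoint. For m₁ we chose 1.2 kcal mol⁻¹ M⁻¹ after an
  explicit information analysis: with a much shallower first transition
  (e.g. m₁ = 0.5, a 2.4 M-wide sigmoid), the Fisher information of the
  design bounds sd(ΔG°₁) near 0.9 kcal/mol per experiment, because a broad
  low-midpoint transition is absorbed by the free native baseline — no
  estimator can recover a 1 kcal/mol ΔG°₁ reliably from such curves at 2%
  noise. The steeper stand-in keeps the recovery experiment informative
  while preserving every published quantity.
* **Intermediate baselines** are probe-differentiated the way a molten
  globule is: hyperfluorescent at 280 nm, unfolded-like at 295 nm,
  native-like by CD. This is both realistic and necessary — an intermediate
  whose signal sits at the N/U midpoint on every probe is mathematically
  indistinguishable from an N/U mixture, and no global fit could see it.

What passing recovery tests *show*: the estimators are unbiased and
well-calibrated under Gaussian noise, linear baselines, and a correctly
specified model. What they do *not* show: robustness to baseline curvature,
probe-correlated noise, slow equilibration or aggregation artifacts — all
present in real denaturation data and all outside this generator.

## Problem sizes and reproducibility

Every generator and fit is a pure function of an integer seed. The recovery
experiments average 10 independent synthetic experiments (each 18 curves of
25 points) with 25 multistarts per fit; the spectral tests use 1000-frame
ensembles of 20 residues; basin tests use 10⁴-point landscapes (a 32² grid
needs ~10 counts per occupied bin before −RT log count noise drops below
1 kT); the oracle comparison uses 200 random graphs of up to 10 nodes. These
sizes were chosen so the complete suite documents the science of the package
in a few minutes of compute while leaving each check statistically
meaningful.

## Known limitations

* The contact typing is rule-based and coarser than geometry-aware
  hydrogen-bond or π-stacking detection (deliberately out of scope).
* Toy ensembles have Gaussian, unimodal fluctuations; multi-basin landscapes
  are emulated only at the projection level, not by the coordinate
  generator.
* Dimeric (concentration-dependent) folding models are not implemented; the
  concentration-dependence screen exists precisely to justify the monomer
  models before fitting, and flags data that would need a dimer model.
* Region annotation and conservation grades are inputs; the package neither
  assigns secondary structure nor computes evolutionary rates.
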