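# caspensemble

Caspases — the proteases that execute apoptosis — interconvert between
monomeric, dimeric and enzymatically active conformations, and their folding
passes through a partially folded intermediate that has persisted across
hundreds of millions of years of evolution. Understanding which residues
scaffold that intermediate requires three kinds of analysis at once:
**residue-interaction networks** over conformational ensembles (who contacts
whom, how persistently, and which residues are communication bottlenecks),
**essential-dynamics free-energy landscapes** (which metastable conformations
an ensemble visits), and **equilibrium-unfolding thermodynamics** (how stable
each state actually is). caspensemble implements all three as one tested R
pipeline, for structural biologists and protein-folding labs who want these
analyses reproducible and verifiable without rerunning MD or wet-lab work.

## The models at the core

**Networks.** Residues are nodes; typed non-covalent contacts (van der
Waals, hydrophobic, electrostatic; heavy-atom pairs within 4 Å, chain
neighbors excluded) are edges weighted by the mean per-frame atom-contact
count. Degree centrality DC(v) = Σ incident mean weights; betweenness
BC(v) = Σ_{s<t} σ_st(v)/σ_st on the graph with edge length 1/weight,
unnormalized. Residues with DC > 20 *and* BC > 1000 form the conserved
scaffolding quadrant. Per-position metrics are averaged across homologs on a
master alignment and stratified by ConSurf-style conservation bins (8–9
high, 6–7 intermediate, 1–5 variable) and structural region.

**Landscapes.** After Kabsch superposition, PCA of the coordinate
covariance gives collective modes; the free-energy landscape over the first
two is G = −RT·ln(P/P_max) on a 2D histogram (T = 298.15 K), with
metastable basins extracted by a persistence criterion and each basin
represented by its nearest frame.

**Folding.** Linear extrapolation method, ΔG(urea) = ΔG°(H₂O) − m·[urea],
K = exp(−ΔG/RT). Two-state N↔U and three-state monomer N↔I↔U
(fN = 1/(1+K₁+K₁K₂), fI = K₁fN, fU = K₁K₂fN); observed signal is the
population-weighted sum of per-probe linear baselines. Global fits share
thermodynamic parameters across probes, concentrations and directions,
profile the baselines exactly, and multistart the remaining 2–4 parameters;
model choice uses AIC plus a calibrated concentration-dependence screen.
Proteolysis kinetics fit I(t) = A·e^(−k_app·t) + C.

A synthetic-data module generates every input with known ground truth —
ensembles with planted orthonormal modes, unfolding curves from preset
thermodynamic parameters (the `"21M"` preset uses the published three-state
free energies 1.0 and 2.7 kcal/mol; `"hub_mutant"` the published two-state
2.3 kcal/mol), conservation tables and region annotations — so every stage
is validated by parameter recovery.

## Worked example

Fit a synthetic three-state unfolding experiment and inspect an ensemble's
landscape:

```r
library(caspensemble)

preset <- folding_preset("21M")
data <- make_unfolding_datasets(preset, noise_sd_fraction = 0.02, seed = 104)
fit <- global_fit(data, model = "three_state", n_starts = 25, seed = 204)
print(fit)
#> <folding_fit_result> three_state model, 450 obs, RSS 0.1008, AIC -3741.64
#>   transition 1: dG = 0.865 kcal/mol, m = 1.254 kcal/mol/M (Cm 0.69 M)
#>   transition 2: dG = 2.746 kcal/mol, m = 0.712 kcal/mol/M (Cm 3.86 M)
concentration_dependence_test(data)$concentration_independent
#> [1] TRUE

ens <- make_toy_ensemble(ensemble_spec(n_residues = 20, n_frames = 1000,
                                       mode_sds = c(2, 1), seed = 7))
p <- pca(superpose(ens)$ensemble, selection = "heavy")
print(p)
#> <pca_result> 120 modes over 40 atoms; leading eigenvalues (A^2): 3.995, 1.086, 0.01068
basins <- find_basins(build_fel(project(superpose(ens)$ensemble, p)))
nrow(basins)
#> [1] 1
```

The fitted transition free energies (0.87 and 2.75 kcal/mol here) estimate
the generating values 1.0 and 2.7 — a single 2%-noise experiment carries
roughly ±0.3 kcal/mol of scatter in ΔG°₁, which is why the recovery
experiments below average ten of them. The leading PCA eigenvalues (3.995
and 1.086 Å²) recover the planted mode variances (4 and 1 Å²), and the
unimodal ensemble yields exactly one free-energy basin.

## The analysis workflow

`analysis/` contains the numbered drivers, each a thin narrative script over
the package that writes its tables under `results/`:

| script | what it does |
|---|---|
| `01_simulate.R` | generates ensembles (water + broadened "urea"), conservation, regions, unfolding data, a proteolysis time course |
| `02_networks.R` | builds RINs, DC/BC, hub classification, region/conservation distributions, family-averaged positional metrics |
| `03_landscape.R` | superposition, PCA, projections, FELs, basins, water-vs-urea breadth |
| `04_folding_fits.R` | concentration screen, AIC model selection, global fits with standard errors, proteolysis kinetics |
| `05_report.R` | end-to-end orchestrated pipeline runs and paired condition comparisons |

Run them in order from the repository root: `Rscript analysis/01_simulate.R`
and so on. The same orchestration is available from R via
`run_pipeline(<config>)` with the bundled
`inst/extdata/demo_config.yaml`.

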