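# pocketprofile

Structure-guided triage of terpene-synthase candidates, plus
Michaelis–Menten characterization of their kinetics.

## The problem

Terpene synthases (TPSs) with the same catalytic function can share very
little overall sequence identity — fungal, bacterial, and plant
linalool/nerolidol synthases (LNSs) overlap by only ~8–15% — yet their
substrate-binding pockets are strongly conserved. Screening genomes for a
wanted activity (say, a selective linalool synthase for microbial linalool
production) therefore works much better on **active-site residues** than on
full sequences. `pocketprofile` implements that workflow for anyone
triaging enzyme candidates from sequence databases against structural
templates:

1. **Pocket extraction** — parse a template structure with a bound ligand
   and collect every polymer residue with a heavy atom within 6.0 Å of a
   ligand heavy atom (minimum-distance rule, boundary inclusive).
2. **Cross-template union** — map a second template's pocket onto the first
   through global alignment and take the union of positions; this unified
   position set defines the active-site profile columns.
3. **Profile projection** — align each candidate to the templates and read
   off the residues at the template positions (`-` where the candidate has
   a gap).
4. **Active-site identity & motif filtering** — score candidates against
   characterized references as `100 × identical / comparable` positions,
   and require both class I TPS catalytic motifs: the aspartate-rich motif
   `D(D/E)XXD` and the NSE triad `(N/D)Dxx(S/T)xxxE`. A candidate inherits
   the label of its nearest reference only above the identity threshold
   (default 90%) with a complete motif set.
5. **Classification views** — sequence similarity networks (edge iff
   alignment score ≥ threshold; GraphML/TSV for Cytoscape) and
   neighbor-joining trees (Newick) from identity distances.
6. **Kinetics** — pyrophosphate-release assay tables → standard-curve
   interpolation → initial rates (longest linear prefix, R² ≥ 0.95) →
   nonlinear least squares on

   v = v_max [S] / (K_m + [S]),  with v_max = k_cat [E₀],

   giving K_m, k_cat, catalytic efficiency k_cat/K_m, and fold
   comparisons between enzymes.

A seeded generator builds toy structures with planted pockets, homolog
families with controlled active-site conservation, and simulated assay
time courses, so the whole pipeline is testable offline.

## Worked example

Extract a pocket from a (generated) template structure:

```r
library(pocketprofile)
set.seed(42)
toy <- make_toy_structure(40, c(5, 12, 20, 33))
model <- parse_structure(toy, id = "TOY")
pocket <- extract_pocket(model, select_ligands(model), cutoff = 6)
print(pocket)
#> Pocket of TOY at 6.0 A: 4 residue(s)
#>   A5 A12 A20 A33
```

Fit Michaelis–Menten kinetics to a simulated PPi-release assay
(truth: K_m = 3.8 µM, k_cat = 6/min at E₀ = 0.25 µM, 5% signal noise):

```r
set.seed(1)
sim <- simulate_assay(sigma = 0.05)
fit <- kinetics_pipeline(sim$standards, sim$assays)
print(fit)
#> Michaelis-Menten fit (n = 6 rates)
#>   Km    = 3.23 +/- 0.17 uM
#>   vmax  = 1.49 +/- 0.014 uM/min
#>   kcat  = 5.97 +/- 0.056 1/min (E0 = 0.25 uM)
#>   kcat/Km = 1.85 1/(min uM)
```

`fit` is an ordinary S3 model object with `coef()`, `summary()`,
`predict()`, `residuals()`, `plot()` and `simulate()` methods.

Compare catalytic efficiencies across enzymes (printed K_m/k_cat values
for characterized linalool/nerolidol synthases):

```r
tab <- data.frame(
  enzyme = c("Ap.LS/GPP", "Aa.LNS/FPP", "Aa.LNS/GPP", "Sc.LNS/FPP"),
  Km   = c(3.8, 9.0, 6.7, 9.6),
  kcat = c(6.0, 3.3, 0.5, 18.7))
efficiency_report(tab, reference = "Ap.LS/GPP")
#>      enzyme  Km kcat efficiency efficiency_display fold_vs_reference fold_display
#>   Ap.LS/GPP 3.8  6.0    1.57900                1.6             1.000            1
#>  Aa.LNS/FPP 9.0  3.3    0.36670                0.4             4.310            4
#>  Aa.LNS/GPP 6.7  0.5    0.07463                0.1            21.200           21
#>  Sc.LNS/FPP 9.6 18.7    1.94800                1.9             0.811            1
```

Note the fold column is computed from unrounded efficiencies — the fungal
linalool synthase is 21-fold more efficient than the LNS on GPP, which the
rounded table values (1.6 vs 0.1) would distort to 16.

The end-to-end synthetic demonstration (`demo_workflow()`) plants two
enzyme subfamilies with conserved active sites, and recovers them as pure
SSN clusters and tree clades, labeling each homolog by its nearest
reference's function.

A thin command-line wrapper over these functions is installed at
`inst/cli/pocketprofile.R` with subcommands `pocket`, `identity`,
`profile`, `ssn`, `tree`, `kinetics`, `simulate`, `run-all`.

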