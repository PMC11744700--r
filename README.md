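# pofpr — photophysics-oriented fingerprints for organic luminophores

Designing solid-state organic emitters — in particular aggregation-induced
emission (AIE) materials, which light up on aggregation instead of quenching —
means reasoning about a handful of structural levers: electron donors and
acceptors, the extent of aromatic conjugation, excited-state intramolecular
proton transfer (ESIPT) motifs, and bulky "conjugation breakers" that disrupt
π-stacking. General-purpose cheminformatics fingerprints (MACCS, Morgan, …)
bury these levers under hundreds of descriptors that are irrelevant to
photophysics and invite overfitting on the small curated datasets this field
has.

`pofpr` implements the *photophysics-oriented fingerprint* (POFP): a 46-digit
descriptor in which digits 1–15 count donor/ESIPT substructures, digits 16–38
count acceptors, digits 39–45 count conjugation breakers (each defined by a
SMARTS pattern, matched with distinct-atom-set counting), and digit 46 is the
number of aromatic atoms. `POFP(num)` holds the counts; `POFP(bit)` their
presence indicators. On top of the fingerprint the package provides the full
analysis stack used to interrogate structure–photophysics relationships:

* **Regression and classification** of emission transition energies
  (`E = 1240/λ`, eV) and of aggregate photophysical classes
  (AIE/ACQ/TADF/AIDF/RTP) and excited-state mechanisms
  (ICT-TICT/ESIPT/NA/CL), with seeded 5-fold cross-validation. Classical
  learners (linear, SVR/SVM, kNN, decision tree, random forest, gradient
  boosting) are delegated to their standard implementations; the reference
  model is a built-in four-layer ReLU fully connected network with exact
  analytic input gradients.
* **Integrated-gradient attribution**: for a trained model `F̂` and baseline
  `s̄`, feature `i` receives `(s_i − s̄_i) ∫₀¹ ∂F̂(s(α))/∂s_i dα` with
  `s(α) = s̄ + α (s − s̄)` (trapezoid over 100 path points), plus an
  unnormalized variant (the path-averaged gradient itself) and a
  fraction-of-total variant whose contributions sum to exactly 1. Sweeps over
  hypothetical fingerprints (e.g. attribution versus aromatic-atom count at a
  `s10 = 0.5, s46 = 6` baseline) expose how the importance of a donor or
  acceptor changes with conjugation scale.
* **A conditional variational autoencoder** over `POFP(num)` conditioned on
  emission energy: decoding the latent origin (μ = 0, no sampling noise) at a
  target wavelength yields the mean fingerprint profile of structures
  emitting there.
* **A synthetic data generator** that assembles donor–acceptor chromophore
  SMILES from fragments and labels them with a stated ground-truth law, so
  the whole pipeline is testable end to end without access to a proprietary
  photophysics database.

SMILES parsing, aromaticity perception and SMARTS matching go through
OpenBabel (ChemmineOB); digit 46 therefore counts atoms aromatic under
OpenBabel's default aromaticity model, which is recorded in the output
metadata of every fingerprint table.

## Worked example

```r
library(pofpr)

# the classic AIE luminogen tetraphenylethylene (TPE)
tpe <- "C(=C(c1ccccc1)c1ccccc1)(c1ccccc1)c1ccccc1"
compute_pofp(tpe)
#> POFP(num) of C(=C(c1ccccc1)c1ccccc1)(c1ccccc1)c1ccccc1
#>   s10 (carbon-carbon double bond) = 1
#>   s46 (aromatic atoms) = 24
```

TPE activates exactly two digits: one carbon–carbon double bond (the
ethylene rotor, digit 10) and 24 aromatic atoms (four phenyl rings,
digit 46). Cross-validating the neural network on a 700-record synthetic
dataset whose emission energies follow a known donor/acceptor/conjugation
law with 0.05 eV Gaussian noise:

```r
ds     <- generate_dataset(700, seed = 42)
energy <- wavelength_to_energy(ds$records$lambda_solid_nm)   # eV
cross_validate(model_spec("fcnn", "regression", seed = 42),
               ds$fingerprints, energy, folds = 5, seed = 42)
#> cv_result (fcnn/regression), 5 folds; mean: r2=0.8698  mae=0.0717  mse=0.0102
```

The cross-validated MAE (0.072 eV) sits close to the generative noise floor
(`0.05·√(2/π) ≈ 0.040` eV plus the clipping nonlinearity), and R² = 0.87
approaches the noise ceiling `1 − σ²/Var(y) ≈ 0.97`. Attributing a
classification:

```r
cls <- fit_model(model_spec("fcnn", "classification", seed = 42),
                 ds$fingerprints, ds$records$feature_class)
res <- classify_and_attribute(cls, tpe)
res$predicted_class
#> [1] "ACQ"
print(res$ig)
#> integrated gradients (normalized_eq3), F(x) = 0.977121, F(baseline) = 0.0689488
#>   s10  -0.98266
#>   s46  +1.89152
```

Under the synthetic ground truth TPE falls in the ACQ region (its rigidity
score exceeds its flexibility score), and the attribution decomposes the
predicted class probability over the two active digits; their sum recovers
`F(x) − F(baseline)` (the completeness identity). Attribution signs on
models trained on *real* databases will differ — they are properties of the
training data, not of the machinery.

A command-line interface wrapping these functions (subcommands
`fingerprint`, `simulate`, `train`, `cv`, `evaluate`, `interpret`, `sweep`,
`cvae-train`, `cvae-generate`) is installed at
`system.file("cli", "pofp.R", package = "pofpr")`.

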