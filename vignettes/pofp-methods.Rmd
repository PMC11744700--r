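---
title: "Methods: the photophysics-oriented fingerprint and its analysis stack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the photophysics-oriented fingerprint and its analysis stack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the scientific and numerical choices behind `pofpr`:
what the fingerprint encodes, how the models and attribution machinery are
defined, what the synthetic data generator does and does not emulate, and
where the design was genuinely open.

## The fingerprint

A molecule's POFP is a vector of 46 non-negative numbers. Digits 1–45 are
substructure counts against a fixed table of SMARTS patterns — 15
donor/ESIPT motifs, 23 acceptors, 7 conjugation breakers — and digit 46 is
the total number of aromatic atoms, a proxy for conjugation scale.
`POFP(num)` keeps the counts; `POFP(bit)` replaces digits 1–45 by presence
indicators (presence = count ≥ 1; digit 46 stays a count in both modes,
and the bit vector is always the elementwise indicator of the num vector).

Three conventions deserve explicit statement:

* **Distinct-atom-set counting.** A symmetric pattern such as `[C]=[C]`
  maps onto one double bond in two atom orders. Matches are deduplicated by
  their matched atom *set*, so tetraphenylethylene (TPE) scores exactly 1 on
  digit 10. The alternative (counting ordered maps) would double every
  symmetric match and is inconsistent with the fingerprint's worked
  examples. The test suite cross-checks every pattern against an independent
  brute-force subgraph enumeration (RDKit, `uniquify = FALSE`, dedup by atom
  set) on a 20-molecule panel.
* **Aromaticity model.** The pattern table is aromaticity-sensitive
  (`[c]` vs `[C]`), and digit 46 is defined entirely by aromaticity flags.
  The package uses OpenBabel's default perception; the model name is
  recorded in the `aromaticity_model` field of every fingerprint table so
  digit-46 values are reproducible. Kekulé and aromatic SMILES spellings of
  the same molecule give identical fingerprints.
* **Implicit hydrogens.** Patterns with hydrogen-count primitives
  (`[O;H]`, `[C;H]`) are matched on the implicit-hydrogen representation;
  molecules are not explicitly hydrogen-added.

### Repairs to the pattern table

Four published patterns cannot work as printed and are repaired in
`pofp_features()`, which keeps the printed spelling alongside the matched
pattern for audit:

* Rows 8/9 (thiophene, furan) print explicit *single* ring-closure bonds;
  a single bond can never match an aromatic ring bond, so the printed
  pattern would silently match nothing. The dash is read as a typographic
  rendering of the ring-closure digit and dropped.
* Row 12 (naphthalene) opens a second ring closure it never closes — a
  syntax error. It is repaired to a fused-bicycle naphthalene pattern. The
  printed fragment is ambiguous between naphthalene and a larger fused
  system; the feature's *name* decides the repair.
* Rows 42/43 print Unicode minus signs in `[B-]`/`[P-]`. (Their names call
  the depicted anions "cations"; the names are kept as published, the
  chemistry is not "corrected".)

Elements representable by the fingerprint are H, B, C, N, O, F, Si, P, S,
Cl, Se, Br, I plus Au, Bi, Ir, Ru, Eu — the five metals of feature 38 prove
those are meaningful fingerprint inputs; other metals are not, and
`clean_records()` rejects molecules containing them (reason
`disallowed_element`). `compute_pofp()` itself never silently zeroes such
molecules: it computes the fingerprint and attaches a warning.

## Dataset handling

Records carry a SMILES plus optional solid-state and nanoaggregate emission
peak wavelengths (nm), fluorescence quantum yield (0–1), lifetime (ns), an
aggregate-feature class (AIE, ACQ, TADF, AIDF, RTP) and an excited-state
mechanism (ICT_TICT, ESIPT, NA, CL — "NA" is *neutral aromaticity*, a real
label, which is why label columns parse empty cells, not the text "NA", as
missing). Regression targets are transition energies `E = 1240/λ` in eV; the
constant is 1240 exactly, as conventionally printed, not 1239.84 — the
conversion is approximate by construction and self-inverse. Missing values
stay missing at load time; records lacking the target of a given task are
dropped at task time. Duplicate SMILES are retained (polymorph entries are
legitimate).

## The synthetic study

Real curated photophysics databases are external resources; the package
instead generates datasets whose ground truth is *stated*, so recovery tests
mean something. The generator assembles chromophores by substituting 0–3
donors, 0–3 acceptors and 0–2 breakers (categorical draws with probabilities
0.2/0.4/0.25/0.15 for donor and acceptor counts, 0.5/0.3/0.2 for breakers)
into one of five aromatic/ethylenic core templates, through single bonds.

With `D` the sum of donor digits 1–15, `A` the acceptor sum 16–38 and `s46`
the aromatic count, the synthetic solid-state energy is

```
E = 3.6 − 0.12·D − 0.10·A − 0.20·min(D, A) − 0.010·s46 + ε,
ε ~ N(0, 0.05 eV), clipped to [1.1, 3.9] eV
```

i.e. ≈318–1127 nm, matching the wavelength span of curated solid-state
data. The functional form and coefficients are this package's invention;
they encode only the field's qualitative laws — donors, acceptors and
conjugation red-shift emission; donor–acceptor co-presence is synergistic.
The class rule compares a flexibility score `X = 2·s10 + 2·s17 +
Σ(s39..s45) + Σ(s13..s15)` with a rigidity score `Y = s46/6`: AIE when
`X > Y`, ACQ when `X ≤ Y − 1` (boundary ties resolve to ACQ), otherwise one
of TADF/AIDF/RTP uniformly — encoding conjugation's double-edged role.
Mechanisms are deterministic functions of the functional groups present
(ESIPT from digits 13–15, ICT_TICT from donor–acceptor co-presence, CL for
non-aromatic donor systems, else NA).

The default study size is 700 records at seed 42, mirroring the scale of
curated solid-state emission datasets (~700 entries). What the generator
does *not* emulate: real structural diversity (five cores, a dozen
fragments), measurement heteroscedasticity, database curation bias, or any
attempt at the true joint distribution of a real database. Passing recovery
tests therefore demonstrates that the *pipeline* is correct — fingerprints
feed models that recover a known law, attributions recover known signs —
not that any particular chemical conclusion transfers to real data.

## Models

Feature columns are standardized per training fold (scaler stored with the
model; constant columns pass through). The built-in reference model is a
four-layer fully connected network — hidden widths (128, 64, 32), ReLU
after each hidden layer, linear output (one unit for regression, one score
per class with softmax for classification) — trained with mini-batch Adam
(learning rate 1e-3, batch 32, ≤500 epochs, early stopping on a 10%
validation split with patience 25), He-initialized from the model seed.
Regression targets are standardized internally and the scaler inverted at
prediction time, which keeps the loss well conditioned at the default
learning rate. These schedule choices fit the small-data regime (~700
rows); all are exposed as hyperparameters.

The network is implemented in base R matrix code rather than a deep-learning
framework, deliberately: attribution needs exact `∂output/∂input`, and the
same backpropagation that trains the network provides it analytically
(verified against central finite differences to <1e-4 relative error).
Classical learners are not reimplemented: `stats::lm` (with rank-deficient
NA coefficients set to 0 — those features carry no information),
`e1071::svm`, `caret::knnreg`/`knn3`, `rpart`, `randomForest`, and
`xgboost` (via the stable `xgb.train` interface, `nthread = 1` for
reproducibility).

Cross-validation shuffles indices from the given seed; classification folds
are stratified per class, relaxed with a warning when a class has fewer
members than folds. Reported metrics are fold means with per-fold values
retained. Metrics follow the standard definitions; weighted F1 weights
per-class F1 by support; `R²` is `NA` (with a warning) for zero-variance
targets rather than a misleading number.

## Integrated gradients

For model output `F̂`, input `s`, baseline `s̄`, and the straight path
`s(α) = s̄ + α(s − s̄)`, the attribution of feature `i` is

* `normalized_eq3`: `(s_i − s̄_i) ∫₀¹ ∂F̂/∂s_i dα` — summing over features
  recovers `F̂(s) − F̂(s̄)` (completeness);
* `unnormalized_eq4`: the path-averaged gradient itself — smoother for
  sweep curves;
* `fraction_of_total`: the normalized attribution divided by the total, so
  contributions sum to exactly 1 (refused with an error when the total is
  0, e.g. at `s = s̄`). This is a distinct, explicitly named variant, not a
  silent replacement of the normalized form.

The integral is approximated by the trapezoidal rule over 100 path points
including both endpoints. The 100-point uniform sampling is the method's
stated convention; trapezoid (rather than a one-sided Riemann sum) is the
most accurate rule at fixed samples. Numerical caveat: a ReLU network is
piecewise linear, so the integrand is piecewise constant with kinks and the
discretization error decays like 1/n_steps rather than the faster rates
smooth integrands would give. On study-scale trained networks the measured
completeness gap at 100 steps is below 0.006 absolute; the tests assert
1e-2 absolute at 100 steps, 1e-3 at 1000 steps, and Cauchy shrinkage across
100/1000/10000 steps. Exactness for linear models (attribution
`w_i (s_i − s̄_i)`) is asserted to 1e-6.

For classification the differentiated quantity is the softmax probability
of the target class (consistent with reporting normalized prediction
weights); raw-logit attribution is available via `of = "logit"`. Gradients
come from the analytic contract where the family provides one (fcnn,
linear) and central finite differences (step 1e-3 on the standardized
scale) otherwise. Non-integer hypothetical fingerprints (a baseline with
`s10 = 0.5`, fractional aromatic counts in sweeps) are deliberately legal
model inputs.

## The conditional variational autoencoder

The encoder maps (fingerprint ⊕ energy) through two ReLU layers (64, 32) to
a mean and log-variance per latent dimension; the decoder maps (latent ⊕
energy) through two ReLU layers (32, 64) back to 46 outputs. The latent
dimensionality defaults to 2 so that the decoder input — latent plus the
energy condition — is 3-dimensional, reconciling the "3D vector" framing of
the architecture with the explicit energy concatenation; it is
configurable. The loss is reconstruction MSE plus `kl_weight` (default 1)
times `KL(N(μ, σ²) ‖ N(0, I))`, optimized with the reparameterization
trick; fingerprint columns and the energy condition are standardized with
training statistics stored in the model. "Generation at σ = 0" is
interpreted as decoding the latent mean `z = 0` with no sampling noise.
The decoder output is linear; counts are clipped at 0 only at report time,
so training gradients are unaffected. Default schedule: 200 epochs, batch
32, Adam 1e-3 (the acceptance study uses 120 epochs, which suffices for the
trend recovery it checks at this data size).

## Reproducibility and degenerate inputs

Every stochastic component (assembly, noise, tie-breaking, weight
initialization, shuffling, fold assignment, reparameterization noise) draws
from R's RNG seeded by an explicit argument, and each seeded entry point
restores the caller's RNG state. Degenerate inputs are handled explicitly:
empty SMILES lists give 0-row tables; header-only record files give empty
datasets; zero-variance targets warn; `x = baseline` gives all-zero
attributions and equal outputs; fraction-of-total with zero total is an
error, not NaN.

## Known limitations

* Digit 46 depends on the aromaticity model; toolkits disagree on exotic
  rings, so fingerprints are comparable only within one model (recorded in
  the metadata).
* The breaker pattern for *spatial conflict of aromatic hydrogen* (row 39)
  fires on any ortho-disubstitution, a coarse proxy for steric clash.
* The synthetic ground truth is nearly linear in the fingerprint by
  construction; it cannot probe how the models handle strongly non-additive
  real chemistry.
* Attribution signs and magnitudes are properties of the trained model and
  its training data. On synthetic models only the signs built into the
  generator are asserted; printed attribution values from externally
  trained models are format examples, not reproducible targets.
* The CVAE decodes *mean* profiles; it is not a molecular generator and
  cannot emit SMILES.
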