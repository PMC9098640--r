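---
title: "Footprinting-guided structure scoring: methods and modeling choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Footprinting-guided structure scoring: methods and modeling choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`hrpfscore` turns hydroxyl radical protein footprinting (HRPF/FPOP) mass
spectrometry intensities into per-residue protection factors, converts
those protection factors into predicted side-chain burial, and uses the
predictions to score and rank candidate protein structural models. This
vignette documents the underlying model, every tunable parameter with its
default and rationale, what the synthetic-data generator does and does not
emulate, and the numerically load-bearing implementation choices.

# The measurement model

## From intensities to residue-level oxidation

A peptide exposed to hydroxyl radicals acquires `k = 0, 1, 2, ...` oxygen
adducts. From the isotopologue peak areas `I_k` the **peptide-average
oxidation** is the intensity-weighted mean adduct count

$$P = \frac{\sum_k k\, I_k}{\sum_k I_k}.$$

Electron transfer dissociation (ETD) preserves side-chain oxidation sites,
so for each c- or z-series fragment ion the **ion oxidation fraction** is

$$f(\mathrm{ion}) = \frac{I_{ox}}{I_{ox} + I_{unox}},$$

with the convention `f(ion_0) = 0` for the empty ion. Differences between
consecutive ladder ions localize oxidation to the residue stretch between
them:

$$\mathrm{events}(i \leftarrow j) = \left[f(\mathrm{ion}_i) -
f(\mathrm{ion}_j)\right] \cdot P.$$

For a complete ladder the sum of per-residue events telescopes to
`f(last ion) * P`: total oxidation is conserved no matter how the ladder is
gapped. `fragment_ladder()` records which ions are absent (zero total
area); `residue_oxidation_from_ladder()` then attributes events to
multi-residue stretches spanning the gaps. c-series ions count from the
N-terminus, z-series ions from the C-terminus; both orientations reduce to
the same residue-level events.

Unlabeled controls carry background oxidation (sample handling,
electrospray). `background_subtract()` subtracts the mean control events
per residue stretch and dose, and flags (rather than silently clips)
negative corrected values.

## Dose response and protection factors

The effective radical dose of each shot is read from an internal adenine
dosimeter as the magnitude of its UV absorbance change, `x = |ΔA|`. At
zero dose there is no labeling, so the dose response is a **straight line
through the origin**. `fit_dose_response()` uses the closed form

$$\hat\beta = \frac{\sum x_i y_i}{\sum x_i^2}, \qquad
\mathrm{SE}(\hat\beta) = \frac{\sqrt{\mathrm{RSS}/(n-1)}}{\sqrt{\sum x_i^2}},$$

with a t-interval on `n - 1` degrees of freedom. All replicate points are
pooled into one regression (triplicates at each dose) rather than fitting
dose means: pooling uses all the information and the per-dose scatter then
feeds the slope uncertainty directly.

The **protection factor** compares the observed slope to the intrinsic
reactivity `R` of the free side chain:

$$\ln PF = \ln\!\left(\frac{R}{\hat\beta}\right).$$

High `lnPF` means the residue reacts much more slowly than the free amino
acid, i.e. it is buried. Non-positive slopes cannot be log-transformed and
are flagged `excluded`; when the slope confidence interval touches zero
the upper `lnPF` bound is reported as `Inf`.

Only residues whose oxidation chemistry is clean enough for quantitative
work are carried into modeling: the **modelable set** is
`r paste(hrpfscore::MODELABLE_RESIDUES, collapse = ", ")` (W, F, Y, H, L).
Methionine and cysteine are always excluded regardless of configuration —
their oxidation is dominated by non-footprinting pathways.

## Burial: the conical neighbor count

Burial of residue `i` is quantified by a **conical neighbor count**

$$NC_i = \sum_{j \ne i} D(d_{ij})\, A(\theta_{ij}),$$

where `d_ij` is the CB–CB distance, `θ_ij` is the angle between the
side-chain direction `CB_i − CA_i` and the inter-residue vector
`CB_j − CB_i`, and both weights are logistic switches:

$$D(d) = \frac{1}{1 + e^{(d - d_{1/2})}}, \qquad
A(\theta) = \frac{1}{1 + e^{s_a (\theta - \theta_{1/2})}}.$$

Neighbors beyond ~9 Å or behind the side chain contribute almost nothing,
so `NC` measures how much material sits *in front of* the side chain — the
direction a hydroxyl radical must come from. Glycine has no CB; a
**pseudo-CB** is constructed from the backbone N, CA, C frame
(`pseudo_cb()`), using a fixed linear combination of the local bond
directions scaled to the ideal 1.53 Å CA–CB length, so every residue gets
a well-defined side-chain direction.

Measured `lnPF` and model-derived `NC` are connected by an empirical
**calibration line** `NC = m · lnPF + b` (`fit_calibration()`,
`predict_nc()`). Predictions are clamped at zero — a negative neighbor
count has no physical meaning — and clamped rows are flagged.

## Scoring and ranking models

For each candidate model the per-residue deviation
`Δ_i = |NC_i^{model} − NC_i^{pred}|` feeds a negative logistic reward

$$s(\Delta) = \frac{-1}{1 + e^{(\Delta - d_0)/\tau}},$$

which saturates near −1 for good agreement and decays to 0 beyond the
midpoint `d_0`. The model score is

$$\mathrm{total} = \mathrm{base} + w \sum_i s(\Delta_i),$$

so more negative is better. `rank_and_select()` sorts ascending with a
lexicographic tie-break on model id; `merge_rescore()` puts a base set and
a perturbed ("mover") ensemble on one footing by rescoring everything with
the same rule. `kabsch_rmsd_ca()` (SVD-based optimal superposition, no
outlier rejection) and `funnel_report()` summarize how well the score
funnels toward low-RMSD models.

# Parameters

| Parameter | Default | Units | Where | Why this default |
|---|---|---|---|---|
| `dist_midpoint` | 9 | Å | `nc_params()` | CB–CB distance where a neighbor counts half; ~2 contact shells |
| `dist_steepness` | 1 | 1/Å | `nc_params()` | soft 2–3 Å switching window |
| `angle_midpoint` | `pi/2` | rad | `nc_params()` | neighbors in the forward hemisphere count |
| `angle_steepness` | `2*pi` | 1/rad | `nc_params()` | sharp cone edge: back-side neighbors contribute < 1% |
| `weight` (`w`) | 9.0 | — | `score_model()` | footprinting term dominates a flat base score without erasing it |
| `d0` | 4 | NC units | `hrf_residue_score()` | deviations beyond ~4 neighbor-equivalents stop discriminating |
| `tau` | 1 | NC units | `hrf_residue_score()` | reward transitions over ~±2 NC units |
| `conf_level` | 0.95 | — | `fit_dose_response()` | conventional interval; coverage verified by simulation |
| `top_n` | 20 | models | `rank_and_select()` | short list for expensive downstream refinement |
| `funnel_top_n` | 250 | models | `funnel_report()` | large enough for stable funnel statistics |
| `rmsd_cutoff` | 5 | Å | `funnel_report()` | near-native threshold for the reported fraction |
| `hist_bin` | 0.5 | Å | `funnel_report()` | half-open `[k·bin, (k+1)·bin)` histogram resolution |
| `residue_offset` | 0 | residues | run config | maps experiment numbering onto model numbering |

All NC parameters are carried in a `nc_params()` object so alternative
burial definitions can be swapped in without touching calling code.

# The synthetic-data generator

`make_toy_structure()` builds a deterministic antiparallel helix bundle
with ideal α-helix geometry (2.3 Å radius, 1.5 Å rise, 100°/residue),
short connecting loops, and two-residue extended terminal tails pointing
away from the fold so the chain termini are genuinely exposed, as real
termini tend to be. The fixed cycled sequence contains all modelable
residue types and glycine (to exercise the pseudo-CB path).

`simulate_labeling()` inverts the full analysis chain: from the structure
it computes true `NC`, maps it through the calibration line to true
`lnPF`, converts to dose-response slopes via the reactivity table, builds
per-dose, per-replicate residue events (plus background, plus optional
truncated Gaussian noise), folds them into complete z-ion ladders, and
emits isotopologue tables whose intensity-weighted mean equals the true
`P` exactly (binomial isotopologue shapes). With zero noise the pipeline
recovers slopes and `lnPF` to machine precision — that inversion is the
package's strongest self-check.

What the generator deliberately does **not** emulate: chromatographic or
ionization variability, isotope-pattern overlap and deconvolution, missed
cleavages, partial ETD ladders with co-eluting species, dosimeter reading
error, or oxidation-induced retention shifts. It validates the arithmetic
of the pipeline, not an instrument.

`make_decoys()` perturbs every atom with independent Gaussian noise of a
chosen σ and records both the pre- and post-superposition Cα RMSD to the
parent, giving decoy sets of controlled, known deviation.

# Numerical choices

- The through-origin slope and its standard error are computed in closed
  form; `lm(y ~ 0 + x)` is used only as an independent cross-check in the
  tests. Closed form is exact, transparent, and faster inside the
  per-residue loop.
- The Kabsch rotation uses base `svd()` with the determinant-sign
  correction to force a proper rotation; no iterative refinement is
  needed and no outlier rejection is performed, so reported RMSDs are
  global.
- `f(ion_0) = 0` is an exact convention, not an estimate: the empty ion
  carries no residues.
- Negative values produced by background subtraction or noise are
  *flagged*, never silently set to zero, except in `predict_nc()` where
  the zero clamp is a documented physical constraint (also flagged).
- Pipeline outputs are written with deterministic ordering and without
  timestamps, so a rerun over the same manifest is byte-identical — the
  `manifest.json` records package version, configuration, and MD5 sums of
  all inputs and outputs.

# Decisions on underdetermined points

Several aspects of a pipeline like this are conventions rather than
consequences, and are worth stating explicitly:

- **Control handling**: background is estimated as the mean of control
  replicates per residue stretch and dose, not by pairing each labeled
  replicate with one control. Pairing would propagate control noise into
  every labeled point; the mean is the lower-variance choice when controls
  are exchangeable.
- **Dosimetry convention**: the dose axis is the magnitude of the adenine
  absorbance change, `x = |ΔA|`, in absorbance units. Which wavelength the
  dosimeter is read at (260 vs 265 nm) is metadata that does not enter the
  computation.
- **Pooled calibration**: the `lnPF`-to-`NC` line is fit once on all
  calibration residues rather than per residue type. Per-type fits would
  be better only with far more calibration points than a typical
  experiment provides.
- **Problem sizes in examples and tests** (64-residue toy fold, 500-decoy
  sets) are this package's own validation choices, selected to run in
  seconds on one CPU while leaving no statistical ambiguity in the
  enrichment checks.
- The command-line interface (`inst/cli/hrpf.R`) is a thin `Rscript`
  wrapper over the exported stage functions: every subcommand is one
  function call, so the CLI adds no behavior of its own and needs no
  separate testing of the science.

# A minimal end-to-end run

```{r, eval = FALSE}
library(hrpfscore)

toy <- make_toy_structure(48)
dir <- tempfile()
sim <- simulate_labeling(toy, simulation_spec(seed = 7), dir)

writeLines(c(
  "inputs:",
  "  isotopologues: isotopologues.csv",
  "  fragments: fragments.csv",
  "  doses: doses.csv",
  "  sequence: sequence.csv",
  "  reactivity: reactivity.csv",
  "  calibration: calibration.csv",
  "  models: structure.pdb",
  "seed: 7",
  paste0("out_dir: ", file.path(dir, "out"))),
  file.path(dir, "run.yaml"))

cfg <- read_run_config(file.path(dir, "run.yaml"))
run_pipeline(cfg)
read.csv(file.path(dir, "out", "scores.csv"))
```
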