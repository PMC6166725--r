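---
title: "Methods: quantifying PPIase substrate recognition and catalysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying PPIase substrate recognition and catalysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppiasekit)
```

## Scope and scientific setting

Ribosome-associated chaperones of the trigger-factor family combine a
general substrate-binding activity with a peptidyl–prolyl cis/trans
isomerase (PPIase) domain. The questions this package quantifies are:
*which* stretches of an unfolded substrate the chaperone recognises
(sequence hydrophobicity and NMR titration mapping), *how fast* the
prolyl bond interconverts on the catalytic domain (CPMG relaxation
dispersion), *how* the catalytic geometry develops as the ω torsion is
driven from trans toward cis (a kinematic torsion scan with
hydrogen-bond tracking), and whether the measured binding
thermodynamics are internally consistent.

Each analysis stage has a synthetic-data generator with known ground
truth, so every downstream claim the package makes is testable without
experimental spectra. This vignette records the models, the defaults
and why they were chosen, the numerical decisions, and the limits of
what the synthetic route can show.

## Hydrophobicity profiling and the proline-aromatic motif

`hydrophobicity_profile()` computes a centred sliding-window mean of a
per-residue hydrophobicity scale. The built-in scale is Roseman's
(1988) side-chain scale (kcal/mol, positive = hydrophobic), the
conventional choice for profiling unfolded chains; the scale is an
ordinary named vector and can be swapped for any other, since the
profile is used only through its sign and ordering. The default window
of 9 residues matches the length scale of chaperone recognition
elements. Terminal positions where the window does not fit are
*undefined* (`NA`), never zero-filled and never computed from a
shrunken window — shrinking would silently bias the termini toward
their own composition.

`hydrophobic_stretches()` reports maximal runs of defined positions
with score above a threshold (default 0: the scale's own sign
convention). `scan_proline_aromatic()` then reports every proline with
an immediately adjacent aromatic residue. The default aromatic
alphabet is {W, F, Y, H}: tryptophan and tyrosine pairs are the
directly observed recognition elements, histidine occurs in known
PPIase substrates, and phenylalanine is included as a conservative
generalisation; the alphabet is an argument, and hit counts are
monotone non-increasing as it is restricted (a tested invariant).

## Titration mapping

Binding of a large chaperone to an unfolded substrate in fast exchange
broadens the substrate's amide resonances; residue-wise intensity
ratios I/I₀ between a titration point and the free reference therefore
map the binding site. The combined chemical shift perturbation is

Δδ = √(Δδ_H² + (Δδ_N/5)²),

with the conventional 1/5 nitrogen scaling; `classify_csp()` buckets
values at 0.015 and 0.025 ppm (the mapping thresholds, configurable).
CSP and intensity analyses are deliberately kept separate: small
binding domains give mostly shift changes, large ones mostly
broadening, so the two observables carry different information.

`call_binding_sites()` implements the run-length rule: a binding site
is a continuous stretch of **more than four** (≥ 5) scoreable residues
with significant intensity reduction. Two significance rules are
provided because "significant" admits two natural readings:

* `"mad"` (default): I/I₀ < median − k·MAD with k = 2. Robust to
  global effects (dilution, uniform broadening) that shift the whole
  profile, which is the main artefact across titration points.
* `"fixed"`: an absolute cutoff (default 0.7), which is monotone in
  the threshold and easier to reason about; the monotonicity (relaxing
  the cutoff never removes called residues) is a tested invariant.

Prolines have no backbone amide and unassigned residues no usable
peak; by default such residues *bridge* a run without counting toward
its length — prolines sit visibly inside real binding sites, and
breaking runs at every proline would veto exactly the sites this
analysis exists to find. A strict no-bridge mode is available.
Site calling is done per titration point, with the final (largest)
point used by the pipeline, since the contrast is strongest there.

`compare_preference()` turns per-site mean reductions under two
conditions into a ranked preference report, reflecting that the extent
of broadening at substoichiometric titrant reports on binding
preference.

### What the titration generator emulates

`generate_titration()` draws per-residue peak tables under a
single-site fast-exchange model: at titrant:substrate ratio r the
bound fraction f_b follows the exact binding quadratic with
dissociation constant K_d (default 47 μM, the measured chaperone
construct–substrate affinity; substrate at 100 μM, a typical NMR
concentration), and

I/I₀ = R₂_free / (R₂_free + f_b · depth · ΔR₂_max),

with R₂_free = 10 s⁻¹ and ΔR₂_max = 200 s⁻¹ by default — a free-state
linewidth typical of an unfolded chain and a bound-state broadening
large enough that a full-depth site loses most of its intensity at the
upper titration points, as observed experimentally. Multiplicative
Gaussian noise (default 2%) models peak-height measurement error.
CSPs grow linearly in f_b toward a per-site maximum.

The generator does **not** emulate: exchange-regime crossover
(slow-exchange doubling of peaks), baseline distortions, peak overlap,
or sequence-dependent relaxation. Recovery benchmarks on this
generator therefore demonstrate the correctness of the calling logic
(run-length rule, bridging, significance thresholds) under realistic
noise — not robustness to spectral artefacts, which enter upstream of
the peak-table level where this package begins.

## CPMG relaxation dispersion

For two-state exchange that is fast on the chemical-shift timescale,
the effective transverse relaxation rate measured in a constant-time
CPMG experiment follows the Meiboom form

R₂eff(ν) = R₂⁰ + (Φ/k_ex)·[1 − (4ν/k_ex)·tanh(k_ex/4ν)],

with Φ = p_a·p_b·δω². Only R₂⁰, k_ex and Φ are identifiable; the
populations and shift difference inside Φ are not separable, and the
package never reports them individually. `r2eff_from_intensities()`
converts intensities via −ln(I/I₀)/T_relax with T_relax = 50 ms by
default.

`fit_dispersion()` performs weighted least squares with
Levenberg–Marquardt steps under bounds (R₂⁰ ∈ (0, 100], k_ex ∈
(0, 10⁵], Φ ≥ 0), multi-started over k_ex ∈ {50, 200, 740, 2000, 5000}
s⁻¹ because the model is weakly identifiable at fast exchange; the
initial Φ is the observed dispersion amplitude times k_ex, floored so
the Jacobian cannot be singular on flat data. A bounded quasi-Newton
fallback covers starts where the LM step fails. Model selection
against the flat (no-exchange) fit uses an F-test at α = 0.05: with the
Φ ≥ 0 boundary this test is conservative, and the measured type-I rate
over 200 seeded flat curves is ~3%. Parameter uncertainties come from
the fit covariance by default, with a seeded residual-resampling
bootstrap as an alternative.

A note on precision: with a single 16-point curve in [25, 1000] Hz and
0.3 s⁻¹ noise at these parameter scales, the Cramér–Rao bound puts the
attainable relative standard deviation on k_ex near 23%; the fitter's
bootstrap spread matches that bound, i.e. it extracts essentially all
the information the curve contains. Tighter estimates require more
points, replicate curves, or multi-field data, not a different
optimiser.

`regime_check()` converts an expected δω (ppm) to Hz at the nucleus
frequency (¹⁵N ratio 0.101329 by default, 800 MHz field) and compares
it with k_ex. Both the angular convention (fast iff k_ex ≥ 2π·δν) and
the direct Hz-versus-s⁻¹ comparison are implemented as modes; the
literature uses both and neither is asserted as canonical here.

## The kinematic ω-torsion scan

The cis/trans transition itself is too slow for unbiased simulation,
so the canonical computational protocol drives the ω restraint center
in small steps. This package re-implements the *kinematics* of that
protocol — not the force field. `torsion_schedule()` describes a drive
from −174° (trans) to 0° (cis) at 0.2° per 2 ps window;
`build_schedule()` expands it to window centers and times. Direction
semantics are anchored operationally: the clockwise path is the
174°-arc through −90° (the twisted *syn* geometry), giving 870 windows
= 1.74 ns and reaching −90° at 0.84 ns; counterclockwise is the
complementary 186° arc through ±180°, 930 windows = 1.86 ns. The
restraint force constant (50 kcal·mol⁻¹·rad⁻²) is carried as metadata
only: the kinematic scan sets ω *exactly* to each center, whereas a
restrained simulation fluctuates thermally about it — that fluctuation
is a force-field phenomenon and out of scope here.

`generate_peptide_scan()` builds an idealized all-trans backbone
(N–Cα 1.46 Å, Cα–C 1.52 Å, C–N 1.33 Å, C=O 1.23 Å, sp² angles; any
internally consistent set would do, as only relative geometry is
analysed) and emits one model per window by rigid rotation of the
N-terminal segment about the peptide C–N bond, plus the initial
structure. `rotate_segment()` is an exact isometry on both the moving
and fixed sets (tested to 10⁻⁶ Å), and the measured ω
(`measure_omega()`, the standard four-atom dihedral in (−180°, 180°])
changes by exactly the applied delta.

Hydrogen-bond criteria: `classify_hbond()` calls a bond *strong* iff
the H···O distance is below 2.5 Å **and** the N–H···O angle is at
least 130°. The distance cutoff is the standard strong-hydrogen-bond
criterion; published strong-bond angle criteria vary, so the angle
threshold is configurable — note that the reference trans-state
geometry (4.3 Å, 134°) is excluded by the distance term alone at any
plausible angle threshold, while the syn-state geometry (2.1 Å, 152°)
classifies strong throughout [130°, 152°].

The default probe placement deserves a comment. The acceptor carbonyl
oxygen rides a circle of radius ≈ 1 Å about the C–N axis, so its
approach to any fixed probe is smooth: with the probe meeting the
oxygen at −90° at a closest approach of 2.2 Å (default), the 2.5 Å
contour is crossed some tens of windows before the contact window.
The tracker therefore reports both the first strong frame and the
closest-approach frame; the latter coincides with the contact window
by construction, and the former is validated in the tests against an
independent closed-form solution of the circle geometry. A
knife-edge first-contact exactly at −90° would require a closest
approach indistinguishable from 2.5 Å and was rejected as numerically
fragile and physically meaningless.

Coordinates are exchanged as standard multi-model PDB. The fixed
format quantises coordinates to 0.001 Å, which limits torsions
re-measured after a file round trip to ≈ 0.05°; analyses that need
exact angles should operate on the in-memory ensemble, which is exact
to machine precision.

## Binding thermodynamics

`dg_from_kd()` applies ΔG = RT·ln(K_d/1 M) with R = 1.987×10⁻³
kcal·mol⁻¹·K⁻¹ and a default temperature of 295.15 K (22 °C, the
calorimetry temperature); `entropy_term()` gives −TΔS = ΔG − ΔH, and
`check_consistency()` verifies both identities against stated
tolerances (defaulting to 0.1 kcal/mol, a typical printed error bar).
Raw isotherm fitting is out of scope: printed calorimetric parameters
are taken as inputs.

## Pipeline, reproducibility and problem sizes

`run_pipeline()` runs simulate → profile → titrate → cpmg-fit →
torsion-scan → thermo from a single validated config (unknown keys are
rejected before any stage runs), writes per-stage TSV/JSON outputs and
a manifest echoing every seed and threshold; a rerun from the same
config is byte-identical, a tested property. All generator randomness
flows through one seeded RNG per spec, isolated from the caller's RNG
state.

The test suite's simulation sizes are chosen to exercise the
statistics at desk scale: 100 seeded titrations (60-residue
substrates, two planted sites each) for the site-recovery benchmark,
50 noisy dispersion curves for parameter-recovery and coverage
checks, and 200 flat curves for the type-I control. The full suite
runs in well under a minute.

## Known limitations

* The titration generator starts at the peak-table level; no spectral
  simulation, overlap or assignment errors.
* The dispersion module commits to the fast-exchange Meiboom model; no
  general two-site (slow/intermediate) treatment is provided, so data
  outside the fast regime should be flagged by `regime_check()` rather
  than force-fitted.
* The torsion scan is kinematic: no energies, no solvent, no thermal
  fluctuation about the restraint center, and consequently no claim to
  reproduce simulated distance traces — only schedule bookkeeping,
  rotation geometry and classification logic.
* Sequence profiling treats residues independently; no structural
  context beyond the window mean.
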