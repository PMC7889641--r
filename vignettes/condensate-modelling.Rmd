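---
title: "Modelling salt-dependent protein condensation with condensr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling salt-dependent protein condensation with condensr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(condensr)
```

## The scientific problem

Many proteins that form liquid condensates at low ionic strength (FUS,
TDP-43, Brd4, Sox2, annexin A11) dissolve at intermediate salt and then
*re-enter* a phase-separated state above roughly 1.5 M salt.  The two
regimes are mechanistically distinct: at low salt, condensation is
stabilized by electrostatic attraction and cation–π contacts on top of
hydrophobic interactions; at high salt, charges are screened out and the
condensate is held together almost entirely by hydrophobic and π-driven
non-ionic contacts.  Arginine-rich peptides such as PR25 (13 Arg and 12
Pro, strictly alternating) show the complementary behaviour: Arg–Arg
repulsion prevents homotypic LLPS at low salt, while screening plus a
salting-out strengthening of Pro/aromatic contacts induces it at high
salt.

`condensr` implements the computational arm of this picture as a tested,
reusable pipeline: a residue-per-bead coarse-grained condensate model
whose electrostatic/hydrophobic balance is switched by salt-regime
presets, direct-coexistence slab simulations and their density/critical
analysis, a WHAM layer for umbrella-sampling pair free energies, contact
and droplet-morphology metrics, and synthetic-data generators that stand
in for cluster-scale MD and wet-lab inputs.

## The model

Each residue is one bead with mass, charge, diameter σ and
hydrophobicity λ ∈ [0, 1] taken from the HPS (hydrophobicity-scale)
parameter set; the bundled table (`load_residue_params()`) is the
Kapcha–Rossky-derived set standard for this model family.  Chains are
flexible polymers with harmonic bonds (r0 = 0.38 nm, k = 1000 kJ mol⁻¹
nm⁻²); residues annotated as globular are treated approximately as rigid
by (a) the 30% hydrophobicity scale-down for buried residues (each
buried residue's λ is multiplied by 0.7 before pair averaging) and (b) a
stiff elastic network (k = 500 kJ mol⁻¹ nm⁻², springs between region
neighbours within 0.9 nm of the initial configuration) instead of true
rigid-body integration.  This preserves the energetic role of folded
domains at desk scale; it does not preserve their exact geometry, which
is a known approximation.

Nonbonded pair energies have three terms, each truncated and shifted to
zero at its cutoff:

* **Ashbaugh–Hatch hydrophobic term.**  With LJ(r) = 4ε[(σij/r)¹² −
  (σij/r)⁶], σij the arithmetic mean and λij = `hydro_scale` · (λi +
  λj)/2:  Φ = LJ + (1 − λij)ε for r ≤ 2^(1/6)σij, else λij·LJ.  ε = 0.2
  kcal/mol (0.8368 kJ/mol).  λ = 0 gives a purely repulsive core; λ = 1
  the full LJ well.  Cutoff 2.0 nm.
* **Debye–Hückel electrostatics.**  χ · qiqj e²/(4πε0εr r) ·
  exp(−r/λD), with relative permittivity 80 and Debye length λD.  The
  multiplier χ emulates the salt regime (see below).  Cutoff
  3.5·λD, capped at 3.5 nm.
* **Cation–π well.**  An extra Lennard-Jones well of depth
  `cation_pi_eps` (default 6 kJ/mol) at σij, applied only to {R,K} ×
  {F,W,Y} pairs, switched on only in the low-salt preset.

### Salt-regime presets

Physical Debye–Hückel theory is not valid at molar salt, so salt is
modulated the way the source model does it: by scaling the terms, not by
shrinking λD (the default λD is 1.0 nm in every regime and is
configurable).  `apply_regime()` encodes:

| regime | χ | hydro_scale | cation–π |
|---|---|---|---|
| low      | 4 | 1.0 | on (6 kJ/mol) |
| moderate | 2 | 1.0 | off |
| high     | 1 | 1.1 (FUS-like) / 1.3 (PR25-like) | off |

The cation–π depth is the one deliberately free parameter of the model:
its published form is not reprinted in the source material, so it is a
configuration knob whose default is set to preserve the qualitative
critical-temperature ordering of full FUS above its PLD at low salt.

## Dynamics

`langevin_run()` integrates BAOAB-discretized Langevin dynamics (chosen
over plainer schemes for its configurational accuracy at large time
steps) with dt = 10 fs, thermostat relaxation time 5 ps, per-bead masses
from the parameter table, and minimum-image periodic boundaries.  A
stability guard refuses dt above a tenth of the stiffest spring period,
and an instability detector aborts on per-step displacements above σ/2.
Runs are exactly reproducible for a fixed seed (the thermostat noise
stream is a private 64-bit Mersenne Twister, independent of R's RNG) and
net momentum is re-zeroed periodically so the slab does not drift
ballistically.  `npt_equilibrate()` provides an optional Berendsen
weak-coupling stage; by default slabs are instead built directly at a
target dense density by `init_slab()` (self-avoiding random walks in the
central quarter of an elongated box, followed by a short
capped-displacement steepest descent to remove core overlaps), which
produces the same NVT coexistence ensemble without barostat fragility at
small system size.

## Slab analysis

`density_profile()` recentres every frame with the circular-mean
construction for periodic coordinates before binning, so interface
smearing from slab drift cancels; total mass is conserved exactly by
construction.  `coexistence_densities()` fits the symmetric double-tanh
step and falls back (flagged) to central/outer 20% averages if the fit
fails.  `classify_llps()` calls LLPS when ρ_dense/ρ_dilute ≥ 10
(inclusive), with a 10⁻³ mg/mL floor on the dilute density.
`fit_critical_point()` fits Δρ = A(1 − T/Tc)^β with the 3D Ising β =
0.325 (fixed, overridable) jointly with the law of rectilinear
diameters; for fixed Tc both laws are linear, so Tc is profiled by a 1-D
search.  Its confidence interval is a *basic* (reflected) bootstrap over
points — in a coverage study at 2% density noise the percentile interval
undercovered (≈0.86) while the basic interval reached ≈0.91, a known
property of skewed small-sample estimators.

## WHAM

`wham_solve()` is the standard self-consistent weighted-histogram
estimator on a uniform grid (default 0.005 nm) with tolerance 10⁻⁷
kJ/mol on window free energies, oscillation-triggered damping (0.5), a
default burn-in of the first 10% of each window (mirroring the dropped
first nanosecond of the reference protocol), and the reference-zero
convention "mean over the largest 10% of the grid" (pair PMFs plateau to
zero at large separation).  Windows whose sampled ranges do not form one
connected union are refused with an island listing, because WHAM cannot
tie the free energies of disconnected islands.  No Jacobian/entropic
correction is applied to the 1-D coordinate: the emulated protocol
restrains lateral motion, making the coordinate effectively
one-dimensional.  `bootstrap_pmf()` implements the Bayesian bootstrap:
whole windows are reweighted by Dirichlet(1,…,1) weights and WHAM is
re-solved per replicate (default 200; the reference protocol does not
print its count).

## Synthetic data: what it emulates and what it does not

The generators define the study conditions for the tests:

* `toy_pair_potential()` encodes only the *qualitative* salt trends of
  atomistic pair PMFs — screened-Coulomb term with the physical Debye
  length plus a Gaussian hydrophobic well deepening linearly with salt,
  wells of order −2 to −14 kJ/mol.  They are deliberately not fits to
  any published curves.
* `sample_umbrella_windows()` performs exact Metropolis sampling of the
  biased Boltzmann density (64 parallel chains, thinned ×5), with the
  reference protocol's defaults: ~31 windows, 0.05 nm spacing over
  0.1–1.6 nm, k = 6000 kJ mol⁻¹ nm⁻².
* `synth_coexistence_points()` draws from the critical scaling law
  itself and is the closed-loop oracle for the critical fit.
* `synth_droplet_mask()` rasterizes non-touching disks with smooth
  low-order boundary perturbations — it emulates segmented fluorescence
  masks, not raw micrographs (no illumination gradients, no touching
  droplets, no segmentation errors).

Passing tests against these generators therefore validate the
*analysis machinery* under known ground truth; they do not validate the
coarse-grained model against wet-lab data, which at full scale requires
cluster-size simulations.

## Desk-scale study design

The published direct-coexistence systems (24 full-length FUS chains ≈
12,600 beads, 400 PR25 peptides = 10,000 beads, ~2.5 μs) are
cluster-scale.  The package's own benchmark, used by the acceptance
tests, is scaled to a desktop while keeping the physics:

* **FUS-like system:** 10 chains of the 50-residue Arg/Tyr-rich model
  sequence ("SYGRGYSGYR" × 5; 20% Arg, 30% Tyr, no anions) in a 5 × 5 ×
  20 nm box, ~1–2 ns per condition.  The cation-only charge pattern
  mirrors the RGG/PLD composition that makes FUS's moderate-salt regime
  its least cohesive: halving χ removes Arg–Arg repulsion *and* the
  cation–π attraction disappears, so the reduced-electrostatics preset
  melts the slab, while the 10% hydrophobic up-scaling restores
  cohesion.  A charge-balanced sequence would instead gain net ionic
  attraction from χ and invert the regime ordering.
* **PR25 system:** 20–50 chains of the exact 25-mer in the same
  geometry, at a lower temperature (the peptide's critical temperature
  is roughly half that of FUS-like chains, as in the reference systems:
  200 K vs 400 K).  The high-salt condition additionally sets the
  screening length to the physical Debye length at 2.7 M salt (0.2 nm):
  a peptide carrying a net +13 charge at desk scale otherwise retains
  unscreened molar-regime Coulomb repulsion that the χ-scaling device
  alone cannot remove, and the benchmark's point is precisely that at
  high salt those charges are screened out.  The low-salt condition
  keeps the default 1.0 nm.
* Simulation temperatures for LLPS calls are chosen between the
  regimes' apparent critical temperatures, following the reference
  protocol of simulating just below the critical temperature of the
  condensing conditions.
* LLPS calls are majority votes over 3 seeds; single-seed calls are
  flagged low-confidence.

At this scale the apparent critical temperatures carry finite-size
shifts of order 10%, interfaces occupy a large fraction of the slab, and
dilute-phase densities are noisy; the pipeline therefore asserts *sign
and ordering* (which condition phase-separates), never the printed
critical-temperature percentages of the full-scale study.

## Numerical choices and degenerate inputs

* Shifted truncation (no tail corrections) keeps energies continuous at
  the cutoffs; the AH term is continuous at 2^(1/6)σij by construction
  and the tests assert both to tight tolerance.
* `init_slab` enforces a minimum inter-bead distance of 0.7·min σ and
  fails with a clear message when the requested density cannot be
  placed within the retry budget.
* WHAM on a single window with vanishing bias reduces exactly to the
  log-histogram; zero-count grid points carry +Inf free energy and are
  excluded from reference averaging.
* Droplet perimeters use an ordered boundary trace smoothed with a
  circular (1,2,1) filter plus the half-pixel convex offset (+π):
  pixel-edge counting would overestimate disk perimeters by ~5% and push
  even perfect disks below the 0.95 circularity level reported for real
  condensates.  The estimator is calibrated on analytic disks (≈0.98 for
  r ≥ 10 px, scale-consistent within 0.01) and squares (≈π/4) in the
  shipped tests.  Circularity is clipped at 1.
* Droplets under 5 px are discarded; touching droplets are not split
  (no watershed), matching the generator's non-touching contract.

## Known limitations

* No explicit ions or solvent; the temperature-independent permittivity
  and regime-χ construction are effective-model devices, not physical
  electrolyte theory at molar salt.
* Globular domains are elastic networks, not rigid bodies.
* No finite-size scaling corrections, interfacial tension, MBAR, 2-D
  WHAM, or autocorrelation-aware effective sample sizes.
* Mixed chain species per box are supported but untested against any
  reference system; single-species boxes are the default.
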