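# condensr

Coarse-grained simulation and analysis of salt-dependent protein
liquid–liquid phase separation (LLPS) in R.

Proteins such as FUS condense at low ionic strength, dissolve at
intermediate salt, and re-enter a phase-separated state above ~1.5 M —
a reentrant transition driven at high salt by hydrophobic and non-ionic
(π-driven) interactions rather than electrostatics.  Arginine-rich
peptides like PR25 show the mirror image: Arg–Arg repulsion blocks
homotypic LLPS at low salt, and screening plus salting-out induces it at
high salt.  `condensr` is for computational biophysicists who want a
tested, desk-scale pipeline for this physics: a residue-per-bead
condensate model with salt-regime interaction scaling, slab
direct-coexistence simulations, and the surrounding analyses.

## The model

One bead per residue (HPS parameter set: mass, charge, diameter σ,
hydrophobicity λ).  Nonbonded pair energy between residues *i*, *j* at
separation *r*:

* Ashbaugh–Hatch hydrophobic term, with LJ(r) = 4ε[(σij/r)¹² − (σij/r)⁶]:

      Φ(r) = LJ(r) + (1 − λij)·ε   for r ≤ 2^(1/6)·σij
      Φ(r) = λij·LJ(r)             otherwise

  where λij = hydro_scale · (λi + λj)/2 and ε = 0.2 kcal/mol.
* Screened electrostatics: χ · qiqj·e²/(4πε0εr·r) · exp(−r/λD).
* An optional cation–π Lennard-Jones well on {R,K} × {F,W,Y} pairs.

Salt regimes are interaction-scaling presets (`apply_regime()`): low
salt = χ 4 with cation–π on; moderate = χ 2, cation–π off (reduced
electrostatics); high = χ 1 with the hydrophobic term scaled up 10%
(FUS-like) or 30% (PR25-like).  Dynamics are BAOAB Langevin (dt 10 fs,
friction time 5 ps) in periodic elongated boxes; coexistence densities
come from double-tanh fits of recentred axial density profiles; critical
points from Δρ = A(1 − T/Tc)^0.325 plus the law of rectilinear
diameters.  A WHAM solver with Bayesian-bootstrap errors reconstructs
umbrella-sampling pair free-energy profiles, and contact-map /
droplet-morphology metrics cover condensate structure.

## Worked example

A reduced direct-coexistence run for the PR25 peptide at high salt
(χ = 1, hydrophobicity +30%), 20 chains in a 5 × 5 × 20 nm box:

```r
library(condensr)
hps  <- load_residue_params()
pr25 <- build_topology(make_sequence("PR25"), name = "PR25")
# chi = 1, hydrophobicity +30%, screening length at its 2.7 M value
scal <- apply_regime("high", "pr_like", temperature = 160,
                     debye_length = 0.2)

state <- init_slab(pr25, 20, c(5, 5, 20), hps, rng_seed = 1)
traj  <- langevin_run(state, scal, temperature = 160,
                      n_steps = 1e5, thin = 2000, rng_seed = 1)
prof  <- density_profile(traj, equil_fraction = 0.5)
pt    <- coexistence_densities(prof)
c(dense = pt$rho_dense, dilute = pt$rho_dilute,
  llps = classify_llps(pt))
```

```
##      dense     dilute       llps
## 845.987035   6.402631   1.000000
```

A dense slab of ~850 mg/mL coexisting with a nearly empty dilute phase
(density ratio ~130, far above the LLPS threshold of 10) — the peptide
phase-separates under the high-salt scaling.  The same call with
`apply_regime("low", "pr_like")` and the default screening length
leaves a density ratio near 1 (no LLPS): screened-out electrostatics
plus strengthened Pro/aromatic attraction, not charge attraction, drive
PR25 condensation.

Inter-chain contacts at the 0.65 nm cutoff and droplet shape metrics:

```r
cm <- interchain_contacts(traj, cutoff = 0.65, equil_fraction = 0.5)
mask <- synth_droplet_mask(c(12, 25), image_size = c(160, 160))
droplet_morphology(mask$mask)
```

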