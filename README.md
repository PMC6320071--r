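# tweezerfold

Analysis of two-state protein folding in dual-trap optical tweezers
experiments, built for the geometry in which a protein (or protein complex)
is tethered between two trapped beads through a 2,260-bp DNA handle — the
"dumbbell" assay used to dissect chaperoned SNARE assembly, and in
particular the Munc18-1:syntaxin-1:VAMP2 *template complex*, the
intermediate in which the SM-family chaperone aligns the N-terminal halves
of the two SNARE motifs before SNAP-25 completes zippering.

The package is aimed at single-molecule biophysicists who record
extension-time trajectories at constant trap separation and want to go from
raw traces to zero-force folding energetics, structural interpretation and
downstream kinetic predictions, with every stage testable against a
synthetic-data generator whose ground truth is known exactly.

## What it computes

**Polymer mechanics.** Both the DNA handle (persistence length 40 nm) and
the unfolded polypeptide (0.6 nm) are worm-like chains with the
Marko–Siggia interpolation

F(x) = (kBT/P) [ 1/(4(1 − x/L)²) + x/L − 1/4 ],

with its exact entropic-energy antiderivative and a vectorised numerical
inverse. Contour lengths convert to residue counts at 0.365 nm per amino
acid.

**Dumbbell equilibrium.** At relative trap separation D the series
force balance D = F/k₁ + F/k₂ + x_DNA(F) + x_p(F) + H is solved per
conformational state (unfolded contour L_p, hard core H), and the total
free energy is G = F²/(2k_traps) + E_DNA + E_p + V.

**Trajectory idealization.** Two-state hidden Markov model with Gaussian
emissions, EM-fitted and Viterbi-decoded (Rcpp backend), yielding dwell
times, occupancies, per-state forces and the transition extension change.

**Landscape fits.** The zero-force unfolding energy ΔV comes from a
one-parameter Boltzmann fit of occupancy versus trap separation through the
full dumbbell model; zero-force folding/unfolding rates and the transition
state come from a Kramers-type fit of the force-dependent rates. Midpoint
(equilibrium) force is interpolated at equal population.

**Structural inference.** Measured extension changes convert to contour
changes and sequestered residue counts under the hard-core convention.

**Binding kinetics.** The tethered-ligand effective concentration
c = (1/N_A)(3/(4πpL))^{3/2} exp(−3R²/(4pL)) feeds the affinity chain
k_on = k_f/c, K_d = k_off/k_on, ΔG_bind = ln(1 M/K_d), and the relative
fusion-rate predictor k_m/k_WT = (r_m/r_WT) exp(G_m − G_WT) scores a
shipped table of template-complex variants.

**Synthetic data.** Gillespie-simulated two-state trajectories and
constant-speed pulling curves whose rates obey detailed balance with the
dumbbell free energy, plus an exact-discretisation Ornstein–Uhlenbeck
bead-noise generator for trap-stiffness calibration by (aliasing-corrected)
Lorentzian power-spectrum fitting.

## Worked example

Simulate a wild-type force scan (eight separations spanning 4.0–6.5 pN,
100 s each at 1 kHz, 1.5 nm noise) and recover the landscape:

```r
library(tweezerfold)

scen  <- wt_template_scenario()          # calibrated WT study conditions
seps  <- separation_for_mean_force(scen, seq(4.0, 6.5, length.out = 8))
trajs <- lapply(seq_along(seps), function(i)
  simulate_constant_separation(scen, seps[i], 100, seed = 100 + i))

fit <- fit_landscape(trajs, scen$state_folded, scen$state_unfolded,
                     scen$traps, scen$handle)
fit
#> <landscape_result> dV = 5.17 +/- 0.03 kBT, F_eq = 5.08 pN, dx = 5.38 nm,
#>   k_f0 = 125 /s, k_u0 = 0.714 /s (8 records)
```

The generating truth was ΔV = 5.2 kBT, midpoint 5.1 pN, Δx = 5.42 nm,
k_u0 = 0.7 s⁻¹ (lifetime 1.4 s): each quantity is recovered within its
expected statistical scatter. The affinity chain and mutant predictions are
plain arithmetic on measured rates:

```r
c_eff <- effective_concentration(tethered_ligand(contour_from_residues(54), 6.34))
dissociation_chain(0.7, intramolecular_kon(132, c_eff))
#>         kd_M binding_energy_kbt
#> 1 0.00000197               13.1

pred <- predict_fusion_rates(template_complex_params())
pred[pred$mutation %in% c("WT", "P335A", "D326K", "L348R"), ]
#>   protein  mutation fold_change fold_change_sd abolished
#> 1 -        WT              1             0.141 FALSE
#> 2 Munc18-1 D326K           5.24          1.17  FALSE
#> 3 Munc18-1 P335A           2.86          0.905 FALSE
#> 4 Munc18-1 L348R          NA            NA     TRUE
```

So the tethered VAMP2 ligand sees an effective ~0.37 mM concentration of
its binding pocket; the inferred bimolecular affinity is K_d ≈ 2 µM
(13.1 kBT), and the stabilising Munc18-1 mutations P335A and D326K are
predicted to speed overall membrane fusion ~2.9- and ~5.2-fold, while a
destabilising mutation with no detectable template complex is reported as
abolished rather than given a number.

`autoplot()` methods are provided for idealized traces and both fit
objects, and `tidy()`/`glance()` return tibble summaries throughout.

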