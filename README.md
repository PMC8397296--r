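# nanosite

Trajectory analysis for Zn(II)-TACN gold nanozymes — monolayer structure,
transient two-metal-ion catalytic sites, and model-free NMR relaxation.

## The scientific problem

Gold nanoparticles coated with thiols that end in a Zn(II)-chelating
1,4,7-triazacyclononane (TACN) crown hydrolyse RNA-model phosphodiesters
(HPNP) the way two-metal-ion enzymes do: catalysis happens when two chelated
Zn ions transiently come close enough (≤ 0.50 nm) to form a *bimetallic
site*, and when substrate oxygens coordinate the Zn ions in defined
*precatalytic* geometries. These sites are dynamic — they form, persist for
picoseconds to nanoseconds, and dissolve — so explaining why one ligand
chemistry out-catalyses another requires statistics over molecular-dynamics
trajectories, not a single structure.

`nanosite` implements that analysis as a reusable, tested R pipeline:

- **Monolayer descriptors** — radial distribution functions and cumulative
  coordination numbers around the gold core, per-atom RMSF after core
  superposition, rotational (P2) autocorrelation of bond vectors, radius of
  gyration, inertia-tensor eccentricity, hydrogen bonds (0.35 nm / 30°
  criterion), close contacts (e.g. Zn···Cl within 0.25 nm), and solvent-shell
  counts.
- **Bundles** — groups of ≥ 3 coating ligands simultaneously interconnected
  by interligand C=O8···H–N9 hydrogen bonds, found as connected components of
  the per-frame HB graph.
- **Events** — per-frame detection of Zn–Zn pairs (cutoff 0.50 nm), mono- and
  bimetallic substrate binding (O–Zn ≤ 0.25 nm), and precatalytic complex
  types 1–3, segmented into maximal contiguous events with existence times;
  population decay `N(t) = N0·exp(−λt)` fitted by nonlinear least squares
  with λ in ns⁻¹; boxplot statistics (quantiles 5/25/50/75/95) of each
  site's median distance from the gold-core centre of mass; state-transition
  counts.
- **Relaxation** — ¹³C T1 prediction by the Lipari–Szabo model-free approach:
  CH-vector P2 autocorrelation, constrained two-exponential fit with plateau
  S², overall tumbling from Stokes–Einstein
  `D_rot = k_B·T / (8πη·r³)` with hydrodynamic radius `r = 1.1·Rg`, spectral
  density `J(ω) = (2/5)[S²τ_r/(1+(ωτ_r)²) + Σ aᵢτᵢ′/(1+(ωτᵢ′)²)]`, and the
  ¹³C–¹H dipolar rate
  `1/T1 = n_H·(d²/4)·[J(ω_H−ω_C) + 3J(ω_C) + 6J(ω_H+ω_C)]`.
- **Synthetic data** — a generator that builds a labelled nanoparticle
  (~1.6 nm core, 60 ligands, 60 Zn, 10 substrates, solvent, counterions) and
  trajectories with *planted* events of known identity, start, duration and
  geometry, so every detector can be verified against exact ground truth
  without running MD.

Everything is tidyverse-native: topologies and results are tibbles, fitted
objects have `tidy()`/`glance()` methods, result types have `autoplot()`.

## Worked example

```r
library(nanosite)

cfg <- synthetic_config(n_ligands = 60, n_substrates = 10, n_waters = 300,
                        n_cl = 110, n_frames = 100, seed = 42)
np   <- build_nanoparticle(cfg)
sch  <- event_schedule(
  schedule_event("ZN_PAIR",  zn1 = 4,  zn2 = 17, start = 10, duration = 6,
                 d_znzn = 0.45),
  schedule_event("PRECAT_2", zn1 = 23, zn2 = 40, substrate = 3, start = 30,
                 duration = 8, d1 = 0.22, d2 = 0.23, d3 = 0.24,
                 d4 = 0.19, d5 = 0.24),
  n_frames = 100)
traj <- generate_trajectory(np, sch, cfg)

build_events(traj, np$topology, kind = "znpair", cutoff = 0.50)
#>   state   zn    start_ps existence_ps median_core_nm
#> 1 ZN_PAIR 4,17        45           30           3.19
#> 2 ZN_PAIR 23,40      145           40           3.19

build_events(traj, np$topology, kind = "precat")
#>   state    zn    substrate existence_ps solvated nucleophile_ready
#> 1 PRECAT_2 23,40         3           40 TRUE     TRUE
```

The detector recovers both planted events exactly: the Zn pair scheduled for
6 frames at 5 ps spacing appears as a 30 ps event, and the type-2
precatalytic complex (phosphoryl oxygens bridging Zn 23 and Zn 40, hydroxyl
oxygen on Zn 23, a Zn-bound water within 0.20 nm poised 0.24 nm from the
nucleophile) is flagged solvated and activation-ready. Note the second Zn
pair: planting a bimetallic complex necessarily creates a Zn–Zn pair too.

```r
rg <- radius_of_gyration(traj, np$topology,
        selection = setdiff(atom_roles(), c("WATER_O", "WATER_H", "CL", "OTHER")))
#> Rg = 1.668 +/- 0.001 nm

dur <- sample_event_durations(5000, lambda_true = 131, dt = 5, seed = 1)
fit <- fit_decay(population_curve(dur * 5))
#> <decay fit: N0 = 4998, lambda = 129.9 ns^-1, ||resid|| = 34.4 (15 points)>

stokes_einstein(300, 8.5e-4, hydrodynamic_radius(attr(rg, "mean")))
#> <tumbling: D_rot = 3.139e+07 s^-1, tau_r = 5.309 ns (r = 1.83 nm, 300 K)>
```

5,000 lifetimes drawn at λ = 131 ns⁻¹ and refitted through the population
curve return λ = 129.9 ns⁻¹ (0.8 % off), and the synthetic particle's
radius of gyration feeds the Stokes–Einstein tumbling model directly.

A complete run — `run_pipeline(run_config(synthetic = cfg, stages = c("simulate",
"structure", "bundles", "events")))` — writes per-stage CSV/JSON plus a
manifest echoing every parameter and seed. A thin shell wrapper lives at
`inst/scripts/nanosite.R`.

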