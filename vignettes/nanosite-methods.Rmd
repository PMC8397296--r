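---
title: "Detecting transient catalytic sites on nanozymes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting transient catalytic sites on nanozymes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanosite)
```

`nanosite` analyses molecular-dynamics trajectories of gold nanoparticles
whose coating thiols end in Zn(II)-chelating TACN crowns. Such particles
hydrolyse phosphodiesters through transiently formed two-metal-ion sites;
the package quantifies when and where those sites form, how long they live,
and how mobile each part of the monolayer is. This vignette documents the
models, the defaults and why they were chosen, what the synthetic fixtures
do and do not emulate, and the numerical choices that matter.

## Geometry and units

Coordinates are handled in nm and times in ps throughout; decay rates are
reported in ns⁻¹ and only converted at reporting time. All distance tests
use the minimum-image convention (orthorhombic fast path, triclinic via a
fractional wrap refined by an explicit neighbour-image search). The source
data never state whether wrapped or unwrapped coordinates were analysed;
minimum-image distances make the two equivalent for every pairwise test in
the package, which is why that convention was adopted. Centres of mass
unwrap the selection about its first atom before mass-weighting, so a group
straddling a periodic boundary is centred correctly. PDB input (Å) is
converted to nm on load.

Rigid-body superposition (for RMSF and rotational ACFs) fits on the gold
core only: the core is the stiffest part of the system and the natural
frame of reference for monolayer motion. Fitting on all atoms would absorb
part of the ligand motion into the alignment and bias RMSF downward.

## Atom semantics

Coordinate formats carry no chemistry, so every analysis starts from an
explicit *label map* assigning `(residue name, atom name)` pairs to roles:
gold, sulfur, alkyl carbons C1–C7, the inner amide (O8, N9), linker
positions 12/15, the outer amide (N18, O19), TACN nitrogens, Zn, the
substrate's P and O3/O4/O5 oxygens (O3 = hydroxyl/nucleophile, O4/O5 =
phosphoryl), water, and chloride. Shipped YAML presets encode the naming
used by the synthetic generator for the two ligand chemistries (alkyl
C12/C15 vs PEG O12/O15 linkers). Every Zn must have TACN nitrogens in its
residue — an unchelated Zn is a labelling error, because all downstream
identity bookkeeping ties a Zn to its carrier ligand.

## Event machinery

**Detection.** A bimetallic site exists in a frame when two Zn ions are
within 0.50 nm (the defining threshold; 0.55 and 0.63 nm are common
sensitivity settings and the cutoff is a plain argument). A substrate is
mono-metallically bound when at least one phosphoryl oxygen sits within
0.25 nm of exactly one Zn and no second Zn touches any substrate oxygen;
bimetallically bound when O4 and O5 reach two different Zn simultaneously.
The precatalytic types are: type 2 — O4 and O5 on two different Zn with O3
on one of them; type 3 (pseudo-bimetallic) — exactly one Zn on the
phosphoryl oxygens while a second Zn holds only O3; type 1 (monometallic) —
one Zn holds O3, O4 and O5 with no other Zn involved. Types are evaluated
2 → 3 → 1: bimetallic evidence outranks pseudo-bimetallic outranks
monometallic. The source definitions do not say what to do when several
patterns hold at once; this precedence resolves ties in favour of the
mechanistically stronger arrangement and is config-exposed. All O–Zn
cutoffs are inclusive (≤); the solvation criteria are strict as defined
(Zn-bound water at d4 < 0.20 nm; nucleophile ready at d5 < 0.25 nm), and
both conventions are applied uniformly.

**Segmentation.** A boolean per-frame series becomes events as maximal runs
of consecutive true frames; one false frame ends an event. A
`gap_tolerance` argument can bridge short interruptions for sensitivity
analysis but defaults to 0 — with 5 ps sampling a single-frame gap is
already a 5 ps dissociation, and bridging it would inflate lifetimes.
Existence time is run length × dt, so the floor is one frame (5 ps at the
default spacing). Identities are the unordered Zn pair, or the
(state, Zn ids, substrate) triple: if the state or the partner Zn changes,
a new event starts.

**Lifetimes.** The population curve N(t) counts events with existence time
strictly greater than t, evaluated at t = 0 and every observed existence
time. It is fitted by nonlinear least squares to N0·e^(−λt) (λ in ns⁻¹),
started from a log-linear regression on the positive part of the curve; a
fit range can restrict the window. At least three distinct existence times
are required — a degenerate curve raises an error rather than returning a
meaningless rate. Site locations are summarised by quantiles 5/25/50/75/95
of each event's median Zn-to-core distance (pooled over both Zn of a pair
and all frames of the event), matching the boxplot convention of whiskers
at the 5th/95th percentiles.

**Flags.** Solvation and nucleophile-readiness use any-frame semantics
within an event: a complex counts as solvated if a qualifying water is
present in at least one of its frames, mirroring how whole complexes are
marked rather than individual frames.

## Bundles

Interligand C=O8···H–N9 hydrogen bonds define a graph over ligands; bundles
are connected components of size ≥ 3. The hydrogen-bond criterion
(donor–acceptor ≤ 0.35 nm and H–D···A angle ≤ 30°) is the de facto
geometric standard in MD analysis; the source is silent on its exact
values, so both are arguments. "Frequency" of a bundle size is reported two
ways — the fraction of frames showing at least one bundle of exactly that
size, and the raw count — because the published bar charts are ambiguous
between the two normalisations. Components larger than 6 are kept under a
">6" bucket rather than discarded: "up to six" reads as an observed range,
not a filter.

## Lipari–Szabo T1 prediction

Internal and overall motions are treated as independent. The internal
CH-vector P2 autocorrelation (computed after superposing every frame on the
gold core, averaged over the equivalent carbons of all ligands and over
attached hydrogens) is fitted to S² + a₁e^(−t/τ₁) + a₂e^(−t/τ₂) under
non-negativity and sum-to-one constraints — a two-exponential fit whose
constant term is the plateau order parameter. Averaging ACFs before fitting
(rather than fitting per ligand and averaging parameters) was chosen
because the per-ligand ACF tail is noisy and the fit is nonlinear: the
pooled ACF has √n-smaller noise where n ligands are equivalent. The fit
window defaults to 2 ns of lags, long enough to expose the plateau for
internal motions of tens to hundreds of ps; it is an argument. Multiple
starts over decades of (τ₁, τ₂) guard the constrained optimiser against
local minima.

Overall tumbling comes from Stokes–Einstein, D_rot = k_B·T/(8πη·r³), with
r = 1.1 × the mean radius of gyration. The default viscosity is
8.5 × 10⁻⁴ Pa·s (water near 300 K) — the source does not state the value
used, so the package default is the standard literature value and it is an
argument. With τ_r = 1/(6 D_rot) and effective times 1/τᵢ′ = 1/τ_r + 1/τᵢ,
the spectral density is

J(ω) = (2/5)·[S²τ_r/(1+(ωτ_r)²) + Σᵢ aᵢτᵢ′/(1+(ωτᵢ′)²)],

the cosine transform of the product correlation function. Relaxation is
¹³C–¹H dipolar only, 1/T1 = n_H·(d²/4)·[J(ω_H−ω_C) + 3J(ω_C) + 6J(ω_H+ω_C)]
with d = (μ₀/4π)·ħγ_Hγ_C/r_CH³ and r_CH = 0.109 nm. CSA and
cross-correlation are neglected: for protonated aliphatic carbons at 9.4 T
the dipolar mechanism dominates and the published workflow gives no CSA
parameters. Spectrometer frequencies default to 400.13 MHz (¹H) /
100.61 MHz (¹³C). In the extreme-narrowing limit the expression collapses
to 1/T1 = n_H·d²·τ_c, which the tests verify to 0.1 %.

## The synthetic generator: what it emulates, what it does not

The generator is jitter, not physics. It builds a labelled particle —
gold beads on a 0.8 nm-radius core (re-centred so the core centre of mass
is exactly the box centre), 60 ligand chains on a deterministic Fibonacci
lattice with the full role sequence, a TACN crown whose three nitrogens sit
exactly 0.21 nm from their Zn, 10 four-atom substrate stubs, water and
chloride placed uniformly outside the monolayer — and evolves it by
independent Gaussian jitter about the initial positions (substrates perform
a reflected random walk in the solvent shell). Scheduled events teleport
the participants into exact template geometries (two-sphere intersection
for the solvation water, so d4 and d5 hold simultaneously; infeasible
triangles raise a schedule error) and home positions guarantee >1.5× the
relevant cutoff outside scheduled intervals.

This is sufficient because every analysis in the package is geometric or
statistical: a detector cannot tell planted geometry from simulated
geometry. What the fixtures deliberately do **not** emulate: forces,
water structure, realistic ligand conformational ensembles, correlated
monolayer motions, or realistic solvent counts (fixtures use hundreds of
waters; the real solvated systems hold ~27,000). Consequently, green tests
certify the *analysis machinery* — recovery of identities, starts,
durations, rates, and relaxation parameters from data with known ground
truth — not the physics of any particular nanoparticle.

Default generator parameters are the study conditions: 1.6 nm core
diameter, 60 ligands/Zn, 10 substrates, 5 ps frame spacing. The jitter
scale (0.02 nm) is a typical heavy-atom thermal amplitude; event-recovery
margins are engineered at ≥3σ so recovery stays exact under jitter. The
internal-motion model for tumbling fixtures is an azimuthal jump process on
a cone (cone angle set by P2(cos θ) = √S², azimuth resampled at rate
1/τ_e) composed with small-step isotropic rotational diffusion: its P2
autocorrelation is exactly S² + (1−S²)e^(−t/τ_e) times e^(−6·D_rot·t) in
expectation, over the whole S² ∈ [0, 1] range — so recovered parameters can
be compared against truth without model error. Sampled event durations are
rounded *up* to whole frames (an event always covers ≥1 frame); the
discretised survival curve still equals e^(−λt) exactly at the frame grid,
which is why rate recovery is unbiased.

## Numerical choices and degenerate inputs

- Frame times must be strictly increasing and uniform within 1e-6 ps;
  violations report the offending frames.
- Triclinic minimum image refines the fractional-rounding candidate over
  the 26 neighbouring images (rounding alone can miss the true image in
  skewed cells).
- Eccentricity (1 − I_min/I_avg) raises a geometry error for exactly
  collinear selections (I_min = 0 with a rank-deficient tensor); near-linear
  rods legitimately approach e = 1.
- The decay fit refuses curves with fewer than three distinct times or
  fewer than two positive counts.
- The constrained ACF fit clips a marginally negative plateau at 0 with a
  warning rather than failing.
- Hydrogens are paired to donors by covalent proximity (< 0.18 nm in the
  first frame) — loose enough to survive thermal jitter on a 0.10 nm bond,
  tight enough that a detached hydrogen is still a labelling error.
- DCD I/O is little-endian CHARMM format with a per-frame unit-cell record;
  the writer/reader pair is cross-checked in the tests against an
  independent reader (bio3d). XTC/TRR are not supported (no R reader
  exists); DCD or multi-frame GRO cover the interchange need.

## Problem sizes in the test and acceptance runs

Verification runs use fixture-scale systems — 12–60 ligands, tens of
frames for event recovery, 5,000 sampled lifetimes per decay rate, 30
tumbling vectors × 4,000–5,000 frames for relaxation — sizes at which the
brute-force oracles (27-image distance enumeration, O(n²) contact scans,
exhaustive 64-case classifier truth tables, union-find components,
trapezoidal Fourier quadrature) are themselves cheap and exact. These
choices are the package's own verification design: each quantity is checked
at a scale where an independent computation of the same quantity is
feasible.

## Known limitations

- Event counting is per contiguous run; a site that blinks off for one
  frame counts twice (by design, matching the no-gap convention); use
  `gap_tolerance` to explore the alternative.
- The hydrogen-bond angle convention is H–D···A at the donor; tools using
  the D–H···A angle at the hydrogen will count slightly differently near
  the cutoff.
- T1 assumes isotropic overall tumbling — appropriate for a quasi-spherical
  particle (eccentricity ≈ 0.05), not for strongly anisotropic bodies.
- The RDF normalises by the ideal-gas density of the target selection in
  the full box; for targets confined to shells (e.g. chelated Zn) g(r) is
  meaningful relative to that convention, and the cumulative number N(r) is
  the more directly interpretable curve.
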