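---
title: "Simulating indirect 14N detection through a 13C spy nucleus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating indirect 14N detection through a 13C spy nucleus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The experiment and the model

Nitrogen-14 is nearly 100% abundant but is a spin-1 nucleus with a
quadrupolar coupling of up to a few MHz, which makes its direct NMR
detection under magic-angle spinning (MAS) hard. A practical alternative is
*indirect* detection through a neighbouring spin-1/2 "spy" nucleus: here a
directly bonded 13C. spinspy simulates the HMQC-type experiment in which
the transfer between 13C and 14N is driven by a long (ms), moderate
(tens of kHz) continuous rf pulse applied on the 14N channel, with no free
evolution delays:

1. start from unit transverse 13C magnetisation `Sx` (the idealised
   product of cross-polarisation; protons are otherwise outside the model);
2. a rotor-synchronised CW 14N pulse of duration `tau_N` converts part of
   it into mixed 13C-14N coherences;
3. the 14N coherence order of interest (single quantum `p = +/-1` or
   double quantum `p = +/-2`) is retained — by projection in the primary
   code path, or by an explicit phase cycle;
4. the selected coherence evolves for `t1` (an integer number of rotor
   periods, split symmetrically around an ideal 13C pi pulse);
5. an identical 14N pulse reconverts it into observable 13C signal.

The simulation is exact for one 13C-14N pair on the 6-dimensional coupled
Hilbert space. The rotating-frame Hamiltonian contains:

* the first-order secular quadrupole term `A20(t) T20`, with the spatial
  part transported quadrupole PAS -> dipolar frame -> crystallite ->
  rotor -> lab through active ZYZ Wigner rotations;
* second-order quadrupole self terms and quadrupole–dipole cross terms,
  computed at each time step by instantaneous van Vleck perturbation
  theory, `H2 = sum_m [V_m^H V_m - V_m V_m^H]/(m w0)` over the N-flip
  components `V_1, V_2` of the non-secular coupling. These scale as
  `1/w0(14N)` and are valid for `wQ << w0` (3 MHz vs 43.5 MHz here). The
  cross terms are the *residual dipolar splittings* that survive MAS and
  mediate the transfer; the self terms produce the characteristic
  second-order lineshape and the isotropic shift
  `3 CQ^2 (1 + eta^2/3) / (40 nu0)` (about +60 ppm for the amine preset,
  +390 ppm for the amide preset);
* the secular heteronuclear dipolar term (`2 IzSz`, MAS time dependent),
  the scalar J coupling, resonance offsets and the rf fields.

Treating the second order as an instantaneous correction rather than
integrating the full lab-frame problem matches the standard "quadrupole to
second order" treatment of MAS simulation engines; the test suite checks it
per crystallite against exact diagonalisation of the full-Zeeman
Hamiltonian (agreement at the third-order scale, tens of Hz) and checks the
powder-averaged isotropic shift against the closed form above to 0.005.

## Parameters that matter

| parameter | units | default | role |
|---|---|---|---|
| `cq_mhz`, `eta_q` | MHz, – | preset | quadrupole coupling and asymmetry |
| `dipole_khz` | kHz | preset | heteronuclear coupling `b/2pi`, signed |
| `euler_qd_deg` | deg | preset | quadrupole PAS -> dipolar frame |
| `mas_khz` | kHz | 25 | spinning rate; `tau_r = 1/mas` |
| `rotor_angle_deg` | deg | 54.7356 | rotor axis; mis-set to model imperfect adjustment |
| `larmor_14n_mhz` | MHz | 43.5 | sets the second-order scale (14.1 T) |
| `tau_n_ms` | ms | 2 | 14N pulse length, whole rotor periods |
| `nu1_n_khz` | kHz | 35 | 14N rf nutation frequency |
| `offset_n_khz` | kHz | 0 | transmitter displacement from the NH4Cl reference, positive towards higher ppm |

Two literature parameter sets ship as presets: `glycine_amine`
(CQ 1.18 MHz, eta 0.54, b = -0.716 kHz, tensors collinear) — a fast-rotating
NH3+ group — and `triglycine_amide` (CQ 3.01 MHz, eta 0.48,
b = -0.928 kHz, orientation (0, 90, 120) deg) — a rigid sp2 peptide
nitrogen. They bracket the quadrupole sizes common in organic solids.

## The transmitter-offset protocol

The second-order interaction displaces the 14N resonance from the
reference carrier (NH4Cl position): by ~2.6 kHz for the amine and
~17 kHz for the amide at 43.5 MHz. The efficiency-versus-offset profile is
double peaked, with a sharp *minimum* exactly on the shifted resonance and
maxima a few kHz either side of it; additional recoupling maxima appear
displaced by the spinning frequency. Experimentally the offset is part of
the set-up optimisation, so the scan and reproduction pipelines use
`optimal_offset()`: a coarse offset scan over ±10 kHz in 2 kHz steps (the
band within which most of the efficiency is retained) whose argmax becomes
the operating offset. Under this protocol the glycine rf-amplitude optimum
falls at 40 kHz and its pulse-length optimum at 2.4–2.6 ms with a plateau
beyond 2 ms; at a fixed on-carrier offset both optima shift (30–35 kHz).

## Numerical choices

* **Propagation.** Piecewise-constant midpoint evaluation, 200 steps per
  rotor period by default (0.2 us at 25 kHz), each step exponentiated
  exactly by Hermitian eigendecomposition of the 6x6 Hamiltonian. The
  scheme is second-order accurate (verified by Richardson step-halving);
  `check_step_convergence()` audits the default for any system — for the
  shipped presets halving the step changes the efficiency by well under
  0.1%, so the default is kept fixed rather than auto-refined, keeping
  scan timings predictable and results exactly reproducible.
* **Rotor-period caching.** Under CW irradiation `H(t + tau_r) = H(t)`, so
  one period propagator per crystallite is computed and whole pulses are
  its matrix powers; free-evolution segments reuse two half-period
  propagators. Caching is exact (equivalence to direct propagation at
  1e-8 is part of the acceptance checks).
* **Phase shifts as z-rotations.** Every non-rf term commutes with the 14N
  `Iz`, so shifting the pulse phase by `phi` multiplies the order-p
  coherence by `exp(-i p phi)` exactly. Phase cycling (4 steps for SQ,
  8 for DQ, cosine receiver weights) and the States quadrature dataset
  (excitation phase advanced by `90/p` degrees) therefore reuse one cached
  propagator and agree with the projection filter to machine precision.
* **Powder averaging.** Deterministic three-angle ZCW-style sets: rank-1
  lattices uniform in `cos(beta)` with `alpha` and `gamma` generated by a
  frozen pair `(g1, g2 = g1^2 mod N)` per shipped size
  {50, 144, 300, 538, 986, 1154, 3722, 6044}, chosen once by minimising
  the quadrature error on all rank-2 Wigner components and the rank-4
  harmonics. Every set of 986 points or more integrates all `<Y2m>` below
  1e-3. The 6044-point set is the reference; scans default to 1154 points,
  which moves grid argmax locations by at most one cell. The glycine SQ
  coherence amplitude changes by 0.5% between the 3722- and 6044-point
  sets; the full echo efficiency, a sharper orientation functional,
  still fluctuates at the 2% level — relevant when comparing absolute
  efficiencies, not argmax positions.
* **Rotor synchronisation.** Pulse lengths are snapped to whole rotor
  periods (scans warn; the single-run interface refuses), and
  `dt1 = n tau_r`, so the first-order quadrupole is refocused exactly in
  `t1` — disabling the second-order terms on resonance freezes the
  indirect dimension, a property test.
* **Processing conventions.** Line broadening `exp(-pi lb t)` gives a
  Lorentzian of FWHM `lb`; spectra are zero filled to 1024 points by
  default; `ppm = 35.9 + 1000 f_khz / 43.5` with the NH4Cl reference
  assumed at the carrier, and the indirect axis corrected for the
  transmitter displacement. Indirect-dimension broadening is exposed
  separately (`lb1_hz`) since simulated interferograms do not relax.

## Design decisions on genuinely open points

* The sense of the quadrupole-to-dipole rotation `(alpha, beta, gamma)` is
  fixed by the documented active-ZYZ chain (the collinear amine case is
  insensitive; for the amide the indirect lineshape is the discriminator,
  and the chain is exposed so the opposite convention is one
  `rotate_rank2()` call away).
* `t1` is split symmetrically around the 13C pi pulse, the natural echo
  geometry; with rotor-synchronised increments the placement only matters
  through second-order evolution.
* Explicit phase tables for the cycle are not prescribed anywhere, so
  projection is the primary selection path and `phase_cycle_run()` (with
  cosine receiver weights) is the cross-check; the two agree to 1e-8.
* The efficiency reference is the initial unit `Sx`; experimental
  efficiencies quoted against cross-polarisation signals involve proton
  physics and relaxation and are deliberately out of scope.

## What the model does and does not capture

The two-spin model reproduces the simulated behaviour of the experiment:
coherence generation above 20% of the initial magnetisation, the breadth
and position of the rf/pulse-length optima, second-order indirect
lineshapes (including their sensitivity to a 0.05 deg rotor-axis mis-set),
and offset robustness on the 10 kHz scale. It contains no protons — so no
decoupling imperfections, no CP dynamics — and no relaxation, so simulated
efficiencies exceed experimental ones and build-up curves lack the decay
that shortens experimental pulse-length optima. Homonuclear 13C J
couplings, 13C CSA (refocused by the pi pulse) and third-order quadrupole
terms are omitted.

## Problem sizes

The test suite runs powder sets of 50–300 orientations for property
checks, 1154 for the end-to-end checks, and touches 3722/6044 once for the
convergence assertions. `scripts/acceptance.R` uses 6044 orientations for
the coherence-generation number and 1154 for the three scan optima; the
full run takes on the order of a minute on one core.
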