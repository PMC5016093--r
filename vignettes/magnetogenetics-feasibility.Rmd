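---
title: "Order-of-magnitude feasibility of magnetogenetics proposals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Order-of-magnitude feasibility of magnetogenetics proposals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(magnetolimits)
library(dplyr)
```

## The problem

Several prominent proposals claim that cells can be made magnetically
sensitive through iron-bearing proteins: a rod-shaped 40-iron-atom complex
said to align with the geomagnetic field like a compass needle; ferritin
fused to mechanosensitive channels (TRPV4) and tugged by static magnetic
fields; and ferritin fused to the heat-gated channel TRPV1 and warmed by
radio-frequency fields. Each claim rests on a physical mechanism —
orientational alignment, force, or heat — whose magnitude can be computed in
closed form from textbook physics and published material parameters.

This package implements those calculations as a reusable, tested chain. For
every mechanism it computes the relevant physical quantity, compares it with
the biophysical threshold the mechanism must reach (channel gating forces,
membrane stress thresholds, the TRPV1 temperature threshold, or thermal
energy kT itself), and reports the signed log-unit gap
$\log_{10}(\mathrm{threshold}/\mathrm{computed})$. The consistent result is
that every proposed mechanism falls short by roughly 4 to 10 orders of
magnitude; the package's role is to make that arithmetic reproducible,
inspectable, and extensible to new parameter regimes.

## Models and assumptions

**Compass alignment.** An atom with $n$ unpaired electrons carries the
spin-only moment $\mu_{\mathrm{eff}} = \sqrt{n(n+2)}\,\mu_B$. Granting the
(physically unsupported) assumption that $N$ atomic moments co-align
perfectly, the complex's moment is $m = N\sqrt{n(n+2)}\,\mu_B$. Its
equilibrium alignment with a field $B$ at temperature $T$ is governed by
$x = mB/kT$; the mean alignment is the Langevin function
$L(x) = \coth x - 1/x \approx x/3$ for weak fields. Both the ratio $x$ (the
order-of-magnitude proxy) and $L(x)$ are computed; for the 40-iron complex
in the 50 µT geomagnetic field both are below $10^{-4}$, about five orders
of magnitude below the claimed alignment of 0.45.

**Magnetizability.** Ferritin is (super)paramagnetic at room temperature:
its induced moment is $m = \xi B$. The single-particle magnetizability
$\xi$ is derived from three independent published bulk susceptibility
measurements, one per normalization dialect: per mole of iron in CGS units
(two records, converted with $\chi_{SI} = 4\pi\times10^{-6}\chi_{CGS}$ and
normalized by $N_A/2400$ particles per mole Fe), and per unit mass in SI
units (normalized by the 580 kDa particle mass). A Curie-law route,
$\xi = N\mu_{\mathrm{eff}}^2/3kT$, cross-checks the unit conversions to
within 2%. The three derivations agree within a few percent; their
arithmetic mean, rounded to two significant digits, gives the consensus
$\xi = 2.4\times10^{-22}\ \mathrm{J/T^2}$ used downstream. The mean was
chosen as the consensus statistic because the three routes are equally
credible independent measurements; any other central summary gives the same
two-digit value.

**Static forces.** Four mechanisms are bounded: the field-gradient pull
$F = \xi B\,dB/dx$; the attraction between two touching field-aligned
ferritins $F = (3\mu_0/2\pi)\,m^2/d^4$ at $d = 2R = 12$ nm (the collinear
attractive geometry is the default; the perpendicular repulsive geometry,
half the magnitude, is available via a flag); the anisotropy torque bounded
by the free-energy gap $\frac{1}{2}\xi B^2$ under the most generous
assumption of infinite anisotropy; and the collective membrane stress of a
particle layer, bounded by close packing ($1/(2R)^2$ per unit area for
square packing, the headline figure; hexagonal packing, larger by
$2/\sqrt3$, via a flag).

**Heating.** Specific loss power (SLP) scales as frequency times field
squared over the conditions of interest, so published measurements taken at
other coil settings are rescaled with that law. A particle holding 2400 Fe
atoms at SLP $P$ emits $Q = P\,m_{\mathrm{Fe}}$ watts; steady Fourier
conduction into water ($\kappa = 0.61$ W/(m·K)) gives a surface rise
$Q/4\pi\kappa R$, an interfacial (Kapitza) step $Q/4\pi R^2 G$ with
$G = 2\times10^{8}$ W/(m²·K), a cell-surface rise $QN/4\pi\kappa r_{cell}$
for $N$ particles treated as a uniform spherical source, and a tissue
heating rate $QN/(\frac{4}{3}\pi r_{cell}^3\rho)$ compared against the
basal brain metabolic rate of $1.2\times10^{-2}$ W/g.

## Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| Bohr magneton $\mu_B$ | 9.274e-24 | J/T | CODATA; displayed one-digit values are display rounding |
| Boltzmann $k$ | 1.380649e-23 | J/K | exact SI |
| temperature | 298 | K | the susceptibility records and kT = 4.11e-21 J refer to room temperature, not body temperature; configurable |
| Fe per ferritin | 2400 | — | maximal 23% w/w iron loading |
| ferritin radius | 6e-9 | m | 12 nm shell diameter; the rise is evaluated at the shell surface (the core is 5–6 nm); configurable |
| consensus $\xi$ | 2.4e-22 | J/T² | mean of the three susceptibility routes |
| static field / gradient | 0.05 T, 6.6 T/m | | reported experimental conditions; the displayed arithmetic uses 7 T/m (see below) |
| AC drive | 25.5 kA/m, 465 kHz | | the heating-experiment coil conditions all SLP records are rescaled to |
| granted SLP | 30 | W/g metal | the best cobalt-doped-ferritin measurement, a deliberately generous ceiling; native ferritin measured < 0.01 W/g |
| thresholds | 2e-13 N; 2 / 5 Pa; 5 K; kT | | hair-cell gating force; TRPV4 / Piezo1 stress; TRPV1 temperature; thermal noise floor |

Constants, the temperature and the rounding policy can be overridden from a
YAML file via `read_config()`.

## Rounding policy and the replicate path

The published analysis displays quantities at single-digit precision. To
make that displayed arithmetic reproducible step by step, the package
carries an explicit rounding policy (`rounding_policy()`): `replicate` mode
rounds designated intermediate inputs to one significant digit with
half-even ties (half-even is required: the alignment ratio 2.5e-5 displays
as 2e-5, and the pair escape ratio 4.5e-9 as 4e-9), while `full_precision`
mode never rounds intermediates. Display rounding at each value's printed
precision happens in both modes.

Two path choices deserve note, both recorded per-row in
`reproduction_table()`:

* The static-force chain feeds the single-digit $\xi = 2\times10^{-22}$ and
  the displayed gradient 7 T/m (not the measured 6.6) in replicate mode;
  full-precision mode uses 2.4e-22 and 6.6 T/m, and its gradient-pull and
  dipole results then differ from the published displays by up to a factor
  ~1.5 — an honest measure of how much the conclusions depend on rounding
  (the log-unit gaps are unaffected at the precision that matters).
* The heating chain propagates the full-precision heat rate
  $Q = 6.68\times10^{-18}$ W and rounds only at display. This single path
  reproduces all four downstream displayed values (1.5e-10 K, 7e-11 K,
  1.7e-9 K, 1.2e-4 W/g) simultaneously; feeding the displayed
  $7\times10^{-18}$ W instead would break the interfacial-step and
  cell-rise values.

Three published numbers cannot be reproduced from their own stated inputs
and are flagged (never silently corrected) in the reproduction table: the
Curie-law magnetizability (published 2.37e-22, computed 2.39e-22 J/T²), and
two rescaled SLP records (published 75 and 130 W/g where the $fH^2$ law
gives ~420 and ~30; the ~30 value is in fact the "granted" SLP the heating
chain uses, suggesting the published 130 is the inconsistent one).

```{r}
rt <- reproduction_table()
glance(rt)
rt |> filter(flagged) |> select(quantity, computed, displayed, printed)
```

## Numerical choices

* `round_sig()` snaps the scaled mantissa at 12 significant digits before
  tie handling, so values that are ties in exact arithmetic (2.5, 4.5) are
  treated as ties despite binary floating point.
* `langevin()` switches to the series $x/3 - x^3/45 + 2x^5/945$ below
  $|x| < 10^{-3}$, where the direct $\coth x - 1/x$ form loses precision to
  cancellation; the direct form is used elsewhere and saturates correctly
  for large $x$. The test suite checks it against independent Boltzmann
  quadrature to $10^{-6}$ absolute over $x \in [10^{-4}, 10^{2}]$.
* `radial_heat_oracle()` validates the analytic $1/r$ profile numerically:
  a conservative finite-volume discretization on a geometric radial grid
  (natural for a $1/r$ solution), with the source flux imposed at the inner
  face and the bath temperature at the outer boundary, solved by the Thomas
  algorithm. On a finite domain the exact steady state is
  $\frac{Q}{4\pi\kappa}(1/r - 1/R_{out})$; the discrete solution converges
  to it at second order, and matches the infinite-bath $1/r$ law to < 1% at
  radii well inside the outer boundary (the tests place the boundary $10^4$
  source radii out and compare in the inner decades). The default problem
  size, 1000 shells, keeps the discretization error near $5\times10^{-6}$.
* Degenerate inputs are rejected with typed conditions
  (`mg_error_invalid`, `mg_error_lookup`); zero drive (an AC amplitude of
  zero) is not an error but yields zero heat and an infinite log-unit gap,
  because implausibility — not failure — is the expected scientific result.

## The scenario generator

`builtin_scenarios()` packages the published parameter sets (the compass
complex, the static-pull experiment, the heating experiment, a 5 T
extrapolation, and native ferritin at its measured non-detection bound).
`random_scenarios()` draws parameters log-uniformly within physically valid
ranges ($\xi \in [10^{-24}, 10^{-20}]$ J/T², $R \in [2, 50]$ nm,
$B \in [10^{-5}, 10]$ T, SLP $\in [10^{-2}, 10^{3}]$ W/g) for
property-based testing; log-uniform sampling matches an analysis whose
quantities span decades. What the generator emulates is parameter
variation, not measurement: it contains no noise model for the historical
susceptibility data and no microphysics (Néel/Brownian relaxation,
blocking dynamics, non-Fourier transport — the last a ≤10% effect at these
scales). Passing property tests therefore demonstrate the exactness of the
implemented scaling laws and the stability of the verdict logic across the
physical parameter space, not agreement with any new experimental data.

## Verdicts

```{r}
verdicts <- evaluate_scenarios()
verdicts |> filter(headline) |>
  select(scenario, quantity, value, threshold, log_unit_gap, gap_phrase)
```

The `headline` flag marks the verdicts corresponding to the central claims;
the 5 T extrapolation (where the dipole mechanism is still ~4 log units
short and the anisotropy torque becomes comparable with kT — the one
potentially useful direction) and the brain-heating-versus-basal-metabolism
comparison (a 1% addition) are deliberately `headline = FALSE`, since they
bound different questions than channel gating.

## Known limitations

* The analysis bounds mechanisms; it does not model the published
  experimental observations themselves, which — if real — must arise from
  something else entirely.
* The torque bound is a free-energy gap under infinite anisotropy, not a
  rotational dynamics calculation.
* SLP is taken as measured (and rescaled); the package does not predict SLP
  from first principles.
* The mapping from an alignment distribution to a claimed "fraction
  oriented roughly parallel" requires an angular tolerance the original
  claim never states; the package computes the ratio and the Langevin mean
  cosine and deliberately provides no fraction-within-cone operation.
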