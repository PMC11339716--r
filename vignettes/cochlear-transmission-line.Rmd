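---
title: "A reduced-order two-duct model of forward and reverse cochlear stimulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A reduced-order two-duct model of forward and reverse cochlear stimulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cochleabox)
```

## The problem

Active middle ear implants deliver mechanical vibration to the cochlea
through a floating mass transducer coupled either to the stapes (oval
window, "forward" stimulation — the physiological entry) or directly to
the round window membrane ("reverse" stimulation).  Which coupling
transmits more vibration to the basilar membrane, and how the answer
changes when the stapedial annular ligament (SAL) is stiffened by
otosclerosis or the round window membrane (RWM) is fibrotic or ossified,
is a question that is hard to settle clinically: no patient receives both
operations, and middle-ear pathology varies between cohorts.

`cochleabox` addresses the question with a deliberately small, fully
transparent physical model: a frequency-domain two-duct transmission-line
("box") cochlea whose two windows carry lumped mechanical closures.  The
package solves the same comparison matrix a simulation study would run —
five pathology scenarios, two pathways, six audiometric frequencies — and
computes the standard verification metrics of cochlear mechanics along
the way.

## The model

### Ducts and partition

The cochlea is straightened into two fluid columns (scala vestibuli, with
the scala media merged into it, and scala tympani) of constant
cross-section $A$, separated by the basilar membrane (BM) and connected
at the apex by the helicotrema.  The lymph is incompressible
($\rho = 1034\ \mathrm{kg/m^3}$, $\mu = 0.0028\ \mathrm{N\,s/m^2}$) and
the outer walls are rigid.  On a grid of $n$ segment centres the ducts
become series acoustic impedances per segment,

$$Z_{duct} = \Delta x \left( \frac{i\omega\rho}{A} + \frac{8\pi\mu}{A^2} \right),$$

the second term being a Poiseuille-type viscous loss.  The partition is
locally reacting with per-area impedance

$$z_p(x, f) = i\omega m(x) + r(x) + c + \frac{k(x)}{i\omega},$$

with

* $m(x) = \rho_{BM}\, t(x) + \frac{\pi}{4} \rho\, w(x)$ — membrane mass
  plus the added mass of an oscillating strip of width $w$ in fluid;
* $k(x) = C\, E_X\, t(x)^3 / w(x)^4$ — clamped-beam bending across the
  width, the direction of the collagen fibres, so the transverse modulus
  $E_X$ dominates;
* $r(x) = \alpha m(x) + \beta k(x)$ — the frequency-domain analogue of
  Rayleigh proportional damping; and
* $c$ — a velocity-proportional surface damping pressure
  $P = -c\,V_{BM}$ applied opposite to the membrane velocity.

The BM is orthotropic: the shear moduli follow
$G_{xy} = E_x E_y / (E_x + E_y + 2E_y\nu_{xy})$ (and cyclically), and the
complementary Poisson ratios follow the symmetry
$\nu_{ij}/E_i = \nu_{ji}/E_j$.  A historical variant of the third
symmetry relation ($\nu_{yz}/\nu_{zy} = E_z/E_y$) circulates in the
literature; it conflicts with the standard form and is available behind
`use_printed_symmetry = TRUE` in `complementary_poisson()` for
comparison.  The reduced-order partition consumes only $E_X$, so the
choice does not affect any solution.

### Windows

Each window is a lumped series stiffness–mass–resistance element in
volume-velocity convention (divide mechanical quantities by the area
squared):

* **Oval window / SAL**: the stapes footplate (area $4.2\ \mathrm{mm^2}$,
  mass 3 mg) rides on an annular ligament ring sheared across its width,
  $K = G \cdot 2\pi r_{fp} t_{ring} / b_{ring}$.
* **Round window**: a clamped circular plate under uniform pressure,
  acoustic compliance $C_a = \pi a^6 / 192 D$ with
  $D = E t^3 / 12(1-\nu^2)$, plus the effective modal mass
  $\tfrac{9}{5}\rho_m t / \pi a^2$.

Both closures carry Rayleigh damping and, in addition, a structural loss
factor $\eta = 0.2$ (complex stiffness $K(1 + i\eta)$).  The loss factor
is a standard soft-tissue hysteretic value; without it the lumped
closures resonate near 3.5 kHz with quality factors of order 50, far
sharper than any measured window impedance.

Pathology acts only here: a scenario multiplies the Young's modulus of
one closure by 100 (`x100`) or replaces it with that of bone, 200 GPa
(`ossified`).  The BM never changes across scenarios.

### Stimuli and the equal-force rule

Forward stimulation applies a uniform pressure over the oval window
membrane ($5.1\ \mathrm{mm^2}$); reverse stimulation over the round
window membrane ($2.3\ \mathrm{mm^2}$).  A 60 dB SPL ear-canal stimulus
is mapped to the oval window through an assumed middle-ear gain of 26 dB
(the ~24 dB tympanic/oval surface ratio plus a 2.5 dB ossicular lever,
rounded to the fixed constant).  The reverse level then enforces equal
delivered force, $L_{RW} = L_{OW} + 20\log_{10}(A_{OW}/A_{RW})$, giving
the 86 / ~93 dB SPL pair and a delivered force of about 2.05 µN.  The
driven areas deserve a note: pressures could also be referred to the
stapes head ($0.58\ \mathrm{mm^2}$), but only the membrane-area pair
(5.1 / 2.3) reproduces the 86→93 dB conversion, so the package uses it
and keeps the stapes-head area as a geometry constant.

## Parameters

| Parameter | Default | Units | Source/rationale |
|---|---|---|---|
| $E_X=E_Z$, $E_Y$ (BM) | $2\times10^6$, $2\times10^4$ | Pa | adopted constitutive set (cochlear FE literature) |
| BM Poisson ratios | 0.3 | — | not measured; mid-range structural value |
| RWM $E$, $\nu$, $t$ | $5\times10^6$, 0.49, 70 µm | Pa, —, m | material set; thickness literature |
| SAL baseline $E$ | $1\times10^5 \times 3.0$ | Pa | unpublished upstream; scale set so the ring stiffness is ~1.5 kN/m, mid-range of published SAL measurements |
| $\rho$, $\mu$ (lymph) | 1034, 0.0028 | kg/m³, N·s/m² | perilymph literature values |
| $\alpha$, $\beta$, $c$ | 100, $6.43\times10^{-7}$, 5000 | 1/s, s, Pa·s/m | adopted damping set ($c$ is conventionally quoted unitless; interpreted as pressure per velocity) |
| window loss factor $\eta$ | 0.2 | — | soft-tissue hysteretic damping |
| BM length; width; thickness | 35 mm; 0.10→0.50 mm; 7→2 µm | — | canonical human box-model values (no mesh published for this model class) |
| duct areas; helicotrema | 1.0 mm² each; 0.3 mm² | — | canonical; SV/ST split unstated upstream, equal by default |
| $n$ segments | 500 | — | converged (<2% change on doubling), ~5 ms per solve |
| Greenwood $A$, $a$, $k$ | 165.4, 2.1, 0.88 | Hz, —, — | human literature constants |

All of these are overridable through the nested YAML configuration
(`cochlea_config()`); `write_resolved_config()` records every effective
value.

## Calibration

Two scalars are calibrated once and frozen:

1. **Partition bending constant $C$** — `calibrate_bm_stiffness()`
   bisects on $\log C$ until the forward characteristic-frequency (CF)
   place at 1 kHz lands on the Greenwood place for 1 kHz.  The frozen
   default is $C = 7176.14$.  With it, the model CF map tracks the
   Greenwood curve within a factor of 2 in frequency over 125–4000 Hz
   (the largest deviation, ×1.38, is at 4 kHz).
2. **SAL stiffness scale** — the baseline ligament modulus is not
   published; the single documented scalar (3.0) puts the annular ring
   stiffness near 1.5 kN/m, the mid-range of published measurements.

The ear-canal gain (26 dB) is an assumption of the stimulus bookkeeping,
not a fitted value.

## Numerical scheme

Nodal analysis of the ladder gives a complex block-tridiagonal system
with 2×2 blocks (one scala-vestibuli and one scala-tympani pressure per
segment), solved by block Thomas elimination in $O(n)$; the relative
residual is recorded on every solution and stays below $10^{-10}$
(verified against a dense LAPACK factorization in the tests).  The
system matrix is identical for forward and reverse runs; only the source
vector differs.  Because the network has no compliance to ground except
the two windows, volume-velocity conservation
$|u_{OW} + u_{RW}| / \max(|u_{OW}|, |u_{RW}|) \le 10^{-6}$ holds in
every cell by construction and is asserted on every run.

Other numerical choices: the CF place is the arg-max of $|d(x)|$ with
parabolic refinement on the log-amplitude, ties broken toward the base,
and boundary maxima reported with a warning; phase is unwrapped base to
apex and referenced to the basal segment, in cycles (negative = lag);
the vestibule probe pressure is interpolated linearly at 200 µm from the
oval window; the stapes is a rigid piston,
$d_{stapes} = u_{OW} / (i\omega A_{fp})$.

## What the fixtures emulate — and what they do not

The configuration generator stands in for external inputs: it
reproduces the five window/membrane areas exactly, the printed material
and damping constants, the five pathology scenarios, and it adds
lognormal perturbation ensembles (`perturb_ensemble()`) for robustness
work.  It does **not** reproduce a 3D geometry: the duct shapes, the
spiral, and the real window anatomies are replaced by canonical
box-model values.  Passing tests therefore certify the reduced-order
physics and its bookkeeping, not anatomical fidelity.

The model is passive and linear: no cochlear amplifier, no nonlinearity,
no time domain.  The middle ear is a fixed scalar gain, so the middle
ear transfer function inherits the reduced model's input impedance: its
low-frequency values (≈ −25 dB re µm/Pa at 125–250 Hz) sit inside
published measurement bands, but it rolls off faster than measured METFs
above 1 kHz because the ossicular chain and stapes rocking modes are not
modelled.

## Known limitations

* **Single-loop topology.**  Both windows sit in one series loop, so
  under equal delivered force the reverse/forward amplitude ratio is
  exactly the pressure ratio $A_{OW}/A_{RW} = 5.1/2.3$ (+6.9 dB) in
  every scenario and at every frequency.  The clinically expected
  *reversal* of that advantage under round-window ossification — where
  the actuator pushes on a plate that no longer yields — requires
  modelling the source–membrane coupling and is outside this topology.
* **High-frequency window–fluid resonance.**  Near the top of the band a
  stiffened window's stiffness reactance can partially cancel the
  mass-dominated cochlear input reactance, so a ×100 stiffening can
  *gain* ~1 dB at 4 kHz.  In that regime the SAL-vs-RWM decrement
  ordering (SAL loss ≥ RWM loss, which holds throughout the band
  wherever the decrements are real losses) flips by 0.07 dB at one
  matrix cell; the corresponding acceptance assertion is left failing
  rather than relaxed, since the orderings are meaningful only where
  stiffening actually impairs transmission.
* **Travelling-wave dispersion.**  The phase lag at the CF place
  averages ~0.7 cycles across 125–4000 Hz and both pathways; fully 3D
  models of the same system report ~0.5.  The accumulated phase is fixed
  once the duct area, the damping constants and the Greenwood-calibrated
  stiffness are set, so the package reports the value its physics
  produces.

## Problem sizes

All shipped results use $n = 500$ segments (grid-converged to <2%), the
six audiometric frequencies, and the full 60-cell matrix, which solves
in a few seconds; the test suite uses coarser grids where only structure
is under test.
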