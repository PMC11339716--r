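# cochleabox

A reduced-order, frequency-domain model of human cochlear mechanics for
comparing **forward (oval-window) and reverse (round-window) mechanical
stimulation**, as delivered by active middle ear implants, under normal
and pathological window conditions.

Clinicians choosing between oval-window and round-window vibroplasty face
a question that clinical data cannot cleanly answer: the two operations
are never performed on the same ear, and middle-ear pathology differs
between cohorts.  `cochleabox` answers it in a controlled setting — a
two-duct transmission-line ("box") cochlea in which the stapedial annular
ligament (SAL) and the round window membrane (RWM) are explicit lumped
closures that can be stiffened 100-fold (otosclerosis staging, fibrosis,
coupling layers) or ossified to bone (200 GPa).

## The model in brief

Two incompressible fluid columns (scala vestibuli and tympani, density
1034 kg/m³, viscosity 0.0028 N·s/m²) are coupled through a locally
reacting orthotropic basilar-membrane partition

    z_p(x, f) = iωm(x) + r(x) + c + k(x)/(iω),

with mass `m(x) = ρ_BM t(x) + (π/4) ρ w(x)`, bending stiffness
`k(x) = C E_X t(x)³ / w(x)⁴`, Rayleigh resistance `r = αm + βk`
(α = 100 s⁻¹, β = 6.43×10⁻⁷ s) and surface damping c = 5000 Pa·s/m.
The oval window is a stapes footplate on an annular-ligament shear ring;
the round window is a clamped elastic plate; the helicotrema shunts the
ducts at the apex.  Nodal analysis gives a block-tridiagonal complex
system solved in O(n); conservation `|u_OW + u_RW|/max(...) ≤ 1e-6` and a
relative residual < 1e-10 are checked on every solve.  Forward
stimulation drives the oval window membrane at 86 dB SPL (60 dB SPL ear
canal + 26 dB assumed middle-ear gain); reverse stimulation drives the
round window at the equal-force level (~93 dB SPL over the smaller area,
~2.05 µN either way).

Metrics include the middle ear transfer function, cochlear input
impedance `Z_C = P_SV / U_stapes`, reverse middle ear impedance,
round-to-oval volume-displacement ratio, characteristic-frequency (CF)
maps against the Greenwood place–frequency curve
`f(x) = 165.4 (10^(2.1(1−x)) − 0.88)`, travelling-wave phase re the
basal edge, and relative BM amplitude at the normal-forward CF place — a
hearing-threshold-change proxy.

## Worked example

```r
library(cochleabox)

model <- build_model()                    # normal scenario, 500 segments
sol <- solve_cochlea(model, frequency = 1000, pathway = "forward")
print(sol)
#> Cochlea solution: forward, 1000 Hz, scenario 'normal'
#>   max |d| = 1.04e-09 m at x/L = 0.599
#>   |u_ow| = 2.21e-12, |u_rw| = 2.21e-12 m^3/s, conservation = 9.1e-13
```

The 1 kHz travelling wave peaks at 60% of the BM length — the Greenwood
place for 1 kHz — with a BM displacement of ~1 nm and window volume
velocities equal to 12 digits (incompressibility).  The full comparison
matrix (5 scenarios × 2 pathways × 6 audiometric frequencies):

```r
records <- run_matrix()
adv <- pathway_advantage(records)        # reverse − forward, dB
dec <- pathology_decrement(records)      # loss re normal-forward hearing, dB
subset(dec, pathway == "forward" & frequency %in% c(125, 1000) &
            scenario %in% c("sal_x100", "rwm_x100"))
#>  scenario pathway frequency decrement_db
#>  sal_x100 forward       125        39.58
#>  sal_x100 forward      1000        16.65
#>  rwm_x100 forward       125        30.71
#>  rwm_x100 forward      1000         6.52
```

Stiffening either window costs tens of dB at low frequencies — SAL
fixation more than RWM stiffening, and 125 Hz more than 1 kHz — while
equal-force reverse stimulation delivers 6.9 dB more maximum BM
displacement than forward stimulation on the normal model (the
oval/round window pressure ratio under equal force).

A command-line front end wraps the same functions:

```sh
Rscript inst/cli/cochleabox.R calibrate            # stimulus table
Rscript inst/cli/cochleabox.R run-matrix --out out # 60-cell matrix + CSVs
```

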