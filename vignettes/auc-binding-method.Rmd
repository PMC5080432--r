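---
title: "Characterizing nanoparticle-protein binding by sedimentation velocity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing nanoparticle-protein binding by sedimentation velocity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aucbind)
```

## The measurement and the model

In a sedimentation-velocity (SV) run, a well-mixed particle solution spins
at constant angular velocity $\omega$ in a sector-shaped cell and an
optical system records radial concentration profiles $c(r, t)$. The
evolution of $c$ is governed by the Lamm equation,

$$\frac{\partial c}{\partial t} =
\frac{1}{r}\frac{\partial}{\partial r}\!\left[ r D \frac{\partial c}{\partial r}
 - s\,\omega^2 r^2 c \right],$$

with the sedimentation coefficient $s$ and diffusion coefficient $D$ as
decoupled parameters. For a sphere,
$s = d^2(\rho_p - \rho_s)/(18\eta)$ and $D = k_BT/(3\pi\eta d)$, so a
measured $(s, D)$ pair inverts to a hydrodynamic diameter and an effective
density.

Protein adsorption changes both the volume and the density of the
sedimenting object. `aucbind` models a particle carrying $N_{avg}$
proteins as the equivalent sphere of volume $V_{NP} + N_{avg}V_P$ with
volume-weighted density
$\rho_{cx} = (\rho_{NP}V_{NP} + N_{avg}\rho_P V_P)/(V_{NP} + N_{avg}V_P)$,
and couples the coverage to the free-protein concentration through the
Hill isotherm $N_{avg} = N_{max}[P]^n/(K_D^n + [P]^n)$. The composed curve
$\bar{s}([P])$ is the fit model: dense metal cores slow down as they
accumulate light protein (friction grows faster than buoyant mass), so the
isotherm typically falls from the bare-particle $s$ to a saturation
plateau. The analytic sign of $d s/d N_{avg}$ equals the sign of
$(\rho_P-\rho_s) - (\rho_{cx}-\rho_s)/3$, which the test suite checks
against numerical derivatives.

Two standing assumptions matter. Binding must be reversible on the
equilibration timescale (the Hill formalism requires it; the
`dilution_shift()` forward prediction is the experimental check), and the
protein must be in large excess over binding sites — which bounds the
measurable $K_D$ from below at roughly 0.01 µM for typical particle
loadings; `fit_isotherm()` warns when a fitted $K_D$ leaves this window,
and at the other end when saturating the isotherm would demand more than
~10 mM protein.

## Parameters and defaults

| Parameter | Default | Why |
|---|---|---|
| Solvent | water, 20 °C ($\eta$ = 1.002 mPa s, $\rho_s$ = 0.99823 g/cm³) | standard scan temperature; buffers override $\eta, \rho_s$ |
| Protein volume $V_P$ | 97.8 nm³ | serum-albumin hydrodynamic shape: equilateral triangular prism, 8.4 nm edge, 3.2 nm thick |
| Protein density $\rho_P$ | 1.3 g/cm³ | typical globular protein; warning outside 1.0–2.0 |
| Loading signal | 0.8 OD | middle of the reliable optical range 0.2–1.2 OD |
| Rotor speed | 12,000 r.p.m. | upper end of the 6,000–12,000 range used for dense gold particles |
| Scans | 45, uniform to the clearing time of the slowest species | matches the 40–50 scans a real run collects |
| Scan noise | 0.005 OD | plausible absorbance-optics noise; configurable, not asserted as any instrument's value |
| Isotherm noise | 2 % relative per replicate, 3 replicates | emulates triplicate-experiment error bars |
| Concentration grid | 12 log-spaced points over $[K_D/30,\,100K_D]$ plus 0 | covers onset and saturation with a bare-particle anchor |
| Fit bounds | $K_D \in [10^{-9}, 10^{-1}]$ M, $N_{max} \in [0, 10\times$ geometric capacity$]$, $n \in [0.2, 5]$ | generous physical box; geometric capacity from a one-protein-thick shell |

All internal computation is SI; user-facing tables use Svedberg, g/cm³,
nm and molar units with explicit converters (`seconds_to_sv()` etc.). The
conversion constants are arranged as matched divide/multiply pairs so that
writing a spec to a config file and reading it back is bit-exact.

## Numerical choices

**Lamm solver.** Conservative finite volume on a uniform radial grid; the
conserved quantity is the sector-weighted mass $\sum_i c_i r_i h$, which
the scheme preserves to machine precision with no-flux boundaries. Face
fluxes use exponential fitting (Scharfetter–Gummel): the flux across each
face solves the local constant-coefficient advection–diffusion problem
exactly, which reduces to centred differencing at low Péclet number and to
upwinding in the advection-dominated limit. This matters because SV
boundaries of dense particles are steep: a plain centred scheme
oscillates there, while exponential fitting stays positive and lets the
solver reproduce the diffusion-free boundary kinematics
$r_{mid}(t) = r_m e^{s\omega^2 t}$ and the square dilution law
$c_{plateau}(t) = c_0 e^{-2s\omega^2 t}$ to a fraction of a percent. Time
stepping is Crank–Nicolson with the step chosen from an advective Courant
number of 0.4; the scheme is first-order near the moving front (the
upwinded limit), so the step-halving self-convergence check is run at 800
radial cells, where halving changes signals by under 0.1 % of loading.
Rotor acceleration is neglected (instant $\omega$), and the initial
condition is uniform loading.

**c(s)-style inversion.** A basis of unit-loading Lamm solutions is built
on the scan geometry and times, one per grid value of $s$, each given the
$D$ implied by the scaling law at an assumed frictional ratio and analyte
density. Weights solve a non-negative least-squares problem with
second-difference Tikhonov regularization, computed on the normal
equations (Cholesky + Lawson–Hanson NNLS) so cost is set by the grid size,
not the number of scan points. Two percent of the column at the base and
0.5 % at the meniscus are excluded from the fit by default
(`fit_margin`): the no-flux pile-up at the base is a boundary artefact of
the cell, not information about the species, and including it lets
grid-mismatch residuals dominate the fit. The default regularization
strength follows the discrepancy principle — the largest $\lambda$ on a
log grid whose refit RMSD stays within 5 % of the noise level (recorded in
the scan metadata, or estimated from radial second differences).
Diffusion information enters through a scalar frictional-ratio line
search (`scan_fr_grid()`): the candidate minimizing refit RMSD is
selected, a one-parameter analogue of 2D $c(s, f/f_0)$ analysis — the
downstream isotherm consumes only weighted-average $s$ and an effective
$D$, so a full 2D map is not needed. A flat RMSD profile is reported as
"f/f0 unresolved" rather than a value.

**Isotherm fit.** Bounded Levenberg–Marquardt on
$(\log_{10}K_D, N_{max}, n)$, multi-started from eight log-spaced $K_D$
values — the SSE surface has a long shallow ridge along which larger
$K_D$, larger $N_{max}$ and smaller $n$ compensate, and single starts can
strand on it. Weights are $1/\mathrm{sd}^2$ from replicate SDs, floored at
10 % of the median SD: with three replicates the sample SD is so noisy
that unfloored inverse-variance weights are dominated by points whose
replicates happened to agree. Flat isotherms return an explicit
"no binding detected" outcome with $N_{max}$ pinned at zero instead of a
spurious fit. Standard errors default to the Jacobian at the optimum
(delta method back to the $K_D$ scale); a parametric bootstrap
(`n_boot`) refits datasets simulated at the fitted curve with per-point
noise $\mathrm{sd}/(c_4\sqrt{n_{reps}})$ — the $c_4$ factor undoes the
small-sample bias of the sample SD. The bootstrap intervals achieve
roughly nominal (58 % observed vs 68 % nominal at 2 % noise) coverage;
the plain Jacobian intervals run a few points lower. Because the ridge
makes the $K_D$ likelihood strongly right-skewed, point estimates from a
single noisy isotherm scatter asymmetrically: medians over ~30 replicate
isotherms at 2 % noise sit within the replicate scatter of the generating
value for weakly-bound systems, but can run 20–30 % high where the
printed uncertainty is a few percent (the method benchmark reports this
honestly rather than calibrating it away).

**Shape analysis.** `shape_series()` back-calculates $N_{avg}$ and
$\rho_{cx}$ from the fitted parameters at each measured concentration and
evaluates $f/f_0$ from the measured $(s, D)$ with the modelled complex
density — no refitting. The thermodynamic parameters were themselves
obtained assuming near-spherical sedimentation, so this is a qualitative
diagnostic, and the output records that caveat in its metadata. Rows whose
modelled complex density does not exceed the solvent density are flagged
and get no $f/f_0$ (no real equivalent sphere). Replicate SDs propagate to
$f/f_0$ by first-order propagation
($f/f_0 \propto D^{-2/3} s^{-1/3}$); no smoothing is applied. For
bare-particle rows the modelled density at the modelled coverage (not the
raw NP density) is used, keeping the series continuous through zero
coverage.

## What the synthetic data emulate — and what they do not

`generate_isotherm()` draws replicate $\bar{s}$ values as
$s_{true}(1 + \varepsilon)$, $\varepsilon \sim N(0, 0.02)$, in triplicate:
the scatter of independent repeat experiments. `generate_scan_experiment()`
composes coverage → complex $(s, D)$ → Lamm simulation → Gaussian optical
noise, so the full pipeline closes the loop: at 0.005 OD noise,
single-species $s$ is recovered within 1 % and $D$ within 10 %, and
scans→inversion→fit recovers $(K_D, N_{max}, n)$ with ~2 % median error.
All randomness flows through explicit seeds (`withr::with_seed`), leaving
the global RNG untouched.

Real AUC data differ in ways the generator deliberately omits:
time-invariant and radially-invariant optical offsets, meniscus optical
artefacts, rotor acceleration and stretching, absorbance nonlinearity
above ~1.2 OD, sample polydispersity beyond a single species per mixture,
and slow equilibration. Passing the closed-loop tests therefore
demonstrates correctness of the estimator under the stated noise model,
not robustness to every instrumental systematic; real-data ingestion
through `read_scan_set()` is best-effort.

## Design choices on open points

- The reference tables' printed $(d_H, \rho, s, D)$ tuples come from
  independent measurements and are **not** mutually consistent under the
  simple sphere inversion (e.g. the 7.0 nm system's $D$ implies 7.4 nm);
  fixtures store the printed values verbatim and no test asserts their
  self-consistency.
- $[P]$ is treated as total protein concentration (valid in the
  large-excess regime the method requires).
- $N_{avg}$ and $N_{max}$ are continuous everywhere; $N_{max}$ is
  reported rounded only in display output.
- Averaging windows for $s_w$ default to the full occupied grid, with a
  peak-window option, since the reference analysis pipeline's choice is
  not specified.
- The benchmark protocol fixes 12 concentrations, triplicates and 2 %
  noise; simulation sizes elsewhere (250–800 radial cells, 15–45 scans,
  30–40 point $s$ grids) were chosen as the coarsest settings at which the
  analytic oracles hold with margin.

## Known limitations

Non-spherical forward hydrodynamics (ellipsoids, bead models), charge and
hydration effects, dynamic density gradients, multi-wavelength optics,
competitive multi-protein binding and kinetic (on/off-rate) modelling are
out of scope. The $K_D$ estimator is median-biased upward at few-percent
noise on ridge-shaped problems, as quantified above; report interval
estimates, not bare points, for single isotherms.
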