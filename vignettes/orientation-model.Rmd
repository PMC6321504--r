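---
title: "Modelling polarized fluorescence from oriented muscle fibers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling polarized fluorescence from oriented muscle fibers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fiberpol)
```

## The measurement and the model

Ghost muscle fibers are glycerinated fibers from which myosin, tropomyosin
and troponin have been extracted, leaving an oriented lattice of F-actin
that can be re-decorated with labelled proteins: 1,5-IAEDANS on Cys707 of
the myosin head (S1), FITC-phalloidin in the actin groove, 5-IAF on Cys190
of tropomyosin. Exciting such a fiber with light polarized parallel or
perpendicular to the fiber axis and analysing the emission in both
orientations yields four steady-state intensities
$({}_\parallel I_\parallel, {}_\parallel I_\perp, {}_\perp I_\perp,
{}_\perp I_\parallel)$ and the two polarization ratios
$P_\parallel = ({}_\parallel I_\parallel - {}_\parallel I_\perp) /
({}_\parallel I_\parallel + {}_\parallel I_\perp)$ and
$P_\perp = ({}_\perp I_\perp - {}_\perp I_\parallel) /
({}_\perp I_\perp + {}_\perp I_\parallel)$.

`fiberpol` models these intensities with a *helix plus isotropic* picture.
A fraction $1-N$ of the probes is ordered: their absorption and emission
dipoles lie on cones of half-angles $\Phi_A$ and $\Phi_E$ about the
filament axis, spiralling along it, while the filament axis itself deviates
from the fiber axis by up to a wobble half-angle $\theta_{1/2}$. The
remaining fraction $N$ is isotropically disordered. $N$ is reported
throughout as the **disordered** fraction — it rises when myosin heads
detach — and the mixture is $(1-N)\,\text{ordered} + N\,\text{isotropic}$
with no per-population renormalization, since both populations share one
absorption cross-section and quantum yield. All intensities are defined up
to one common scale, so every comparison is made on sum-normalized
quadruples.

Each intensity is the orientation average
$\langle (\mathbf a\cdot\hat e_{exc})^2 (\mathbf e\cdot\hat e_{em})^2\rangle$
in the lab frame (fiber along OZ, light along OY, polarizers along OZ/OX).

### Why the cone azimuths are averaged independently

Two conventions exist for the relative azimuth of the absorption and
emission dipoles on their cones. If both dipoles ride the helix at a
*locked* common azimuth (offset $\delta$ fixed by the molecular angle
$\gamma$ between them), the crossing $P_\parallel = P_\perp$ for collinear
dipoles without wobble falls at $\approx 51.9^\circ$. If instead the two
azimuths are averaged *independently* — as happens physically when the
probe rotates about the cone axis during the excited-state lifetime — the
model gives $P_\perp = -P_\parallel$ identically, so the ratios cross
exactly at the magic angle
$\Phi = \arccos(1/\sqrt 3) = 54.7356^\circ$, and the sign of
$P_\parallel - P_\perp$ alone says whether the mean dipole angle is below
or above $54.7^\circ$. Only the independent convention reproduces these
standard interpretive rules of fiber fluorimetry, so it is the default;
`quadrature_settings(azimuth = "locked")` selects the alternative, which is
retained for comparison and validated against its own Monte-Carlo sampler.
Under the independent convention the molecular angle $\gamma$ still
constrains the cone pair through feasibility,
$|\Phi_A - \Phi_E| \le \gamma \le \Phi_A + \Phi_E$, and through the tie
used in fitting (below).

### Evaluation

With independent azimuths, the azimuth averages reduce every component to
the two wobble moments $\langle\cos^2\theta_f\rangle$ and
$\langle\cos^4\theta_f\rangle$, which have closed forms for both supported
wobble distributions: uniform in the polar angle on $[0, \theta_{1/2}]$
(the default reading of a stated *maximal* deviation) and uniform over the
spherical cap (`wobble = "solid_angle"`). The forward model is therefore
exact arithmetic; the locked variant keeps a two-dimensional quadrature
(equally spaced azimuth nodes, which are exact for the degree-4
trigonometric integrand, and Gauss–Legendre in $\theta_f$ with a half-node
convergence check). Both routes are tested against direct Monte-Carlo
sampling of the same geometry to better than $10^{-3}$ relative.

## Inverse problem

`fit_orientation()` minimizes the squared distance between sum-normalized
observed and modelled quadruples over $(\Phi_E, N, \theta_{1/2})$, with
bounds $\Phi_E \in [0^\circ, 90^\circ]$, $N \in [0,1]$,
$\theta_{1/2} \in [0^\circ, 60^\circ]$, and $\Phi_A$ tied to
$\Phi_E$ as $\Phi_A = |\Phi_E - \gamma|$. The tie removes one degree of
freedom (the experiments report a single cone angle because both moved in
parallel), and the absolute value keeps the tie continuous where
$\Phi_E < \gamma$, which the optimizer needs; both branches keep the
molecular angle feasible. The loss is unweighted because no per-component
variance is available and the common scale is unknown.

A normalized quadruple has three degrees of freedom, matching the three
free parameters, and in practice the map is invertible away from the
degenerate corners: a deterministic 54-start grid
(6 $\Phi_E$ × 3 $N$ × 3 $\theta_{1/2}$ values) followed by bounded
quasi-Newton refinement recovers random feasible states noise-free to
better than $0.1^\circ$ in $\Phi_E$ and $0.005$ in $N$. Because the start
grid is fixed, fits are reproducible bit-for-bit. Two safeguards are
flagged rather than silently resolved: `degenerate` when two minima tie
within SSR $10^{-6}$ but disagree by more than $2^\circ$ in $\Phi_E$ or
$0.05$ in $N$, and `disordered_only` when $N$ fits above 0.98, where the
ordered parameters mean nothing. `fit_ensemble()` aggregates 8–10 fibers
per condition into means ± SEM, excluding (and counting) failed fibers.

## From wobble to bending stiffness

For a semiflexible filament of length $L$, fixed at one end, thermal
bending gives $\sin^2\theta = 0.87\,(kT/\varepsilon)\,L$, so
$\varepsilon = 0.87\,kTL/\sin^2\theta_{1/2}$. The package treats $\theta$
in this relation as the wobble half-angle $\theta_{1/2}$ of the orientation
model (its defining geometric quantity). Defaults $L = 1\,\mu m$ and
$T = 293.15\,$K (room temperature) are configuration values; with them a
stiffness of $5\times10^{-26}\,\mathrm{N\,m^2}$ corresponds to a plausible
wobble of about $15^\circ$. Stiffness is reported in units of
$10^{-26}\,\mathrm{N\,m^2}$. The two conversions are exact mutual inverses,
and angles at the $\theta = 90^\circ$ boundary are flagged.

Because calcium also rotates the actin monomers themselves, tropomyosin
angles are additionally expressed in the rotating F-actin frame:
`corrected_phi_e()` computes
$\Phi_E^{corr} = \Phi_E^{Tpm} - (\Phi_E^{actin} - \Phi_E^{actin,ref})$,
with the no-S1, low-calcium (blocked-state) actin angle as the default
reference frame (configurable in `run_config()`).

## ATPase analysis

Assays titrate actin-activated S1 ATPase from pCa 8 to 4.
`normalize_activity()` subtracts the S1-alone baseline and rescales the
whole curve (replicates jointly) to its own maximum; `fit_hill()` fits
$a(\mathrm{pCa}) = \text{floor} + \text{amplitude}/(1 +
10^{\,n_H(\mathrm{pCa} - \mathrm{pCa}_{50})})$ by bounded
Levenberg–Marquardt least squares, multi-started over a pCa$_{50}$ grid,
with replicates entering one SSR (preserving the error structure; for
balanced designs this is indistinguishable from averaging first).
Only pCa$_{50}$ feeds the downstream calcium-sensitivity call; $n_H$ is
estimated but not interpreted. Fits at a parameter bound and flat curves
are flagged or rejected, never silently returned.

## Mutant signatures and classification

`delta_table()` compares mutant and wild-type fiber ensembles per shared
condition with two-sided Student's t-tests (pooled variance by default —
the era's standard "Student's t-test" — with Welch as an option) and makes
trinary calls: `up`/`down` when $p < \alpha$ (default $\alpha = 0.05$),
else `norm`. `signature_from_deltas()` maps the calls to a 14-feature
vector: one calcium-sensitivity column (up/down when the pCa$_{50}$
difference exceeds ±0.1 with non-overlapping standard errors; reported
mutant-versus-wild-type differences are ≥ 0.12, so 0.1 separates them from
preparation scatter), one tropomyosin-stiffness column (the sign of
$\Delta\varepsilon$ for the tropomyosin probe without S1 at high calcium),
and six high/low-calcium pairs. Tropomyosin *shifts toward the inner actin
domain* are the negated $\Delta\Phi_E$ sign (a drop in angle is an inward
shift); *actin switching-on* is the $\Delta\Phi_E$ sign of the actin probe;
*strong binding of the myosin heads* requires the negated $\Delta\Phi_E$
and negated $\Delta N$ calls of the S1 probe to agree — the two are always
cited together as joint evidence — and discordance yields `missing` with a
logged conflict.

The published effect matrix for twelve mutations in the three muscle
tropomyosin genes ships as a versioned CSV
(`inst/extdata/tpm_mutation_signatures.csv`). It has 14 feature columns —
calcium sensitivity and tropomyosin stiffness are single columns, the rest
high/low pairs. Four *consensus* rows distil each myopathy group's defining
strong-binding behaviour: congenital fiber-type disproportion (CFTD) has
more strongly bound heads at both calcium levels; cap myopathy (Cap) fewer
at high calcium but more at low calcium with ATP; nemaline myopathy (NM)
fewer at high *and* low calcium; distal arthrogryposis (DA) more at high
calcium with normal troponin-induced tropomyosin shifts.
`classify_signature()` finds the nearest reference by Hamming distance over
mutually non-missing features, normalized by the number compared, and flags
ties between groups within one feature. A trinary encoding cannot express
the *magnitude* distinction that separates NM from Cap (NM shows the more
pronounced high-calcium decrease); the NM consensus row encodes it
qualitatively as a decrease at both calcium levels, and a magnitude-aware
extension is deliberately out of scope.

## The synthetic-data generator

`default_scenario()` fixes a truth table emulating the study design: three
probes, high/low calcium, without S1 and with S1 in the nucleotide-free,
MgADP and MgATP states, 10 fibers per condition. Printed wild-type values
anchor it: S1 disordered fractions 0.393 (rigor, high Ca²⁺), 0.432 (low
Ca²⁺) and 0.576 (MgATP), S1 angles 44.7° → 51.2°, actin angles
48.4° → 47.5° with stiffness 4.2 → 5.5 ×10⁻²⁶ N m², tropomyosin stiffness
13.9/16.1 → 7.5 ×10⁻²⁶ N m², corrected tropomyosin angles consistent with
the 56.7°/58.6° (no S1) and 54.2°/54.7° (rigor) pairs, and mutant
pCa$_{50}$ values 6.84 (E173A), 6.92 (R90P), 7.33 (E150A), 6.69 (A155T)
against 6.5 for the wild type. Unprinted cells (ADP intermediates, low-Ca
actin stiffness, disordered fractions of the filament probes) are realistic
interpolations chosen once: the S1 wobble is fixed at 25°, tropomyosin and
actin probes carry disordered fractions 0.20 and 0.15.

Mutant truths perturb the wild type with the trinary structure of the
reference matrix at illustrative magnitudes — 1.5° tropomyosin shifts, 1.2°
actin shifts, 2° and 0.06 for the S1 angle and disordered fraction, and
5×10⁻²⁶ N m² for tropomyosin stiffness (the scale of the printed halving
from 12.2 to 6.8) — documented as illustrative, not measured.

Measurement noise is multiplicative lognormal per intensity component with
unit mean and CV 2%, chosen so that simulated SEMs over 8–10 fibers
resemble published error bars; no noise magnitudes are reported, so this is
a design choice. All variance is placed in measurement noise (true
fiber-to-fiber parameter scatter is unreported); consequently passing
recovery tests demonstrates correctness of the inverse machinery under the
stated noise model, not robustness to biological heterogeneity,
instrumental drift, photobleaching or probe-angle variation, which the
generator deliberately omits. One caveat surfaced by the simulations
honestly: per-fiber stiffness estimates inherit the weak sensitivity of the
quadruple to small wobble angles ($\varepsilon \propto 1/\sin^2\theta$), so
the stiffness feature is the least reliably significant at n = 10 — which
is also a caution against over-reading small printed stiffness changes.

## Numerical choices and problem sizes

Angles are degrees at every interface and radians internally. Optimizer
tolerances are $10^{-12}$ relative; the start grid is seedless and fixed.
Simulation-based test sizes were chosen to make the checks sharp at
interactive run times: 40–100 random states for round-trip sweeps, 40
replicate ensembles for coverage, 60 seeds for Hill-bias checks, and
two-variant pipelines for the end-to-end classification test. All
randomness flows from explicit seeds, so every result in the test suite and
in `scripts/acceptance.R` is reproducible.

## A worked example

```{r, eval = FALSE}
sc <- default_scenario(c("WT", "E173A"))
ds <- generate_fiber_dataset(sc, seed = 11)
report <- run_pipeline(ds$fibers)
report$classifications$E173A$label   # "CFTD"
```
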