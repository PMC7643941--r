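---
title: "Dual-basin structure-based simulation and smFRET forward modeling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-basin structure-based simulation and smFRET forward modeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sbmfret)
```

## The model

`sbmfret` simulates the spontaneous open/closed ("clamshell") motion of a
two-domain binding protein carrying an explicit donor/acceptor dye pair, and
converts the resulting trajectories into the observables a single-molecule
FRET experiment records. The force field is a structure-based (Gō-type)
model with *two* native basins: every pairwise contact present in either
reference conformation contributes a multibasin term

$$C_{ij}(r) = \Big(1 + (\sigma_{NC}/r)^{12}\Big)
  \Big(1 + G(r, r^{\alpha}_{ij})\Big)\Big(1 + G(r, r^{\beta}_{ij})\Big) - 1,
  \qquad
  G(r, r_0) = -A\, e^{-(r - r_0)^2 / 2\sigma^2},$$

where $r^{\alpha}$ and $r^{\beta}$ are the native distances in the open and
closed conformations. With the default amplitude $A = 1$ each well floor sits
at exactly $-1$ (in reduced energy units $\varepsilon_0 = 1$); a contact seen
in only one conformation keeps a single Gaussian factor; a degenerate dual
record with $r^{\alpha} = r^{\beta}$ reduces exactly to the single-basin
form. The total potential adds harmonic bonds
($\varepsilon_r = 50$), angles ($\varepsilon_\theta = 40$), harmonic
improper/planar dihedrals ($\varepsilon_{\chi i} = 10$,
$\varepsilon_{\chi p} = 40$), proper dihedrals
$\varepsilon\,[(1-\cos\Delta\phi) + \tfrac12(1-\cos 3\Delta\phi)]$, and
$\varepsilon_{NC}(\sigma_{NC}/r)^{12}$ excluded volume
($\varepsilon_{NC} = 0.1$, $\sigma_{NC} = 2.5\ \mathring{A}$) over all
remaining pairs. Dynamics are integrated with a BAOAB-split Langevin scheme
(reduced units, $k_B = 1$, timestep $0.002$, friction $\gamma = 1$ per
reduced time unit unless overridden); with zero friction the scheme reduces
to velocity Verlet, which is how the energy-conservation tests run.

The note about the Gaussian width deserves emphasis: the well width enters
as the standard deviation of a standard Gaussian,
$\exp(-(r-r_0)^2/2\sigma^2)$. The width is not uniquely pinned down by the
functional form alone, so it is a configurable parameter with default
$\sigma = 0.5\ \mathring{A}$ at atomic resolution and
$1.0\ \mathring{A}$ for the C$\alpha$-scale synthetic system, where one well
subsumes side-chain breadth.

## From trajectory to camera trace

The FRET observable chain is: per-frame inter-chromophore distance
$R_\mathrm{dye}$ (mass-weighted centers of the chromophore atoms, linkers
excluded) $\to$ instantaneous efficiency $E = 1/(1 + (R/R_0)^6)$ $\to$
camera binning, where a bin averages `round(exposure / step_duration)`
consecutive efficiencies and a trailing partial bin is discarded. By
convention a single Förster radius — derived from the *mean* orientation
factor $\kappa^2 = (\cos\theta_{AD} - 3\cos\theta_D\cos\theta_A)^2$ — is
applied to all frames; a per-frame $\kappa^2$-resolved mode exists but is
not the default, matching how experimental distances are inferred from one
$R_0$. The rescaling law $R_0 \propto (\kappa^2)^{1/6}$ converts a reference
$R_0$ between orientation regimes; the spectroscopic compute mode uses
$R_0[\mathring{A}] = 2.108\,(\kappa^2\, n^{-4}\, Q_D\, J)^{1/6}$ with $J$ in
$M^{-1}cm^{-1}nm^4$, stated explicitly because the textbook prefactor is
otherwise unit-ambiguous.

Physical time is assigned *a posteriori*: reduced-model steps have no
intrinsic duration, so the mean closed-state dwell (maximal runs with
$R_\mathrm{dye} < 60\ \mathring{A}$) is matched against the experimental
mean dwell. For the reference system, a 212 s$^{-1}$ opening rate gives a
4.7 ms dwell, and matching $1.9\times10^7$ simulated steps to it assigns
$\approx 0.25$ ns per step, which in turn makes a 1 ms camera exposure an
average over $4\times10^6$ steps. Dwell detection debounces runs shorter
than `min_dwell` (default 100 steps) to suppress barrier-top recrossings —
the cutoff criterion itself uses no hysteresis — and truncated first/last
runs never enter the mean.

## Landscapes and rates

Free-energy surfaces are Boltzmann inversions of binned occupancies,
$\Delta G^* = -k_B T \ln(P(x_i)/P_\mathrm{max})$ with
$k_B = 0.0019872$ kcal/mol/K; the most occupied bin is exactly zero and
empty bins are undefined (`NA`), never zero. The transition rate over a 1-D
profile is the overdamped mean-first-passage form with constant diffusion
coefficient $D$,

$$\frac{1}{k} = \int_{x_\mathrm{start}}^{x_\mathrm{end}} \frac{dx}{D}\,
 e^{G(x)/k_BT} \int_{x_\mathrm{start}}^{x} dy\, e^{-G(y)/k_BT},$$

evaluated by trapezoidal quadrature on the bin grid (reflecting start,
absorbing end). The printed double-integral form with an unbounded inner
limit is ambiguous as written; this package implements the standard MFPT
expression above, which reproduces the flat-profile closed form
$k = 2D/L^2$ to better than 1% and the overdamped Kramers rate within 20%
at a 5 $k_BT$ barrier (both covered by tests). $D$ itself comes from a
linear fit to the mean-square displacement of the reaction coordinate
($D = \mathrm{slope}/2$ in 1-D), with 1 $\mathring{A}^2$/ns = 10
$\mu m^2$/s for unit conversion. Treating $D$ as constant is a deliberate
simplification; evaluating the integral at a low and a high $D$ brackets
the rate.

## What the synthetic generators emulate

Because every stage must be testable offline, the package ships first-class
generators rather than fixtures:

* **Telegraph traces** — exponential dwells in two states with per-state
  FRET levels and optional additive Gaussian read noise
  (default sd 0.05 when enabled; reproduction presets use 0 because the
  forward model compares idealized efficiencies). The generator returns the
  true switch points so dwell detectors can be checked against ground
  truth.
* **Toy dual-basin bead systems** — 2–10 beads whose end-to-end interaction
  is exactly the multibasin contact, with a quadrature Boltzmann occupancy
  prediction (including the $r^2$ radial Jacobian) for the 2-bead case.
* **A synthetic clamshell protein** — a fully synthetic 344-residue,
  two-domain C$\alpha$ model with one explicit donor and acceptor dye,
  constructed so that its rest geometry reproduces the reference system's
  printed coordinates: the inter-domain pair (12, 237) has the largest
  C$\alpha$ distance change (35 → 22 $\mathring{A}$, $\Delta = 13$), the
  label-site pair (67, 181) moves 57 → 49.3 $\mathring{A}$
  ($\Delta = 7.7$), and the thermally averaged chromophore separation lands
  near 69 $\mathring{A}$ (open) and 56 $\mathring{A}$ (closed). The closed
  conformation is a rigid rotation of domain 2 about a hinge axis; hinge
  residues ride the axis so the backbone is unstrained in both basins, and
  the four key residues sit on triangulated hairpin surface loops.

Design choices worth knowing about:

* **Dye representation.** Each dye is a five-bead chain (two zigzag linker
  beads, a junction bead, and a two-bead chromophore that defines the
  transition dipole). The rest offsets are deliberately *longer* than the
  target separations imply, because thermal linker flexing compacts the
  realized dye positions — the same compaction the reference system shows.
  Dye beads carry reduced mass 0.05 so the slow pendulum-like linker modes
  equilibrate within desk-scale runs; masses are free parameters of a
  reduced-units model and do not affect equilibrium averages.
* **Contact definition.** A plain heavy-atom (or C$\alpha$) distance cutoff
  — default 4.5 $\mathring{A}$ atomic / 6.5 $\mathring{A}$ C$\alpha$,
  sequence separation ≥ 3 — rather than a screened "shadow" map, because
  the cutoff is fully reproducible from the structure alone. Pairs closer
  than $\sigma_{NC}$ are never contacts (a Gaussian well under the
  $r^{-12}$ wall is unphysically stiff), and bonded pairs are never
  duplicated as contacts.
* **Closed-specific contact weight.** Contacts unique to the ligand-bound
  conformation default to weight 0.33, the midpoint of the 0.2–0.46
  calibration range; `scan_contact_weight()` recalibrates it against a
  target closed-state occupancy.
* **Dihedral strengths.** Proper-dihedral strengths are normalized so their
  total is a fixed fraction (default 0.5) of the total contact strength,
  split 2:1 between backbone and side-chain torsions.
* **Numerical conditioning.** Angle terms whose reference angle is within
  0.3 rad of 0 or $\pi$, and torsions with near-collinear internal triples,
  are excluded at build time: their forces contain $1/\sin\theta$ and
  $1/|b_1 \times b_2|^2$ singularities. The affected atoms remain held by
  bonds and contacts. Every force routine is validated against a central
  finite-difference oracle to $10^{-5}$.
* **Temperature.** The reduced temperature is calibrated by matching mean
  C$\alpha$ RMSF to a reference (e.g. explicit-solvent) value through a
  linear fit; 0.3 reduced units is the reference operating point.

## What passing tests do and do not show

The synthetic clamshell reproduces the reference system's *geometry* and
its printed dye-separation bands (69 ± 5 and 56 ± 8 $\mathring{A}$), and its
domain and dye coordinates are positively coupled. It does not reproduce
the exact R$_\mathrm{domain}$–R$_\mathrm{dye}$ Pearson correlation of the
real protein (0.73): that number depends on the specific dye-linker noise
structure of the all-atom system, while the stand-in's dominant noise is
rare linker-compaction events, giving correlations around 0.3–0.6 at
desk-scale sampling. Tests therefore assert the printed bands and positive
coupling, not the exact correlation. Likewise, desk-scale runs here are
$10^5$–$10^6$ steps; the reference aggregate of $10^{11}$ steps is a
configuration preset, not a test condition, so slowly-converging statistics
(dye orientation distributions, transition counts) carry wider error bars
than the printed ones.

## Degenerate inputs and edge policies

Empty traces, empty atom selections, zero-length dipoles, zero-variance
correlation inputs, exposures shorter than one step, and landscapes with
undefined interior bins all raise typed errors rather than propagating
`NaN`s; `mfpt_rate(fill = TRUE)` opts into linear interpolation across
empty bins. Mixture fits flag degenerate solutions (component sigma below a
quarter bin width, or coincident means) instead of failing. The
single-cutoff dwell detector treats sub-`min_dwell` runs by flipping the
shortest offender into its neighbors until none remain, which is symmetric
and order-independent for well-separated flickers.
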