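# sbmfret

Dual-basin structure-based molecular simulation with single-molecule FRET
forward modeling, in R.

Single-molecule FRET (smFRET) watches one labeled protein switch between
conformations — for a clamshell-type biosensor, an open and a closed state
read out as a low- and a high-efficiency FRET level. Conventional explicit
solvent molecular dynamics cannot reach the seconds of sampling an smFRET
movie covers, so the two techniques rarely meet on the same time axis. This
package implements the bridge: a computationally cheap all-atom Gō-type
force field whose contact potential has *two* native basins, so the protein
interconverts spontaneously, plus the full forward model that turns such
trajectories into the quantities an smFRET instrument records.

The multibasin contact for atom pair $(i,j)$ with native distances
$r^\alpha$ (open) and $r^\beta$ (closed) is

$$C_{ij}(r) = \left(1 + (\sigma_{NC}/r)^{12}\right)
  \left(1 + G(r, r^\alpha_{ij})\right)\left(1 + G(r, r^\beta_{ij})\right) - 1,
\qquad G(r, r_0) = -A e^{-(r-r_0)^2/2\sigma^2},$$

embedded in a standard structure-based potential (harmonic bonds/angles,
dihedrals, $r^{-12}$ excluded volume) and integrated with BAOAB Langevin
dynamics in reduced units. Downstream, the package computes
inter-chromophore distances ($R_\mathrm{dye}$), orientation factors
$\kappa^2$, Förster radii, instantaneous efficiencies
$E = 1/(1+(R/R_0)^6)$, camera-exposure-binned traces, dwell-time kinetics
with timestep calibration against experimental dwells, Gaussian-mixture
histogram decomposition, Boltzmann free-energy landscapes, MSD-based
diffusion coefficients, and mean-first-passage-time transition rates.

Audience: simulators who want to predict or interpret smFRET observables,
and single-molecule spectroscopists who want a structural model behind
their traces.

## Worked example

```r
library(sbmfret)

# two-state telegraph emulation of the biosensor at ligand K_D:
# 4.7 ms mean dwells, idealized FRET levels 0.35 (open) / 0.65 (closed)
model <- two_state_model(k_open_to_closed = 1000 / 4.7,
                         k_closed_to_open = 1000 / 4.7,
                         noise_sd = 0, step_duration = 1e4, seed = 1)
trace <- generate_two_state_trace(model, duration = 2)

# camera blurring: at 1 ms the two states resolve, at 100 ms they merge
for (exposure in c(1, 100)) {
  b <- bin_exposure(trace$efficiency, model$step_duration, exposure)
  fit <- fit_gaussian_mixture(
    build_fret_histogram(fret_trace(b$binned, exposure, b$bin_size),
                         bin_width = 0.02),
    n_components = if (exposure == 1) 2 else 1)
  cat(sprintf("%5g ms exposure: component means %s\n", exposure,
              paste(round(fit$components$mean, 2), collapse = ", ")))
}

# dwell kinetics recover the generating rate and calibrate the timestep
d <- detect_dwells(trace$efficiency, 0.5, direction = "above")
cal <- calibrate_timestep(d$mean, 4.7e-3)
cat(sprintf("mean closed dwell: %.0f steps -> %.3g ns per step\n",
            d$mean, cal$step_ns))

# dual-basin clamshell: basin-resolved dye separations
cs <- synthetic_clamshell()
topo <- clamshell_topology(cs)
tr <- run_langevin(topo, cs$open$xyz,
                   list(n_steps = 50000, output_stride = 100,
                        temperature = 0.3, friction = 1, seed = 1))
rdye <- compute_r_dye(tr, cs$donor$chromophore, cs$acceptor$chromophore)
cat(sprintf("open-basin R_dye: %.1f +/- %.1f A -> FRET %.2f at R0 62 A\n",
            mean(rdye[50:500]), sd(rdye[50:500]),
            fret_efficiency(mean(rdye[50:500]), 62)))
```

prints

```
    1 ms exposure: component means 0.35, 0.65
  100 ms exposure: component means 0.51
mean closed dwell: 466 steps -> 1.01e+04 ns per step
open-basin R_dye: 71.0 +/- 4.8 A -> FRET 0.31 at R0 62 A
```

Reading the output: at 1 ms exposure the mixture fit resolves the two
generating FRET levels exactly; at 100 ms — twenty times the mean dwell —
time-averaging collapses them into one population near the occupancy-
weighted midpoint 0.5. The dwell detector then measures the mean closed
residence (466 of the 10 µs generator steps ≈ 4.7 ms), and matching it to
the experimental 4.7 ms dwell recovers the generator's step duration
(10 µs), the same calibration that assigns ~0.25 ns to a structure-based
simulation step. The last lines run actual Langevin dynamics on the
synthetic clamshell's dual-basin force field: started open, the dye
separation fluctuates around ~70 Å, i.e. below-midpoint FRET, as expected
for the open conformation at a 62 Å Förster radius.

The end-to-end workflow (build → simulate → FRET → analyze →
landscape/rate) also runs from one declarative YAML config via
`run_pipeline("run.yaml")` or the thin CLI at `inst/scripts/sbmfret`.

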