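---
title: "Membrane permeability from umbrella sampling: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Membrane permeability from umbrella sampling: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(permflux)
```

## The model

permflux estimates how fast a small solute crosses a lipid bilayer from
biased (umbrella-sampling) simulations of its motion along the membrane
normal $z$. The physical model is the inhomogeneous solubility-diffusion
(ISD) picture: permeation is one-dimensional diffusion over a
free-energy landscape $W(z)$ with a position-dependent diffusion
coefficient $D(z)$. The local resistance of a slab at depth $z$ is

$$R(z) = \frac{e^{W(z)/RT}}{D(z)},$$

and the permeability is the reciprocal of the integrated resistance,

$$P = \left[ \int_{z_1}^{z_2} R(z)\, dz \right]^{-1},$$

with $z_1, z_2$ placed in bulk water on either side (default
$\pm 2.3$ nm), where $R(z)$ is negligible so the result is insensitive
to the exact limits. The ISD model assumes the normal coordinate
relaxes slowly compared to everything orthogonal to it, that the memory
of the friction is short, and that a single reaction coordinate
suffices. These assumptions are known to bias absolute permeabilities
of real membranes; relative values across membranes for the same
solute are far more reliable, which is why the package's validation
leans on internal consistency and synthetic ground truth rather than
absolute agreement with experiment.

All internal units are nm, ps and kJ/mol. Conversions
($1$ nm/ps $= 10^3$ m/s, $1$ nm$^2$/ps $= 10^{-6}$ m$^2$/s,
$1$ pL $= 10^{-15}$ m$^3$) are applied exactly once, at reporting
boundaries (`integrate_permeability()`, `reference_permeability()`,
`radius_from_volume()`).

## The synthetic generator as ground truth

`membrane_model()` defines a smooth parametric landscape: a Gaussian
free-energy barrier centred at $z=0$ (optionally flanked by symmetric
interfacial wells) shifted so that $W(\pm L) = 0$, and a diffusivity
that dips from a bulk value to a core value through a Gaussian profile.
`simulate_window()` integrates the overdamped Langevin equation

$$dz = \left[ -\frac{D(z)}{RT}\big(W'(z) + k_u (z - z_0)\big) + D'(z)
\right] dt + \sqrt{2 D(z)\, dt}\; \xi,$$

with Euler–Maruyama stepping in the Itô convention. The $D'(z)$
divergence term is not optional: without it the stationary density
under position-dependent diffusivity is not Boltzmann, and the test
suite contains a discriminating check (a 10-fold diffusivity dip with
$W \equiv 0$ must leave the biased histogram exactly the Boltzmann
density of the bias alone).

This 1D process is the minimal dynamics whose exact permeability *is*
the ISD integral, so `reference_permeability()` (fine trapezoidal
quadrature of $e^{W/RT}/D$) provides analytically known ground truth
for end-to-end recovery tests, and the first-passage machinery
(`first_passage_time()` against the closed-form double integral in
`mean_first_passage_theory()`) validates the integrator itself.

Default study conditions mirror a typical membrane umbrella protocol:
windows every 0.1 nm, harmonic spring $k_u = 1000$ kJ/mol/nm$^2$,
temperature 320 K, three replicates per centre (emulating several
ligands sampled per window). Landscape presets anchor the barrier
heights to values reported for cisplatin in model bilayers
(40 kJ/mol DOPC-like, 62 kJ/mol for an asymmetric plasma-membrane
model without cholesterol, 70 kJ/mol at 33% cholesterol; the
cancer-membrane analogue keeps the 70 kJ/mol barrier but an
order-of-magnitude lower core diffusivity). Diffusivities
($5\times10^{-3}$ nm$^2$/ps bulk, $1$–$2\times10^{-3}$ core,
$1.2\times10^{-4}$ for the cancer-like preset) are plausible scales for
a small rigid solute; they were chosen once as study conditions, not
fitted. The default timestep 0.01 ps keeps the dimensionless stiffness
$k_u D \Delta t/RT < 0.05$; a guard refuses timesteps whose rms
displacement exceeds half the barrier width.

What the generator deliberately does *not* emulate: lateral
heterogeneity, slow collective lipid modes, memory friction,
orientational degrees of freedom of the permeant, and force noise from
a thermostat. Passing recovery tests therefore demonstrates the
*analysis chain* is unbiased and its error bars calibrated for
diffusive dynamics — not that the ISD model is accurate for any real
membrane.

## PMF reconstruction (WHAM)

`solve_wham()` iterates the standard self-consistent equations over
per-window histograms on a shared uniform grid,

$$\rho(z_b) = \frac{\sum_i n_i(z_b)}{\sum_i N_i e^{(f_i - u_i(z_b))/RT}},
\qquad f_i = -RT \ln \sum_b \rho(z_b)\, e^{-u_i(z_b)/RT},$$

until the largest change in any $f_i$ falls below $10^{-6}$ kJ/mol
(gauge $f_1 = 0$; $\rho$ kept normalised). The bin width default of
0.02 nm resolves the 0.1 nm window ladder with five bins per spacing
without starving counts. Zero-count bins are reported as `NA`, never
interpolated; the resistance integrator fails loudly if such bins fall
inside the integration limits. No symmetrisation about $z=0$ is
applied. The test suite pins the fixed point against an independent
direct minimisation of the WHAM negative log-likelihood.

Two aggregation modes exist because "average of all ligands" is
ambiguous: the default solves WHAM per replicate and averages the
referenced profiles (`mode = "replicate-average"`); `mode = "pooled"`
solves one WHAM over all histograms. Profiles are referenced by
shifting the mean over a declared bulk-water region (default
2.0–2.3 nm) to zero.

Uncertainties follow the histogram-bootstrap convention: each of
`n_boot` draws (default 400; scaled-down runs use 50) picks one
complete histogram per centre with replacement from the replicates at
that centre, re-solves and re-references; `sigma_W` is the per-bin
standard deviation over draws. Centres with a single replicate fall
back to multinomial resampling of that histogram's counts, with a
warning. Note this sigma estimates the spread of a *single-ligand*
profile; as the error bar of the replicate-averaged profile it is
conservative by roughly $\sqrt{n_\text{rep}}$.

## Diffusion profile (force-correlation method)

For each window the diffusion coefficient comes from the
force-fluctuation autocorrelation,

$$D(z) = \frac{(RT)^2}{\int_0^\infty \langle \Delta F_z(t) \Delta F_z(0)
\rangle\, dt},$$

with $\Delta F_z$ the instantaneous minus mean systematic force on the
permeant. The ACF uses the biased $1/N$ estimator; a single
exponential $A e^{-t/\tau}$ is fitted over lags up to the first drop
below $A e^{-3}$, and the integral is taken analytically as $A\tau$
("fit prior to integration"). For a harmonic window on a locally flat
landscape this is the Ornstein–Uhlenbeck identity
$A = k_\text{eff} RT$, $\tau = RT/(k_\text{eff} D)$, so
$(RT)^2/(A\tau) = D$ *independently of the effective stiffness* — the
estimator needs no knowledge of the local curvature of $W$.

The recorded force is the total systematic force
$-W'(z) - k_u(z - z_0)$; when only positions are available (pull files
without forces), the restraint force is reconstructed with a warning.
Errors use the four-block convention: each window is split into four
contiguous quarters, $D$ estimated on each, the block mean used as the
value and the block standard deviation as its error. Across replicates
the block errors combine in quadrature with the replicate-scatter
standard error.

The estimator's sampling noise grows with $\tau$ (slowest at the
diffusivity minimum); at the default window length
($2\times10^5$ steps, i.e. 2 ns) and three replicates, recovery of a
five-fold diffusivity dip is accurate to well within 20% at every
centre.

## Resistance, permeability and errors

`resistance_profile()` interpolates $D(z)$ linearly onto the PMF grid
(the exponential of $W$ dominates the shape, $D$ varies slowly) and
forms $r = e^{W/RT}/D$. Integration is trapezoidal; uncertainties
propagate to first order assuming independent bins:

$$\sigma_r = r\sqrt{(\sigma_W/RT)^2 + (\sigma_D/D)^2},\qquad
\sigma_R^2 = \sum_b (w_b \sigma_{r,b})^2,\qquad
\sigma_P = \sigma_R / R_\text{total}^2,$$

with $w_b$ the trapezoid weights. Bin-to-bin covariance of WHAM errors
is real but unquantifiable from histogram bootstrap alone; declaring
independence is the package's documented choice. $P \cdot
R_\text{total} = 1$ holds at machine precision by construction.

## Uptake kinetics and the spherical cell

Experimental uptake curves are reduced by
`fit_first_order()` to $C(t) = C_\infty (1 - e^{-kt})$ (unweighted
least squares; the saturating form is chosen because uptake plateaus,
and a flag adds a free baseline). For a spherical cell of volume $V$
(radius $r = (3V/4\pi)^{1/3}$), the rate constant maps to permeability
as $P = kr/3$, with `kinetic_constant()` as the exact inverse. A
2 pL cell gives $r \approx 7.82\ \mu$m.

## Structural observables

`density_profile()` converts per-frame particle $z$ positions to
number densities (counts per frame per bin volume);
`headgroup_peak()` locates the head-group maximum with a three-point
parabolic refinement; `thickness_regression()` fits the peak distance
against cholesterol mole fraction by OLS; `order_parameter()` computes
the second-Legendre $S = \langle 3\cos^2\theta - 1\rangle/2$ per chain
carbon (range $[-0.5, 1]$, no sign negation — callers supply the
orientation cosines, so the choice of bond vector stays with them).
`simulate_membrane_frames()` places species from declared Gaussian
mixtures so all of this is testable without trajectories.

## Numerical choices and problem sizes

* WHAM tolerance $10^{-6}$ kJ/mol on $\max_i |\Delta f_i|$, iteration
  cap $10^5$; bootstrap draws warm-start from the previous solution.
* Exponential and uptake fits use Levenberg–Marquardt
  (`minpack.lm::nlsLM`) with data-driven starting values; a log-linear
  fallback handles pathological ACFs.
* Quadratures (`reference_permeability()`,
  `mean_first_passage_theory()`) use $\geq 4001$-point trapezoid
  grids, stable to $<0.1\%$ under doubling.
* Test and validation runs use deliberately modest sizes chosen for a
  laptop-scale workflow: $2\times10^4$–$10^6$ Langevin steps per
  window, 47–51 windows, three replicates, 50 bootstrap draws
  (scaled down from the 400 used for production error bars), 400
  first-passage particles. The methods are size-agnostic; production
  analyses should raise the sampling and `n_boot`.

## Known limitations

* The bootstrap sigma describes single-ligand spread (conservative for
  the replicate mean); covariance between bins is ignored in error
  propagation.
* The single-exponential ACF model underestimates $D$ when the force
  memory is strongly multi-exponential; block scatter flags this but
  cannot remove it.
* Euler–Maruyama has $O(\Delta t)$ weak bias; at the default
  $\Delta t$ the stationary-variance bias of a stiff window is
  $\approx 1\%$, visible only in very long OU checks.
* The flat-bottomed coverage check of a PMF is only meaningful over
  the span of window centres; bins beyond the outermost centre are
  sampled by bias tails alone and carry little information.
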