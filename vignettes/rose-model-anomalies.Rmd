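---
title: "The rose model of water: potential, sampling, and anomaly mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The rose model of water: potential, sampling, and anomaly mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rosewater)
```

## The model

The rose model describes water in two dimensions.  A molecule is a
Lennard-Jones disk carrying three hydrogen-bonding "arms" encoded not as
explicit sites but as an angular modulation of the pair attraction.  The
pair energy of molecules $i$ and $j$ is

$$U(\vec X_i, \vec X_j) = U_{LJ}(r_{ij}) + U_{HB}(\vec r_{ij}) +
  U_{HB}(\vec r_{ji}),$$

where $U_{LJ}$ is the standard 12-6 form
$4\epsilon_{LJ}[(\sigma_{LJ}/r)^{12} - (\sigma_{LJ}/r)^6]$ and each
molecule contributes its own, independent half of the hydrogen-bonding
energy:

$$U_{HB}(\vec r_{ij}) = \frac{\epsilon_{HB}}{2}\, s(r_{ij})\, U(\theta_{ij}),
\qquad U(\theta) = a_2 \sin^2(3\theta) + a_1 \sin(3\theta).$$

Here $\theta_{ij}$ is the direction from $i$ to $j$ seen in the body frame
of molecule $i$, so the three-petal rose function $U(\theta)$ plays the role
of three bonding arms spaced $120^\circ$ apart.  The radial factor $s(r)$ is
a double-sided cubic switch that is zero outside
$[r_{HB} - r_{FWHM},\, r_{HB} + r_{FWHM})$, reaches 1 at the bond distance
$r_{HB}$, crosses $1/2$ exactly at the half-width points, and has zero slope
at all three knots.  With the amplitudes used here ($a_1 = 0.7$,
$a_2 = -0.3$) the minimum of $U$ over angle is exactly $-1$, so a fully
formed bond — both molecules pointing an arm at each other at distance
$r_{HB}$ — is worth exactly $-\epsilon_{HB}$; the $1/2$ prefactor of each
half is what makes this normalisation work.  Because the two halves are
independent, the model admits *half bonds*: one molecule bonded to a
partner that does not reciprocate.

All quantities are reduced: energies and temperature by
$|\epsilon_{HB}|$ ($k_B = 1$), lengths by $r_{HB}$.

Two parametrisations are built in:

| preset | $\epsilon_{LJ}$ | $\sigma_{LJ}$ | notes |
|---|---|---|---|
| `mb`   | 0.1 | 0.7       | Mercedes-Benz-like; LJ core well inside the bond distance |
| `real` | 0.2 | $2^{-1/6}$ | LJ minimum moved onto $r_{HB}$; more water-like correlations |

Both share $\epsilon_{HB} = 1$, $r_{HB} = 1$, $r_{FWHM} = 0.35$,
$a_1 = 0.7$, $a_2 = -0.3$.

```{r potential}
p <- rose_parameters("mb")
# an optimal full bond: each molecule sees the other at a rose minimum
xi <- c(0, 0, pi / 6); xj <- c(1, 0, pi + pi / 6)
pair_energy(xi, xj, p, box = 20)   # -eps_hb plus the (small) LJ term at r = 1
```

### Interaction cutoff

Pair interactions are truncated, without shift or tail correction, at
$r_c = \min(2.5\,\sigma_{LJ},\ L/2)$, never below $r_u = r_{HB} + r_{FWHM}$
so the bonding window is never clipped.  $2.5\sigma$ is the conventional LJ
truncation; the neglected tail is at most a few times $10^{-3}\epsilon_{HB}$
per pair and smooth in both density and temperature, so extremum *positions*
— the quantities this package maps — are insensitive to it.  The cutoff is a
field of `rose_parameters()` for users who want a different policy (up to
the half-box bound that minimum imaging imposes).  The integrals that
define the translational order parameter and the pair entropy always run to
$L/2$ regardless of the potential cutoff.

## Monte Carlo sampling

Sampling is canonical (NVT) Metropolis in a periodic square box with
minimum imaging.  One *cycle* is $N$ translation attempts plus $N$ rotation
attempts; for each attempt the particle is drawn independently and
uniformly, so on average every molecule is translated and rotated once per
cycle.  Proposals are uniform: displacements in
$[-\delta_t, \delta_t]^2$, rotations in $[-\delta_r, \delta_r]$; acceptance
is $\min(1, e^{-\Delta U/T})$ with the exponent clamped below $-700$ so
that the overlapping random starting configurations cannot overflow the
exponential.

The proposal maxima default to $\delta_t = 0.1$, $\delta_r = 0.4$ rad and
stay **fixed**.  An optional auto-tuner (`adjust_dmax = TRUE`) drives both
toward roughly 40% acceptance during equilibration and then freezes them,
but it is off by default because the pseudo-diffusion coefficient is only
comparable across state points when all runs share one proposal scale.

Runs start from random configurations; equilibration resolves the initial
overlaps.  Production is divided into independent series, and every
uncertainty this package reports is the standard error over the series
block means.

The compiled engine keeps Verlet neighbour lists (radius
$r_c + \text{skin}$, skin 1.0) with the periodic image shift of each pair
frozen into the list entry; coordinates are left unwrapped between list
rebuilds so the inner loop needs no minimum-image branches, and a rebuild is
triggered whenever accumulated displacements could invalidate a list.  A
second, tighter list (radius $r_u + \text{skin}$) serves rotation moves,
which only re-evaluate the moving molecule's own half-bonds.  Every
accepted move's $\Delta U$ is accumulated and checked in the test suite
against independently computed total energies, which bounds list errors by
the floating drift ($\sim 10^{-12}$ over $10^4$ cycles).

### Observables

* **Virial pressure** $P = \rho T - \langle\sum_{i<j} r\,u'(r)\rangle/2A$,
  with $r\,u'(r)$ evaluated at fixed orientations; the angular factor of
  the bonding term contributes no radial derivative.
* **Radial distribution function** accumulated to $L/2$ (bin width 0.02 by
  default), normalised so that $\rho\int g\,2\pi r\,dr$ counts partners.
* **Translational order** $t = \rho^{1/2}\int_0^{L/2} |g - 1|\,dr$
  (trapezoidal over the binned $g$): zero for an ideal gas, growing with
  pair correlation.
* **Bond-orientational order** $q_l$ ($l = 3, 6$): per particle the
  magnitude of the mean of $e^{il\theta}$ over first-shell neighbours
  (lab-frame bond angles, shell cutoff 1.2 = the first minimum of $g$ after
  the bonding peak), then averaged over particles; particles without
  neighbours contribute zero.
* **Pair entropy**
  $s_2 = -\pi\rho\int_0^{L/2} [g\ln g - g + 1]\, r\,dr$, the two-body term
  of the excess-entropy expansion; empty bins take the integrand's limit
  value 1.
* **Hydrogen bonds per molecule**: a full bond is counted when *both*
  half-bond energies fall below a threshold, $-0.125\,\epsilon_{HB}$ by
  default (half of a quarter of the full bond depth).  The counting rule is
  energetic because the potential is energetic — there is no geometric
  bond definition in the model — and the threshold is exposed because any
  such cut is a convention.  Half bonds are tallied separately.
* **Pseudo-diffusion** $D^*$: the slope of the mean-square displacement
  (from unwrapped coordinates, averaged over particles) against cycle
  index, least-squares fitted over the second half of the recorded window
  to discard the short-time transient.  $D^*$ is proportional to, not equal
  to, a physical diffusion constant, and is only meaningful at fixed
  $\delta_t$.

## Mapping anomalies

A normal liquid compresses into order: on each isotherm $D^*$ falls with
density, $t$ rises, $s_2$ falls.  The waterlike anomalies are the regions
where these trends invert, and the package locates them from grid scans
(`run_grid_scan()`) with a uniform rule (`find_extrema()`): an interior
grid point is an extremum when the discrete derivative changes sign there
and the point differs from **both** flanking means by more than $k$ times
the combined standard error ($k = 1$ by default, since the block-mean SEs
are themselves the only uncertainty measure available), with the location
refined by a three-point parabolic fit.

* **Density anomaly (TMD)**: the temperature of maximum density at
  constant pressure equals the temperature of the pressure minimum at
  constant density, so the locus is read off the $P(T)$ columns of the
  scan.
* **Diffusion anomaly**: a local minimum of $D^*(\rho)$ followed by a
  local maximum; the region spans the densities between the pair.
* **Structural anomaly**: the same pairing applied to $t$ (maximum then
  minimum: order *decreasing* on compression) or to $s_2$ (minimum then
  maximum: entropy *increasing* on compression).
* **Orientational maxima**: local maxima of $q_3(\rho)$ or $q_6(\rho)$;
  for the six-fold parameter of the `real` preset only the first maximum
  scanning from low density defines the locus, because a second rise
  toward the dense triangular structure follows.

`hierarchy_report()` orders the non-empty regions by their maximum
temperature and by polygon area in the $(\rho, T)$ plane; regions whose
polygons must be closed along a scan edge are flagged censored, and when
the two orderings disagree the nesting is reported `"partial"` rather than
forced into a total order.

## Problem sizes and their consequences

The package defaults are chosen for a single workstation core:

* `mc_settings(profile = "desk")` — $N = 100$, $10^5$ equilibration cycles,
  10 series of $2\times10^4$: a single state point in tens of seconds;
  pressure standard errors around $10^{-2}$.
* `mc_settings(profile = "scan")` — $N = 100$, $2\times10^4$ equilibration,
  10 series of $3\times10^3$, structural sampling every 40 cycles: a
  hundred-point density-temperature grid in minutes.
* `mc_settings(profile = "paper")` — $N = 200$, $10^6$ equilibration,
  20 series of $10^6$: publication-scale statistics, hours per state
  point.

The statistical consequences are worth stating plainly.  The shallow
high-temperature tails of the anomaly boundaries need pressure resolution
of order $10^{-3}$, which only the `paper` profile delivers.  At `scan`
scale the extremum rule detects the *deep* parts of each anomaly reliably
and misses shallow ones near the boundary temperatures, so the measured
maximum anomaly temperatures are noisy within roughly one temperature grid
step, and boundary curves are sparser than at full scale.  At the lowest
temperatures ($T^* \lesssim 0.13$) the bonded network relaxes slowly and
the short equilibration leaves some residual disorder, inflating pressures
slightly; this steepens the approach to the pressure minimum but does not
move detected minima outside grid resolution.

## What the synthetic configurations do and do not emulate

All inputs are generated internally: uniform random starts (the production
condition), and triangular/honeycomb lattices plus exact coordination
"stars" used as known-answer fixtures for the order parameters and bond
counting.  A perfect honeycomb or triangular lattice cannot tile a square
periodic box (the required aspect ratio $\sqrt 3$ is irrational), so the
lattice constructors return a minimally sheared lattice; tests therefore
assert exact values ($q_3 = 1$, $q_6 = 1$, 3 bonds per molecule) only on
the exact local patches, and near-unity on the periodic lattices.  Passing
tests demonstrate correctness of the estimators and the sampling machinery,
not realism of the model itself — the model has no third dimension, no
explicit protons, and a rigid three-arm symmetry.

## Numerical choices

* Trapezoidal quadrature for all RDF-derived integrals; $g = 0$ bins enter
  the entropy integrand at the limit value 1 with no epsilon padding.
* Angles are reduced to $[-\pi, \pi)$ where a canonical value is needed;
  stored orientations stay unreduced so displacement bookkeeping never
  jumps.
* Exact coincidence of two particles raises an error rather than returning
  an infinite energy: valid states never contain it, and a silent infinity
  would mask indexing bugs.
* Degenerate parabolic refinement (three collinear points) falls back to
  the grid point.
* The per-run RNG is a counter-seeded xoshiro256++ stream in the compiled
  engine, so a run is bit-reproducible from its integer seed and
  independent of R's RNG state; R-level randomness (initial placement)
  goes through R's RNG under the same seed.  Per-state-point seeds come
  from `seed_manager()`, an affine map modulo a 31-bit prime, collision-free
  across state-point indices.

## Limitations

* Truncation effects: pressures carry a small, smooth negative bias from
  the unshifted cutoff; absolute pressures at different cutoffs differ,
  extremum positions do not (within grid resolution).
* The extremum rule is local (immediate flanks only); it will not pool
  evidence across several grid points, which is the price of making no
  smoothness assumption.
* No NPT ensemble, no molecular dynamics, no free-energy or phase-boundary
  machinery; solid phases appear only as high-$q_l$, low-$D^*$ state
  points, not as classified phases.
* Finite size: $N = 100$–200 disks; no finite-size scaling is attempted.
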