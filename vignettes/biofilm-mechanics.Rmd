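---
title: "Mechanics and morphometrics of wrinkling biofilms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanics and morphometrics of wrinkling biofilms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biofilmorph)
```

## The physical picture

A bacterial colony growing on an agar plate is, mechanically, a thin stiff
film bonded to a much thicker, softer substrate. The film grows; the
substrate does not. The mismatch puts the film under in-plane compression
with strain $\varepsilon = g/(1+g)$, where $1+g$ is the linear growth
factor. Past a critical strain the flat film becomes unstable: it either
*wrinkles* — deforming together with the substrate into a periodic
undulation — or *delaminates*, detaching locally to form blisters. Which
pathway wins, and at what wavelength, is set by three layers, not two: when
a biofilm is peeled off agar it leaves behind a thin, soft *residual layer*
of matrix polysaccharide, and this compliant interlayer changes the
foundation the film feels.

`biofilmorph` implements this trilayer picture end to end: a linear
stability solver for the critical wavelength and strain, a finite-strain
finite-element simulator of the growth process, the image and contour
morphometrics used to quantify real colonies, and seeded generators of
synthetic data with ground truth for every analysis stage.

## Trilayer linear stability

With a sinusoidal undulation ansatz of wavenumber $n$, the longitudinal
stress the film must carry is

$$S(n) = \frac{G_f h_f^2 n^2}{3} + \frac{\tilde K(n)}{h_f\, n^2},
\qquad
\tilde K(n) = \frac{4 G_s n}{n h_r (G_s/G_r - 1) + 2},$$

where $G_f, G_r, G_s$ are the shear moduli of film, residual layer and
substrate, $h_f, h_r$ the film and residual thicknesses, and $\tilde K$ is
the combined foundation stiffness of residual layer plus substrate. The
first term is the bending cost (rising with $n$), the second the foundation
cost (falling with $n$), so $S$ always has an interior minimum. The solver
minimises $S$ on $\log n$ over $n h_f \in [10^{-3}, 10^3]$ and polishes the
result with a root solve of the analytic $\mathrm{d}S/\mathrm{d}n = 0$; the
returned stationarity residual $|\mathrm{d}S/\mathrm{d}n|\,n/S$ is below
$10^{-8}$. Direct minimisation rather than root finding was chosen because
it is robust to flat minima and equivalent at stationarity. Then

$$n_{cr} = \arg\min_n S, \qquad \lambda_{cr} = 2\pi/n_{cr}, \qquad
S_{cr} = S(n_{cr}), \qquad \varepsilon_{cr} = S_{cr}/3G_f.$$

Setting $G_r = G_s$ (or $h_r = 0$) recovers the classical bilayer limit with
$\tilde K = 2 G_s n$ and the closed form
$\lambda_{cr}/h_f = 2\pi\,(G_f/3G_s)^{1/3}$, which the solver reproduces to
$10^{-6}$ relative across four decades of stiffness contrast — that closed
form is the main analytic oracle of the test suite. Note that the
$\varepsilon_{cr} = S_{cr}/3G_f$ convention differs from the textbook
bilayer critical strain $\tfrac14 (3G_s/G_f)^{2/3}$ by a constant factor;
both are exposed (`bilayer_critical_strain_classical()`) so users can
convert.

Two derived quantities summarise delamination propensity: the effective
substrate modulus $G'_s = \tilde K(n_{cr})\, h'_s$ and the normalised
adhesion $\Gamma^* = \Gamma/(h_f G'_s)$, small values of which favour
delamination. The depth of the strained region $h'_s$ has no closed form in
the trilayer theory; the package defaults to $1/n_{cr}$, the decay depth of
a sinusoidal surface load on a half space, and exposes it as an argument.

**Fitting the residual layer.** $G_r$ is the one parameter that cannot be
measured directly. `fit_residual_stiffness()` recovers it from measured
$(G_f/G_s,\ \lambda/h_f)$ pairs by least squares against the model, holding
$h_r/h_f = 0.3$ (the measured average). The objective is minimised by
bisection on the sign of its derivative over $\log(G_r/G_f)$ in the bracket
$(10^{-3}, 1]$ — the residual layer is softer than the film by construction
— with a golden-section fallback if a coarse 9-point profile of the
derivative shows the objective is not unimodal. Solutions at the bracket
edge are flagged as boundary solutions. On noiseless model-generated data
the true ratio is recovered to $10^{-3}$; under 5% multiplicative
log-normal noise, recovery is typically within a few percent.

## Finite-element growth simulation

The simulator works in plane strain on the rectangle
$[0, L] \times [0, h_s + h_r + h_f]$ with the multiplicative growth split
$F = F_e F_g$: $F_g = \mathrm{diag}(1+g, 1)$ in the film and residual layer
(1-D growth along the plate), $F_g = I$ in the substrate. Each layer is a
compressible neo-Hookean solid,

$$\Psi(F_e) = \frac{\mu_e}{2}\left(I_C - 2 - 2\ln J\right)
 + \frac{\lambda_e}{2}(\ln J)^2,
\qquad \mu_e = G,\quad \lambda_e = \frac{2G\nu}{1 - 2\nu},$$

and the total energy $\Pi = \sum_e A_e\, \Psi(F_{e})\, J_g$ is assembled
over first-order (constant-strain) triangles, for which one-point
quadrature is exact. The mesh is a structured crossed-triangle grid: four
triangles per quad around its centroid, layer interfaces exactly on element
rows, `elements_per_hf` rows through the film (default 4), two through the
residual layer, and substrate rows coarsening geometrically (ratio 2) with
depth. Boundary conditions confine the growing layers:
$u_1 = 0$ on both side walls and $u_2 = 0$ at the bottom.

Default parameters follow the biofilm system: $h_r/h_f = 0.3$,
$h_s/h_f = 10$, $G_r/G_f = 0.1$, $\nu = 0.45$ in all layers (the
near-incompressible value that keeps the compressible formulation
convergent), growth increment $\Delta g = 0.002$ up to $g_{max} \le 1$, and
domain length $L = 10\,\lambda_{cr}$ (from the linear-stability prediction)
to keep finite-size effects small. The energy and its analytic gradient are
evaluated in compiled code; each increment is minimised by L-BFGS-B on the
free degrees of freedom, warm-started from the previous step.

Three numerical choices deserve mention:

* **Symmetry breaking.** The flat state is an exact equilibrium at every
  $g$, so an energy minimiser warm-started on it never wrinkles on its own
  within the linear-stability window (this is asserted by a test). Before
  each minimisation the film surface is therefore perturbed vertically by a
  multi-sine of amplitude $10^{-4} h_f$ whose phases are drawn once from the
  configuration seed, making onset reproducible rather than driven by
  floating-point roundoff.
* **Stopping rule.** The nonconvex energy near the bifurcation makes a tiny
  fixed gradient tolerance unattainable; convergence is accepted on
  L-BFGS-B's relative energy criterion (`factr = 1e7`, about $10^{-9}$
  relative) or on the projected-gradient tolerance, whichever comes first,
  and the optimiser is restarted up to three times across the bifurcation
  where its curvature memory goes stale. Non-convergence is an error, never
  silently accepted.
* **Onset measure.** Under confined growth the whole film thickens, so the
  raw vertical surface displacement is nonzero even in the flat state.
  Onset is therefore detected on the surface *deflection* — the peak
  deviation of $u_2$ from its lateral mean — crossing $0.01\,h_f$.

The wrinkle wavelength of a simulation is measured exactly as in the image
analysis: FFT of the surface profile ten increments past onset, dominant
nonzero mode. At stiffness contrast $G_f/G_s = 10$ the simulated onset
strain agrees with $\varepsilon_{cr}$ from linear stability to about 3% and
the wavelength lands on the predicted mode exactly; a mesh-doubling test
moves onset by well under 10%. Locking of first-order triangles at
$\nu = 0.45$ is mitigated by mesh density and accepted as a fidelity limit.

Post-processing returns per-element Green–Lagrange strain
$e = (F_e^T F_e - I)/2$, its 2-D deviator, and the von Mises equivalent
strain $\varepsilon_{vM} = \sqrt{2 e'_{ij} e'_{ij}/3}$.

## Colony morphometrics

The image pipeline mirrors the standard transmission-image workflow:

* **Normalisation and segmentation.** The background of a transmission
  image is its brightest substantial histogram peak (256 bins, lightly
  smoothed counts, mode refined to sub-bin precision as the median of the
  pixels in the peak bin). Intensities are rescaled affinely so the minimum
  maps to 0 and the background mode to 0.9; after a 3×3 median filter, the
  first histogram valley below the background peak is the binarisation
  threshold, and the colony is the largest dark connected component with
  holes filled. The brightest-peak rule (rather than the global mode) is
  what keeps segmentation correct when the colony covers most of the frame.
* **Ring counting.** The stripe count $N(r)$ on a circle of radius $r$ is
  the dominant FFT harmonic of the bilinearly interpolated angular
  intensity profile, searched from harmonic 3 upward (lower harmonics
  reflect centring and ellipticity, not stripes), cross-checked against the
  dominant circular autocorrelation period; disagreement beyond one
  harmonic flags the sample and excludes it from the wavelength fit. A ring
  whose dominant harmonic does not rise a factor 20 above the median
  harmonic power is flagged as unpatterned.
* **Wavelength.** Counts from all frames are pooled and fitted through the
  origin, $N = 2\pi r/\lambda$, giving
  $\lambda = 2\pi \sum r_k N_k / \sum N_k^2$; $R_p$, the innermost
  patterned radius, is reported per frame. The colony centre used
  everywhere is fixed from the frame nearest 12 h, so later shape changes
  do not move the reference.
* **Contours.** The boundary is extracted sub-pixel as the 0.5 iso-contour
  of the Gaussian-blurred mask ($\sigma = 1.1$ px). This removes the pixel
  staircase (which would bias perimeter upward by several percent) while
  rounding corners only at a fixed pixel scale; measured acircularities are
  $\alpha = 1.004$ for a discretised circle of radius 200 px and
  $\alpha = 1.264$ for a square (exact: $4/\pi \approx 1.273$). For
  curvature and velocity the contour is resampled to 512 equal arc-length
  points and smoothed with a circular Gaussian of 2 samples; local
  quadratic fits over a 9-point Gaussian-weighted window give analytic
  derivatives, hence curvature and outward normals, and velocities connect
  each point to its nearest neighbour on the next contour.
* **Expansion break.** The critical time $t_c$ is the breakpoint of a
  continuous two-segment linear fit of mean radius versus time, grid-searched
  over interior sample times; a best breakpoint at the grid edge, or an SSE
  no better than a single line, is reported as "no break detected".
* **Blisters.** From a side-view profile, the baseline is the mean height
  of the outer 10% of samples on each side, $H$ the peak elevation above
  it, and $W$ the width at half height with linear interpolation of the
  crossings — so $H$ and $W$ are exactly invariant to baseline offset and
  horizontal translation.
* **Interfacial energies.** `interface_hierarchy()` encodes the comparator
  logic: delamination comes first when the film–substrate adhesion
  $\Gamma$ is smallest (immediately when it is zero); a film–liquid energy
  exceeding the film–air energy drives blister walls into internal contact
  followed by peak merging; the reversed hierarchy predicts lateral
  collapse of neighbouring blisters instead.

## Synthetic data: what it emulates, and what it does not

Every analysis stage is exercised against seeded generators that store
their ground truth:

* `gen_radial_pattern_image()` — a dark disk on a bright background with
  angular modulation whose per-ring stripe count is
  $N(r) = \mathrm{round}(2\pi r/\lambda)$. This keeps the local spacing
  within half a stripe of $\lambda$ (and inside the bifurcation bracket
  $[\lambda/\sqrt2, \lambda\sqrt2]$), which is the measurable content of
  stripe bifurcation; radial phase continuity of real bifurcating wrinkles
  is not reproduced, and does not affect ring counting.
* `gen_colony_series()` — contours expanding piecewise-linearly with a
  velocity break at $t_c$ and a petal modulation
  $r = R(t)(1 + a(t)\cos k\theta)$ ramping up after $t_c$.
* `gen_blister_series()` — flat-topped generalised-Gaussian side profiles
  whose FWHM narrows to exactly $2h_f$ (wall contact) while the height
  grows; the exponent rises over stages so early bumps are wide and smooth,
  late ones steep-walled.
* `gen_stiffness_dataset()` — the trilayer model solved over a range of
  stiffness contrasts with multiplicative log-normal noise
  ($\exp N(0,\sigma)$, strictly positive).

Noise models are additive Gaussian on images and multiplicative log-normal
on wavelengths. What the generators do *not* emulate: uneven illumination,
stitching seams, out-of-focus blur, colonies touching the frame,
non-circular cores, or the mechanical coupling between neighbouring
blisters. Passing the round-trip tests therefore demonstrates correctness
of the measurement operators under the stated statistical structure, not
robustness to every artefact of real microscopy.

## Problem sizes and runtime choices

The shipped configurations are sized for a single CPU: demonstration scans
use 8–15 stiffness ratios, synthetic images are 384–512 px, and the
reference simulation (contrast 10, $L = 10\lambda_{cr}$, 4 element rows per
film thickness, horizontal spacing $\lambda_{cr}/16$, about 7 700
triangles) runs in well under a minute, stopping 12 increments after onset.
Monte-Carlo recovery checks in the test suite use 12–50 seeded replicates.
All of these are arguments, not constants; larger studies only need larger
values.

## Known limitations

* The stability theory is linear and small-strain; it predicts onset and
  wavelength, not post-buckling amplitudes, creases or folds.
* The simulator has no contact, no cohesive/delaminating interfaces, no
  remeshing and no viscoelasticity; blister formation itself is therefore
  outside its scope (the blister module measures geometry, it does not
  simulate it).
* First-order triangles at $\nu = 0.45$ are mildly locking-prone; the
  near-incompressible limit $\nu \to 0.5$ is not reachable.
* $h'_s$ (strained-depth) and hence $G'_s$ and $\Gamma^*$ carry a
  documented convention ($h'_s = 1/n_{cr}$); comparisons across studies
  should fix the same convention.
* The validity bound of the *bilayer* model at low stiffness contrast
  (flat-to-wrinkle transition disappearing near $G_f/G_s \approx 1.3$)
  comes from an external phase diagram and is not recomputed here; the
  trilayer model needs no such bound in the regimes exercised.
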