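---
title: "Methods: an oscillatory network model of grid cells under arena geometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an oscillatory network model of grid cells under arena geometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`gridscape` simulates how the spatial firing structure of entorhinal
grid cells depends on the geometry of the enclosure an animal explores.
This vignette is the package's own account of the model, the analysis
pipeline, and the numerical and design choices behind them.

## The model

A virtual animal forages in a 2-D arena.  Its velocity drives a
three-stage network:

**Head-direction (HD) layer.**  A Kohonen self-organizing map is trained
on unit heading vectors $\psi = [\cos\theta, \sin\theta]$ drawn
uniformly over $[0, 2\pi)$.  After training, every neuron's weight
vector is a unit vector (its preferred direction) and the layer's
response to a heading is the dot product $\psi^\top W$, i.e. the cosine
of the angle between heading and preference.  Defaults: an 8 x 8 sheet
(64 directions), 10,000 training samples, a Gaussian neighbourhood
shrinking from half the sheet to below one neuron and a learning rate
decaying 0.5 to 0.01.  The sheet sizes and schedule are package
choices; the 2-D sheet folds onto the 1-D circle of directions, so
preferred directions cover the circle with occasional gaps of a few
times the mean spacing at the fold lines.

**Oscillatory path integration.**  One forced limit-cycle (Hopf normal
form) oscillator per HD neuron:

$$\dot u = -v\,[\Omega + \beta s\,\theta_{HD}] + u\,[\mu - (u^2+v^2)],
\qquad
\dot v = u\,[\Omega + \beta s\,\theta_{HD}] + v\,[\mu - (u^2+v^2)]$$

with carrier frequency $\Omega = 12\pi$ rad/s, limit-cycle parameter
$\mu = 1$, spatial gain $\beta = 50$, timestep $dt = 0.01$ s, and $s$
the running speed.  The phase in excess of the carrier integrates
$\beta \times$ (displacement projected on the preferred direction), so
each oscillator path-integrates one directional component of position:
$\phi_k(t) = \Omega t + \beta\, (X(t)-X(0))\cdot u_k$.  The intrinsic
spatial wavelength of the population code is therefore $2\pi/\beta
\approx 0.126$ arena units, which fixes the scale of every spatial
analysis downstream.

*Speed convention.*  We take $s$ as speed in units/s (displacement per
step divided by $dt$).  Read instead as raw per-step displacement, the
phase gained per unit distance becomes $\beta\,dt \le 0.5$ rad/unit —
a spatial wavelength of more than twelve arena units, so no sub-arena
periodicity could form in any of the enclosures studied.  The speed
reading is the one that produces spatially periodic firing at all.

*Integration.*  Because the instantaneous frequency is constant within
a timestep, the polar form of the oscillator decouples exactly: the
phase rotates rigidly by $\omega\,dt$ and the squared radius follows a
closed-form logistic relaxation toward $\mu$.  We advance both in
closed form.  This matters twice over: explicit Euler at these
frequencies ($\omega\,dt \approx 0.4$-$0.6$) inflates the limit-cycle
radius several-fold, and even a high-order integrator's tiny per-step
phase error accumulates differently across oscillators over a
half-million-step session, slowly translating the interference pattern
and washing the spatial structure out of time-averaged rate maps.  With
the exact update the unforced radius is $\sqrt\mu$ to machine precision
and phase error is zero.

**Lateral anti-Hebbian network (LAHN).**  A single layer of $n = 20$
neurons reads the full oscillator state (both $u$ and $v$ components,
input dimension $m = 2 \times 64$).  The response recurrence

$$\xi_i(t) = \sum_j q_{ij}\chi_j(t) + \sum_k w_{ik}\xi_k(t-1)$$

is taken as settled within each 10 ms sample,
$\xi(t) = (I - w)^{-1} q\,\chi(t)$: the lateral loop is much faster
than the input timestep, and the settled solution is the only bounded
reading once anti-Hebbian learning grows the lateral weights beyond
unit spectral radius (the raw one-step recurrence overflows within
tens of steps).  Plasticity is Hebbian with an Oja decay on the
afferents and anti-Hebbian on the laterals (zero diagonal),

$$\Delta q_{ij} = \eta_F[\chi_j\xi_i - q_{ij}\xi_i^2], \qquad
  \Delta w_{ik} = -\eta_L\,\xi_i(t)\,\xi_k(t-1),$$

with $\eta_F = \eta_L = 0.01$.  So trained, the afferent rows converge
to the principal subspace of the input stream while the laterals
decorrelate the responses.

*Temporal correlation.*  The lateral update pairs the current response
with the previous sample's, so its decorrelating force is proportional
to the lag-1 response correlation.  On temporally white input it has
zero expectation and the lateral weights merely drift; the network is
meant for — and is tested on — slowly varying streams such as the
oscillator states, where lag-1 and instantaneous correlations nearly
coincide.

*Stability.*  The lateral rule integrates response products without
decay, so it is only conditionally stable: with $\eta = 0.01$ the
dynamics is well-behaved when the leading covariance eigenvalue of the
input stream is of order one or below.  The oscillator drive is
therefore gain-normalised by $1/\sqrt{m}$ before the LAHN — the
oscillator population norm is $\approx\sqrt{N}$ whatever the sheet
size, so this is a pure global gain that leaves the principal subspace
and all spatial structure unchanged while keeping the printed learning
rates inside their stable regime for any sheet size.

## The foraging model

Heading performs a bounded random walk: each step draws a turn
uniformly from $[-\rho\,dt, \rho\,dt]$ with $\rho = 20$ rad/s.  Speed
equals the distance to the nearest wall, clamped to
$[\text{min\_speed}, \text{speed\_cap}] = [0.05, 0.5]$ units/s.  The
wall-distance rule slows the animal near borders; the floor is
essential, because pure distance-proportional speed makes the log of
the wall distance a driftless random walk — simulated agents end up
crawling at the boundary for most of the session instead of foraging.
With the floor, occupancy over a 1.8-unit square is close to uniform
(relative occupancy entropy above 0.95).  Steps that would cross a wall
(possible only within min_speed x dt of a wall) are rejected and
redrawn, then reflected off the wall normal.  Given a seed, every
trajectory is bit-reproducible.

## Arenas

All boundaries are closed polylines (arcs discretised at 360 vertices
per full circle), with point containment by the even-odd rule and wall
distance as the minimum over boundary segments:

* regular $n$-gons inscribed in a circle, vertices at angles $2\pi k/n$;
* two rooms (squares of side 1.8 or circles of the same diameter)
  joined by a corridor of width 0.8 and length $d$ — the published
  room/corridor dimensions of the two-compartment experiments.  The
  0.8 figure is taken as the corridor *width* and the separation $d$ as
  its length, since the distance study varies the separation;
* concave arenas — annulus, horseshoe (two concentric semicircular
  arcs closed by straight caps) and an S (two horseshoes joined at a
  common end, one inverted).  An inner radius of zero degenerates to
  the disc / half-disc.  The inner radius is the experimental variable;
  with no outer radius dictated by the protocol, we use 3 for the
  annulus and horseshoe studies (inner 0..2) and 2 for the S study
  (inner 0..1), keeping at least a one-unit-wide band;
* a 5 x 2 rectangle whose breadth grows linearly to 5 x 5.  The
  schedule is a package choice: the transformation runs over the first
  half of the session and the arena stays square thereafter, giving
  roughly balanced time in the two configurations (a transformation
  spanning the whole session would leave under 2% of samples in the
  square configuration and make the decoding study degenerate).  The
  configuration label switches from 1 to 2 when the breadth reaches
  99% of the square side.

## Rate maps, autocorrelograms and gridness

Rate maps average the rectified response in square bins of 0.01 arena
units (Gaussian-smoothed with sigma = 1 bin over visited bins;
unvisited bins stay missing).  The bin size follows from the model: the
envelope of the interference pattern decorrelates on the $2\pi/\beta$
scale, with the first autocorrelation minimum near 0.05 units, so bins
must be well below that for the ring of nearest firing fields (radius
0.08-0.14 units) to be resolvable at all.  At 0.02 units and above the
ring merges into the central peak and the gridness annulus lands on
noise.

The spatial autocorrelogram is the Pearson correlation of the map with
itself at every 2-D lag, computed only over pixels visited in both
shifted copies; lags sharing fewer than 20 pixels are masked.  The
per-lag sums are obtained exactly via FFT cross-correlations (verified
against a naive quadruple loop to 1e-10).

The hexagonal gridness score (HGS) correlates the annulus-masked
autocorrelogram with its rotations:
$\min(r_{60}, r_{120}) - \max(r_{30}, r_{90}, r_{150})$.  The annulus
runs from the first local minimum of the radially averaged
autocorrelogram to 1.5x the radius of the ring peak, i.e. it hugs the
ring of six nearest peaks, with the peak search bounded to three times
the first-minimum radius so a distant noise maximum cannot capture the
mask; when no interior minimum exists the fall-back is 0.2-0.8 of the
maximum lag, flagged low-confidence.  A wider annulus (we tried 2.5x)
mixes in the shared radial structure of outer rings, which inflates
all five rotation correlations alike: an ideal hexagonal lattice then
scores ~0.93, whereas the ring-hugging annulus scores it ~1.3 and an
ideal square lattice strongly negative.  Ellipticity is the axis ratio
of an origin-centred ellipse fitted to the first-ring peaks (at least
three required); half-arena similarity reflects one half of the map
onto the other across an equal-area cut and correlates jointly visited
bins.

For two-room arenas the *global* HGS is computed on the whole-arena
map and the *local* HGS as the mean of the two per-room maps (corridor
samples excluded).

**A caveat on absolute scores.**  A single neuron-map's HGS at these
arena sizes rests on a handful of independent envelope cells inside the
annulus, so the five rotation correlations are noisy, and because the
score takes a minimum of two minus a maximum of three, pure noise is
biased negative (about $-1.4$ times the correlation s.d.).  Absolute
HGS values are therefore pipeline-dependent; comparisons across
conditions, which share the bias, are the meaningful output.  Study
scores average over the grid-like units of each run (all neurons with
positive whole-map HGS, and in any case the five best) and over seeds.

## The geometry studies

Each study trains the full model from scratch per seed (the
head-direction layer, which depends only on heading statistics, is
shared across arena conditions within a seed) and summarises per-seed
linear trends by the majority slope sign and median $R^2$:

* **connected shapes** — square-square, square-circle, circle-circle;
  local/global HGS of the best grid neuron tracked across training
  checkpoints (full-session replays through frozen snapshot weights);
* **connected distance** — separation 0.1..1; final local/global HGS
  against distance.  Sessions must be long enough for several corridor
  trips; at the default 900 s a run makes a handful of crossings,
  matching the "trips per session" framing of the original protocol;
* **convex** — square (side 0.9) vs isosceles trapezoid (parallel
  walls 0.2 and 1.0, length 1.9, the published trapezoid proportions);
  per-half HGS across the equal-area vertical cut, half-map
  similarity, ellipticity;
* **concave** — HGS against inner radius for annulus, horseshoe, S;
* **transforming** — decoding the configuration (rectangle vs square)
  from LAHN population activity with a single-hidden-layer MLP
  (20 hidden sigmoid units, online backpropagation on squared error,
  learning rate 0.01, 200 epochs, stratified 80/20 train/test split,
  threshold 0.5; every 5th timestep used as a sample).  Three decoders
  are compared: one fed the *online* response log of the network
  learning to convergence during the session (the concurrent-training
  protocol), one fed the session replayed through a partially trained
  snapshot (earliest checkpoint at or after 10% of the convergence
  iteration, frozen), and one fed the replay through the untrained
  initial weights.  Decoder inputs receive one global gain ($1/$ the
  overall response s.d.) so the fixed learning rate is meaningful
  whatever the response scale; the per-feature structure that
  distinguishes a trained from a naive network is untouched.  Feeding
  the online log to the "trained" decoder is deliberate: with
  all-frozen replays both decoders sit near the ceiling set by
  position information alone and the trained/naive asymmetry cannot
  appear.

Convergence of the LAHN is monitored as the mean absolute net change
of the afferent weights per element per step over 1,000-step windows;
if the 1e-5 tolerance is not reached within the session the end of the
run is used as the convergence point (at these session lengths the
drift diagnostic plateaus around 1e-4, dominated by stationary
stochastic fluctuation rather than systematic learning).

## Problem sizes

Default sessions are 600 s of simulated time (60,000 steps; 900 s for
the two-room studies, which need corridor traffic), five seeds per
study, with the full radius/side grids available as function defaults
and coarser subgrids used in the package's acceptance runs.  A full
single run — trajectory, SOM, oscillator drive, LAHN training and
20-neuron gridness scoring — takes a few seconds on one CPU.

## What the synthetic data does and does not emulate

The generator reproduces the *protocol* of the modelled experiments:
curvature-constrained foraging under geometric constraints, border
slow-down, multi-session designs.  It does not emulate realistic
rodent kinematics (accelerations, head scanning), sensory input of any
kind, or boundary-anchored corrections: position enters the network
only through path integration from the starting point.  That last
point is a known limitation with a visible consequence — firing
patterns are functions of path-integrated position, so a pattern
cannot re-anchor separately in each room of a connected arena, and the
local-to-global reorganisation of grid fields over learning reported
in two-room experiments has no mechanism here beyond what the
training-driven growth of response structure provides.  Passing trend
tests on connected arenas should be read with that in mind.

## Known limitations

* Absolute HGS magnitudes are implementation-dependent (binning,
  smoothing, masking); only orderings and trends transfer.
* The anti-Hebbian lateral rule has no decay term, so the LAHN is
  conditionally stable (see above); streams with leading covariance
  eigenvalue well above one destabilise it at the printed learning
  rates.
* The equal-area half split is a vertical cut; arbitrary split axes
  are supported for rate maps but not for the study drivers.
* The MLP decoder is intentionally small and briefly trained, as in
  the modelled study; it is a probe of linearly-available information,
  not a ceiling.
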