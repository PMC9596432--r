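---
title: "Adhesin placement and multicellular aggregation: model and methods"
author: "piliagg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adhesin placement and multicellular aggregation: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(piliagg)
```

## The question

Bacteria that adhere to each other through retractile surface filaments
(type IV pili) can form multicellular aggregates.  Whether the adhesive
machinery is concentrated at one pole or spread over the whole cell surface
changes how two colliding cells can bind: a polar patch requires both
partners to present their patch at the contact, whereas dispersed adhesins
make essentially every collision bindable.  `piliagg` implements a minimal
biophysical model of this difference and the image statistic used to score
its consequence — the typical aggregate size — so the in-silico comparison
(dispersed adhesins aggregate more than patch-localized ones, and
non-adhesive cells not at all) can be reproduced at desk scale.

## Cell model

A cell is a rigid molecule of one large body sphere (radius
$\sigma_B = 5$) and $n = 19$ small adhesin spheres (radius $\sigma_P = 1$,
the unit length) whose centers sit on the contact sphere of radius
$\sigma_B + \sigma_P = 6$, i.e. adhesin spheres tangent to the body
surface.  Two placements are built by `build_cell_template()`:

* **localized** — a closely packed hexagonal patch: rings of 1, 6 and 12
  lattice points projected radially onto the contact sphere.  Radial
  projection contracts in-plane distances, so the planar lattice spacing is
  rescaled (fixed-point iteration) until the minimum projected center
  distance is exactly $2\sigma_P$: the patch is "closely packed" in the
  sense of tangent adhesin spheres, confined to one side of the body.
* **dispersed** — a near-uniform spherical point set: a Fibonacci sphere
  refined by a short deterministic inter-point repulsion relaxation.  For
  $n = 19$ the minimum pairwise distance is ≈ 4.6, far above overlap.

Pair interactions (all between *different* cells; the molecule is rigid so
intra-cell terms are irrelevant and excluded):

* body–body and body–adhesin: purely repulsive truncated-and-shifted
  Lennard-Jones (WCA),
  $E_{XY}(r) = \epsilon + 4\epsilon[((\sigma_X+\sigma_Y)/r)^{12} -
  ((\sigma_X+\sigma_Y)/r)^6]$ for $r < 2^{1/6}(\sigma_X+\sigma_Y)$, zero
  beyond, with $\epsilon = 1$ in units of $k_BT$;
* adhesin–adhesin: a soft cosine well,
  $E_{PP}(r) = A\,[1 + \cos(\pi r/r_c)]$ for $r < r_c = \sigma_P$, zero
  beyond.  $A = -8$ models adhesive (pilin-expressing) cells — a pair of
  fully engaged adhesins is bound by $2A = -16\,k_BT$ — and $A = 0$ the
  non-adhesive control.

Both potentials have zero value *and* zero slope at their cutoffs, so
forces are continuous everywhere; the soft well has no hard core (the
force also vanishes at $r = 0$).

## Dynamics

Cells follow underdamped Langevin dynamics at $k_BT = 1$, integrated with
the BAOAB splitting (half kick, half drift, exact Ornstein–Uhlenbeck
velocity refresh, half drift, half kick).  With the friction off
($\gamma = 0$) the scheme reduces to velocity Verlet, which is what the
energy-conservation test exercises.

**Time unit and friction.**  The unit of time $\tau$ is defined as the
average time a free adhesin-sized particle needs to diffuse one unit
length.  Reading this as $\langle|\Delta r|^2\rangle = \sigma_P^2$ at
$t = \tau$ in three dimensions gives $D_P = \sigma_P^2/(6\tau)$ and, with
unit atom mass, a friction rate $\gamma = 6/\tau$.  A cell receives drag
summed over its 20 constituent atoms: translational friction
$\Gamma_t = 20\gamma m$ acting on mass $M = 20$, and rotational friction
from the same per-atom drags about the center, which for an isotropic
approximation of the inertia tensor ($I = \tfrac23\sum_i |u_i|^2$, the
mean principal moment) yields the *same* relaxation rate $\gamma = 6$ for
translation and rotation.  A free cell therefore diffuses with
$D = k_BT/(\gamma M) = 1/120$, which the test suite verifies against a
time-averaged MSD.  Alternative readings of the diffusion convention would
rescale times by an $O(1)$ factor only.

**Rigid-body bookkeeping.**  Orientations are unit quaternions rotated by
the angular velocity at each drift half-step; adhesin world coordinates
are always regenerated from the quaternion, never integrated
independently, so the rigid geometry is exact by construction (verified to
$10^{-9}$ over $10^4$ steps).  The time step is $0.05\,\tau$.

**Numerical safeguards.**  Any single pair force is capped at a
configurable bound (default $10^3$) so a pathological initial overlap
cannot eject a cell; configurations with overlapping bodies are refused at
initialization (rejection sampling enforces center distance
$\ge 2\sigma_B$); a cell displaced by more than $10^6$ box lengths in one
step, or any non-finite coordinate, aborts the run with an
integration-blow-up error naming the step.

**Neighbor search.**  Pairs are tracked with a Verlet list (direct
$O(N^2)$ scan with a 3-unit skin, rebuilt on displacement) — at a few
hundred cells spatial cell lists would add complexity without measurable
benefit — plus a cached per-pair list of *candidate* adhesins built with a
1-unit slack and invalidated once any cell has translated or rotated far
enough ($|\Delta x| + 6\,\Delta\theta > 0.5$) to change what could
possibly interact.  The cache only prunes; exact cutoff tests decide every
interaction, and an all-pairs, all-atoms reference path must agree to
$10^{-10}$ in the test suite.

## Protocol and presets

Each replicate runs: random placement → equilibration → a recording window
(snapshots at fixed intervals) → uniaxial plate compression of the final
recorded configurations → projection and quantification.  Compression
mimics cells settling under an agar pad before imaging: two one-sided
repulsive walls (the same WCA form per atom, in the wall-normal
coordinate) close at constant speed along $z$ to a centered gap, after
which $z$ is no longer periodic.  The walls start one wall-cutoff
*outside* the box faces: cells wrapped across the $z$ boundary would
otherwise begin behind a wall with a divergent overlap force.

Two presets (`sim_config()`):

| preset | cells | box | equilibration | recording | compression |
|---|---|---|---|---|---|
| `paper` | 512 | $500^3$ | $8\times10^8\,\tau$ | 300 frames / $1.5\times10^8\,\tau$ | $2\times10^7\,\tau$, gap 500→50 |
| `desk`  | 64  | $160^3$ | $2\times10^5\,\tau$ | 10 frames / $10^4\,\tau$ | $5\times10^3\,\tau$, gap 160(+margin)→16 |

The `paper` preset records the published schedule; at $1.6\times10^{10}$
steps per replicate it is documentation, not a desk computation.  The
`desk` preset keeps the same cell count per volume within a small factor
(64/160³ vs 512/500³), the same 10:1 compression, and an equilibration
long enough for every cell to diffuse several inter-cell spacings
(mean first-encounter time is $\sim 2.6\times10^4\,\tau$ at this density,
so $2\times10^5\,\tau$ allows several binding opportunities per cell).
Desk-scale aggregates are therefore *young*: dispersed-adhesin runs reach
clusters of ~5–10 cells rather than the larger aggregates a $4000\times$
longer schedule would grow, which compresses — but does not reorder — the
differences between strains.  By default the final 3 recorded frames are
compressed independently and their fitted sizes averaged per replicate.

## From configurations and micrographs to the occupancy field

Simulated configurations are projected onto the $x$–$y$ plane:
each body is a filled disk of radius $\sigma_B$ and a pixel is foreground
iff its center lies inside a disk (periodic metric).  The
pixel-center-in-disk rule is chosen over area-weighted anti-aliasing
because it is exactly checkable by lattice enumeration.

Micrographs are binarized by adaptive thresholding — foreground where the
intensity falls below the local mean over a `block_size` window minus an
`offset` (cells are dark in phase contrast; a flag flips the polarity for
fluorescence) — followed by morphological opening then closing with exact
Euclidean disk structuring elements.  The published protocol does not
report its neighborhood or radii; the defaults (block 51 px, offset 2% of
the dynamic range, opening radius 1, closing radius 2) are standard for
100×-objective phase contrast at ~0.065 µm/px and are all exposed.  Two
consequences worth knowing:

* the local-mean threshold cannot segment objects much larger than the
  block (their interiors approach the local mean) — irrelevant at these
  cell sizes, but a caveat for other data;
* closing with radius 2 merges structures closer than ~4 px.  Inside an
  aggregate, where cells touch, this is harmless (the size statistic works
  at the aggregate scale); it does mean pixel-exact recovery can only be
  scored on fixtures whose cells are separated, which is how the
  calibration fixture is built (`min_separation = 20`).

## The aggregate-size statistic

For a binary field $\phi$ the normalized spatial autocorrelation is
$$C_{\phi\phi}(r) = \frac{\langle \phi(0)\,\phi(r)\rangle}{\langle\phi^2\rangle},$$
the average over all pixel pairs.  It is computed by FFT — circular for
periodic projections, zero-padded with per-lag valid-pair normalization
for micrographs — and radially averaged into 1-px bins (bins without pairs
are dropped).  Binary fields give $C(0)=1$ exactly and
$C(r\to\infty)\to\langle\phi\rangle$, the area fraction, which the suite
asserts.  The profile is then fitted with an offset exponential
$$C_{\phi\phi}(r) = C_\infty + (1-C_\infty)\,e^{-r/a},$$
and **$2a$ is reported as the aggregate size**.

Fitting choices (the source protocol reports none of these):
weighted nonlinear least squares with per-bin weights
$\propto\sqrt{\text{pair count}}$; default fit range
$r \in [0, \min(L/4, 150\,\text{px})]$ excluding bins with fewer than 100
pairs (boundary-starved bins otherwise dominate micrograph fits);
parameter bounds $0 \le C_\infty \le 0.999$ and
$0.1\,\text{px} \le a \le L$; starting values from the large-$r$ plateau
and the $1/e$ crossing, with the $C_\infty$ start floored at 0.01 (a start
of exactly zero makes the initial Jacobian singular on near-zero-plateau
profiles such as single-disk images).  Non-convergence and bound-pinning
are flagged, never returned as silent success.

As a particle-space cross-check, `cluster_cells()` builds contact clusters
by union-find over inter-cell adhesin pairs closer than $r_c$.  In
`run_experiment()` the reported cluster statistics are *medians over the
recorded snapshots*: with $A = 0$ a single snapshot can transiently
contain an unbound adhesin pair within $r_c$ at these densities, and the
median over well-separated snapshots (interval $10^3\,\tau$, far beyond
the ~$60\,\tau$ lifetime of such contacts) measures persistent structure.

## Synthetic data: what it does and does not emulate

All tests run on generated inputs (no micrographs from the study are
deposited):

* `make_correlated_binary()` — iid Bernoulli fields (no structure beyond
  the pixel), thresholded smoothed Gaussian noise (correlation length
  monotone in the kernel scale — the thresholded field's correlation is
  *not* exactly exponential, so only monotonicity is ever asserted), and
  uniform or clustered disk packs.
* `make_micrograph()` — phase-contrast-like images: dark disks (diameter
  15 px ≈ 1 µm at 0.065 µm/px) with bright halos, a multiplicative
  illumination plane, Gaussian sensor noise (default sd 0.01, SNR ≈ 60
  for the 0.6 contrast — an sCMOS-scale noise floor chosen so the
  threshold offset of 2% of range sits at 2σ of the noise, the regime the
  adaptive-threshold defaults are designed for), and salt-and-pepper
  pixels, with the exact disk mask as ground truth.  Cells cluster tightly
  (spread ≈ one cell diameter) so aggregated cells touch, as under an
  agar pad.
* `make_exponential_profile()` — exact evaluation of the fit model, used
  for fit-recovery calibration so that no false analytic identity is
  asserted about image-derived profiles.

Every generator is bit-reproducible from its seed and restores the
caller's RNG state.  None of this emulates real optics (no point-spread
function, no defocus, no 3-D structure), cell shape (A. baylyi are rods;
the model and fixtures use spheres/disks), growth, or pilus dynamics —
the model deliberately freezes the adhesive machinery, as in a
retraction-motor deletion background.  Passing tests therefore show that
the *pipeline* is faithful and the *model's* strain ordering is
reproducible, not that the model quantitatively predicts real aggregate
sizes.

## A worked miniature

```{r mini, eval = FALSE}
par_adh <- cell_params(A = -8)
tmpl <- build_cell_template("dispersed", par_adh)
cfg <- sim_config("desk", n_cells = 16, box_lengths = c(100, 100, 100),
                  t_equilibrate = 5e3)
st <- initialize_system(cfg, tmpl, par_adh, seed = 1)
eq <- run_phase(st, cfg, tmpl, par_adh, "equilibrate", seed = 2)
comp <- run_phase(eq$state, cfg, tmpl, par_adh, "compress", seed = 3)
img <- project_state_to_binary(comp$state)
aggregate_size(img)
cluster_cells(eq$state, tmpl, r_c = par_adh$r_c)$n_clusters
```

The full comparison (three strains × five replicates on the desk preset)
is `run_experiment(default_strains(5), preset = "desk", base_seed = 1)`;
it takes roughly a quarter of an hour on one CPU and is exactly what
`scripts/acceptance.R` runs.

## Known limitations

* Cells are spheres; rod shape, growth and division are out of scope.
* Pili are static adhesive sites: no extension/retraction forces, no
  twitching, no DNA uptake.
* The desk preset trades equilibration depth for tractability; absolute
  aggregate sizes are smaller than a full-schedule run would give, and
  only the strain *ordering* is asserted stochastically (4 of 5 matched
  seed sets).
* The isotropic-inertia approximation ignores the slight anisotropy of
  the localized template's mass distribution; rotational time scales are
  correct to within that $O(1)$ geometric factor.
* Hydrodynamic interactions are absent (free-draining Langevin drag).
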