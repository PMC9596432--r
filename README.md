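# piliagg

Rigid-body Langevin simulation of adhesin-patterned bacterial cells, and
image-based quantification of the multicellular aggregates they form.

## The problem

Type-IV-pili let bacteria stick to one another.  Where the adhesive
machinery sits on the cell changes what aggregation that adhesion can
produce: cells whose adhesins are concentrated in a polar patch can only
bind partners patch-to-patch, while cells with adhesins dispersed over the
whole surface can bind in any collision orientation.  `piliagg` is for
researchers who want to simulate that difference with a minimal physical
model and to quantify aggregate sizes — from simulated configurations *or*
from phase-contrast micrographs — with a single, reproducible statistic.

## The model and the statistic

Each cell is a rigid molecule: one body sphere (radius `sigma_B = 5`) plus
19 adhesin spheres (radius `sigma_P = 1`, the unit length) on its surface,
placed either as a hexagonally packed polar patch (`localized`) or
near-uniformly (`dispersed`).  Bodies repel through truncated-shifted
Lennard-Jones (WCA) potentials; adhesins of different cells bind through a
soft cosine well

    E_PP(r) = A [1 + cos(pi r / r_c)],   r < r_c = 1,

with `A = -8` (adhesive) or `A = 0` (non-adhesive control), all energies in
units of kT.  Cells move by underdamped Langevin dynamics (BAOAB, time step
0.05 tau) in a periodic box; after equilibration the configuration is
squeezed between two plates along z (mimicking settling under an agar pad),
projected onto the x-y plane as a binary occupancy field phi, and the
radially averaged spatial autocorrelation

    C(r) = <phi(0) phi(r)> / <phi^2>

is fitted with an offset exponential `C(r) = C_inf + (1 - C_inf) exp(-r/a)`.
**Twice the correlation length, `2a`, is the reported aggregate size.**  The
same statistic runs on binarized micrographs (adaptive threshold + opening +
closing), and a particle-space union-find over adhesin contacts provides an
independent cross-check on simulated data.

## Worked example

The headline comparison — localized vs dispersed adhesins vs non-adhesive
control, five matched replicate seeds each, 64 cells in a 160^3 box:

```r
library(piliagg)
res <- run_experiment(default_strains(5), preset = "desk", base_seed = 1)
res$summary
```

```
        strain   pattern  A n mean_size   sd_size mean_n_clusters
 dispersed_A-8 dispersed -8 5 12.862661 0.7507185              10
  dispersed_A0 dispersed  0 5  6.918476 0.2077386              64
 localized_A-8 localized -8 5 11.255889 0.7435236              27
```

Read: with binding on, dispersed adhesins condense 64 cells into ~10
clusters (mean cluster ~6 cells) and an image-space aggregate size of
~12.9 length units; the localized patch yields mostly dimers and trimers
(~27 clusters) and a size of ~11.3; the non-adhesive control stays at 64
singleton cells with a size of ~6.9, just under an isolated cell's disk
correlation scale (a single body disk of radius 5 fits at 2a = 8.5; the
control's plateau-corrected fit sits slightly below it).  The ordering
dispersed > localized > non-adhesive held in all five matched seed sets of
this run.  One replicate takes about a minute on one CPU; the full panel
roughly a quarter of an hour.

Single images work the same way:

```r
mg  <- make_micrograph(seed = 7)                  # synthetic phase contrast
m   <- preprocess_micrograph(mg$image)            # binary_image
aggregate_size(m)
#> aggregate_size: 2a = 25.4
```

A thin command-line front end (`exec/piliagg`) exposes the same pipeline as
`simulate`, `binarize`, `quantify`, `fixtures` and `experiment`
subcommands; trajectories are written as extended XYZ with a JSON sidecar.

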