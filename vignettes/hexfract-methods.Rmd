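---
title: "Methods: geometry, fractal metrics and the oligomer equilibrium in hexfract"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: geometry, fractal metrics and the oligomer equilibrium in hexfract}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hexfract)
```

`hexfract` models the self-assembly of a hexameric enzyme into
Sierpiński-order triangular complexes and implements the quantitative
analyses used to characterize such assemblies: interface accounting,
box-counting dimension, rigid-body and scattering geometry, a coupled
mass-action equilibrium, and mass-photometry quantification. This
vignette records the model assumptions, the parameters that matter, and
the numerical decisions, in the order a user meets them.

## The coarse-grained building block

A hexamer is a D3-symmetric ring of three dimers (six monomer beads).
`geometry_params()` holds the defaults, all lengths in nm and angles in
degrees:

* `hexamer_width = 10` — centre-to-centre spacing of adjacent hexamers.
  Calibrated so a three-hexamer edge spans 30 nm, the measured edge of
  the compact 36mer; the level-2 (54mer) edge then spans
  `4 × 10 = 40` nm, matching the measured 54mer.
* `ring_radius = hexamer_width / 3 ≈ 3.33` — distance of monomer centres
  from the hexamer centre. This value is not free: the radius of
  gyration of a level-k assembly is
  `Rg(k)² = ring_radius² + Σ_j (2^(j−1) w / √3)²`, which doubles exactly
  per level **iff** `ring_radius = w/3`. With that choice the generated
  hierarchy is exactly self-similar and the mass–radius regression over
  levels 0–4 returns `log 3 / log 2` to machine precision
  (`mass_radius_dimension()`), which is the invariant the package treats
  as load-bearing. A slightly larger ring (e.g. 3.5 nm) breaks exact
  doubling at low levels and steepens the slope by ~0.025.
* `monomer_radius = 2.2` — bead radius; beads of adjacent bonded
  hexamers interpenetrate by up to ~1.4 nm at the interface, which is the
  contact; `validate_assembly()` allows overlap up to 1.6 nm and rejects
  anything worse.
* `dihedral_level1 = 60`, `dihedral_level2 = 34` — the dimer–dimer
  torsions at the two fractal interface generations, used by the closure
  analysis only: all generators build planar (z = 0) assemblies, because
  class averages and schematics are 2D projections and planarity keeps
  the generators exact.

Every hexamer shares one global orientation, with corner-dimer
directions at 90°/210°/330° to the lattice. A corner then always lies
30° away from any neighbour direction, which gives three properties we
rely on: every pair of adjacent hexamers registers exactly one
dimer–dimer candidate contact (corner sites ~1.34 nm apart, inside the
0.15 · width tolerance); three-way junction groups form only at the
centres of *down*-pointing hexamer triangles (the compact 36mer has
exactly one, at its centroid); and the three outermost corners of any
Sierpiński-order triangle point outward, unpartnered.

## Interface accounting and frustration

`find_candidate_contacts()` defines a dimer's corner site as
`hexamer centre + corner_direction · width/2` and links sites within the
tolerance (default 0.15 · width, chosen so generated neighbours always
register exactly one contact). `realize_bonds()` selects a
maximum-cardinality bond set under the passivation rules — at most one
bond per dimer (the non-participating monomer's termini would clash) and
at most one per junction group (the interface cannot support a
three-fold association). The search is exact: contacts are split into
connected components and solved by depth-first branch and bound; ties
between optima resolve to the lexicographically smallest bond set by
dimer id. A brute-force subset enumeration backs this in the tests. The
rejected alternative of a genuine C3 junction interface is available as
`allow_c3 = TRUE` for comparison.

`frustration_scan(n)` enumerates *every* connected layout of up to `n`
hexamers on the triangular lattice (free polyhexes, grown
canonically and deduplicated under the 12-element lattice symmetry
group) and records the minimal unsatisfied count `3H − 2I`. Because the
contact structure distinguishes up- from down-pointing triangles, each
free shape is scored in both orientation classes and the better one
counts. The scan reproduces the known free polyhex counts
(1, 1, 3, 7, 22, 82, 333, ...) and shows that at 9 hexamers the
Sierpiński level-2 layout is the unique minimizer, with the same 3
unsatisfied corners as a single hexamer — the sense in which fractal
stoichiometries are the most efficient way to satisfy this interface.

## Box-counting dimension

`rasterize()` renders an assembly into a binary silhouette: `"disc"`
draws monomers as filled discs; `"ring"` draws each hexamer as an
annulus with an open centre, emulating the ring-shaped hexamer densities
of negative-stain class averages. The render scale places the assembly's
bounding box across ~90% of the frame (350 px frames mirror the particle
boxes used for 2D classification). The annulus half-thickness is the one
knob without a measured counterpart: it stands in for the threshold
applied to the real class averages before counting, which is
unpublished. The default, `monomer_radius / 2` = 1.1 nm, is a
calibration: with it the fixed-grid protocol below reads
`D ≈ 1.58` for the rendered 18mer and `D ≈ 1.64` for the 54mer at
matched pixel scale, inside the ±0.05 bands around the experimentally
reported 1.53 and 1.67. It is exposed as `blob_radius_nm`.

`box_count()` overlays a non-overlapping regular grid and counts boxes
containing foreground, over nine box sizes evenly spaced 85–17 px (the
published endpoints and count) and three grid offsets
(0, s/3, 2s/3 of each box size s — the published protocol used three
grid positions whose exact placement is unpublished;
fractional-of-box-size offsets keep the three phases comparable across
scales). Partial border boxes count. `fit_dimension()` then offers two
aggregations:

* `"per_offset"` (default) — ordinary least squares of `log N` on
  `log(1/s)` per offset; `D` is the mean slope, `D_sd` the spread over
  offsets, `R²` from the pooled fit. This mirrors the experimental
  fixed-grid scan and is what the class-average emulation uses.
* `"min_cover"` — counts are minimized over grid phases per size before
  the single regression. This is the direct discretization of the
  covering-number definition of the box dimension and converges
  markedly better on deep mathematical fractals: on a level-8
  subdivision raster (2048 px, tight margins, box sizes 8–512 px) it
  reads 1.59, where the per-offset protocol reads ~1.55 against the
  analytic 1.585. Analytic-oracle checks therefore use `"min_cover"`.

For analytic targets the exact set is rasterized with zero margin so box
sizes are exact fractions of the edge; rendered particles keep a 5%
margin. Degenerate inputs: images without foreground are rejected; constant
counts (e.g. an all-foreground frame at saturating sizes) raise a
degenerate-fit warning and return `D = 0`.

Three independent generators of the same set — recursive subdivision,
the seeded chaos game (midpoint map, burn-in 10 iterations), and the
Pascal-parity mask (odd binomials via the bitwise Lucas identity) —
agree within ±0.05 at matched resolution, which is the package's
cross-oracle for the estimator.

## Rigid-body geometry and scattering

The dimer–dimer dihedral is the standard four-point torsion over
(outer monomer of A, com A, com B, outer monomer of B), right-handed
about the A→B axis, reported unsigned by default. The outer monomer is
the interface-participating bead; the exact atom selections behind the
published angles are not fully specified, so the participating-monomer
convention is adopted and documented. Note that in the planar generated
assemblies the participating bead lies on the com–com axis and the
torsion is degenerate by construction — the operation is meant for
resolved (non-planar) conformations and constructed inputs, and raises a
degenerate-geometry error otherwise.

`rotation_between_conformations()` superposes the target onto the
reference by the Kabsch algorithm on an aligned bead subset, then
decomposes the residual optimal rotation of a probe subset into
axis–angle form; constructed rotations of a few degrees are recovered to
1e-6, mirroring the small dimer rotations that distinguish free from
assembled hexamers.

`closure_gap(θ)` builds three rigid planar 18mer units in the flat
54mer layout, folds the two inter-unit joints out of plane by θ (torsion
about the bond axis, hinges at the bonded corner-site midpoints,
symmetric ±θ signs), and reports the distance between the two corner
sites that should form the third interface. The gap is zero in the
plane, grows monotonically with θ, and is of order 10 nm at the
level-1 angle of 60° — the coarse-grained version of the observation
that the intra-18mer interface geometry cannot close a triangle of
18mers, so the inter-18mer joint must relax. In this rigid-hinge model
the closure root found by `closure_root()` lies near 0°: the model has
no torsion offset built into the interface, so it reproduces the
qualitative claim (closure requires an angle well below 60°) but not the
published 34°, which would require the atomistic interface geometry of
the deposited structures (out of scope).

Scattering uses the exact Debye sum over bead pairs (`I(0) = n²`,
uniform form factors, no solvent or contrast terms). `guinier_fit()`
regresses `ln I` on `q²` over the largest low-q window with
`q·Rg ≤ 1.3`, iterated to self-consistency, and errors on non-decaying
profiles. On noiseless Debye profiles of every generated assembly the
fitted Rg lands within 3% of the direct mass-weighted Rg. For mixtures,
`mixture_rg()` reports the z-average
`Rg² = Σ c_n M_n² Rg_n² / Σ c_n M_n²`, because a Guinier fit of a
mixture weights each species by its forward scattering ∝ M²; combined
with the equilibrium model this reproduces the concentration-driven rise
of apparent Rg.

## The oligomer equilibrium

The species set is the experimentally observed ladder — monomer, dimer,
hexamer, 18mer, 54mer — closed at 54 subunits because no larger discrete
species was identified; growth beyond 54mers at high concentration is
outside the model and flagged here. Each species' overall constant is
the product of its interface constants (dimer: 1 dimeric; hexamer: +3
heterologous; 18mer: +3 level-1 fractal; 54mer: +9 level-1 and +3
level-2). Two couplings act multiplicatively on fractal interfaces only:

* protonation, `g = (1 + 10^(pH − pKa))^(−m)` with `m = 2`
  protonatable contacts per interface (the two glutamate–histidine
  pairs). The interface pKa is never printed; the default 8.2 is an
  assumption placed between the day/night intracellular extremes 7.3
  and 8.4 so the assembly transition spans the physiological range, and
  it is exposed in `eq_conditions()`. The titration midpoint shifts 1:1
  with pKa, which the tests verify.
* ligand linkage, `h = (1 + L/K_L)^(−p)` with order `p = 2`, modelling
  substrate/product binding as competitive stabilization of the open,
  fractal-incompetent dimer rotation on both sides of the interface;
  `K_L = 2e-4` M puts disassembly in the (sub)millimolar range.

The shipped constants are **fitted, not measured**
(`scripts/calibrate_ladder.R` re-derives them): `K_dim = K_hex = 1e14`
/M make free monomer and dimer negligible above ~10 nM;
`K_f1 = 1.54e6` /M places ~85% of subunits in 18mers at 50 nM and
pH 7.5 (the calibration anchor is ">80% at 50 nM"); `K_f2 = 3e4` /M
keeps 54mers rare below ~1 µM, consistent with larger assemblies
appearing only at micromolar concentrations. `K_f2 ≤ K_f1` is enforced:
the level-2 joins are the weaker generation.

`solve_equilibrium()` solves `Σ n β_n m^n = C` for free monomer `m` by
bisection on `log m` (the left side is strictly increasing), 200
iterations on a bracket spanning up to 400 decades; all intermediate
arithmetic stays in log space, since `β_54` for the default ladder
overflows double precision. Conservation holds to a relative residual
below 1e-9 across random ladders, which the tests check at 1,000 draws.
Setting `K_f1 = 0` removes 18mers and 54mers entirely — the in-silico
analogue of the hexamer-only interface mutants. `activity_index()`
averages per-species relative activities over subunit fractions; the
default map (fractal species at α = 0.5) encodes the observed two-fold
activity gap between wild type and a hexamer-only variant as a
calibration, not a prediction.

## Mass-photometry quantification and the synthetic generators

`simulate_mp()` samples particles in proportion to species molar
concentrations (the landing-rate assumption: each complex counts once)
and adds Gaussian mass error with `sd = max(4 kDa, 2% of mass)`, a
typical single-particle mass-measurement resolution; the generating
truth travels with the events. `quantify_mp()` histograms events with a
Freedman–Diaconis bin width (floor 5 kDa) computed per candidate mass
window — the narrowest well-populated peak sets the bins, because the
pooled multimodal distribution would suggest ~100 kDa bins — and fits
all species jointly by least squares, one bin-integrated Gaussian per
candidate stoichiometry with its mean confined to
`n · monomer_mass ± 10%` and free amplitude and width. Bin-integrated
components keep particle counts exact even when a peak is narrower than
a bin; a joint fit (not per-peak) handles overlapping heavy-species
peaks; windows with no events warn and count zero. Subunit fractions
follow as `n · count_n / Σ k · count_k`, and
`fractions_to_particles()` / `particles_to_fractions()` interconvert the
two published conventions. At 10,000 events the pipeline recovers
generating subunit fractions within ±0.03, with replicate-mean bias
below 0.01.

The generators emulate the *statistics* of the study's raw data — mass
event streams, multiplicative scattering noise with ten-frame
averaging, stain-like blur and speckle on silhouettes — not the
instruments: no interferometric movies, no detector models, no CTF or
class averaging. Passing tests therefore demonstrate correctness of the
estimators under the stated noise models, not robustness to every
artefact of real micrographs. One honest limitation found while testing:
salt-and-pepper speckle at 1% scatters enough dimension-2 dust across a
350-px frame to bias box-counting upward by ~0.2 regardless of
estimator, so the robustness test asserts stability under 0.3% speckle
and separately asserts the direction of the 1% bias;
`degrade_image()` itself accepts speckle up to the 5% contract limit.

## Reproducibility, sizes and conventions

Every stochastic operation takes an explicit integer seed and records
it; reruns are bit-identical, and `run_pipeline()` writes a resolved
config echo, a MANIFEST and a summary JSON (12 significant digits) that
is byte-stable across reruns. Units are nm and degrees; ids are 0-based
across the assembly tables. Problem sizes used by the default test and
acceptance runs were chosen to exercise the scaling regimes at desk
scale: subdivision depth 8 (6,561 triangles) at 1024–2048 px for the
analytic dimension, assemblies to level 4 (486 subunits) for
mass–radius scaling, the polyhex scan to 9 hexamers (6,572 free
shapes), 10,000 mass events per quantification and 100 seeded
replicates for the bias check.

Known limitations, beyond those noted above: the generators do not
produce the sporadically observed irregular assemblies; the equilibrium
is pathway-agnostic (whether 54mers grow from preformed 18mers is not
established); and the geometric model carries no energetics beyond bond
counting.
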