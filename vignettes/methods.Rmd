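---
title: "Methods: fitting and refining atomic models in cryo-EM density"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fitting and refining atomic models in cryo-EM density}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cryofit)
```

cryofit implements the post-reconstruction stages of a single-particle
cryo-EM project: placing atomic models into density, deforming them
locally, restraining their stereochemistry during refinement, and
validating the result against independent half maps.  This vignette is the
package's own account of the models and procedures it implements, the
parameters that matter, the numerical choices behind them, and what the
synthetic fixtures do and do not demonstrate.

## Density maps, statistics and scoring

A `density_map` is a scalar grid on orthogonal axes with a voxel size and a
Cartesian origin (the centre of the first voxel).  Cryo-EM reconstructions
sit in boxes padded with near-zero solvent, which deflates the naive map
standard deviation and makes Z-scores incomparable with crystallographic
maps.  `robust_map_stats()` therefore histograms the voxel values into
finely sampled bins (10,000 by default over the full range), discards the
voxels in the single modal bin — the solvent peak — and computes the mean
and variance from the remainder.  The bin count is a documented choice: one
modal bin is removed regardless of width, so the estimator only assumes the
solvent level is the most common value.

The fit of a model pose to density is the Z-weighted density sum

$$S = \sum_a w_a \, \frac{\rho(\mathbf{x}_a) - \mu}{\sigma},$$

with trilinear interpolation $\rho(\mathbf{x}_a)$ at atom centres, robust
moments $\mu, \sigma$, and weights $w_a$ equal to the atomic number by
default (a unit-weight mode is provided; the literature names the score but
not the weight, so both are exposed).  Positions outside the grid
contribute the solvent level (0) and are flagged rather than raising an
error, because randomized pose searches legitimately wander into padding.
The score is invariant under affine rescaling of the map when the
statistics are recomputed.

Two numerical consequences of trilinear scoring matter for interpretation.
First, the interpolated field underestimates density peaks between voxel
centres, so the score optimum of even a noiseless map sits a fraction of a
voxel (~0.3–0.5 A at 1 A voxels) away from the generating pose; rigid-body
"identity" checks in the tests use that tolerance.  Second, straight
poly-alanine helices have two near-degenerate score ridges — the
end-over-end flip and the one-residue screw register — whose refined scores
differ by ~0.1% at 4 A.  This is a property of the data, not the optimizer;
it is why the orientation of a helix is treated as its own binary decision
(`orient_helix()`) and why recovery experiments use a compact bent-helix
domain with no such degeneracy.

## Reciprocal space conventions

Spatial frequency is $s = 1/d$ in inverse Angstrom throughout, so a
temperature factor multiplies every Fourier coefficient by
$\exp(-Bs^2/4)$: negative $B$ sharpens, positive $B$ blurs, and the zero
frequency term is untouched.  `scale_to_reference()` places maps with
different sharpening histories on a common scale by matching per-shell mean
amplitudes to a reference map or curve, either as one constant per shell
(exact shell-mean matching, used before half-map cross-validation) or as a
spline in $s$ through the shell estimates (tracks smooth falloffs better
inside shells).  Neither variant can undo a strong exponential exactly —
the reweighting varies within each shell while the estimate is per-shell —
so recovery of a sharpened map is accurate to ~1%, not machine precision.

Model structure factors are computed by rasterizing each atom as a
five-Gaussian electron scattering density.  With $f(s) = \sum_i a_i
\exp(-b_i s^2/4)$ (the International Tables Vol. C parameterization; an
X-ray Cromer–Mann table is shipped alongside with its constant term as a
fifth $b=0$ Gaussian), the real-space kernel is

$$\rho(r) = \sum_i a_i \left(\frac{4\pi}{b_i + B}\right)^{3/2}
  \exp\!\left(-\frac{4\pi^2 r^2}{b_i + B}\right),$$

where $B$ is the atom's temperature factor.  The widths are floored at
$b_i + B \ge 5\,\mathrm{A}^2$ so every term stays resolvable on ~1 A
grids; all generator models carry $B = 20\,\mathrm{A}^2$, a value typical
of sharpened 3–4 A reconstructions, so the floor is inactive in practice.
Gaussians are truncated where the widest term falls to $10^{-4}$ of its
peak, which bounds the single-atom amplitude error against the analytic
form factor at ~3% near the band edge.

## The synthetic-density generator

`simulate_map()` band-limits the model transform at the nominal resolution
and adds white Gaussian voxel noise; `simulate_half_maps()` duplicates the
signal with two independent noise realizations, emulating reconstructions
from disjoint particle half-sets.  The generator emulates the *signal
content* of a reconstruction — band limit, solvent padding, half-map
independence — and deliberately not the imaging physics: no CTF, no
alignment error, no solvent flattening, and white rather than colored
noise.  Passing tests therefore demonstrate algorithmic correctness on
band-limited data with independent noise, not end-to-end performance on
real micrographs.  Noise levels are specified relative to the robust signal
sd (`noise_rel`); 0.5 makes a 4 A band-limited pair estimate its own
resolution near 4 A by the FSC 0.143 criterion, which is the realism
anchor used in the experiments.

The model generators provide the study objects: `build_ideal_helix()`
(poly-alanine, $\phi=-57^\circ$, $\psi=-47^\circ$, standard bond geometry,
1.56 A rise), `build_ideal_duplex()` (A- or B-form RNA/DNA with canonical
Watson–Crick pairing), `shake_model()` (i.i.d. Gaussian displacement with
the requested expected RMSD) and `bend_model()` (rigid hinge rotation).
Duplexes are built by placing idealized base pairs under helical symmetry
— A-form rise 2.81 A / twist 32.7°, B-form 3.38 A / 36.0°, documented
defaults since the literature names the forms but not one canonical
parameter set.  Base pairs themselves are constructed by a least-squares
in-plane fit of each pattern's hydrogen-bond distances using idealized
monomer geometry (Chemical Component Dictionary ideal coordinates, shipped
as plain text), and the helix axis threads the midpoint of the two
base-ring centroids so that intra-strand stacking falls inside the
parallel-plane detector's default acceptance windows without modelling
base inclination.

## Jiggle fitting

`jiggle_fit()` draws `n_trials` rotation–translation hypotheses about the
selection centroid.  Trial $c$ of $N$ uses a fraction $1 - c/N$ of the full
rotation range and of the translation range $s$, so early trials explore
and late trials stay near the input pose.  Hypotheses are scored by the
Z-weighted sum; the best `n_top` (default 20) are polished by
`rigid_body_refine()` and re-scored, and the best refined pose replaces the
input only if it beats the input's own refined score.  Translations are
drawn symmetrically in $[-r, r]$ per axis (a one-sided range would bias the
search direction).  The range $s$ is the user's statement of positional
uncertainty: searches with $s$ far larger than the true displacement fill
the candidate list with poses on neighbouring features, so the experiments
set $s$ to the displacement scale being tested, and use more trials
(400–800) than the interactive default because a compact ~30-residue
domain subtends a narrower rotational convergence basin than the larger
domains the method is typically applied to.

`rigid_body_refine()` is a derivative-free coordinate search over the six
rigid-body parameters: steps start at 2° and half a voxel, shrink by half
when a sweep fails to improve, and terminate below 0.1° / 0.01 A or at an
evaluation budget (200 per parameter).  Two robustness additions matter on
curved score valleys: an accepted direction is ridden with doubling steps
(pattern-search acceleration), and the coordinate stages alternate with a
Nelder–Mead simplex polish until neither improves.  The refined score
never falls below the starting score.

`find_helices()` seeds a six-dimensional helix search at the strongest
local maxima (at least 5 A apart) of a 5 A low-passed copy of the map,
scores an ideal helix over a deterministic quasi-uniform orientation set
(super-Fibonacci sampling, so results are seed-independent), refines the
best orientation per seed and suppresses overlapping placements.
`orient_helix()` builds the 180°-flipped copy about a perpendicular axis,
jiggle-fits both candidates and returns the higher refined score — at 4 A
the carbonyl and C-beta positions separate the orientations by ~4% of the
score; towards 7 A helices become featureless tubes and the decision
degrades toward (but stays above) chance, matching the published trend.

`fold_screen()` ranks candidate domains against a segmented map (spherical
segments default to 34 A for protein domains, 17 A for RNA motifs).  The
map is low-passed to 5 A; each domain is centred on the segment's density
centroid and scored over a quasi-uniform orientation ensemble with
translation-only local refinement per orientation; the best pose then
receives a full six-parameter polish, mirroring how molecular-replacement
candidates are refined before assessment.  The contrast score,
$(S_{max} - \bar S)/\mathrm{sd}(S)$ over the domain's pose ensemble, is
the decision statistic: values above about 3 indicate a correct solution,
and on a self-consistency screen (a helical-bundle domain against its own
5 A map, 300 orientations) the measured contrast is ~10.

## Morphing

`morph()` deforms a nearly correct model into density without breaking
local geometry.  For each residue a five-residue fragment centred on it is
rigid-body fitted to the map; each residue then receives the robust
average of the operators of its spatial environment (residues with atoms
within `env_radius`, default 10 A): operators are sorted by the mean
displacement they induce on the central residue's atoms, the top and
bottom quarter are discarded, translations are averaged arithmetically
(anchored at the residue centroid) and rotations by a hemisphere-aligned
quaternion mean.  Per-fragment fits are bounded (default 15°, 2 A per
pass) because a five-residue helical fragment can otherwise jump a
one-residue screw register; morphing applies local shifts by design, and
serial iterations (typically four) carry the model the full distance.
Larger environments give smaller per-pass shifts and need more passes.
A 15°-bent 40-residue helix morphed four iterations against a 4.5 A map
of the straight truth recovers to well under half its starting RMSD,
and running the same morph against one half map leaves the model-map FSC
against the held-out half map within 0.05 per shell — morphing does not
absorb half-map-specific noise.

## Restraints

External restraints carry prior structural knowledge into refinement.
`generate_reference_restraints()` emits one distance restraint per
corresponded atom pair whose reference distance is below 4.2 A (and whose
residue separation is at least 2 within a chain): long enough range to
brace local structure, short enough to tolerate global conformational
differences between target and reference.  By default only main-chain +
C-beta (protein) and backbone + glycosidic-N (nucleic acid) atoms are
restrained, keeping the pair count near-linear in size.
`generate_jelly_restraints()` is the same generator with the model as its
own reference — current distances become targets, a pure stiffness
regularizer with zero energy at generation.
`generate_hbond_restraints()` emits O(i)–N(i+4) targets of 2.9 A wherever
the current distance is under 3.5 A, and
`generate_helix_fragment_restraints()` slides a 9-residue window,
superposes an ideal helix and, when the backbone RMSD is below a tolerant
1.5 A, emits the ideal fragment's internal backbone distances — these do
not require well-formed hydrogen-bond geometry to fire, which is the point
at low resolution.

Distance restraints enter the target through the Geman–McClure robust loss
$\rho(\Delta) = \Delta^2 / (1 + (\Delta/c)^2)$ on the sigma-standardized
residual: quadratic near zero, saturating at $c^2$, so restraints that
disagree strongly with the data exert vanishing force instead of dragging
the model toward an outlying target.  The scale $c$ defaults to 5 standard
deviations.

`detect_base_pairs()` identifies canonical Watson–Crick and G:U pairs from
N/O contact geometry: all pattern hydrogen-bond distances within ±0.5 A of
their reference values, base planes within 35°, and a planarity guard on
the normalized signed volume of the glycosidic attachment atoms (|volume|
≤ 0.3).  The guard replaces a sign-consistency chirality test because on
idealized pairs those four atoms are coplanar and the sign is numerical
noise; a large volume marks a pyramidal arrangement no pair class can
produce.  G:U pairs are genuinely ambiguous between wobble and
reverse-wobble geometries, so `generate_base_pair_restraints()` emits both
alternatives as a jointly selected multi-target group;
`select_multi_targets()` activates, each refinement cycle, the alternative
with the least total squared deviation from the current geometry.
`detect_stacking()` fits orthogonal least-squares planes through predefined
planar groups (bases, Phe/Tyr/Trp/His rings, Arg guanidinium) and accepts
pairs with near-parallel normals (≤30°), normals pointing along the
centroid-centroid vector (≤30°, which is what separates stacking from
mere coplanarity) and centroid separation of 2.5–4.5 A.

## Refinement

`refine_coords()` minimizes geometry + density.  The geometry term sums
harmonic covalent bond/angle restraints derived from the idealized monomer
table (bonded pairs are atoms within 1.75 A in the ideal coordinates;
their ideal distances and angles are the targets), the robust external
restraints above, harmonic torsion restraints and a parallel-plane term
$\sin^2\theta / \sin^2\sigma$ on the inter-normal angle, whose gradient
uses the eigenvector perturbation formula for the least-squares plane
normal.  All gradients are analytic and verified against central finite
differences.

The density term has two modes.  Real space: the negated per-atom
Z-weighted score with the trilinear gradient.  Reciprocal space:
$w\,\sum_h |\alpha F_{calc} - F_{obs}|^2 / \sum_h |F_{obs}|^2$ over
coefficients to the resolution cutoff, with $\alpha$ the least-squares
amplitude scale (exact-gradient by the envelope theorem) and the gradient
back-propagated through the Gaussian rasterizer.  Because the quadratic
loss asks the model to explain *all* density, refining a partial model
against a map containing additional components pulls it toward the
unexplained features — that failure mode is intrinsic and is exactly what
`refine_masked_region()` exists for: the map is masked around the model
(cosine soft edge) before reciprocal refinement, so individual components
of a larger reconstruction can be refined in isolation.

The optimizer is deliberately first order: each cycle re-selects
multi-target alternatives, then takes up to 15 gradient steps, each capped
at a maximum atom shift (0.5 A) and backtracked so the total never
increases; nonbonded quartic repulsion below 2.2 A (excluding 1-2/1-3
pairs, including symmetry mates from `expand_symmetry()` when a point
group is supplied) keeps contacts physical.  The density gradient is
auto-balanced once, at the first cycle, against the RMS of the *covalent*
geometry gradient (not the total: balancing against a total that includes
the external restraints would silently cancel their effect), and the user
weight multiplies that balanced contribution — `weight = 1` means pull
comparable to the stereochemistry, larger values favour the data,
`weight = 0` is geometry-only regularization.  The scale is fixed after
cycle 1 so there is one well-defined objective whose accepted steps are
monotone.  This replaces resolution-dependent maximum-likelihood
weighting with one scalar, a documented simplification: the testable
substance here is the construction of the target (restraints, robust
weighting, multi-target selection, masking, symmetry), not the engine.

## Half-map cross-validation

`cross_validate()` shakes the model (default 0.5 A expected RMSD, removing
memory of previous refinement), refines against half map 1 only, and
reports the model-map FSC against half map 1 (`FSC_work`) and against the
independent half map 2 (`FSC_test`), after placing the halves on a common
amplitude scale.  Gap statistics (max and mean of work − test) are
computed over shells up to the refinement cutoff plus the cutoff shell.
Large gaps mean the model absorbed noise specific to the working half; a
sharp drop of `FSC_work` just beyond the refinement cutoff is the same
pathology seen from the other side — predictive power lost exactly where
fitting stopped.  In real-space runs the cutoff is applied by low-passing
the working map, which is what a resolution limit means for a local
density fit.

The overfitting experiment mirrors the published demonstration and its
design matters.  Overfitting requires the model to have enough freedom
relative to the data, so the experiment uses a small model in a tight box
(18 residues, 26³ voxels: roughly one parameter per two observed
coefficients inside the cutoff) with noise at the signal level; in a
generously padded box a first-order optimizer simply cannot absorb noise
and the paired arms are indistinguishable.  The restrained arm refines
with jelly + hydrogen-bond restraints at moderate data weight and a
robust scale raised to 15 so the restraints stay active at shake-scale
deviations; the overfitted arm removes external restraints, weakens the
covalent sigmas several-fold and overweights the data — the
"restraint weights near zero, heavy data weight" limit.  The overfitted
arm then shows both hallmarks: a strictly larger work/test gap and a
sharp `FSC_work` drop past the cutoff.

## Problem sizes and determinism

All experiments run on generated fixtures: 32³–64³ boxes at 1 A voxels,
15–60-residue models, 10-seed repetition for success-rate experiments.
These sizes were chosen so the full suite exercises every claim at desk
scale; the algorithms contain nothing that depends on box size beyond FFT
cost.  Every stochastic step takes an explicit integer seed, RNG state is
restored after use, and quasi-uniform orientation sets are deterministic,
so identical inputs give bit-identical outputs.

## Known limitations

No CTF or colored-noise simulation; orthogonal voxel axes only (no
crystallographic symmetry); no B-factor or occupancy refinement; no
beta-strand search; the first-order optimizer needs more cycles than a
second-order engine would and relies on the per-cycle shift cap for
stability; trilinear scoring carries a sub-voxel lattice bias that puts
rigid-body optima ~0.3 A from generating poses on 1 A grids.
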