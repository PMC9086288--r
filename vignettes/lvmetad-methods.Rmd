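---
title: "Localized-volume well-tempered metadynamics on model potentials: methods and design"
author: "lvmetad"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Localized-volume well-tempered metadynamics on model potentials: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem this package addresses

Estimating the binding free energy of a small ligand on a *shallow, solvent-exposed*
protein surface pocket is hard for plain molecular dynamics: binding and unbinding
are rare events, and the bound state is an ensemble of loosely related poses rather
than a single well-defined minimum.  Localized-volume well-tempered metadynamics
(LV-MetaD) attacks this by (i) restraining the ligand to a localized volume around
the putative site — large enough to contain the bound poses, their neighbourhood
and a fully solvated shell — and (ii) depositing a history-dependent repulsive
bias on three collective variables (CVs) adapted to that volume, so the ligand
diffuses reversibly between bound and unbound states within the volume.

`lvmetad` implements the full LV-MetaD workflow at desk scale: a Langevin
sampler on toy host–guest potentials stands in for the solvated all-atom system,
while the CV geometry, the bias, the reweighting and the free-energy analysis are
the real method.  Because the file formats follow the PLUMED COLVAR/HILLS/FES
conventions, the analysis half (`reweight`, `fes`, `basins`, `deltag`) can be
applied unchanged to externally produced all-atom runs.

## Collective variables of the parabolic-solid volume

The restraint volume is a solid of revolution about the host–ligand axis
(aligned to +x by convention) whose boundary is the paraboloid
$r_\perp^2 = k\,(a - a_0)$, with $a$ the axial coordinate measured from the
volume origin and $r_\perp$ the transverse distance.  The CVs are

* $\rho$ — the distance between the guest and host (reference-group) centres of
  mass, in Å;
* $\tau = r_\perp / \sqrt{k\,(a - a_0)}$ — the dimensionless transverse
  coordinate: $\tau = 0$ on the axis, $\tau = 1$ on the paraboloid surface;
* $\theta$ — the azimuth of the transverse projection about the axis, measured
  from a fixed reference direction (the projection of +y, or +z when the axis is
  nearly parallel to y); periodic in $(-\pi, \pi]$.

Two points were genuinely open and are resolved here as package design choices:

* **The functional form of $\tau$.**  The method literature names $\tau$ as "the
  parameter that defines the parabolic-solid shape" without printing a formula.
  We define $\tau = r_\perp/\sqrt{k (a - a_0)}$, which is dimensionless, equals 1
  exactly on the volume boundary, and fluctuates at the O(0.1) scale consistent
  with the customary Gaussian width of 0.04 used on this variable in production
  runs.  This is an interpretation, flagged as such.
* **The plane of $\theta$.**  Descriptions of the method mention the azimuth of
  the projection "on the x-y plane" even though the volume axis is x.  For a
  paraboloid about x the physically meaningful azimuth is measured in the plane
  *perpendicular* to the axis; that is what we implement.

On the axis $\theta$ is degenerate: we set $\theta = 0$ there (a measure-zero
tie-break) and regularise $\partial\theta/\partial r$ by flooring the transverse
distance at 0.01 Å, capping the gradient magnitude at 100 Å$^{-1}$ so bias
forces never blow up when the guest crosses the axis.

The walls are half-harmonic in the CVs, $k_w(\rho-\rho_{max})_+^2 +
k_w(\tau-\tau_{max})_+^2$, plus an axial floor at $a_{min} > a_0$ that keeps the
paraboloid parameterisation defined.  $\theta$ is periodic and unbounded.

## The sampler

The toy systems are sampled with underdamped Langevin dynamics using the BAOAB
splitting, with the Ornstein–Uhlenbeck friction step integrated exactly:
$v \leftarrow c_1 v + \sqrt{1 - c_1^2}\,\sqrt{k_BT/m}\,\xi$, $c_1 =
e^{-\gamma_f \Delta t}$.  Units are Å, ps, amu, kcal/mol, K with
$k_B = 0.0019872041$ kcal/mol/K and the conversion 1 kcal/mol = 418.4 amu
Å$^2$/ps$^2$.  All Gaussian draws come from R's RNG, so a single `set.seed()`
makes every trajectory — and every COLVAR/HILLS file — bit-reproducible.
Thermostats, barostats, constraints and explicit solvent are deliberately out
of scope: the Langevin bath plays the role of solvent friction and noise.

## The well-tempered bias

Hills are deposited every `stride` ps at the current CV position with the
well-tempered height rule $h = h_0\, e^{-V(s,t)/k_B\Delta T}$,
$k_B\Delta T = k_B T(\gamma - 1)$, so the bias converges to
$-(1 - 1/\gamma)\,F(s)$ up to a slowly growing offset.  The production defaults
mirror the protocol used for solvated protein–ligand systems ($h_0 = 0.287$
kcal/mol, stride 1 ps, widths 1 Å / 0.04 / $\pi/8$ on $(\rho, \tau, \theta)$,
$\gamma = 20$ at 298 K).  Three implementation choices worth recording:

* **$\theta$ hills are periodic.**  An azimuth about an axis is periodic by
  construction; the hill kernel wraps $\Delta\theta$ into $(-\pi,\pi]$.
* **Direct summation.**  The bias and its gradient are evaluated by direct
  summation over the deposited hills (with an $e^{-34}$ tail cutoff), in
  compiled code.  No interpolation cache is used: at toy problem sizes direct
  summation is affordable and exact, which keeps the bias force identically
  equal to $-\nabla V$ (verified against finite differences at $10^{-6}$
  relative tolerance).
* **Deposition is confined to the volume.**  While the walker is beyond the
  $\rho$ or $\tau$ wall no hill is dropped.  Otherwise the accumulating bias
  partially compensates the wall and softens it by a factor approaching
  $\gamma$, letting the walker leak far outside the nominal volume.  With
  confinement the walls keep their nominal stiffness and the harmonic tail
  bound on wall excursions holds.

In 1D mode (a `model_potential` of dimension 1) the CVs collapse to $\rho$
alone, no volume restraint is applied (the quartic is confining), and the whole
machinery becomes analytically checkable.

## Reweighting and the free-energy map

Frames are reweighted with the time-dependent bias-offset estimator
$$c(t) = \frac{1}{\beta}\ln\frac{\sum_s e^{\beta\gamma V(s,t)/(\gamma-1)}}
{\sum_s e^{\beta V(s,t)/(\gamma-1)}},\qquad
w_i \propto e^{\beta\,(V(s_i,t_i) - c(t_i))},$$
with $V(s,t)$ containing hills deposited up to and including $t$ (matching the
run loop, which writes a frame at a hill time with that hill already present).
The sums run over a uniform grid of the *interior* of the restraint volume —
cells beyond the walls carry wall energy the (confined) bias never compensates
and would distort the estimator — with at least 4 cells per smallest hill
width per dimension.  The default reweighting window is the final 2/13 of the
run, mirroring the convention of reweighting the last 100 ns of a 650 ns
production trajectory; the toy fixtures set explicit windows instead.

The free energy is projected on (d, N): d is the guest distance to a
configurable reference group in nm (whole-host COM by default, a specific
sub-site such as a metal-cluster analogue when requested — both conventions
occur in practice and the package supports either), and N is the
hydrogen-bond/salt-bridge count from the rational switching function
$$s(r) = \frac{1 - ((r-d_0)/r_0)^n}{1 - ((r-d_0)/r_0)^m},\qquad
n = 8,\; m = 12,\; d_0 = 0,\; r_0 = 2.5\ \text{Å},$$
summed over the configured donor–acceptor pairs.  The formula is 0/0 at
$r = r_0$; the analytic limit $n/m$ is substituted there, and distances below
$d_0$ clamp to $s = 1$.  Which atom pairs define N is configuration input: the
toy systems use the guest against the polar host sites; for real structures
the user supplies the pairs.

Cell errors come from a block analysis: the window is split into contiguous
blocks (default 5 — a conventional choice; the block count is not critical
once errors plateau, which the tests check), each block's weights are
renormalised, and the cell error is the block-mass-weighted standard error of
the per-block free energies.  Cells sampled by fewer than two blocks are
flagged, not zeroed.

Basins are detected by steepest-descent watershed on the (d, N) grid
(8-neighbourhood, ties toward the lower linear index): local minima within
`depth_cutoff` of the global minimum seed basins, and shallower catchments are
merged across their lowest boundary saddle.  Basins are labelled by Roman
numerals in order of increasing minimum.  Independent of the watershed,
`assign_basin()` classifies (d, N) points against explicit rectangular
windows, e.g. the published furosemide–mitoNEET basin windows shipped in
`furosemide_basin_windows()`.

The binding free energy is $\Delta G = -k_BT\ln(W_{bound}/W_{unbound})$ over
two disjoint regions of the reweighted ensemble, with a block standard error of
the same ratio.  An optional standard-state term $k_BT\ln(V_{unbound}/V^0)$
with $V^0 = 1660$ Å$^3$ is available but **off by default**: whether a quoted
unbinding free energy includes the volume correction is often unstated, so the
package reports both numbers when asked.  $V_{unbound}$ is the geometric volume
of the unbound shell inside the restraint, computed by grid quadrature.

## Toy fixtures: what they emulate and what they do not

The fixture registry freezes two systems.

**1D double well** (barrier 5 kT, asymmetry 1 kT, minima 4 Å apart, 298 K):
the minimal system with a rare-event barrier and an analytically known answer —
for 1D the free-energy profile *is* the potential, and well-to-well $\Delta F$
comes from deterministic quadrature.  The toy metadynamics settings
($h_0 = 0.06$ kcal/mol, $\sigma = 0.2$ Å, $\gamma = 10$, 1 ps stride, 8 ns runs
with a 3 ns window, $\Delta t = 0.01$ ps, friction 3 ps$^{-1}$, mass 40 amu)
are scaled to the ~3 kcal/mol toy barrier rather than taken from the all-atom
protocol: hills narrow against the well width ($\sqrt{k_BT/U''} \approx 0.3$ Å)
keep the $O(\sigma^2 F'')$ kernel-width bias of the converged profile small,
and late-stage heights an order of magnitude below kT keep the residual ripple
of $V(s, t_{end})$ well inside a half-kT band.

**3D host–guest pocket**: one apolar site (3.0 kcal/mol, range 1.6 Å)
flanked by two polar sites (1.0 kcal/mol, range 1.2 Å) near the apex of a
parabolic volume ($k = 2.5$ Å, $a_0 = -1$ Å, $\rho_{max} = 9$ Å,
$\tau_{max} = 1.2$, $k_w = 20$ kcal/mol, axial floor 0.5 Å), guest mass 50 amu,
friction 2 ps$^{-1}$, $\Delta t = 5$ fs; metadynamics at $h_0 = 0.3$ kcal/mol,
widths (0.4 Å, 0.1, $\pi/6$), $\gamma = 10$, 12 ns with a 6 ns window (the
bound/unbound weight ratio drifts on nanosecond timescales as the bias
refines, so the window and block length are chosen to dominate that drift
time — shorter windows make the block error an underestimate).  The
bound region is $\rho < 4$ Å; the "solvated" shell is $7 \le \rho \le 8.5$ Å,
where the pocket interaction is negligible.  The quadrature oracle integrates
the *restrained* potential (pocket plus walls) over the same two regions, so
simulation and reference measure exactly the same quantity.  All magnitudes
are package choices — the real system suggests no toy analogue.  The pocket is
deliberately *shallow and wide* (a free-energy range of a few kcal/mol inside
the volume): reweighting weights must undo the bias-flattened ensemble, so
their dispersion grows exponentially with the free-energy range, and a deep
narrow pocket would leave the weighted averages dominated by a handful of
frames at desk-scale run lengths.  The resulting bound-vs-shell free-energy
difference is still a non-trivial ~2 kcal/mol.

What passing on these fixtures shows: the CV geometry, bias accumulation,
height recursion, reweighting, block errors and region free energies are
implemented correctly and consistently, at the statistical precision a desk-
scale run affords.  What it does not show: force-field realism, solvent
granularity, pose heterogeneity of a real ligand, or convergence behaviour at
the 650 ns all-atom scale — none of which the toy potentials model.

## Numerical choices and degenerate inputs

* Quadrature: midpoint rule on uniform grids; the reported discretization
  error is a Richardson estimate from recomputation at doubled spacing.
  Halving the spacing moves fixture free energies by well under 0.01 kcal/mol.
* $c(t)$ sums are stabilised by max-subtraction; grid spacing must resolve
  every hill width (at least 4 cells per $\sigma$), enforced with an error.
* Hill times must strictly increase (`sequencing error` otherwise); frames
  must be strictly time-ordered; ragged or headerless COLVAR files fail with
  the offending line number.
* Non-finite forces or positions abort a run naming the step index and the
  last recorded frame.
* Float formatting is fixed (%.6f for CVs, %.10g for energies), making
  identical configs produce byte-identical files — determinism is tested at
  the file level.
* Watershed ties break toward the lower linear cell index; unsampled cells
  are NA everywhere, never silently zero.

## Problem sizes

The shipped tests and the acceptance analysis run the 1D fixture at 8 ns
(three seeds) and the 3D fixture at 12 ns (one seed per analysis), with
quadrature references on grids of ~10^3 (1D) and ~2×10^6 (3D) points.  These
sizes were chosen so the whole suite completes in minutes on one core while
every tolerance above retains a safety margin; they are package choices, and
all of them can be scaled up through the fixture arguments.

## Known limitations

* The toy host is rigid and implicit-solvent; N counts site contacts, not
  geometric hydrogen bonds (no angular criterion).
* `invert_cvs` assumes the host reference point lies on or behind the
  paraboloid apex so the ray-sphere intersection is unique; exotic geometries
  violating this raise a geometry error rather than guessing.
* The Tiwary–Parrinello estimator assumes a quasi-static bias; the earliest,
  rapidly filling part of a run should not be inside the reweighting window.
* Leader clustering of contact fingerprints depends on frame order (by
  design, for determinism); it is a pose-bookkeeping tool, not a general
  clustering method.
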