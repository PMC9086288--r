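# lvmetad

Localized-volume well-tempered metadynamics (LV-MetaD) for ligand binding on
shallow protein-surface pockets, as a desk-scale R toolkit: a Langevin
simulator on model host–guest potentials plus the full analysis chain —
Tiwary–Parrinello reweighting, free-energy maps over (distance, H-bond count)
with block-average errors, watershed basin detection, and standard-state
binding free energies.  File formats follow the PLUMED COLVAR/HILLS/FES
conventions, so the analysis half also applies to externally produced
all-atom runs.

**Who it is for.**  Method developers and students who want a transparent,
fully testable implementation of the LV-MetaD workflow, and practitioners who
need the *analysis* half (reweighting → FES → basins → ΔG) for PLUMED-style
output of production runs on systems like the mitoNEET–furosemide surface
complex.

## The method

The ligand is restrained to a parabolic solid about the host–ligand axis
(surface `r_perp^2 = k (a − a0)`), and a well-tempered bias is deposited on
three collective variables:

* `rho` — guest–host COM distance (Å),
* `tau = r_perp / sqrt(k (a − a0))` — dimensionless transverse coordinate
  (`tau = 1` on the paraboloid),
* `theta` — azimuth about the axis (rad, periodic).

Hills of initial height `h0` are dropped every `stride` ps with the
well-tempered rule `h = h0 exp(−V(s,t)/kB ΔT)`, `kB ΔT = kB T (γ−1)`
(production defaults `h0 = 0.287` kcal/mol, widths `(1 Å, 0.04, π/8)`,
`γ = 20`, stride 1 ps at 298 K).  Frames are reweighted with

```
c(t) = (1/β) ln [ Σ_s exp(βγV(s,t)/(γ−1)) / Σ_s exp(βV(s,t)/(γ−1)) ]
w_i  ∝ exp(β (V(s_i, t_i) − c(t_i)))
```

and the free energy is projected on `(d, N)`: `d` the distance to a
configurable reference group (nm) and `N = Σ s(r_ij)` the H-bond/salt-bridge
count with the rational switching function

```
s(r) = (1 − ((r − d0)/r0)^n) / (1 − ((r − d0)/r0)^m),   n = 8, m = 12, d0 = 0, r0 = 2.5 Å
```

(`s(r0) = n/m` by the analytic limit).  `ΔG = −kBT ln(W_bound/W_unbound)`
with block-analysis errors; every quantity has an independent brute-force
quadrature oracle on the toy systems.

## Worked example

The frozen 3D fixture — a shallow pocket (one apolar + two polar sites)
inside a parabolic volume — run for 12 ns with hills every 1 ps, reweighting
the final 6 ns (about a minute on one core):

```r
library(lvmetad)

fx  <- host_guest_fixture(seed = 1)          # frozen study conditions
run <- run_lv_metad(fx$system, fx$vol, fx$metad, fx$langevin,
                    observables = fx$observables, out_stride = fx$out_stride)
an  <- analyze_host_guest(run, fx)           # c(t), weights, bound-vs-shell dG
ref <- hg_reference_delta_g(fx)              # deterministic quadrature oracle

cat(sprintf("dG(sim) = %.2f +/- %.2f kcal/mol | dG(quadrature) = %.2f kcal/mol\n",
            an$delta_g, an$err, ref))

ktv <- kT(fx$temperature)
fes <- project_fes(run$colvar, an$weights, "d", "nhb",
                   x_edges = seq(0, 1.0, by = 0.025),
                   y_edges = seq(0, 2, by = 0.1), kT = ktv, n_blocks = 5)
find_basins(fes, depth_cutoff = 1.5)$basins[, c("label", "F_min", "x_lo", "x_hi")]
```

```
dG(sim) = -1.82 +/- 0.18 kcal/mol | dG(quadrature) = -2.01 kcal/mol
  label F_min x_lo  x_hi
1     I  0.00 0.00 0.425
2    II  1.38 0.25 0.800
```

The simulated binding free energy agrees with the quadrature reference within
about one block standard error; the (d, N) map resolves the bound basin (I,
around the pocket, d below ~0.4 nm) from the shallow solvated shell (II,
1.4 kcal/mol higher).  A frame at
`d = 0.85` nm with `N = 7` contacts classifies into the published bound-state
window of the furosemide–mitoNEET map:

```r
assign_basin(0.85, 7, furosemide_basin_windows())
#> [1] "I"
```

## Command line

A thin Rscript wrapper (`inst/cli/lvmetad.R`) exposes the pipeline:

```sh
Rscript inst/cli/lvmetad.R simulate --config inst/extdata/host_guest_demo.yaml --prefix run
Rscript inst/cli/lvmetad.R reweight --colvar run.colvar --hills run.hills --out w.dat
Rscript inst/cli/lvmetad.R fes      --colvar run.colvar --weights w.dat --out run.fes
Rscript inst/cli/lvmetad.R basins   --fes run.fes --out basins.json
Rscript inst/cli/lvmetad.R deltag   --colvar run.colvar --weights w.dat \
        --bound rho:0:4 --unbound rho:7:8.5 --out dg.json
Rscript inst/cli/lvmetad.R demo
```

`simulate` is byte-reproducible for a fixed seed; every output file carries a
provenance header (config hash, seed, version).

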