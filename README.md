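# bluemoonti

Blue-moon constrained sampling and thermodynamic integration for a toy
model of the spliceosome branching active site.

## The problem

In the first step of splicing (branching), the 2'-OH of the branch-point
adenosine attacks the scissile phosphate of the 5'-splice site while the
G(-1)-O3' leaves, in an active site organised by two catalytic Mg2+ ions
(M1, M2) and a monovalent ion (K1) held by U6 snRNA oxygens (G52, A59,
G60, U80). Replacing K+ at the K1 site by Li+ raises the rate-limiting
activation free energy and weakens the driving force of the reaction.
Studies of this system compute the free-energy profile along the
reaction coordinate

    xi = d2 - d1,

the breaking-bond length (G(-1)-O3'--P, d2) minus the forming-bond
length (BPA-O2'--P, d1), by *blue-moon* sampling: dynamics constrained
at fixed xi via a SHAKE-type solver, the mean of the constraint's
Lagrange multiplier lambda estimating the free-energy gradient,

    dF/dxi = < Z^-1/2 (lambda + kB T kappa) > / < Z^-1/2 >,
    Z = sum_i m_i^-1 |d sigma/d r_i|^2,

with kappa the geometric (Fixman) term, followed by trapezoid
integration of the mean force over a 16-window schedule (xi = -1.4 to
1.6 A in 0.2 A steps) with errors propagated in quadrature.

This package re-implements that free-energy machinery — the constrained
Langevin integrator, the multiplier bookkeeping, the metric correction,
trapezoid integration with error propagation, and profile-feature
extraction (R, TS1, I, TS2, P) — together with the trajectory
observables used around it (hydrogen-bond frequency under the
below-2.2 A / 180 +- 50 degree criteria, proton-transfer detection,
Li+ binding-pose classification, relative mean square fluctuation, and
a bare-Coulomb electric-field surrogate). Instead of a QM/MM
Hamiltonian it runs on a small analytic active-site model whose exact
free-energy profile is available by one-dimensional quadrature, so
every stage of the pipeline is verifiable against a closed-form oracle.
The surface is calibrated so that the exact profile carries the
reported profile features for each ion.

## Worked example

```r
library(bluemoonti)

params <- calibrated_pes("K")       # deterministic, ~25 s
model  <- build_active_site("K")
run <- run_profile_pipeline(model, params, master_seeds = c(101, 102, 103),
                            window_ps = 12, equil_ps = 2)
run$features
```

```
Profile features (two_ts)
 state       xi      F sigma_F
     R -1.40000  0.000  0.0000
   TS1 -0.40068 13.584  0.1380
     I  0.01397 11.179  0.1668
   TS2  0.55808 13.220  0.1996
     P  1.40273 -4.162  0.2404
     name  value  sigma
 dF_R_TS1 13.584 0.1380
 dF_I_TS2  2.041 0.2601
   dF_R_P -4.162 0.2404
```

The pipeline samples 16 constrained windows (20,000 retained steps each,
three replicate seeds), averages the Lagrange multipliers after the
equilibration discard, applies the blue-moon correction (below 0.3% of
the mean force on every window where the force is substantial),
integrates with the trapezoid rule and extracts the features: a
13.6 kcal/mol rate-limiting barrier to the phosphorane intermediate, a
~2 kcal/mol second barrier, and a -4.2 kcal/mol reaction free energy —
with the lithium-calibrated surface the same protocol yields 16.2, ~3.2
and -2.3 kcal/mol.

The study itself is organised as numbered drivers:

```sh
Rscript analysis/01_build_model.R          # active-site geometry tables
Rscript analysis/02_calibrate_surface.R    # calibrated surfaces + oracle profiles
Rscript analysis/03_sample_profiles.R      # constrained sampling -> profiles
Rscript analysis/04_geometry_observables.R # hb1, PT1, poses, RMSF, fields
Rscript analysis/05_report.R               # side-by-side K+/Li+ report
```

Each writes TSV tables (with `#` metadata headers recording the
configuration hash and seeds) under `results/`.

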