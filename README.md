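# linkerelast

Elastic properties of the kinesin neck linker from network modes and
pulling ensembles.

The neck linker is the ~14–18 residue peptide that couples a kinesin motor
head to the coiled-coil neck; its stiffness and its order–disorder
transition set how the two heads communicate force while walking on a
microtubule. This package is an analysis workflow for that mechanics,
aimed at computational biophysicists. It has three parts:

1. **Dynamic domains** (`enm`/`domains` functions): approximate normal-mode
   analysis of a C-alpha elastic network with distance-attenuated pair
   force constants `k(R0) = C exp(-|R0|^2 / r0^2)`, per-residue deformation
   energies
   `E_i = 1/2 sum_j k(R0_ij) |(d_i - d_j)·R0_ij|^2 / |R0_ij|^2`,
   and a domain decomposition that clusters 1.2 nm cubes by rigid-body
   motion similarity `S_ij = 3|Ωi+Ωj|/|Ωi−Ωj| + |Ti+Tj|/|Ti−Tj|` at
   coarseness `c`.
2. **Pulling ensembles** (`chain_*`/`run_*` functions): a coarse-grained
   (one bead per residue) overdamped Langevin simulator that equilibrates a
   peptide, stretches it with a constant force conjugate to the end-to-end
   distance for 1 ps, then relaxes it force-off — for the wild-type linker
   stand-in, its Asn→Ala / Lys→Ala / Pro→Ala mutants and a poly-alanine
   reference, at forces 130–1300 kJ/mol/nm.
3. **Fluctuation-relation free energies** (`work_*`/`*_estimate`
   functions): per-trajectory work `W = F Δd`, Gaussian moment fits, the
   Crooks-style crossing point of forward/reverse work distributions, the
   Jarzynski average `ΔG = −kBT ln⟨e^{−βW}⟩` (and its Gaussian closed form
   `μ − σ²/2`), occupancy-histogram ΔG, bootstrap confidence intervals,
   and quadratic stiffness fits of ΔG versus fractional extension, plus
   the worm-like-chain force–extension law.

The methods vignette (`vignettes/linker-elasticity.Rmd`) documents the
models, parameter choices and limitations.

## Worked example

Recompute the crossing-point free energies from the bundled reference
work-distribution moments (all-atom pulling ensembles of the five linker
variants at F = 1300 kJ/mol/nm):

```r
library(linkerelast)
Rscript analysis/04_reference_crossings.R
#>        peptide delta_g_reported dg_recomputed rel_diff_pct
#>    neck_linker           1462.4       1469.37     0.476538
#>       ala_only            882.0        883.24     0.140976
#>  no_asparagine            690.5        691.90     0.203339
#>      no_lysine            752.8        757.92     0.679922
#>     no_proline            997.6        998.52     0.092096
```

Each row intersects the two fitted Gaussians (stretch and relax work, in
kBT) and lands within 0.7% of the reported ΔG — within 0.3% for the rows
with narrow relax distributions; the residual is rounding of the printed
moments. The wild-type linker both absorbs more work when stretched and
stores a larger stretch/relax free-energy difference than any variant.

Run the scaled coarse-grained study (5 sequences × 5 forces, 200
trajectories per cell, ~1 min):

```r
Rscript analysis/03_pull_study.R
#>  stiffness fits (dG = a f^2 + b, kBT):
#>       sequence quadratic_coef intercept r_squared
#>    neck_linker           8997    -2.321    0.9985
#>  no_asparagine          17233    -2.523    0.9964
#>      no_lysine          10846    -1.065    0.9984
#>     no_proline           8811    -4.086    0.9946
#>       ala_only           9289    -1.338    0.9992
```

Every chain behaves as an effective harmonic spring in its fractional
extension (R² > 0.99), with ΔG rising monotonically with force; the
coefficients are properties of the coarse-grained model (mutant-vs-wild
contrasts are qualitative, not calibrated to all-atom values — see the
vignette). `analysis/01_domains.R` runs the domain stage (supply a motor
PDB for the full-size analysis), `02_equilibrate.R` the equilibration
summaries, `05_stiffness_wlc.R` the stiffness refits and a worm-like-chain
force table; outputs land under `results/`.

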