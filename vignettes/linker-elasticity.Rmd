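---
title: "Methods: network domains, pulling ensembles and fluctuation-relation free energies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network domains, pulling ensembles and fluctuation-relation free energies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(linkerelast)
```

The kinesin neck linker is a short (~14–18 residue) peptide joining a motor
head to the coiled-coil neck; its order–disorder transition and effective
spring stiffness underlie the motor's force generation. This package
implements the three stages of an analysis of that stiffness: (i) a
dynamic-domain decomposition of a motor structure from elastic-network
normal modes, which places the linker in a soft region between rigid heads;
(ii) ensembles of constant-force stretching and force-off relaxation
trajectories of the isolated linker peptide and its alanine-substitution
variants, generated here by a coarse-grained Langevin simulator; and (iii)
fluctuation-relation estimators that turn the per-trajectory work samples
into stretch/relax free-energy differences and, across forces, into an
effective quadratic stiffness.

## 1. Elastic network model and dynamic domains

Each residue is a node at its C-alpha position. Every pair interacts
through a harmonic spring in the pair distance with force constant

$$k(R^{0}_{ij}) = C \exp\left(-|R^{0}_{ij}|^2 / r_0^2\right),$$

which decays fast enough that candidate domains do not interact through the
network. The Hessian of $E=\sum_{ij}\tfrac12 k(R^0_{ij})(|R_{ij}|-|R^0_{ij}|)^2$
at the reference structure is diagonalized; the six rigid-body zero modes
are removed and each remaining mode $d$ is scaled to
$\sum_i |d_i|^2 = f N$ with $f = 1\,\mathrm{nm}^2$. The deformation energy
of residue $i$ under a displacement field $d$,

$$E_i = \tfrac12 \sum_j k(R^0_{ij})\,
  \frac{|(d_i-d_j)\cdot R^0_{ij}|^2}{|R^0_{ij}|^2},$$

is the harmonic strain of its bonds; it vanishes identically for uniform
translations and infinitesimal rotations (asserted to 1e-8 kJ/mol in the
test suite), so low values mark internally rigid regions.

Modes are admitted while their residue-averaged deformation energy stays
strictly below a threshold (default 400 kJ/mol, the customary starting
point for separating rigid from flexible regions). The structure is then
cut into cubes of 1.2 nm side anchored at the bounding-box minimum
(half-open bins, so the partition is deterministic); cubes with at least 3
atoms and mean energy strictly below the threshold get a rigid-body fit
$d_i = T + \Omega \times R_i$ by linear least squares about the cube
centroid, and cube pairs are scored with

$$S_{ij} = 3\,\frac{|\Omega_i+\Omega_j|}{|\Omega_i-\Omega_j|}
  + \frac{|T_i+T_j|}{|T_i-T_j|},$$

rotations weighted triple because they discriminate domains more reliably.
$S$ is singular for identical motions, so each quotient is capped at $10^6$
when its denominator falls below $10^{-12}$; clustering depends only on the
ordering of similarities, not their magnitude. Cube pairs with
$S > S^{\max}/c$ (strict, coarseness $c > 1$, default 10) are linked and
the connected components of that graph are the dynamic domains. We read
the cluster rule ("all cubes contributing to the relation compose one
cluster") as transitive closure, i.e. connected components; a seeded
single-linkage growth would give the same partition whenever the similarity
graph is transitively closed, and the package's property tests only rely on
behaviour both readings share (domain count non-increasing in $c$, a single
all-encompassing domain at large $c$).

Two parameter readings deserve a note.

* **The force-constant scale $C$.** The source value is printed as
  "47.400" kJ/mol/nm^2 in a locale where the period is a thousands
  separator. A scale of 47.4 would put every deformation energy three
  orders of magnitude below the 400 kJ/mol threshold and make threshold
  mode selection vacuous; only $C = 47\,400$ is consistent with per-mode
  average energies in the hundreds of kJ/mol. The package default is
  therefore `C = 47400`, and all formulas are linear in $C$, so any other
  convention rescales energies and thresholds together.
* **The decay length $r_0$.** Not fixed by the method's description. We
  default to 0.3 nm, the classic exponential-decay scale for C-alpha
  networks, expose it everywhere, and provide `enm_benchmark()` which
  re-runs the mode analysis over $r_0 \in \{0.3, 0.5, 0.7\}$ nm and reports
  the mode-energy ladder, the number of threshold-selected modes and the
  below-threshold residue fraction (see `analysis/01_domains.R`).

`read_ca_structure()` extracts one C-alpha per residue via bio3d, resolving
alternate locations to the highest-occupancy conformer and recording
missing residues as gaps (never interpolating); degenerate geometries
(collinear structures, disconnected networks) are errors, not silent
results.

## 2. The coarse-grained pulling simulator

The reference protocol for the pulling stage is all-atom steered MD in
explicit solvent. This package deliberately replaces that machinery with a
one-bead-per-residue overdamped Langevin model, which is the right level
for testing the estimator pipeline end to end: at the scale of the motor,
viscous forces dominate and overdamped dynamics is a valid approximation,
and the statistical structure of the data (near-Gaussian end-to-end
fluctuations in an energy well, near-constant-rate extension under strong
constant force, approximately Gaussian forward/reverse work distributions)
is reproduced. What is *not* claimed is quantitative agreement of
sequence-specific free energies with all-atom values; only qualitative
contrasts between the wild type and its mutants are meaningful here.

The potential is

$$E = \sum_{\text{bonds}} \tfrac{k_b}{2}(b_i-b_0)^2
    + \sum_{\text{angles}} \tfrac{k_{\theta,i}}{2}(\theta_i-\theta_{0,i})^2
    + \sum_{|i-j|\ge 3}\left[ 4\epsilon_{ij}\!\left(
      \frac{\sigma_{ij}^{12}}{r_{ij}^{12}}-\frac{\sigma_{ij}^6}{r_{ij}^6}
      \right) + \frac{k_e q_i q_j}{r_{ij}} e^{-r_{ij}/\lambda_D} \right]$$

with parameters per residue (see `default_residue_params()`):

| parameter | default | rationale |
|---|---|---|
| bond length $b_0$ | 0.38 nm | C-alpha virtual bond |
| bond stiffness $k_b$ | 1e4 kJ/mol/nm^2 | stiff but stable at dt = 2 fs |
| angle $k_\theta$, $\theta_0$ | 25 kJ/mol/rad^2, 2.12 rad | flexible backbone; Pro: 75, 1.85 rad (stiff kink) |
| $\epsilon_i$ | 0.2–1.2 kJ/mol | linear map of Kyte–Doolittle hydropathy |
| $\sigma_i$ | $0.5\,(m_i/110)^{1/3}$ nm | bead size from residue volume |
| charges | K, R: +1; D, E: −1 | net side-chain charge, screened Coulomb with $\lambda_D = 1$ nm, $\epsilon_r = 80$ |
| H-bond term | N, Q: 0.8; S, T, Y: 0.3 kJ/mol | polar side-chain attraction added to $\epsilon_{ij}$ |
| friction $\gamma$ | 50 ps^-1 | solvent-dominated bead friction |

The integrator is Euler–Maruyama,
$x \leftarrow x + F\,\mathrm{d}t/(m\gamma) + \sqrt{2 k_B T \mathrm{d}t /(m\gamma)}\,\eta$,
at $\mathrm{d}t = 2\times10^{-3}$ ps (matching the reference protocol's
step). The discretization biases stationary variances by
$\mathcal{O}(\mathrm{d}t\,k/(m\gamma))$, below 0.5% for every interaction in
the default parameterization; the physics tests therefore compare against
exact quadrature oracles with 3-standard-error bands plus a small
discretization allowance. A divergence guard aborts with advice to reduce
`dt` if any coordinate leaves a 1e3 nm box. Forces are the exact analytic
gradient, asserted against central finite differences at 1e-6 relative.

The protocol mirrors the reference workflow: equilibrate (default 6 ns;
the bundled analysis scripts use 1–2 ns, which these chains need to relax
from the extended start, and state that choice as the desk-scale problem
size); select the frame from the trailing 20% window whose end-to-end
distance is nearest the window mean (ties resolved to the latest frame);
run `n_ensemble` stretches of 1 ps at constant force applied along the
instantaneous first-to-last bead axis; then relax each final state for 1 ps
with the force off, pairing trajectories 1:1. Ensemble defaults are the
study conditions — 1e4 trajectories per cell and forces
{130, 400, 700, 1000, 1300} kJ/mol/nm — and every trajectory's RNG seed is
a fixed function of (master seed, phase, index), so any cell or single
trajectory is reproducible in isolation, bit for bit.

The wild-type 19-mer shipped with the package is a **synthetic stand-in**:
the structural source of the linker does not print its sequence here, so
the fixture honors the documented constraints (Ile-4, Pro-8, Pro-14, at
least one Asn and one Lys) without claiming to be the biological sequence.
Mutants are derived from it programmatically (Asn→Ala, Lys→Ala, Pro→Ala),
and the reference chain is an 18-residue poly-alanine.

## 3. Work accumulation and free-energy estimators

For a constant-magnitude force conjugate to the end-to-end distance $d$,
the accumulated work telescopes to $W = F\,(d_\text{final} -
d_\text{initial})$ during the stretch. During relaxation the force is off
in the dynamics, yet the analysis needs a reverse work distribution; we
define it with the **same** $F$ over the reversed displacement,
$W = F\,(d_\text{initial} - d_\text{final})$ — the conjugate-protocol
reading of the forward/reverse pair. This is a modelling choice, flagged
here deliberately: with it, the two distributions sit on a common axis and
their crossing is the free-energy difference in the Crooks sense, and for
a linear test system the construction is symmetric and exactly solvable,
which is how the estimator is validated.

Estimators, all in units of $k_BT$:

* **Gaussian fits** are moment fits (sample mean, unbiased SD) — bin-free,
  so the crossing does not depend on histogramming choices.
* **Crossing point**: equality of the two fitted normal densities. Equal
  variances give the midpoint of the means exactly; unequal variances give
  a quadratic whose root between the two means is returned (the crossing
  between the peaks), with both roots exposed in an attribute. When no
  root lies between the means — heavily overlapping distributions at very
  weak force — the estimator errors rather than extrapolate, and the study
  driver records that cell as failed and continues.
* **Jarzynski**: $\Delta G = -\ln \langle e^{-W}\rangle$ with a
  log-sum-exp reduction (overflow-safe for works in the thousands of
  $k_BT$). For Gaussian work the closed form $\mu - \sigma^2/2$ is also
  provided; both are second-law-bounded by $\bar W$, asserted on every
  ensemble the suite generates.
* **Occupancy histogram**: $\Delta G_{A\to B} = -\ln (n_B/n_A)$ from visit
  counts of two configurational regions, validated against Boltzmann
  quadrature on a tilted double-well Langevin sampler.
* **Uncertainties**: percentile bootstrap over trajectory resampling
  (default 1000 replicates; the reported ± of the reference table is of
  unstated origin, so the package makes its own uncertainty convention
  explicit).

The bundled reference table (`reference_work_moments()`) carries the
all-atom stretch/relax work moments of the five variants at 1300 kJ/mol/nm
with their reported crossing free energies; recomputing the crossing from
the printed moments alone reproduces the reported values to 0.09–0.68%
(the residual is dominated by rounding of the printed inputs, and is
tightest — ≤0.3% — for the rows with the narrower relax distributions).
We read the table's ± values as ensemble standard deviations; that reading
is what makes the recomputation close to this level.

## 4. Elastic observables

* **Fractional extension** $f = (d - d_\text{relaxed}) / (L_c -
  d_\text{relaxed})$ with contour length $L_c = 0.4\,\mathrm{nm} \times
  n_\text{residues}$ — 0 at the relaxed mean, 1 at full extension.
* **Stiffness**: least squares of $\Delta G = a f^2 + b$. The linear term
  is constrained to zero because the reference analysis reports exactly a
  quadratic coefficient and an intercept per curve; a three-parameter
  variant is available behind `linear_term = TRUE`. On the scaled
  coarse-grained study the quadratic describes the data with $R^2 > 0.99$.
* **Worm-like chain**: the standard interpolation $F = (k_BT/L)\,
  [\tfrac14 (1-x/L_c)^{-2} + x/L_c - \tfrac14]$. The source prints $x/L$
  in the linear term, which is dimensionally inconsistent for an
  interpolation between the low-force and divergence regimes; the package
  implements the standard $x/L_c$ form by default and keeps the as-printed
  variant behind `as_printed = TRUE` for comparison.
* **Gaussianity** of end-to-end windows is assessed with a KS test against
  the moment-fitted normal at $\alpha = 0.01$ — the reference analysis
  fits visually; a test statistic makes the check assertable.

## 5. What the synthetic data does and does not show

The generator emulates: relaxation of an extended chain into a compact
equilibrium with near-Gaussian end-to-end fluctuations inside an energy
well (with slow well-hopping producing the non-Gaussian long-run windows
seen in the equilibration summaries); near-constant-rate extension under
strong constant force with proximal pair distances staying flat while the
pulled ends extend; and forward/reverse work ensembles that are
approximately Gaussian and well separated at strong force. It does not
contain explicit solvent, proline cis/trans isomerization kinetics,
secondary-structure formation, or any calibration to sequence-specific
all-atom energetics — so a passing suite demonstrates the correctness of
the estimators and the qualitative phenomenology, not transferability of
the coarse-grained $\Delta G$ magnitudes to real peptides.

Problem sizes used by the tests and the acceptance script — chosen as the
package's desk-scale defaults — are 1–2 ns equilibrations, 200-trajectory
ensembles for the factorial study (1e4 for the single-cell estimator
validation), and 1e6-sample closed-form checks. The full-scale study
(`analysis/03_pull_study.R 10000`) is a single argument away.

## 6. Known limitations

* The ENM benchmark against the published per-mode energies of the motor
  dimer requires the external PDB structure (id 3kin) and the exact
  network variant of the original domain-analysis tool; with $r_0$ an open
  parameter, agreement should be checked across the sweep rather than at a
  single value.
* The crossing estimator is undefined for near-identical forward/reverse
  distributions (fully reversible or near-zero-force cells); this is
  inherent to the construction, surfaces as a per-cell error, and is the
  reason the study driver tolerates failed cells.
* Euler–Maruyama is first-order; halve `dt` rather than trust tail
  quantities if you push the bond stiffness or friction far from the
  defaults.
* The stand-in sequence satisfies positional constraints only; conclusions
  specific to the biological sequence require supplying it.
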