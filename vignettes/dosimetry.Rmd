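---
title: "Methods: the intratumoral cisplatin dosimetry model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the intratumoral cisplatin dosimetry model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TumorDosim)
```

## The model and its assumptions

The package models cisplatin transport after direct injection into a
lung tumor. The tumor is a set of voxels (typically at CT resolution,
1 mm); each voxel superposes an extracellular and an intracellular
compartment. Three processes act on the extracellular concentration
$\varphi_e$: diffusion with a spatially uniform coefficient $D$,
clearance by perfusion at rate $k_f$ into a well-mixed systemic fluid
compartment $\varphi_f$ of volume $V_f$ (drained renally at rate
$k_r$), and irreversible uptake at rate $k_i$ into the intracellular
compartment $\varphi_i$, where cisplatin binds DNA and accumulates
monotonically:

$$\dot\varphi_e = D\nabla^2\varphi_e - (k_i+k_f)\,\varphi_e,\qquad
  \dot\varphi_i = k_i\,\varphi_e,\qquad
  \dot\varphi_f = \frac{k_f}{V_f}\!\int_V \varphi_e\,dV - k_r\varphi_f .$$

Because uptake is one-way and the fluid compartment does not feed back,
$\varphi_i$ has a finite asymptote. For a point injection of mass $m_j$
the asymptote is the time integral of the screened diffusion kernel, and
superposition over $N$ sites gives

$$\varphi_i(\vec r,\,t\to\infty)=
  \sum_{j=1}^{N}\frac{k_i\,m_j}{D\,|\vec r-\vec r_j|}\,
  e^{-|\vec r-\vec r_j|/L},\qquad
  L=\sqrt{\frac{D}{k_i+k_f}} .$$

`steadyStateField()` evaluates exactly this expression. Two details
matter:

* **Normalization.** The free-space Green's function of
  $D\nabla^2-(k_i+k_f)$ carries a $1/(4\pi)$ prefactor that the
  expression above omits. Which convention produced the published
  per-patient numbers is not stated, so both are exposed through
  `greens_mode`: `"paper"` (no $4\pi$, the default) and `"physical"`.
  Every classification-, slope- and ratio-level quantity in the package
  is invariant to the choice (the test suite asserts the exact $4\pi$
  scaling of minimal doses and the exact invariance of the power-law
  exponent and $R^2$); only absolute dose intercepts differ. The
  cohort-replay tests support the default: with `"paper"` the
  regenerated responding-volume percentages track the published
  per-patient values closely, while `"physical"` would shift every
  field down by over a decade.
* **Source singularity.** The kernel diverges at $r=0$. Distances are
  floored at half a voxel edge, $r_\mathrm{eff}=\max(r,h/2)$, which
  renders source voxels finite and keeps the field strictly decreasing
  away from an isolated site — a property the tests rely on.

$L\approx 0.99$ mm at the defaults. This single length scale controls
everything: a tumor responds only where some injection site is within a
few $L$, which is why distributing a fixed dose over several sites is
so much more effective than one central injection in large tumors.

## Parameters

| Parameter | Default | Units | Origin |
|---|---|---|---|
| $D$ | $2.47\times10^{-6}$ | cm²/s | empirical molecular-weight law for tissue at 37 °C |
| $k_i$ | $1.05\times10^{-4}$ | 1/s | uptake measured in head/neck and gastric carcinoma |
| $k_f$ | $1.46\times10^{-4}$ | 1/s | fit to blood cisplatin kinetics of a monitored patient |
| $V_f$ | 12200 | ml | same fit |
| $k_r$ | 0 | 1/s | not published; irrelevant to the asymptotic response path |
| $\mu$ | $-2.59$ | log10 mg/ml | Gaussian fit to 72-h IC50 of 75 NSCLC cell lines |
| $\sigma$ | 0.50 | log10 mg/ml | same fit |
| response fraction | 0.66 | — | $1-0.7^3$: RECIST 30% diameter reduction on a sphere |

Internal units are cm, s, mg, with concentrations in mg/ml (=
mg/cm³); file interfaces use mm and convert at the boundary.

## Stochastic thresholds and the response rule

IC50 heterogeneity across tumor cells is emulated by drawing an
independent apoptosis threshold $\varphi_t=10^x$,
$x\sim\mathcal N(\mu,\sigma)$, for every voxel. A draw is a
*replicate*; `predictResponse()` uses 25 replicates by default (seeds
`seed+1 … seed+25`), averages the responding-volume percentage
$V_\mathrm{response}$ across them, and classifies a responder when the
mean reaches 66% (inclusive). The published analysis does not state its
replicate handling; averaging stabilizes the small-sample noise of
single draws and is documented here as this package's convention. For
minimal doses the median over replicates is used instead, as medians
respect the exact per-replicate linearity described next.

## Minimal effective dose: an exact percentile reduction

The field is exactly linear in total dose at fixed plan geometry, so no
search over doses is needed. With the unit-dose field $\Phi(v)$ and
thresholds $\varphi_t(v)$, voxel $v$ is covered at dose
$M\ge M_v=\varphi_t(v)/\Phi(v)$, and the smallest dose covering at
least a fraction $f$ of the $N_\mathrm{vox}$ voxels is the $k$-th
smallest $M_v$ with $k=\lceil f\,N_\mathrm{vox}\rceil$. The test suite
verifies this reduction against a bisection search on the coverage
predicate to 0.1%.

## The site planner

The published work cites a prior placement algorithm that seeks the
most homogeneous distribution pattern; its details are not reproduced
there, so the planner is re-specified here as a deterministic,
auditable procedure: seed 1 is the occupied voxel nearest the mask
centroid; seeds 2…n maximize the minimum distance to the chosen set
(first-index tie-break); Lloyd iterations then alternate
nearest-site assignment with centroid snapping until a fixed point
(at most 100 rounds). Equidistant partitioning minimizes the
heterogeneity of a superposed monotone kernel; the coefficient of
variation of the unit-dose field (`homogeneityCost()`, population-SD
convention) is reported for audit, and the tests check it never
increases across Lloyd rounds and beats 50 random site pairs on a
sphere. There is no randomness anywhere in the planner, and plan
geometry is independent of dose, which the linearity of the field
makes exact. Doses are split equally (`apportionDose()`); the
published protocol gives no per-site weights.

## Sphere surrogates and what they do (not) show

Only tumor volumes are published, not segmented shapes, so the cohort
replay and the dose-law fits run on centered digital spheres
(`makeSphereMask()`): voxel-center-inside rasterization at 1 mm,
with the sub-voxel alignment of the sphere center chosen (among
center/corner per axis, deterministically) to keep the discretized
volume within 2% of the request down to 0.5 cm³.

Spheres preserve the quantities that are dominated by volume and
injection count: the regenerated binary predictions match the printed
prediction column for at least 27 of 32 patients (test-asserted), and
the power-law exponents land inside the printed confidence intervals.
They do *not* preserve shape-sensitive quantities:

* mid-range $V_\mathrm{response}$ values (e.g. the printed 57 or 72)
  depend on the true geometry and are monitored only qualitatively;
* a sphere is the most favorable geometry for a *single central*
  injection — every boundary point is equally close to the center — so
  the dose gap between one and five injections is compressed relative
  to irregular shapes. The measured order-of-magnitude saving at
  40 cm³ is about 2.6 on spheres, short of the ≥3 implied by the
  published power-law coefficients, while the five-minus-one exponent
  difference itself is reproduced almost exactly. The corresponding
  acceptance test is left failing rather than tuned, and this geometric
  argument is the package's explanation.

## Parameter sensitivity

`sensitivityAnalysis()` re-runs the cohort replay with $D$, $k_i$,
$k_f$ and $\mu$ perturbed tenfold each way. Two conventions deserve
note:

* The $\mu$ perturbation scales the *linear-scale* median IC50, i.e.
  shifts $\mu$ by $\log_{10}$(factor). Multiplying the (negative)
  log-mean itself by 0.1 would *raise* every threshold two-hundredfold
  and shift predictions toward negatives — the opposite of the
  published sensitivity row, which the linear-scale reading reproduces
  exactly (tested on the packaged cohort).
* The published analysis reports identical confusion matrices under
  all rate-constant perturbations. Under the model as stated this
  cannot hold: a tenfold change of $D$ rescales $L$ by $\sqrt{10}$ and
  collapses (or inflates) coverage for any geometry whose responding
  volume is not saturated. The package computes what the model
  actually implies — large shifts — and the corresponding acceptance
  expectation is left failing with this analysis rather than made to
  pass artificially.

## The transient solver and its numerics

`transientSimulate()` integrates the full system explicitly on a box
padded around the mask (default margin: five decay lengths), with
uniform coefficients everywhere and zero concentration on the box
faces, emulating free space. The time step obeys
$\Delta t \le 0.9\,h^2/(6D)$. Two Laplacian stencils are provided. The
textbook 7-point stencil has an anisotropic near-field error: its
lattice Green's function overshoots on-axis at two-voxel separations
regardless of resolution, which makes a per-voxel 5% comparison against
the continuum kernel unattainable. The default is therefore the
27-point stencil with face/edge/corner weights 16/36, 4/36, 1/36,
whose leading truncation error is isotropic; the stencil-comparison
test measures the difference directly, and the solver-versus-kernel
acceptance test verifies 5% agreement (0.25 mm grid, shell between two
voxel edges and three decay lengths, 24 h of simulated time).

Mass bookkeeping: with $k_r=0$ the scheme conserves
extracellular + intracellular + fluid mass up to the flux absorbed at
the Dirichlet faces. That absorbed fraction shrinks exponentially with
the margin; the conservation tests use a 10 mm margin, where closure
is within 0.5% over the full trajectory and the limiting intracellular
fraction equals $k_i/(k_i+k_f)\approx0.418$.

The solver is a verification path only — the response pipeline always
uses the asymptotic kernel, which is what the published evaluation
describes.

## Reproducibility and problem sizes

All stochastic quantities take an explicit seed, threshold fields are
reproducible bit-for-bit, and derived seeds (per patient, per volume,
per injection count) are deterministic functions of the master seed
kept inside 32-bit range. The dose-law reproduction uses the 28
packaged cohort volumes below 40 cm³ at 1 mm voxels with 25 replicates
(about 40 000 voxels for the largest sphere, a few seconds in total);
the solver-verification runs use sub-millimetre grids of roughly
10⁵ voxels and a few thousand time steps, the most expensive test at
around 20 s. These sizes are the package's chosen desk-scale defaults
and are stated here so they can be scaled up deliberately.

## Known limitations

* $D$ and $k_f$ are spatially uniform; fibrotic or necrotic regions,
  interstitial pressure and angiogenesis are not modeled.
* The mapping of a 72-h constant-exposure IC50 onto a post-bolus
  intracellular asymptote is an inherited assumption of the model.
* IC50 thresholds pool adenocarcinoma and squamous-cell lines; no
  histology-specific distributions are offered.
* $k_r$ is not published; it defaults to 0 and never influences the
  response path.
* Sphere surrogates, as discussed, compress single-versus-multi-site
  dose ratios and blur borderline responding-volume values.
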