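---
title: "Model and methods behind astroabm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods behind astroabm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(astroabm)
```

## The model

`astroabm` simulates the growth of a breast-cancer brain metastasis on a
2-D lattice in which the decisive microenvironmental actors are astrocytes.
Each site of a 300 x 300 grid (one site = 25 µm) holds exactly one of:
empty space, a tumor cell, an anti-metastatic astrocyte, a pro-metastatic
astrocyte, or an inert neutral agent. Time advances in 17-hour steps — the
interval over which an unimpeded tumor cell divides with probability 0.5,
matching a ~34 h doubling time — and a standard run is 150 steps (about 3.5
months). The run starts from a single tumor cell at the center; astrocytes
are seeded at a chosen density and spatial pattern, all anti-metastatic, and
never move or die.

Three coupled processes drive the dynamics, applied each step in a fixed
order (astrocyte sweep, tumor sweep, drug update), with agents visited in a
fresh uniformly random order within each sweep:

**1. Astrocyte reprogramming.** Every tumor cell exerts influence on
astrocytes within a 7 x 7 neighborhood, decaying with Euclidean distance
$d_i$ as a logistic kernel

$$I(d_i) = \frac{\kappa}{1 + e^{S (d_i - d)}},$$

with steepness $S = 3$ and half-maximal distance $d = 1.5$ lattice units.
An astrocyte sums these contributions and normalizes by the theoretical
maximum $I_{\max}$ — the kernel summed at unit magnitude over all 48
neighborhood sites, $I_{\max} \approx 7.23$ — giving $I_{norm} \in [0, 1]$.
Its probability of irreversibly switching to the pro-metastatic phenotype
this step is

$$P_{switch} = \frac{1}{1 + e^{-S_A (I_{norm} - \theta)}},$$

which equals 50% exactly at the conversion threshold $\theta$ and is
re-evaluated from the current neighborhood every step. The sigmoid is
followed literally: far from any tumor the switch probability is the small
leak $1/(1+e^{S_A \theta})$, not zero.

**2. Astrocyte-modulated tumor division.** A tumor cell sums the same
kernel over astrocytes in its 7 x 7 neighborhood, with anti-metastatic
neighbors contributing $-\alpha$-scaled weights and pro-metastatic
neighbors $+\beta$-scaled weights, normalizes by the same $I_{\max}$
(the tightest constant guaranteeing $I_{norm,T} \in [-1, 1]$ for
$\alpha, \beta \le 1$), and divides with probability

$$P_{div} = \frac{1}{1 + e^{-S_T I_{norm,T}}},$$

which is exactly 0.5 in an astrocyte-free neighborhood. Division requires
an empty Moore-8 neighbor; the daughter site is chosen uniformly among the
empty ones, and daughters do not act until the next step. There is no
migration, no intrinsic death, and no tumor heterogeneity.

**3. Chemotherapy.** Drug enters from the lattice boundary (Dirichlet dose
$C_b$ while dosing, zero-flux between doses), diffuses by an
alternating-direction implicit (ADI) scheme, decays by a per-step factor,
and is absorbed at tumor-occupied sites. Therapy starts once the tumor
reaches 3,000 cells — evaluated at the end of a step, with dosing beginning
the next step — and then cycles 14 dosing steps / 7 rest steps. A tumor
cell senses the effective concentration
$C_{eff} = C (1 - G_f\, N_{pro}/8)$, reduced by gap-junction contact with
pro-metastatic Moore neighbors, and dies with probability
$1/(1+e^{-k (C_{eff} - T)})$. Astrocytes and neutral agents are unaffected
by drug; division is attempted before the death draw, and death removes
only the parent.

Neutral agents exist to decouple astrocyte function from crowding: the
total non-tumor occupancy is fixed at half the grid (45,000 agents), so
changing astrocyte density only exchanges astrocytes for inert occupants.

## Parameters

| Parameter | Meaning | Range | Default |
|---|---|---|---|
| $\alpha$ (`effectAntiMet`) | anti-metastatic suppression magnitude | 0–1 | 0.15 |
| $\beta$ (`effectProMet`) | pro-metastatic promotion magnitude | 0–1 | 0.85 |
| $\theta$ (`conversionThreshold`) | normalized influence at 50% switching | 0–1 | 0.25 |
| $\kappa$ (`effectPerTumorCell`) | per-tumor-cell influence magnitude | 0–1 | 1 |
| $S_A$ (`switchSensitivity`) | switching sigmoid steepness | 8, 16, 32 | 32 |
| $S_T$ (`divisionSensitivity`) | division sigmoid steepness | 4, 8, 16 | 8 |
| $S$, $d$ | kernel steepness, half-distance | fixed | 3, 1.5 |

The kernel constants $S$ and $d$ are fixed; the six swept parameters above
are the sensitivity-analysis space (`sobol_parameter_sets()`).

### How the default regime was chosen

The reference experiments this simulator re-creates were run under a fixed
"pro-metastatic" baseline whose exact values are not public. The defaults
here were therefore calibrated once against the qualitative constraints the
reported results impose, and then frozen:

* tumors with switching disabled still grow to thousands of cells, close
  to astrocyte-free growth — so $\alpha$ must be mild (0.15 gives
  front-cell division probabilities ~0.35 under full anti-metastatic
  cover, versus the 0.5 baseline);
* reprogramming roughly doubles-to-triples final burden and burden rises
  monotonically with astrocyte density — so $\beta$ must dominate
  $\alpha$ and conversion must ride the advancing tumor front rather than
  fire spontaneously ($\theta = 0.25$ with $S_A = 32$ keeps the
  zero-influence leak at $3\times10^{-4}$ per step while a front-adjacent
  astrocyte converts within a step or two);
* sensitivities sit at the middle/upper levels of their canonical sets.

With these values the simulator reproduces the directional structure of
the reference experiments (verified in the test suite at 20 matched-seed
replicates): switching-enabled burden exceeds switching-disabled by about
4x, burden rises monotonically across densities 0/0.25/0.5, inverse-radial
seeding beats radial, and under chemotherapy the reprogrammable arm grows
through treatment while the anti-only arm collapses. Reported quantitative
means cannot be matched without the non-public constants and are not
claimed.

### Chemotherapy constants

The drug constants are likewise artifact calibrations, in normalized dose
units. $C_b = 1$ defines the scale. $D_c = 2500$ lattice²/step follows
from small-molecule diffusivity (~$10^{-6}$ cm²/s) on a 25 µm lattice and
a 17 h step, reduced for brain-tissue tortuosity; it lets the drug front
reach the grid center within a few dosing steps. The kill curve uses
$T = 0.5 C_b$, $k = 20$: a cell bathed at the boundary dose is almost
certainly killed, one below ~0.35 dose units is essentially safe, and the
advancing front carries a cell past the 50% kill point within about two
dosing steps. Decay retains 90% per step; tumor cells absorb 5% of local
drug; $G_f = 1$ puts gap-junction protection at the strength where full
astrocyte contact means complete blockade — the regime in which protective
"hot spots" form. All constants are plain config fields
(`chemo_params()`), so transcribed values can replace them wholesale.

## Numerical choices

**ADI variant.** The diffusion step is a row-implicit sweep followed by a
column-implicit sweep, each a backward-Euler tridiagonal solve (Thomas
algorithm). A trapezoidal (Peaceman–Rachford) ADI step rings and can go
negative at diffusion numbers of order $10^3$; the fully implicit variant
is L-stable and positivity-preserving at any step size, conserves mass
exactly under zero-flux boundaries (verified to $10^{-10}$ relative in the
tests), and has the uniform boundary dose as its exact fixed point under
all-edge Dirichlet forcing. It is first-order in time; a `substeps` config
field subdivides the step when higher accuracy is wanted.

**One global $I_{\max}$.** The normalization constant is computed once for
the full interior neighborhood and reused at edge sites, keeping 7.23 a
global constant; astrocytes on the boundary therefore see a slightly lower
maximal normalized influence. Influence neighborhoods truncate at the grid
edge (no wraparound or mirroring) — the domain is a bounded avascular
tissue patch.

**Update order and RNG.** Within a step: the full astrocyte sweep precedes
the tumor sweep, so astrocytes switched this step already influence tumor
cells this step, while newborn tumor cells are skipped until the next
step. Per tumor cell the draw order is fixed (division draw, placement
draw if dividing, death draw while dosing) so trajectories are bit-for-bit
reproducible from `(config, seed)`; a compiled kernel and a pure-R
reference implementation are held draw-for-draw identical in the tests.
Replicate seeds derive deterministically from `(base_seed, index)`, which
is what makes matched-seed condition comparisons meaningful.

**Morphometrics.** Fractal dimension is plain origin-anchored box counting
(sizes 2–32, OLS slope in log–log space) on the boundary mask — tumor
cells with at least one *empty* Moore neighbor; astrocyte or neutral
contact does not make a cell "boundary". Lacunarity is variance/mean² of
masses over a non-overlapping window tiling (population variance; partial
edge windows dropped; scalar records use window 8, with
`lacunarity_spectrum()` exposing the other sizes since the reported
experiments do not state their window). Eccentricity uses the eigenvalues
of the bulk tumor coordinate covariance. Because the tilings are anchored
at the origin, these two boundary metrics are exactly translation
invariant only for shifts that are multiples of the tiling sizes — the
price of specifying plain box counting with no offset averaging.
Degenerate inputs (empty masks, fewer than two points, zero variance)
return `NA` with a warning rather than failing; collinear point sets give
eccentricity exactly 1.

**Seeding patterns.** The six layouts are weighted samples without
replacement (largest-key exponential race), with weights: uniform = evenly
spaced sublattice trimmed/topped-up to the exact quota; random = constant;
clustered = 30 square blocks around uniform cluster seeds; radial =
max-distance minus distance-to-center; inverse-radial = distance-to-center;
gradient = column fraction. Exact per-pattern geometry in the reference
experiments is not public; these weight functions are stand-ins with the
stated qualitative properties, and the cluster count is an exposed
argument. Under the radial weight the core packs so densely that at 30%
density the tumor seed is usually confined below the site-percolation
threshold and barely grows — stronger confinement than the reported radial
mean, but the same ordering (radial lowest, inverse-radial highest).

**Sobol sampling and PRCC.** The sensitivity harness uses an unscrambled
Gray-code Sobol sequence (Joe–Kuo direction numbers, first 6 dimensions;
the all-zero point is skipped) mapped affinely onto the four continuous
parameters and by equal thirds onto the two discrete level sets. PRCC is
computed by rank-transforming all columns, residualizing parameter and
output ranks on all other parameters by OLS, and correlating the
residuals; the tests pin it against an independent precision-matrix
oracle. Group comparisons delegate to `wilcox.test`, `aov` and
`kruskal.test`; per-step residualization of morphometrics on tumor count
uses OLS with centered fallback when counts are constant.

## What the simulator does and does not emulate

The simulator *is* the data generator for all experiments: there is no
external data. It emulates the spatial logic of astrocyte reprogramming —
local, cumulative, irreversible — and its consequences for growth,
morphology and chemoprotection. It does not model cell migration,
astrocyte proliferation or death, microglia or T cells, tumor phenotypic
heterogeneity, vasculature, 3-D growth, or pharmacokinetics beyond a
single diffusing species. Passing tests therefore demonstrate internal
correctness and the stated directional phenomena under the shipped regime,
not quantitative agreement with any biological measurement.

## Problem sizes used in the tests

Unit and oracle tests run on grids up to 64 x 64. The directional
acceptance checks use the full 300 x 300 grid at 150 steps (200 steps for
the chemotherapy arms, so that both arms complete at least two full
treatment cycles after crossing the 3,000-cell threshold under the
shipped growth rates) with 20 matched-seed replicates per condition —
enough to order the condition means cleanly, as the reported contrasts are
separated by many standard errors. Replicates whose seed happens to be
wedged in a fully enclosed pocket (no empty Moore neighbor ever) cannot
receive therapy and are excluded from treatment-response summaries; at
50% occupancy this affects roughly one replicate in twenty.

## Known limitations

* Quantitative means depend on unpublished baseline constants; only
  directional structure is validated.
* The radial layout stand-in over-concentrates the core (see above).
* Box counting and lacunarity are anchored-tiling estimators; masks
  shifted by non-multiples of the tiling sizes change the estimates
  slightly.
* The ADI variant trades temporal order of accuracy for robustness;
  increase `substeps` for smooth-field accuracy studies.
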