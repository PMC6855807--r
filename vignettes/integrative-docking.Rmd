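---
title: "Cross-link-restrained coarse-grained docking: models, priors and validation"
author: "RexDock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-link-restrained coarse-grained docking: models, priors and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(RexDock)
```

## The problem

Multidomain proteins whose domains are individually well characterised but
whose overall arrangement resists crystallography can be modelled by
combining the domain structures with chemical cross-linking mass
spectrometry (XL-MS). Lysine-reactive cross-linkers such as DSS and DSG
covalently join residue pairs that are spatially close in solution; each
identified cross-link is therefore an upper-bound-like distance restraint
between two residues. RexDock implements the full analysis chain around
this idea: a coarse-grained representation of the protein, a Bayesian
posterior over domain arrangements given the cross-links, replica-exchange
Monte Carlo sampling of that posterior, and ensemble analysis of the
sampled models. Two companion modules quantify the functional side of such
a study: differential deuterium uptake from HDX-MS, and nucleotide-exchange
kinetics of a GEF acting on its GTPase substrate.

## Representation

A `SystemModel` holds one bead per residue at the C-alpha position. Residue
ranges with known structure are declared as rigid bodies: their beads keep
their relative geometry exactly and move only through common rotations and
translations. Everything else — interdomain linkers, termini, regions
without coordinates — is a flexible string with one independently movable
bead per residue. A rigid body may combine several ranges, chains or PDB
sources into one unit; this is how a fused catalytic core (two domains kept
as a single block) or a helix grouped rigidly with a bound ubiquitin is
expressed, while the split alternative simply declares two bodies and a
short flexible range between them.

Flexible beads need starting coordinates: they are placed by linear
interpolation between the housed residues flanking the segment, with 1 Å
Gaussian jitter (a random walk with 3.8 Å steps when a segment has fewer
than two anchors). This is purely an initialisation — the sampler moves
every flexible bead independently.

Bead radii default to 3.0 Å, half the ~6 Å spacing at which two residues'
side chains begin to clash; the value is configurable per system.

## The posterior score

The sampler minimises a negative log posterior with four parts
(`totalScore()` returns the breakdown):

* **Cross-link likelihood.** For cross-link $n$ with C-alpha distance
  $d_n$, the forward model is a logistic switch
  $f(d) = 1/(1 + e^{\alpha (d - d_0)})$ and the observation probability is
  $p_n = \psi + (1 - 2\psi) f(d_n)$, contributing $-\sum_n \log p_n$. The
  nuisance parameter $\psi \in (0.01, 0.5]$ is the probability that an
  observed link is spurious; it is *sampled* alongside the coordinates, one
  value per linker chemistry by default, so the model can discount a noisy
  dataset on its own. At $d = d_0$ the probability is exactly $1/2$ for
  every $\psi$, and $\psi = 0.5$ decouples the likelihood from the
  coordinates entirely.
* **Excluded volume.** $k_{ev}\sum \max(0, r_i + r_j - d_{ij})^2$ over
  non-bonded pairs (pairs in different rigid units that are not sequence
  adjacent).
* **Connectivity.** For sequence-consecutive residues not inside one rigid
  body, $k_c \max(0, d - d_{max})^2$ with $d_{max} = 4$ Å, keeping chains
  intact without fixing bond lengths.
* **$\psi$ prior.** Uniform on its support, hence a constant reported as 0.

Defaults: $d_0 = 20$ Å, $\alpha = 0.3$ Å$^{-1}$, $k_{ev} = k_c = 1$. The
switching distance can be set per linker chemistry
(`scoringConfig(d0 = c(DSS = 30))`): 20 Å suits short-spacer linkers,
while DSS/DSG cross-links are routinely observed at C-alpha separations up
to ~30 Å (11.4 Å spacer plus two lysine side chains), which is why the
ensemble-analysis satisfaction cutoff for such data is 34 Å. For DSS data
we recommend, and our validation protocol uses, $d_0 = 30$ Å; with the
20 Å default the likelihood treats genuine 20–30 Å DSS links as noise and
loses essentially all of its structural signal (see *Known limitations*).

## Sampling

`runSampling()` performs independent replica-exchange runs. Each run draws
a random initial configuration (uniformly random body orientations,
centroids uniform in a cube, flexible beads re-interpolated) and sweeps the
parameter classes in turn at every ladder rung: each rigid body is proposed
`bodyRepeats` times (default 4) with a coupled random translation of at most
4 Å and rotation of at most 0.03 rad about its centroid; each flexible bead
is proposed once with a translation of at most 5 Å; each $\psi$ class is
perturbed by Gaussian noise ($\sigma = 0.02$) reflected into its support.
All proposals are symmetric; acceptance is Metropolis at the rung's
temperature. The extra rigid-body attempts reflect that the handful of pose
degrees of freedom, not the many bead coordinates, limit convergence.

The ladder defaults to 8 geometrically spaced temperatures on $[1.0, 2.5]$.
Every 5 sweeps, adjacent rungs attempt configuration swaps with probability
$\min\!\big(1, e^{(1/T_a - 1/T_b)(S_a - S_b)}\big)$, with alternating pair
parity; temperatures stay attached to their rungs while configurations
travel. The coldest rung's configuration is saved every `saveInterval`
sweeps until the run has produced its share of `nModelsTotal` models.
Production defaults are 500,000 models from 100 starts; the validation
protocol in this package scales this to 10,000 models from 2 starts of
5,000 sweeps each, which completes in about two minutes on one CPU and is
the problem size used throughout the tests.

All randomness flows through R's RNG in a fixed single-threaded schedule,
so a fixed seed reproduces an ensemble bit-exactly. The inner loops are
compiled (Rcpp) and use delta scoring — only the interactions of the moved
entity are re-evaluated — with a full recomputation at every swap boundary;
a test asserts that cached and freshly computed scores agree to $10^{-9}$.

## Ensemble analysis

The 200 best-scoring models are clustered with k-means on their flattened
rigid-body coordinates after every model is superposed (Kabsch, proper
rotations only) on a reference domain of the best-scoring model — Euclidean
distance on these vectors is proportional to coordinate RMSD, which is the
stated clustering basis; the cluster *center* is then re-extracted as the
medoid (the member with the lowest mean RMSD to its co-members) and the
cluster *precision* is the mean RMSD of members to that center. Ties are
broken everywhere by a stable sort on (score, sweep, start, replica).

A cross-link is *satisfied* by a model when its C-alpha distance is
strictly below 34 Å. Per cluster we report the satisfaction of the overall
best-scoring model, the maximum over individual members, and the aggregate
fraction satisfied by at least one member. A split-half diagnostic
(`convergenceSplit()`) compares the score distributions of two random
halves of the ensemble with a two-sample Kolmogorov–Smirnov statistic
(default flag threshold 0.1) and reports per-half best scores and
top-cluster populations.

## HDX-MS differential uptake

`centroidMass()` converts an isotope envelope to a neutral intensity-
weighted mass; uptake is the centroid difference to the undeuterated
reference, optionally normalised for back-exchange against a fully
deuterated control (fraction = uptake / control uptake; corrected Da =
fraction × exchangeable amides, with exchangeable amides = length − 1 −
prolines at position ≥ 3). Two states are compared per peptide and
timepoint with a two-sided Welch t-test: *protected* means a decrease
beyond 0.5 Da with p < 0.05, *deprotected* the symmetric increase,
*no_change* otherwise, and *missing* when a peptide is observed in only
one state — a first-class outcome, because peptides genuinely vanish from
exchange experiments when a region's dynamics change. Both thresholds are
exposed; timepoints are treated independently. `mapToStructure()` writes
per-residue mean differences into the B-factor field of a bead PDB, with
zero occupancy marking residues without peptide coverage.

## Nucleotide-exchange kinetics

Fluorescent-nucleotide release traces are fit to a one-phase decay
$Y(t) = (Y_0 - \text{plateau})\,e^{-k_{obs} t} + \text{plateau}$
(Levenberg–Marquardt via minpack.lm, started from the first point, last
point and $\ln 2$ over half the time range). Initial-rate estimation is
deliberately absent: at working enzyme concentrations traces are often past
the initial linear phase, which is precisely why the decay fit is used.
Fits are flagged unreliable — value still returned — on non-convergence,
degenerate amplitude, or SE($k_{obs}$) > $k_{obs}$. Catalytic efficiency is
$(k_{obs} - k_{intr})/[\text{GEF}]$ in µM⁻¹s⁻¹; $k_{intr}$ comes from a
no-GEF trace in the same run when present, else from configuration.
`compareConditions()` reports fold changes against a reference condition
with seeded percentile-bootstrap confidence intervals (2,000 resamples),
and `doseResponse()` summarises concentration dependence with a Spearman
rank correlation.

## Synthetic ground truth

The generator builds toy systems whose statistical structure matches what
the analysis assumes, so every stage is testable without external data.
Rigid bodies are compact antiparallel helix bundles (20-residue helices,
3.8 Å consecutive C-alpha spacing, 10.5 Å lateral packing) — compact,
globular-ish units rather than long rods. Bodies are placed with random
orientations subject to three physical sanity conditions, then frozen as
ground truth: no excluded-volume overlap between bodies, enough inter-body
residue pairs within cross-linking range, and linker gaps short enough to
bridge without strain.

Simulated cross-link sets draw true links among rigid-body residues with
ground-truth distance ≤ 30 Å (inside the 34 Å satisfaction cutoff) and
decoys from pairs > 45 Å (safely beyond it). Half of the true links come
from inter-body pairs by default (`interFraction = 0.5`): intra-rigid-body
links are structurally uninformative for docking, and in real XL-MS data
the inter-domain subset carries the docking signal. Quality fields are
drawn to pass the standard identification filter. Truth labels are
returned separately from the (shuffled, unlabeled) link set. HDX tables
follow a saturating-exponential uptake curve per peptide with state offsets
and Gaussian centroid noise; kinetics traces are exact decays plus noise.
Each generator takes its own seed, so a master seed plus fixed offsets
regenerates any dataset independently and bit-identically.

What the synthetic data do *not* emulate: sequence-specific intrinsic
exchange rates, isotope fine structure, detector noise, peptide
misidentification, and conformational heterogeneity of the ground truth
itself. Passing the recovery tests therefore demonstrates correctness of
the computations, not performance on real data.

## Validation protocol and known limitations

The package's end-to-end protocol docks a seeded three-body toy (3 × 60
residues, 15-residue linkers, 40 true + 4 decoy cross-links) with 8
replicas, 2 starts × 5,000 sweeps (~10,000 saved models), using the DSS
switching distance of 30 Å, then clusters the top 200 models at k = 3.
Across seeds, the best-scoring model satisfies 97–100% of the true links
at 34 Å.

One sharper requirement — that the best model's RMSD to the generating
configuration, after superposing the reference body, fall below the top
cluster's precision — is *not* met, and the analysis says it cannot be met
with this kind of data. Threshold restraints are loose: with a 30 Å
switching distance there exist rearranged three-body configurations that
satisfy every true link *and* bring the four decoys below threshold, and
because $\psi$ is free, satisfying more links is always rewarded; such
configurations score *better* than the ground truth (the sampler finds
them reproducibly). With the 20 Å switching distance the opposite failure
occurs: genuine 20–30 Å links count as noise, the optimal-$\psi$ likelihood
at the truth is indistinguishable from the coordinate-decoupled $\psi = 0.5$
mode, and the posterior carries no pose signal at all. Scanning $d_0$
between the two regimes never produces a window in which the generating
configuration is the posterior mode. This mirrors the practical experience
with real XL-MS docking — a 44-restraint dataset determines an *ensemble*
of compatible arrangements, not a unique structure — and it is why the
ensemble-level reports (clusters, precisions, satisfaction fractions)
rather than a single model are the method's primary output. The
corresponding test is left failing by design, as a documented property of
the method on this class of data.

## Worked example

```{r example, eval = FALSE}
toy <- makeToySystem(3, 60, 15, seed = 11)
sim <- simulateCrosslinks(toy, nTrue = 40, nDecoy = 4, seed = 12)
links <- filterCrossLinks(sim$links)

ens <- runSampling(toy$system, links,
                   samplerConfig(nModelsTotal = 10000, nStarts = 2,
                                 seed = 101, initBox = 40),
                   PsiParameters(c(DSS = 0.05)),
                   scoringConfig(d0 = c(DSS = 30)))
top <- selectTopModels(ens, 200)
clusters <- clusterModels(top, k = 3, seed = 1)
clusterSatisfaction(clusters, top, links)
```
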