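# RexDock

Integrative modelling of multidomain protein architecture from chemical
cross-linking mass spectrometry (XL-MS), for structural biologists who have
crystal structures of individual domains, a table of cross-link
identifications, and no structure of the full-length assembly. The package
also ships the two functional-analysis companions such a study typically
needs: HDX-MS differential deuterium uptake and guanine-nucleotide-exchange
(GEF) kinetics.

## The model

The protein is coarse-grained to one bead per residue at the C-alpha
position. Structured ranges are rigid bodies; linkers and unstructured
regions are flexible strings of beads. A configuration *M* is scored
against cross-link data *D* by a Bayesian posterior
p(M | D, I) ∝ p(D | M, I) p(M, I), realised as a negative log score:

- cross-link likelihood: per link *n* with C-alpha distance *d_n*, forward
  model f(d) = 1 / (1 + exp(α (d − d₀))) and observation probability
  p_n = ψ + (1 − 2ψ) f(d_n), contributing −Σ log p_n. The uncertainty ψ of
  each linker class is itself sampled on (0.01, 0.5];
- excluded-volume prior: Σ max(0, r_i + r_j − d_ij)² over non-bonded pairs;
- connectivity prior: max(0, d − 4 Å)² for consecutive residues not held in
  one rigid body;
- a flat ψ prior (constant).

Configurations and ψ are sampled by replica-exchange Metropolis Monte
Carlo (8 rungs, temperatures 1.0–2.5; rigid-body moves ≤ 4 Å and
≤ 0.03 rad, flexible-bead moves ≤ 5 Å, Gaussian ψ moves with reflecting
boundaries). The best-scoring models are clustered by k-means on RMSD
after superposition of a reference domain; each cluster reports its medoid
center, precision (mean RMSD to the center) and cross-link satisfaction
(fraction of links with C-alpha distance < 34 Å).

HDX-MS uptake is the intensity-weighted centroid-mass difference to the
undeuterated reference, normalised against a fully deuterated control when
back-exchange matters; two states are compared per peptide/timepoint by a
Welch test with an effect-size floor. Nucleotide-release traces are fit to
a one-phase decay Y(t) = (Y₀ − plateau)·exp(−k_obs t) + plateau, and
catalytic efficiency is (k_obs − k_intr) / [GEF] in µM⁻¹s⁻¹.

A synthetic-data module generates seeded ground-truth systems (compact
helix-bundle bodies), cross-link sets with decoys, two-state HDX tables
and kinetics traces, so the entire pipeline is testable end to end without
downloads.

## Worked example

Simulate a three-body ground truth, dock it from its cross-links alone,
and analyse the ensemble:

```r
library(RexDock)

toy   <- makeToySystem(3, 60, 15, seed = 11)   # 210 residues, 2 linkers
sim   <- simulateCrosslinks(toy, nTrue = 40, nDecoy = 4, seed = 12)
links <- filterCrossLinks(sim$links)           # id_score > 28, deltaS < 0.95, FDR < 0.05

ens <- runSampling(toy$system, links,
                   samplerConfig(nModelsTotal = 10000, nStarts = 2,
                                 seed = 101, initBox = 40),
                   PsiParameters(c(DSS = 0.05)),
                   scoringConfig(d0 = c(DSS = 30)))  # DSS chemistry
top      <- selectTopModels(ens, 200)
clusters <- clusterSatisfaction(clusterModels(top, k = 3, seed = 1),
                                top, links)
ens; clusters
```

```
ScoredEnsemble: 10000 models, 210 beads
  total score: min 21.287, median 41.058, max 358.272
ClusterReport: k = 3
  cluster 1: 103 members, precision 7.70 A
  cluster 2: 42 members, precision 4.06 A
  cluster 3: 55 members, precision 9.18 A
```

The minimum total score (21.29) is reached at ψ ≈ 0.09, i.e. the sampler
explains the data with ~9% presumed-spurious links — consistent with the 4
decoys among the 44 restraints. The top cluster satisfies 95.5% of the
cross-links in its best-scoring member and 100% in aggregate
(`clusters@satisfaction[[1]]`): the ensemble, not any single model, is the
result. Cluster precisions of 4–9 Å quantify how sharply 44 threshold
restraints determine each arrangement.

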