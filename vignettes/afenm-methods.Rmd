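---
title: "From AlphaFold confidence scores to elastic network models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From AlphaFold confidence scores to elastic network models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

AlphaFold2 attaches two statistical confidence measures to every
prediction: the per-residue pLDDT (0–100; stored in the B-factor column
of its PDB output) and the predicted aligned error (PAE), an N×N matrix
in Ångström, capped at 31.75 Å, estimating how wrong residue *i*'s
position is when the structure is aligned on residue *j*. Both scores
correlate with the protein's intrinsic dynamics: regions and residue
pairs that fluctuate strongly in explicit molecular dynamics score
poorly. `afenm` exploits that correlation to build elastic network
models (ENMs) — the harmonic Cα restraint networks used to stabilize
coarse-grained (e.g. MARTINI) protein models — directly from a
predicted structure, without any reference simulation.

# The model

## Confidence-scaled force constants

The central assumption is that the distance between two Cα atoms is
approximately Gaussian with the (symmetrized) PAE as its standard
deviation. Treating the corresponding free energy
ΔG(r) = −k~B~T·ln P(r) as a harmonic well gives

$$k_{ij} \;=\; \frac{k_B T}{\mathrm{PAE}_{ij}^2},$$

with k~B~ = 0.0083145 kJ/(mol·K) and PAE in nm
(`forceConstant()`, exactly inverted by `paeFromForceConstant()`).
Because the raw PAE matrix is not symmetric, the mean of the (i,j) and
(j,i) entries is used (`symmetrizePae()`). At the default 310 K, a PAE
of 1.85 Å maps to 75.3 kJ/(mol·nm²); the package's threshold pair
(k > 75 ↔ PAE < 1.85 Å) is an exact equivalence, asserted in the test
suite rather than resolved in favour of either formulation.

## Bond selection

`buildAfEnm()` bonds a pair (i, j) iff all of the following hold:

| rule | default | why |
|---|---|---|
| pLDDT~i~ > `plddtMin` and pLDDT~j~ > `plddtMin` | 90 (strict) | below ~90 the local structure is not reliable enough to restrain |
| Cα distance ≤ `cutoffNm` | 0.9 nm | conventional ENM reach; balances sensitivity and specificity |
| different chains **or** \|i−j\| ≥ `minSeqSep` | 3 | bond and angle terms of the simulation force field already govern i±1 and i±2 |
| k = k~B~T/PAE² > `kMin` (mode `af_scaled`) | 75 kJ/(mol·nm²) (strict) | a spurious restraint is worse than a missing one, so the PAE gate is deliberately conservative |

Strict inequalities follow the thresholds' published phrasing and are
what make the 75 ↔ 1.85 Å equivalence consistent. Three modes share
the membership machinery: `af_scaled` (PAE-scaled k), `af_const` (same
membership, one generic k) and `standard` (scores ignored; every
eligible pair within the cutoff gets the generic 500 kJ/(mol·nm²), the
conventional MARTINI setting; also available as `buildStandardEnm()`).
Networks serialize to GROMACS `[ bonds ]` sections (`writeItp()`,
default bond function type 6 — harmonic without generated exclusions,
the common elastic-network convention; type 1 selectable) and to
lossless JSON/CSV bond tables.

## Fluctuation metrics

`distanceStdMatrix()` computes σ~d~, the per-pair standard deviation of
Cα–Cα distances across an ensemble — an alignment-free measure of
global dynamics, reported in Å. The population (1/ΣW) normalization is
used rather than the sample one: ensembles here have hundreds to
thousands of frames, where the distinction is negligible, and the
population form is what the harmonic (Boltzmann-Gaussian) analysis
predicts exactly. `residueFlexibility()` condenses σ~d~ into the
per-residue σ~d,n~: the mean σ~d~ to the n nearest *nonbonded*
neighbours, where "nearest" ranks by trajectory-mean distance (not by
any single frame) and "nonbonded" excludes \|i−j\| ≤ 1 within a chain.
Ties break toward the smaller residue index, making the profile
deterministic. n = 20 is the default for protein-sized systems —
correlations with confidence scores are flat for n ≈ 10–70 — but n
must be scaled down for chains so short that 20 neighbours would span
most of the molecule. `rmsf()` (optionally rigid-aligned to the
ensemble mean, one refinement pass) and the B = (8π²/3)·RMSF²
conversion support comparison against crystallographic B-factors;
`radiusOfGyration()` gives the per-frame compactness.

## Score–dynamics statistics

`correlateScores()` reports Pearson R, Spearman ρ, Kendall τ and mutual
information. MI uses a fixed equal-width 16×16 histogram (natural log):
deterministic and directly testable against a permutation null, at the
cost of a small positive bias on independent data; k-NN estimators are
a possible extension, not a default. `fitLinearScore()` is ordinary
unweighted least squares of score on metric, pooled per residue (or
per pair); per-system fits are the same operation applied per group.
`sweepSensSpec()` sweeps a score threshold and reports
sensitivity/specificity against a fluctuation cutoff in both score
orientations (pLDDT-like: high score ⇒ rigid; PAE-like: low score ⇒
rigid). Conditioning sets that are empty yield `NA`, never 0 — the
curves simply end. `deviationProbability()` gives the fraction of
pairs whose reference distance deviates from the ensemble mean by more
than a relative tolerance (default 20%).

## Ensemble comparison

`fitPca()` extracts the two highest-variance modes of the 3N Cα
coordinate covariance after rigid superposition onto the ensemble mean
(one refinement iteration); each mode's largest-magnitude loading is
made positive, so the basis is reproducible. `projectEnsemble()` maps
any ensemble into that 2D space (superposing every frame onto the
basis mean first; coarse-grained backbone beads map to Cα sites by
residue index, overridable). `klGaussian()` compares two projected
clouds with the closed-form Kullback–Leibler divergence between their
moment-matched 2D Gaussians, with a 1e-10 ridge on each covariance.
The Gaussian estimator was chosen over histogram KL because it is
deterministic, has no bin-placement parameters, and the projected
clouds of harmonic or near-harmonic ensembles are close to Gaussian
anyway. KL is asymmetric and the literature leaves the direction
implicit; `compareEnsembles()` therefore reports
KL(candidate‖reference) as its headline number and the reverse
direction alongside.

# The synthetic benchmark generator

Real validation data for this method — microsecond atomistic
trajectories — cannot ship with a package. `makeToyModel()` instead
builds toy systems in which every quantity the pipeline estimates is
known by construction.

**Geometry.** A self-avoiding Cα trace with 3.8 Å virtual bonds, as
one compact globule (`single_domain`) or two globules joined by a
short, deliberately kinked linker (`two_domain_linker`; kinks keep
backbone torsions restrainable by distance springs — a straight
segment's axial torsion is invisible to them). The two domains are
placed with touching surfaces so that genuine inter-domain contacts
exist for an over-constraining network to pin.

**Ground-truth network and the isostatic scaffold.** Each domain
receives a *confident-contact scaffold*: an isostatic set of exactly
3m−6 contacts (sequence separation ≥ 3, within the network cutoff)
built by a Henneberg-type construction — seed triangle, then each
vertex attached by a well-spread tripod of three bonds. Isostaticity is
not an aesthetic choice but a theorem-driven one: in a harmonic
network, the sum over bonds of k~b~·Var(extension~b~)/k~B~T equals the
rank of the Hessian (≤ 3N−6), so *only* a network with no redundant
constraints can realize Var = k~B~T/k on every bond simultaneously.
Redundant networks — any cutoff ENM of a compact protein — shrink
per-bond fluctuations below their nominal value. Among several growth
realizations the scaffold with the largest smallest internal Hessian
eigenvalue is kept (near-coplanar tripods create soft modes), and the
two-domain generator rejects geometries below a conditioning floor.
Scaffold bonds carry ground-truth fluctuation σ ~ U(0.3, 0.6) Å;
linker attachments and six inter-domain hinge bonds are soft
(σ ~ U(2.5, 3.5) Å), producing a connected, rigid, exactly isostatic
"truth network" whose harmonic ensemble realizes large inter-domain
motion over rigid domains.

**Two score channels.** The physical channel (the ToySystem's `pae`
slot) encodes the Gaussian distance-distribution semantics directly:
scaffold contacts carry their ground-truth σ as PAE; all other pairs
get large values (5–20 Å), emulating an AlphaFold run that is
confident about a specific contact set. pLDDT is 93–98 for rigid and
69–75 for flexible residues. The regression channel
(`makeSyntheticScores()`) instead generates scores through the pooled
empirical relations pLDDT = clip(101.3 − 9·σ~d,20~ + ε, 0, 100) and
PAE = clip(2.4 + 0.7·σ~d~ + ε′, 0.01, 31.75) with i.i.d. Gaussian
noise (so the PAE comes out non-symmetric, like real output). The two
channels serve different experiments: regression-coefficient and
threshold-sweep recovery use the regression channel; the
network-construction and fluctuation-recovery loop uses the physical
channel — under the regression channel's intercept of 2.4 Å no pair
can ever pass the 1.85 Å bond gate, so it cannot exercise the builder.

**Harmonic sampling.** `sampleHarmonicEnsemble()` draws frames from
the exact Boltzmann Gaussian of the network Hessian: eigenmodes with
variance k~B~T/λ, the six near-zero rigid-body modes (below 1e-8 of
the largest eigenvalue) discarded. More than six near-zero modes is an
error naming the connected parts: a floppy network has directions of
infinite Gaussian variance and no meaningful sample. Two supplements
make deliberately sparse networks sampleable:
`addChainSprings()` (stiff i±1 ≈ 8000, soft i±2 ≈ 100 and very soft
i±3 ≈ 20 kJ/(mol·nm²)) stands in for the bonded, angle and dihedral
terms a real coarse-grained force field always provides — exactly the
terms whose existence motivates the AF-ENM's sequence-separation rule
— and `addContainment()` adds a ~2.5 kJ/(mol·nm²) spring between all
remaining pairs, the stiffness whose 310 K fluctuation is about 1 nm,
standing in for the mean effect of excluded volume and solvent caging
that bounds quasi-mechanisms (e.g. domains twisting about a linker) at
protein-scale amplitudes.

**The recovery experiment runs in the linear-response regime.** The
designed check of the force-constant map is: build the AF-ENM from the
physical PAE channel, sample each rigid domain component
(`networkComponents()`), recompute σ~d~ along every bond, and compare
with √(k~B~T/k) at the sampling temperature. At 310 K this comparison
is confounded by a real physical effect: the *distance* observable is
anharmonic in the displacements, and transverse fluctuations of the
softer internal modes inflate distance fluctuations beyond the
harmonic prediction by tens of percent even on a well-conditioned
isostatic scaffold (the package reproduces this inflation if run at
310 K — an instructive experiment in itself). The recovery test and
the acceptance script therefore sample at 2 K, where mode amplitudes
are far inside the linear regime and the measured per-bond σ matches
√(k~B~T/k) to within a few percent, Monte-Carlo error included. The
ensemble-comparison experiments, which are qualitative, sample at
310 K.

**What the toys do and do not show.** Passing these experiments shows
the machinery is self-consistent: readers, builder, sampler and
metrics close the loop on systems where the answer is known. The toys
have no secondary structure, no side chains, no solvent, Gaussian
score noise rather than AlphaFold's MSA-depth-dependent artefacts, and
score fields that are consistent with their own ground truth by
construction. None of that licenses quantitative claims about real
proteins; for those, the published benchmarks against explicit MD
remain the reference.

# Numerical choices and degenerate inputs

* Internal coordinates are nm; all reported fluctuation metrics are Å
  (matching the conventional 2 Å / 2.5 Å thresholds). pLDDT written
  on a 0–1 scale (one ColabFold dialect) is detected (all B ≤ 1) and
  rescaled ×100 with a warning.
* Rigid-body mode tolerance: eigenvalues below 1e-8 × the largest are
  "near-zero"; ≤ 6 of them are dropped silently (a collinear
  two-particle system has only 5), more is a floppy-network error.
* Off-diagonal PAE = 0 inside the cutoff is an error naming the pair
  (a zero-variance bond is unphysical); diagonal zeros never matter
  because of the separation rule.
* First altloc wins; insertion-coded residues keep file order;
  residues are indexed contiguously in file order and PAE row k maps
  to the k-th residue. Multimer PAE blocks pass through untouched.
* ITP output prints r0 to 5 decimals (nm) and k to 2; JSON bond
  tables use 17 significant digits and round-trip exactly.
* `fitLinearScore()` errors on constant x; `correlateScores()` flags
  Pearson R as `NA` on constant input but still reports ranks and MI.
* Empty conditioning sets in sweeps are `NA`, never 0.

# Problem sizes

The test-suite and acceptance experiments use 40-residue two-domain
toys (17+6+17), 20 000 frames for per-bond fluctuation recovery
(Monte-Carlo standard error ≈ 0.4% of σ), 1500 frames per ensemble
for the KL comparison, and 20 replicates of n = 500 for regression
recovery. These sizes put every Monte-Carlo error comfortably inside
the asserted tolerances while keeping a full run on one CPU within a
few minutes.

# Known limitations

* The force-constant map treats PAE as a literal distance standard
  deviation; PAE also absorbs model uncertainty unrelated to dynamics
  (MSA depth, conditional folding), which the generator does not
  emulate.
* σ~d,n~ requires n eligible partners per residue and errors
  otherwise; choose n ≲ N/3 for short chains.
* The Gaussian KL estimator summarizes each projected cloud by two
  moments; strongly multimodal projections (distinct conformational
  basins) would need a mixture or histogram estimator.
* Harmonic sampling is exact only for the harmonic model; at
  physiological temperature the distance observable of soft networks
  is visibly anharmonic (see above), which is a property of elastic
  network models generally, not of this implementation.
* `readStructure()` keeps one Cα per residue and ignores everything
  else; no full-atom topology perception, no AlphaFold pickle input.
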