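---
title: "Methods: imbalanced QSAR classification and applicability-domain screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: imbalanced QSAR classification and applicability-domain screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, the defaults and the design decisions
behind `qsarscreen`, and states plainly what the synthetic test bed does and
does not demonstrate about real assay data.

## 1. The pipeline and its assumptions

The package implements a ligand-based virtual-screening workflow for binary
activity against a protein target (the motivating system is small-molecule
inhibition of the PD-1/PD-L1 immune checkpoint):

curation → descriptors → clustering + applicability domain → classifier with
out-of-bag validation → probability-and-domain screening of a drug library.

The central assumptions are the usual QSAR ones: activity is a function of
2D/3D structure as captured by the descriptor families; the training
chemistry is representative of the screening chemistry *inside* the
applicability domain; and labels are binary with a heavily imbalanced prior
(on the order of 1–2% actives).

## 2. Curation

* **Standardization.** The largest organic fragment is kept (most heavy
  atoms; ties broken by canonical-SMILES order; a structure with no
  carbon-containing fragment is an error). Acyclic 1,3-tautomers are
  normalized deterministically — enols to ketones and iminols to amides,
  always at the lowest-index match, iterated to a fixed point; ring double
  bonds are never rewritten, so phenols and other aromatics are preserved.
  This is a small, documented rule set rather than a full tautomer
  enumerator: it makes standardization idempotent and makes the common
  keto/enol pairs collapse, which is what deduplication needs.
* **Deduplication** is by standard InChI, which encodes stereochemistry:
  enantiomers are distinct records. The surviving representative is the
  member with the smallest id, making the result independent of input order.
  Groups that disagree on the label are returned for explicit resolution;
  the default policy is `drop` (conservative), with `prefer_active`,
  `prefer_inactive` and `majority` available because assay-level
  re-adjudication is not algorithmically reproducible.
* **Splits** are stratified by label — the minimal reading of "random but
  both classes adequately represented" that guarantees a fixed class count
  is achievable. `split_dataset()` also accepts explicit per-class test
  counts, because a published partition's realized counts (e.g. 14 actives
  among 878) generally differ by ±1 from proportional rounding, and
  reproducing published bookkeeping requires using the printed composition
  as an input.

## 3. Descriptors

| family | length | source |
|---|---|---|
| MACCS keys | 166 | Open Babel SMARTS definitions; column *k* = key *k* |
| circular (Morgan/ECFP) | 1024 (radius 2) | Open Babel ECFP, 4096-bit, OR-folded |
| hashed path | 2048 | own implementation, linear paths ≤ 7 bonds |
| 1D & 2D panel | 242 | frozen manifest (below) |
| AUTOCORR3D / MORSE / RDF / WHIM | 80 / 224 / 210 / 114 | own implementations |
| voxel grid | `n³` (default 1331) | own implementation |

* **Morgan radius** defaults to 2 (ECFP4-equivalent), the community default;
  it is a parameter. Folding from 4096 to 1024 bits preserves the
  monotone growth of the set-bit set with radius.
* **Path fingerprints** enumerate simple linear paths of 1–7 bonds on the
  heavy-atom graph; each path string (the lexicographic minimum of its two
  reading directions, elements interleaved with bond orders) is hashed by a
  31-adic string hash modulo 2³¹−1 into 2048 positions. Deterministic and
  platform-independent.
* **The 242-column 1D & 2D manifest** is frozen: 42 MQN-style counts (atom,
  bond, polarity and topology counts, ring-size histogram), 20
  physicochemical values (Open Babel's logP/TPSA/MR estimators, H-bond
  donors/acceptors, rotatable bonds, ring statistics), 16 element counts, 20
  topological indices (Wiener, Balaban J, Zagreb, Randić/χ, Kier κ,
  eccentricity statistics), and 144 2D autocorrelations (Broto–Moreau ATS,
  centered ATSC, Geary GATS; lags 1–8 × six atomic weightings: unit, mass,
  van der Waals volume, Sanderson electronegativity, polarizability,
  intrinsic state). Column *identity and order* are guaranteed stable across
  runs; numeric parity with any external descriptor program is explicitly
  not a goal, since no public enumeration of the original panel exists.
* **3D families** are functions of interatomic distances or of the weighted
  principal axes, hence invariant to rigid motion of the pose: MORSE is the
  scattering transform `Σ w_i w_j sin(s·r_ij)/(s·r_ij)` for s = 0…31 over
  seven weightings; RDF is `Σ w_i w_j exp(−β (r − r_ij)²)` on r = 0.5…15 Å
  (step 0.5, β = 100 Å⁻²) — for a diatomic this peaks at the bond length,
  which the tests exploit as a closed-form oracle; AUTOCORR3D averages
  `w_i w_j r_ij` over pairs at topological lag 1…10 (eight weightings);
  WHIM reports 19 statistics (eigenvalues, proportions, symmetry and
  emptiness measures and derived totals) of the weighted coordinate
  covariance under six weightings. Single-atom geometries produce zero-filled,
  flagged vectors.
* **Voxel grids** translate the heavy-atom centroid to the center of a cubic
  grid (default 11 voxels/axis over a 15 Å edge) and deposit each atom's
  property weight through a Gaussian of width σ (default 0.7 × voxel pitch)
  integrated *exactly* over each voxel (separable erf form), truncated at
  3σ. Conservation — grid sum equals total deposited weight — then holds to
  well under 2% for molecules that fit the grid, and the deposition is
  exactly mirror-symmetric for mirror-symmetric conformers. Properties:
  atomic number, Gasteiger or MMFF94 partial charges (Open Babel), and
  additive atomic logP/MR contributions from the package's own coarse
  element/ring-state table (these two weightings are heuristic and labelled
  as such; grid geometry, not weight fidelity, is what the descriptors
  probe). Molecules extending beyond the grid raise a warning carrying the
  clipped weight fraction.
* **Docked poses.** `adopt_docked_pose()` transfers coordinates from a
  docking output onto the reference atom order after verifying the two
  records are the same molecule (InChI connectivity layers). Atom matching
  uses iterative neighborhood-label refinement; residual automorphic ties
  are broken by coordinate proximity then index — chemically neutral because
  tied atoms are symmetry-equivalent. Docking itself is out of scope: scores
  arrive as data (TSV), never from running a docking engine.

## 4. Clustering and the applicability domain

Sphere exclusion (Taylor–Butina) on Tanimoto distance: molecules are ranked
by neighbor count at `sim_cutoff` (default 0.35), leaders capture their
unassigned neighbors, the four largest clusters become A–D (decreasing
size), and smaller residual clusters are attached to the most similar
leader. The exclusion cutoff is a method parameter to be tuned until four
major clusters emerge for the corpus at hand; no claim of parity with any
proprietary clustering tool is made — the analytically specified surface is
the AD rule, which depends only on the centroids and the threshold.

Centroids maximize mean Tanimoto similarity to the other members (ties by
canonical SMILES, then id). `prune_to_x()` moves members below the 0.195
similarity threshold into category X and recomputes centroids **once** — a
single pass keeps the procedure deterministic and terminating, at the cost
that a few molecules may end below the threshold against the recomputed
centroid. A query is in-domain iff its maximum similarity over the A–D and X
centroids is at least the threshold; the boundary is inclusive (0.195 itself
is inside), and the domain is monotone in the threshold. If X is empty the
rule degrades to four centroids and the model is flagged.

The similarity fingerprint defaults to the 1024-bit circular family — the
same family the model selection favours — and is configurable.

## 5. Classifiers and class imbalance

* **Random forest** (`randomForest`): 500 unpruned trees by default; each
  tree's stratified bootstrap draws exactly `n_min` molecules *per class*
  (`sampsize = (n_min, n_min)`), the published recipe for a 3:200 imbalance.
  OOB votes give per-molecule probabilities; `oob_metrics()` scores OOB
  predictions at a configurable vote cutoff. Because balanced bootstraps
  train the trees under a 50:50 prior, the 0.5 majority vote is generous to
  the active class; the screening rule evaluates probabilities at 0.64, and
  recovery analyses on synthetic data use that same cutoff (see §7).
  Permutation importance ("mean decrease accuracy", scaled) drives top-k
  descriptor selection (k ∈ {25, 50, 100, 150} in the motivating study).
* **SVM** (`e1071`): RBF kernel, `class.weights` balanced as `n/(2·n_class)`,
  probabilities by Platt scaling, inputs z-scored (kernel methods are
  scale-sensitive; the forest is not, and receives raw descriptors). The
  published hyperparameters C = 3.593813663804626 and
  γ = 0.007742636826811269 are accepted verbatim; `tune_svm()` grid-searches
  C ∈ [1, 50], γ ∈ [10⁻⁴, 10⁻²] by stratified cross-validation.
* **MLP**: four hidden ReLU layers of 50 units, sigmoid output, binary
  cross-entropy, Adam (lr 10⁻³), batch 36, 500 epochs, glorot-uniform
  initialization, z-scored inputs — implemented in base R matrix code
  because no installed R package provides this architecture. Training is
  exactly seed-reproducible (identical loss curves). Plain (unweighted)
  cross-entropy is the default, matching the published recipe, so on
  uninformative inputs predictions collapse to the majority class.
* **Validation**: OOB for forests; stratified 10-fold cross-validation
  (pooled out-of-fold confusion matrix) for all families. Metrics follow the
  standard definitions SE = TP/(TP+FN), SP = TN/(TN+FP); MCC is 0 when a
  denominator factor vanishes.

## 6. Screening

A library molecule passes iff `p_active ≥ 0.64` **and** it is in-domain;
when a docking table is supplied and a ΔG cutoff is configured (−11 kcal/mol
is the conventional value), the affinity becomes a third conjunct — it is
off by default because docking in the motivating workflow was used
qualitatively after the QSAR criteria. Ties on probability are broken by
maximum centroid similarity, then id, for a fully deterministic ranking. The
report writes the complete per-molecule table plus a summary with the
out-of-domain breakdown by nearest cluster.

## 7. The synthetic test bed — what it shows and what it does not

`generate_dataset()` assembles molecules combinatorially (decorated ring
cores × linkers × substituents). Actives contain a biphenyl system AND an
amide or 1,3-oxazole — motifs recurrently associated with PD-L1 inhibition —
and every label is verified post hoc by SMARTS matching, so before noise the
planted rule is *exact*. Defaults mirror the study conditions: 1.4% actives
(the 403-in-28 319 class balance), 1% label-flip noise, fully deterministic
per seed. Activity is substructure-determined rather than
property-determined so that fingerprint models can in principle reach
MCC ≈ 1, keeping model-family comparisons interpretable.

Two structural consequences of these conditions deserve emphasis:

* **Label noise dominates the observed-label ceiling.** At 1.4% actives, a
  1% symmetric flip rate makes roughly 40% of the *observed* actives random
  molecules. A perfect classifier therefore scores SE ≈ 0.6 and MCC ≈ 0.75
  against the observed labels — not because it is wrong but because the
  labels are. Recovery of the *planted rule* is the meaningful quantity, and
  it is measured by scoring OOB votes at the pipeline's own active-calling
  rule (p ≥ 0.64) against the noiseless truth; the acceptance suite requires
  MCC ≥ 0.9 there and ≈ 0 after label shuffling. Published OOB metrics from
  the real corpus (MCC ≈ 0.95–0.98) are **not** reproducible from synthetic
  data for the same reason; the corresponding acceptance check runs the
  surrogate honestly and is expected to fail until the deposited corpus is
  supplied.
* **The synthetic space is combinatorially uniform; real corpora are not.**
  Public assay corpora are dense around a few medicinal-chemistry series, so
  one giant cohesive cluster dominates and nearly all of the corpus sits
  inside its own applicability domain. The generator's space is much more
  diverse by construction, so circular-fingerprint similarity to any single
  centroid molecule is typically below 0.195 and the AD is conservative:
  planted screening hits top the probability ranking but can fall outside
  the domain. The AD *properties* (boundary inclusivity, monotonicity,
  rejection of deliberately unrelated chemistry — verified at generation to
  have Tanimoto < 0.15 to the training pool) are what the tests establish;
  per-cluster counts and hit pass-rates of any real campaign are not
  reproducible from synthetic chemistry and are not claimed.

3D tests use freshly embedded geometries; conformer realism and docking-pose
realism are out of scope.

## 8. Numerical and engineering choices

* Chemistry primitives (canonical SMILES, stereochemistry-aware InChI,
  SMARTS matching, MACCS/ECFP bits, logP/TPSA/MR, 3D embedding, partial
  charges) are delegated to the Open Babel executable through a batch
  interface; molecules are passed positionally so records the toolkit
  rejects surface as explicit NAs rather than silent shifts.
* All stochastic stages consume explicit seeds; the pipeline derives
  per-stage seeds by salting one global seed with the stage name, so stages
  re-run in isolation reproduce themselves. Re-running a configuration
  reproduces the OOB confusion matrix exactly.
* Pairwise-similarity clustering materializes the n×n Tanimoto matrix; this
  is the right trade-off up to a few tens of thousands of molecules, and the
  vignette-scale analyses here run at n ≤ 3 000. The test suite and the
  acceptance script state the problem sizes they use (400–29 197) as their
  study design.
* Degenerate inputs are defined, not accidental: all-zero fingerprints have
  similarity 0 (with a warning); MCC with a zero denominator factor is 0;
  single-atom geometries yield zero-filled flagged 3D vectors; descriptor
  values undefined for a molecule are imputed 0, flagged, and columns
  flagged in more than 1% of molecules are excluded from training.

## 9. Known limitations

* MACCS/ECFP bit semantics follow Open Babel's SMARTS definitions; other
  toolkits' implementations of the "same" fingerprints differ in detail, so
  cross-toolkit bit-level parity is not expected.
* The tautomer normalizer covers acyclic 1,3-shifts only.
* The atomic logP/MR contribution tables used for voxel weighting are
  coarse, package-own schemes — adequate for grid-geometry descriptors, not
  for property prediction.
* The 242-descriptor panel is a frozen package-defined manifest; its columns
  are reproducible, their values are not interchangeable with other
  descriptor software.
* Exact reproduction of proprietary clustering output, of published
  per-cluster counts, and of published screen hit lists is out of scope; the
  package reproduces the *rules* (AD, thresholds, balanced training,
  metrics) and verifies them property-by-property.
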