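---
title: "Graph-based inhibitor classification: models and methods"
author: "GraphPLI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-based inhibitor classification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

GraphPLI classifies small molecules as inhibitors of a target enzyme
(developed around acetylcholinesterase, the enzyme that hydrolyzes
acetylcholine in the synaptic cleft) from two graph representations: the
molecule's bond graph and the protein's residue contact map. This vignette
is the package's own account of the models it implements, the choices that
were genuinely open, and what its tests do and do not establish.

## Graph representations

**Molecules.** A SMILES string is parsed (through OpenBabel, via
ChemmineR/ChemmineOB) into a heavy-atom graph: atoms are nodes, bonds are
undirected edges, hydrogens stay implicit. Each atom carries a
105-dimensional feature vector

\[ h = [\,\delta_1,\dots,\delta_{100},\;
       \tfrac{q-\mu_q}{\sigma_q},\;
       \tfrac{r-r_{\min}}{r_{\max}-r_{\min}},\;
       I_{\text{aromatic}},\; c_R,\; c_S\,] \]

with a one-hot over atomic numbers 1–100, a z-scored formal charge, a
min–max-scaled van der Waals radius, an aromaticity flag and a two-slot
CIP chirality descriptor. Charge and radius statistics
(`computeNormStats()`) are frozen on the training corpus and reused for
new molecules, so the encoding of a molecule depends on the corpus only
through four scalars.

Decisions that were open and how they were settled:

* *Charge.* The feature is the **integer formal charge**, z-scored. Partial
  charges would require a charge model (and its parameters) and would make
  the featurization non-reproducible across toolkits; the formal charge is
  exact and toolkit-independent. With a degenerate corpus
  ($\sigma_q = 0$) the charge feature is emitted as 0.
* *One-hot vocabulary.* Atomic numbers 1–100 in order. Elements beyond 100
  are rejected at parse time rather than silently truncated.
* *Chirality.* $c_R = (1,0)$, $c_S = (0,1)$, achiral/unresolved $=(0,0)$.
  R/S is derived from the MDL tetrahedral parity written by OpenBabel
  combined with a CIP priority ranking implemented here (sphere-by-sphere
  comparison of atomic numbers over the hierarchical digraph, with
  duplicated atoms for multiple bonds and ring closures). Exotic CIP
  tie-break rules (isotopes, descriptors of descriptors) are not
  implemented; a tie yields "none". The assignment was validated against
  an independent cheminformatics toolkit on classic chiral molecules
  (alanine and phenylalanine enantiomers, halogenated methanes).
* *Van der Waals radii* come from a fixed per-element table bundled with
  the package (Bondi values for the main group, literature values for
  metals), so $r_{\min}, r_{\max}$ depend on the corpus but never on a
  toolkit version.

**Proteins.** A structure (PDB or mmCIF, read with bio3d) is reduced to
one node per standard residue with an alpha-carbon. An edge joins residues
whose Cα–Cα Euclidean distance is **strictly below 8.0 Å**. Cα distances
are the dominant contact-map convention; the cutoff is applied strictly,
so a pair at exactly 8.0 Å is not a contact. Sequence neighbors are kept
when within the cutoff (no $|i-j|$ exclusion). Each residue carries a
24-dimensional vector: a 20-slot amino-acid one-hot (alphabetical by
three-letter code), a 3-class secondary-structure assignment
(helix/sheet/coil) and a binary exposure flag, set when the relative
accessible surface area is at least 25%.

Secondary structure and accessibility come from a DSSP output file when
one is supplied (`ingestDssp()`): the 8 DSSP classes map as
{H, G, I} → helix, {E, B} → sheet, everything else → coil, and absolute
ASA is divided by the residue-type maxima of Tien et al. (2013), clipped
to [0, 1]. DSSP emits a single class per residue, so the "ss3
distribution" is a one-hot. Without DSSP, a geometric fallback
(`assignSsFallback()`) labels a residue helix when an i→i+4 Cα distance
falls in 5.5–6.8 Å (the ideal helix gives ≈6.2 Å), sheet when an i→i+2
distance exceeds 6.4 Å (extended geometry: 7.6 Å), else coil; chains
shorter than 5 residues are all coil. Its accessibility proxy is
$\max(0, 1 - n_{10\text{Å}}/12)$ from the 10 Å neighbor count. The
fallback is a deliberately simple heuristic that is exact on the
package's idealized fixture chains; on real structures DSSP should be
preferred.

## The ligand encoder

A modified GraphSAGE with **deterministic dilated neighborhood sampling**
replacing stochastic neighbor sampling. After a learnable linear
projection of the 105-dimensional features to 128 dimensions (the paper's
per-layer map is 128×128, so an input adapter is required), three layers
aggregate, for every atom $i$,

\[ h_i \leftarrow \sigma\!\big(W_k \cdot
   \mathrm{mean}\{\,h_u : u \in N_{2^k}(i)\,\}\big), \qquad k = 0, 1, 2 \]

where $N_{2^k}(i)$ is the set of atoms at shortest-path distance
**exactly** $2^k$ (1, 2, then 4 bonds) and $\sigma$ is a LeakyReLU
(slope 0.01). The three layers have separate weights. Two conventions
were open:

* *"exactly $2^k$" vs "within $2^k$".* The layer-by-layer reading (bonded
  atoms, then two-bond neighbors, then four-bond neighbors) supports
  exact distances; that is what is implemented, and the three shells are
  provably disjoint (a tested invariant).
* *Empty shells.* Small molecules have no atoms at distance 4 (any
  triangle at $k=2$). An empty shell falls back to aggregating over the
  atom itself, which keeps the layer information-preserving instead of
  zeroing the state.

A 4-head attention pooling follows: head $m$ scores atom $i$ as
$Q^{(m)} h_i / \sqrt{128}$, softmaxes over atoms, pools, and the four
128-dimensional head outputs are concatenated and projected by a 512×512
map to the molecule-level vector.

## The protein encoder

Two graph-attention layers over the contact map, four heads of width 32.
Head $d$ computes scaled dot-product scores
$e^{(d)}_{mn} = (W_q^{(d)} h_m)^\top (W_k^{(d)} h_n)/\sqrt{32}$ on the
attention neighborhood of $m$ — its contact neighbors **plus itself**
(self-attention guarantees every softmax is over a non-empty set) —
normalizes with a softmax, and aggregates value projections. The
concatenated 128-dimensional output passes through a 128×128 projection
with bias, a residual connection and GraphNorm (per-graph, per-channel
standardization with learnable scale and shift, $\varepsilon = 10^{-5}$).
Global average pooling and a 128→512 projection produce the protein-level
vector.

Choices made where the architecture description was ambiguous or
inconsistent:

* Per-head projection matrices (not shared across heads): the head-indexed
  value projections force per-head parameters, and a single shared map
  would make the four heads identical up to the softmax.
* The layer-1 residual adds a 24-dimensional input to a 128-dimensional
  activation; a learnable 24→128 adapter resolves the mismatch. Layer 2
  uses the identity residual.
* A bias added before GraphNorm is absorbed by the per-channel centering;
  it is kept for fidelity to the printed form, and its gradient is
  exactly zero (observed in the gradient checks).

## Fusion and classification head

Fusion is **bidirectional cross-attention at node level**: protein tokens
attend over ligand tokens and vice versa. Node states (128) are lifted to
512 dimensions by learnable per-side maps; each direction uses 512×512
query/key/value maps, four 128-dimensional head subspaces with
$1/\sqrt{128}$ scaling, softmax over the key sequence, concatenation, an
output projection, then a residual connection and per-token LayerNorm.
Mean pooling over residues and over atoms gives two 512-vectors whose
concatenation is the 1024-dimensional joint representation. The
architecture description pools each encoder to a single global vector
*and* describes node-level fusion with per-side token counts; the
node-level reading is implemented (it is the only one under which the
per-token pooling is meaningful), and the pooled encoder outputs are
exposed for inspection but feed no gradient.

The head is $1024 \to 512$ (LeakyReLU, BatchNorm) → dropout 0.2 →
$256$ (LeakyReLU) → a **single logit** → sigmoid. A two-row final layer
appears in one printed formula, but the scalar binary cross-entropy used
for training requires one probability; the single-logit head is the
consistent reading. LeakyReLU is used in both hidden layers as printed
(a prose mention of GELU is not followed). BatchNorm uses batch
statistics during training and running statistics (momentum 0.1) at
evaluation, so evaluation is deterministic and supports single samples.

Training minimizes the clipped binary cross-entropy
($\varepsilon = 10^{-7}$) with Adam (learning rate $10^{-3}$, weight
decay $10^{-5}$), batch size 32, for up to 100 epochs: a linear warm-up
from 10% of the base rate over the first 10 epochs, then
reduce-on-plateau (×0.7 after 5 consecutive epochs without validation
improvement; the patience counter resets on improvement or decay). The
best-validation-loss checkpoint is retained. All gradients are
closed-form reverse-mode derivations, verified end to end against central
finite differences at tolerance $10^{-4}$ (relative, with an absolute
floor at the finite-difference noise level).

## Curation pipeline

`runFilterPipeline()` applies, in order: SMILES canonicalization (salts
stripped to the largest organic fragment — standard practice; the
original description does not state a convention), inorganic removal
(≥1 carbon and all elements in {H, B, C, N, O, F, P, S, Cl, Br, I}),
Lipinski's rule of five (MW ≤ 500 Da, logP ≤ 5, H-bond donors ≤ 5,
acceptors ≤ 10 — all inclusive), the Veber criteria (rotatable bonds
≤ 10, topological polar surface area ≤ 140 Å² — inclusive), and PAINS
substructure alerts, followed by canonical-SMILES deduplication. Every
rejection is logged with its stage and failed rules.

Descriptor provenance: MW, logP (OpenBabel's atom-contribution model) and
TPSA come from OpenBabel; H-bond donors and acceptors are counted on the
parsed structure with Lipinski's original definitions (acceptors = N+O
count, donors = N–H plus O–H count) because toolkit-specific SMARTS
definitions disagree with the printed rule; rotatable bonds use the
standard rotor SMARTS with unique matches (ibuprofen = 4). The PAINS
catalog bundled here is a curated 16-pattern subset of the well-known
published alert families (rhodanines, quinones, catechols, azo dyes,
hydroxyphenyl hydrazones, alkylidene barbiturates, …), shipped as a
versioned TSV; it is not the full ~480-pattern set, which is documented
as a limitation.

## Dataset curation

Activity labeling uses IC50 ≤ 1 μM (inclusive) for positives; replicate
measurements collapse to their geometric mean before labeling. Negatives
are drawn from the >1 μM pool without replacement to exact 1:1 balance.
Splitting is 8:1:1, stratified by species × label with largest-remainder
rounding (ties resolved train → validation → test), which reproduces
per-species split tables deterministically; whether the original split
was stratified is not stated, but stratification is the only convention
under which per-species near-balanced split counts are reproducible.

## Synthetic fixtures and what the tests show

All test inputs are generated in code:

* `genMolecules()` emits five designed violators — an inorganic salt, a
  rigid MW-567 scaffold that passes every other rule, hexachlorobenzene
  (logP 5.6, everything else passing), a 14-rotor glyme chain, and a
  rhodanine PAINS core — plus rule-passing hetero-substituted chains.
* `genChain()` emits Cα traces with exact geometry: ideal helix (rise
  1.5 Å, 100° twist, radius 2.3 Å, so d(i,i+4) ≈ 6.2 Å < 8 Å), extended
  (3.8 Å collinear spacing) or an irregular coil. Writers emit PDB,
  minimal mmCIF and synthetic DSSP files.
* `genInteractionDataset()` plants a separable signal: positives contain
  at least one nitrogen atom, negatives none, with IC50 values drawn
  consistently with the labeling rule (positives log-uniform on
  0.01–1 μM, negatives on 1.5–100 μM), balanced classes and canonical
  uniqueness. The protein is held fixed. A trivial atom-count baseline
  separates this dataset perfectly — so the end-to-end learning check
  (training accuracy ≥ 0.95 within 30 epochs on n = 400) is a
  *necessary-condition* test of the full differentiable pipeline, not a
  capability claim about real bioactivity data. The fixtures emulate
  none of the hard parts of real data: activity noise, assay
  heterogeneity, scaffold bias, species imbalance or structure quality.

Desk-scale problem sizes were fixed once: n = 400 interaction records, a
24-residue fixture protein, molecules of roughly 5–15 heavy atoms, batch
size 32, up to 30 epochs with an early stop once training accuracy
reaches the criterion. Dimensions of the model itself (105, 24, 128,
512, 1024) are never scaled down.

## Numerical conventions

* LeakyReLU slope 0.01 everywhere an activation appears in the encoders
  and head.
* Softmax is computed with max-subtraction; normalization invariants are
  asserted to 1e-12 in the tests.
* Metric conventions: precision, recall and MCC return 0 on a zero
  denominator; AUC is the rank statistic (ties count half) and returns
  0.5 when a class is absent; the classification threshold for
  confusion-based metrics is 0.5; the screening confidence threshold is
  inclusive (≥ 0.97 by default).
* All stochastic steps (initialization, shuffling, dropout, balancing,
  splitting, fixture generation) derive from explicit integer seeds;
  re-running any pipeline stage with the same seed is bit-identical.

## Known limitations

* CIP assignment covers the dominant priority rule only; molecules whose
  stereocenters require higher CIP rules are reported unassigned.
* The PAINS catalog is a representative subset, not the full published
  set.
* The geometric secondary-structure fallback is calibrated on idealized
  geometry; real structures should use DSSP output.
* Automatic binding-pocket detection is out of scope; `cropResidueWindow()`
  crops to user-specified residue windows only.
* Training is CPU-only and single-threaded beyond BLAS; it is sized for
  the synthetic datasets, not for full-scale bioactivity corpora.
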