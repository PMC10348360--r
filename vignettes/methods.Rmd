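---
title: "Chemistry- and geometry-biased self-attention for molecular property prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chemistry- and geometry-biased self-attention for molecular property prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`molbert` learns molecular representations by fusing three views of a
molecule inside one transformer encoder:

* **1D** — the heavy-atom token sequence read off the SMILES string, paired
  with a per-atom NMR chemical-shift token sequence.  A global node `<G>` is
  prepended; its final representation is the whole-molecule embedding.
* **2D** — the bond dissociation energy (BDE) matrix $B$ (kJ/mol, zero off
  the bonds), min-max normalised over the bonded entries to $B_{norm}$, and
  its binarisation $M$ (the adjacency mask, with self-connections and a
  fully connected global node).
* **3D** — the raw interatomic distance matrix $D_{raw}$ (Å) of a single
  relaxed conformer, transformed by a small learned module into the
  *distance fraction matrix* $D$.

Each encoder layer computes, per attention head,

$$A = \mathrm{softmax}\!\left(\frac{QK^\top}{\sqrt{d_k}}\right), \qquad
A_{2d} = A \odot M + \lambda\, B_{norm}, \qquad
A_{3d} = A_{2d} + D,$$

and the attended values $A_{3d} V$ flow through the usual output
projection, residual connections, layer norms and position-wise
feed-forward network.  $\lambda$ defaults to 0.2.  Note that $A_{3d}$ is
deliberately **not** re-normalised to row-stochastic form: the element-wise
gate and the additive biases are applied to the softmax output as written,
so attention rows sum to 1 only before gating.

There are no positional encodings.  Token order carries no chemical
meaning, so the architecture is permutation-equivariant over atoms and
permutation-invariant in the global node — the central correctness property
the test suite asserts numerically (tolerance 1e-5).

## Pre-training

Four self-supervised tasks are trained jointly on corrupted inputs:

* $L_A$, $L_N$ — mean cross-entropy reconstructing the original atom and
  NMR tokens at corrupted positions.  20% of each sequence is selected
  (independently for the two sequences), and within the selection 80% is
  replaced by `<M>`, 10% by a random different valid token, 10% kept.
  Both rates are configurable; the reconstruction loss scores all selected
  positions by default (`scored_actions = "mask_only"` restricts it).
* $L_B$ — mean squared error predicting $B_{norm}$ entries for bonded pairs
  from the two endpoint representations (concatenation orders averaged so
  the prediction is symmetric; each unordered pair counted once).
* $L_{3D}$ — the token representations are projected to 3-vectors
  $r' = W_r r$ and the geometry is re-derived from them: distances over all
  atom pairs (Å), bond angles over bonded triples and torsions over bonded
  quads (radians, unsigned).  Each family contributes its mean squared
  error against the conformer's true values.

The total is the uncertainty-weighted sum
$L = \sum_k L_k/\sigma_k^2 + \sum_k \log \sigma_k$ with learnable
$\sigma_k$ (parameterised as $\log\sigma$, initialised at 0).  For fixed
components the stationary point is $\sigma_k^2 = 2L_k$, which the tests
verify through the implemented gradient.

**Averaging, not summing.** The printed loss definitions use plain sums;
summed losses scale with molecule size and destabilise the
$\sigma$-balancing, so each family is averaged by default and raw sums are
available via `aggregate = "sum"`.

## Fine-tuning

A two-layer ReLU head (hidden width 64 by default, dropout 0.1) reads the
global-node representation.  The objective retains the pre-training loss as
a regulariser with weight 0.1 by default (`pretrain_reg_weight = 0` gives
plain supervised training).  Optimisation is Adam with linear warmup over
the first tenth of the steps — warmup matters here: a randomly initialised
head sends large early gradients into the encoder, and without warmup those
can scramble pre-trained features before the head settles.  By default the
reported model is the epoch with the best validation metric
(`select_by_valid`), which is what the validation share of the 80/10/10
protocol is for; the alternative is the final epoch.

Two controls are available for judging what pre-training contributes.
`freeze_encoder = TRUE` trains the head on a *fixed* untrained encoder —
the random-features control that isolates representation quality, and the
comparison the acceptance checks use.  Fine-tuning an untrained encoder
end-to-end (an untrained checkpoint with default settings) is the other
control; at the desk scale this package runs at — tens of pre-training
molecules, a composition-linear label — that variant is statistically
indistinguishable from the pre-trained model across seeds (each wins on
some), which is worth knowing before reading too much into single-seed
comparisons.  Published gains for this model family come from pre-training
corpora four orders of magnitude larger.

Evaluation follows the scaffold protocol:
Bemis-Murcko-style scaffolds (ring systems plus linkers; atom-order
independent Weisfeiler-Lehman keys), groups assigned greedily largest-first
to fill an 80/10/10 train/validation/test partition so no scaffold spans
two splits, with a seeded random fallback when fewer than three scaffolds
exist.  Metrics are RMSE and $R^2$ for regression and rank-based ROC-AUC
for binary tasks, with mean and standard deviation over independent runs.

# Design choices where the design was open

**Distance encoder.**  The distance channel is specified only as a learned
transformation of $D_{raw}$.  A naive dense projection along the position
axis would break permutation equivariance, so the implemented module is
position-shared throughout: each pairwise distance is lifted into a fixed
basis (the raw distance, a decaying exponential, and Gaussian bumps at
1-8 Å), each token's distance profile is mean-pooled into an embedding and
passed through one standard transformer layer, and the score for pair
$(i,j)$ combines the pair's basis features with both tokens' encoded
profiles.  Setting the pair projection to select the raw-distance feature
and silencing the token terms makes the module the identity
(`distance_encoder_identity()`), which the tests exploit to verify the
wiring: $D = D_{raw}$ exactly.  $D$ is computed once per molecule and
shared across layers and heads; its global-node row and column are zero
(the global node carries no geometry).

**Multi-head.**  The algebra above is single-head as printed; the
implementation applies the 2D/3D biases per head with $M$, $B_{norm}$ and
$D$ broadcast, and `n_heads = 1` recovers the literal equations.
Post-norm residual placement and a 4x feed-forward width follow standard
transformer practice.

**Corruption rates.**  Two stated rates conflict (a whole-sequence 80/10/10
replacement versus "about 20%" masking); the implementation follows the
BERT convention — select 20% of positions, apply 80/10/10 within the
selection — and exposes both rates, so `select_rate = 1` reproduces the
literal whole-sequence reading.

**Surrogate chemistry.**  The NMR shifts and bond energies that feed the
model are produced in the original work by trained neural predictors that
are not redistributable.  The package substitutes deterministic lookups:
shifts keyed by the atom's radius-1 environment (element plus the sorted
multiset of neighbour elements and bond orders) and bond energies keyed by
(element, element, bond order) with literature-typical mean values, both
packaged as documented CSVs (`inst/extdata/`).  The architecture needs
consistent, chemically varying values rather than any particular predictor,
and user-supplied tables can override both channels exactly
(`nmr_override`, `bde_override`).  Unknown environments fall back to an
element default; unknown bond keys to an order default.

**Conformers.**  Coordinates come from a seeded random start refined by
BFGS on a molecular-mechanics-style penalty (covalent-radius bond lengths,
hybridisation-dependent angles, sp2/aromatic planarity, soft non-bonded
repulsion, signed-volume restraints at stereocentres), with analytic
gradients.  The single relaxed conformer stands in for the "ground state"
structure.  Enantiomers are embedded as exact mirror images: optimisation
always runs with the first stereocentre's handedness normalised and the
reflection is applied afterwards, so a pair's distance multisets agree to
machine precision rather than merely to tolerance.

**Chirality.**  The unsigned torsion convention (arc-cosine of the plane
normals) is mirror-invariant, and so are distances — so the 3D channels
cannot separate enantiomers, which the mirror-symmetry tests document as a
representational fact.  Two opt-ins break the symmetry where that is
wanted: chiral atom tokens (`use_chiral_tokens`) and signed torsions
(`signed_torsions`).  Neither is claimed to reproduce any particular
published configuration.

**Bond angles.**  The angle about atom $j$ in a bonded path $i\!-\!j\!-\!k$
is computed as `atan2(|u x v|, u . v)` with $u = r_i - r_j$,
$v = r_k - r_j$, the numerically stable and translation-invariant form; a
printed cotangent variant is not translation-invariant as written and was
not adopted.  Collinear triples give exactly $\pi$; degenerate torsions
(three collinear atoms) are skipped with a warning when targets are built
and guarded by epsilon clamps inside the differentiable loss.

**Normalisation caveat.**  Min-max normalisation sends the weakest bond to
$B_{norm} = 0$, so binarising $B_{norm}$ recovers a subset of the bonds,
not all of them — $M$ is therefore always derived from $B$, never from
$B_{norm}$.

# The synthetic fixture generator

`generate_fixtures()` emits small valid molecules from parameterised
templates — alkanes, ethers, alcohols, amines, halides, substituted
benzenes, and a set of saturated/aromatic ring cores (cyclohexane through
naphthalene and biphenyl) — spanning 2-16 heavy atoms, with optional
@/@@ enantiomer pairs.  The template mix keeps roughly a third of the set
acyclic and spreads the rest over many distinct scaffolds so that scaffold
splitting produces non-trivial partitions.  Each molecule carries a
regression label

$$y = 0.8\,n_C + 2.5\,n_O + 1.8\,n_N + 3.0\,n_{hal} + 0.5\,n_{arom}
      + \varepsilon,\quad \varepsilon \sim N(0, 0.1^2),$$

a closed-form function of composition (`fixture_label()`), so that
fine-tuning has a learnable target with known structure.  What the
generator does **not** emulate: realistic conformational ensembles,
tautomers, charged species, measured assay noise, or any property that
depends on 3D shape rather than composition.  Passing tests therefore
demonstrate that the machinery learns and generalises on a controlled
task — not that it reproduces published benchmark accuracy on real
datasets, which would require external data and far larger pre-training.

# Numerical choices and problem sizes

All training runs on an in-package reverse-mode automatic differentiation
engine over dense matrices (no external deep-learning runtime); every
primitive's gradient is tested against central finite differences, and a
full encoder step is spot-checked end to end.  Optimisation uses Adam
(lr 1e-3, default batch 8).  Dropout masks, corruption draws, shuffling and
initialisation all derive from explicit seeds, so trajectories are
bit-reproducible; with learning rate 0 parameters are bit-stable.
Divergence (non-finite loss) aborts with the last finite state flagged.

The paper-faithful architecture (6 layers, 512 dimensions, 8 heads) is the
default configuration; the test suite and the acceptance script run a
reduced desk-scale configuration — 2 layers, 64 dimensions (32 for the
ablation comparison), 64 pre-training molecules for 30 epochs, a
500-molecule fixture table for fine-tuning — chosen so the full suite
completes on one CPU in minutes while still exercising every code path.
The ablation switches mirror the channel-removal experiments: `"no3d"`
zeroes $D$ and drops $L_{3D}$; `"nochem"` replaces the NMR sequence by a
constant token, $B_{norm}$ by the plain mask $M$, and drops $L_N$ and
$L_B$.

# Known limitations

* The SMILES reader covers the organic subset the generator and common
  datasets use (B, C, N, O, F, P, S, Cl, Br, I; aromatic forms; brackets
  with charge, H-count and @/@@; rings, branches, dots).  Exotic elements
  map to `<UNK>`; cis/trans bond markers are read but not enforced
  geometrically.
* The conformer embedder targets idealised geometry; it is adequate for
  the feature channels but is not a substitute for a quantum-chemistry or
  force-field package when accurate structures are the goal.
* Surrogate NMR/BDE values are chemically plausible constants per local
  environment, not predictions; absolute scales matter less than their
  consistency, and both can be overridden from user tables.
* Uncorrupted fine-tuning inputs mean the SSL regulariser re-corrupts per
  step; with very small batches this adds gradient noise that the default
  weight (0.1) keeps modest.
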