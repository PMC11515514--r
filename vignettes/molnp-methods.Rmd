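---
title: "molnp: models, study conditions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{molnp: models, study conditions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the science it implements: the
neural-process models and their assumptions, the tunable parameters and
why their defaults are what they are, what the synthetic generators do and
do not emulate, and the numerical and design choices made where the design
was genuinely open. It states no empirical result that the test suite and
`scripts/acceptance.R` do not themselves compute.

## The model

A task (or function) is a real-valued property over molecules, observed at
$O_i$ input points. A neural process conditions on $C$ labelled *context*
points and outputs, for each *target* input, a Gaussian predictive mean
and variance. Targets are assumed conditionally independent given the
contexts — the predictive factorizes over target points. This is the
central modelling assumption: the NP captures epistemic uncertainty about
the task through the function encoding, but no posterior correlation
*between* targets (unlike a GP posterior).

Computation proceeds in three steps:

1. **Encode**: $h_\theta$ (3 fully connected layers, ReLU) maps each
   $(x_{c,j}, y_{c,j})$ to a per-point encoding $r_j$.
2. **Aggregate**: the global function encoding $r$ is the *mean* of the
   $r_j$. The mean is commutative, so the model is exactly invariant to
   context permutations; it is also stable across the widely varying
   context sizes the training regime draws (a sum would scale the
   encoding with $C$). An empty context set encodes to the zero vector, a
   convention that makes "no information" a well-defined input.
3. **Decode**: $g_\theta$ (3 layers; the last layer holds the $\mu$ and
   raw-scale heads) maps $(r, x)$ to the predictive moments. The variance
   is `softplus(raw) + 1e-4`; the floor prevents likelihood spikes at
   near-interpolated points from dominating the objective.

The **CNP** decodes $r$ deterministically. The **LNP** adds a latent path
(2 layers) mapping $r$ to a diagonal Gaussian over $z$ (length 64); the
decoder consumes $z$ instead of $r$. Training uses a single
reparameterized sample of $z$ from the posterior conditioned on contexts
*and* targets, plus a KL term against the posterior conditioned on
contexts alone. This standard variational-NP regularizer is the package's
decided stand-in for the latent-path regularization, chosen because it has
the intended effect — reducing the encoder's sensitivity to any one sample
of the task — and a closed form that the tests verify against
`klDiagGaussian`. At test time the LNP decodes the posterior *mean* of
$z$ (deterministic); averaging over $S$ samples is available as an option
and returns moment-matched mixture moments.

All stochastic paths take explicit seeds; CNP prediction is deterministic.

### Layer indexing

Layers are numbered from the input: the decoder is `decoder.1` …
`decoder.3`, with `decoder.3` the $\mu/\sigma^2$ head. "The last two
decoder layers" therefore means `decoder.2` and `decoder.3`; the LNP's
latent path contributes `latent.1` and `latent.2`. This convention fixes
the adaptable subset used by fine-tuning.

## Meta-training

Each epoch visits every task once in random order. Per visit, context and
target sizes are drawn uniformly from half-open intervals (default
$[20, 150)$) and disjoint index sets of those sizes are subsampled, with
$C + T \le O_i$; the per-task negative predictive log-likelihood is
averaged over a mini-batch of 16 tasks and one Adam step is taken
(learning rate $10^{-3}$, gradient-norm clip 10 — the optimizer settings
are the package's choice where the procedure is otherwise silent). The
expectation in the objective is estimated with one split draw per task
visit by default (`splitsPerVisit` raises it).

Randomizing the split sizes is not a nuisance: it controls **effective
epochs** $e_e = e\,\bar n / O_i$, the average number of times a datapoint
is seen (as context or target). Keeping $e_e$ low is what protects the
maximum-likelihood-trained CNP from overconfidence; `runOverfitSweep`
demonstrates the failure mode by driving the sampled fraction to 1.

Two implementation notes:

- Mini-batches are represented as concatenated rows with a task-index
  vector; `rowsum` performs the per-task aggregation. This is numerically
  identical to a padded 3D task batch with masking and avoids the padding
  overhead; the memory contract for large target sets is instead provided
  by `chunkedPredict`, which splits targets into bounded passes and is
  exact because the decoder factorizes over targets.
- Tasks smaller than the minimum requested sizes are handled by a rescue
  rule that shrinks both ranges proportionally (each size at least 1);
  the training regime is not expected to encounter such tasks, but the
  splitter must not fail on them.

Gradients of both objectives are derived by hand (the encoder/decoder are
small MLPs) and verified against central finite differences in the test
suite; finite-difference stencils that straddle a ReLU kink are detected
by step-size instability and excluded from the comparison rather than
papered over with loose tolerances.

## Fine-tuning (adaptation at meta-test time)

A meta-trained NP applied to a divergent test function can be adapted on
the function's own $C$ contexts by mimicking meta-training: each epoch
re-splits the contexts into fresh disjoint new contexts ($C' = 20$) and
new targets ($T' = 20$; the 20-shot preset uses 5/5) and backpropagates
the NP objective through a small adaptable subset — the last two decoder
layers, plus the last two latent-path layers for LNPs — leaving everything
else bitwise frozen. Freezing bounds the capacity that can overfit $C$
points; the frozen encoder preserves the meta-learned representation.

The desired adaptation budget is stated in effective epochs (default 20)
and converted to actual epochs as $e = \lceil e_e C / T' \rceil$: the
package counts *target* views, since only target predictions enter the
loss being optimized; counting context views as well
($e = \lceil e_e C/(C'+T')\rceil$) is exposed as `effectiveEpochMode =
"both"`. The fine-tuning learning rate defaults to $10^{-4}$ — an order
below meta-training, a conventional choice for adapting a trained model
that the source procedure leaves open. Split sizes stay fixed across
adaptation epochs; only the index draws are fresh.

## Molecular representations

**Fingerprints** are binary hashed circular substructure fingerprints
(default length 1024, radius 3): per-atom integer invariants seeded from
element, degree, H count, charge, ring and aromaticity flags are
iteratively combined with sorted neighbour invariants and bond orders,
and all (atom, radius) invariants are folded modulo the bit length. The
hash dialect is package-specific (every toolkit's is); tests assert the
contracts — determinism, length, binary entries, sane Tanimoto behaviour —
and cross-check parse-level facts against an independent toolkit, not bit
indices. Tanimoto similarity of two all-zero fingerprints is defined as 1
(identical empty bit sets), preserving "identical inputs ⇒ similarity 1".

**Graphs** are heavy-atom graphs (hydrogens become a count feature) with
one-hot blocks for element ({C,N,O,S,F,Cl,Br,I,P,B,Si,other}), H and
heavy-neighbour counts (capped at 6 with an overflow bin), formal charge,
hybridisation ({sp,sp2,sp3,sp3d,sp3d2,other}), ring/aromatic/chiral
flags, and real-valued mass (scaled by 1/100 to keep features O(1)) and
Van der Waals/covalent radii. Bond features: type one-hot
(single/double/triple/aromatic), conjugation and ring flags, stereo
one-hot. SMILES parsing, ring perception and aromaticity come from the
OpenBabel-backed ChemmineR stack; a syntactic validator rejects malformed
SMILES (unbalanced brackets, unpaired ring closures) before parsing, since
the backend is permissive about them. The featurizer configuration is
stored on every graph and on model checkpoints so dimension mismatches
fail loudly.

**Graph encoder**: atom and bond features are pre-embedded by 2-layer
FNNs (50 hidden units) into length-25 vectors — bond embeddings summed
over each atom's bonds (empty sum = zero vector for isolated atoms) —
and concatenated into length-50 atom states. Three rounds of single-head
scaled-dot-product attention over each atom's neighbour set follow
(queries/keys from a single-layer FNN, values linear; softmax over the
neighbour set only), each round updating by residual add then linear +
ReLU; no gated recurrent units. A superatom connected to every atom,
initialized as the mean atom state (the initialization is the package's
choice), then participates in three further rounds on the augmented graph
— real atoms keep exchanging messages with their neighbours *and* with
the superatom — and its state passes through a small FNN to the length-50
molecular representation. Attention operates on atom states only after
pre-embedding; bond features are not re-injected inside attention rounds
(decided where the description leaves it open). Head count is 1,
configurable. The representation is exactly permutation invariant, which
the tests check together with a directional-derivative probe showing the
output depends on every parameter group.

## Synthetic study conditions

The generators define the package's desk-scale study conditions; they are
stated here once, as the package's own choices, and the tests and
`scripts/acceptance.R` run them as written.

**Sinusoids**: tasks $y = A\sin(\rho(x - B))$ with $A \sim U[0.1, 5]$,
$B \sim U[0, \pi]$, $x \sim U[-5, 5]$, no label noise, 100 points per
task — the classic meta-learning regression family. The
meta-generalization study trains a CNP (widths 64) on 500 tasks at
$\rho = 1$ for 300 epochs with split sizes $\sim U[10, 48)$ (scaled to
$O_i = 100$), then evaluates mean target MSE on held-out $\rho = 1$ tasks
(20 contexts) against the task-variance baseline, and on $\rho = 1.5$
tasks — the frequency shift that collapses generalization. The recovery
arm fine-tunes on 100 contexts of each shifted task ($e_e = 20$,
$C' = T' = 20$).

**Synthetic molecular tasks**: labels are sparse linear functions of
fingerprint bits, $y_i = (\lambda w_{shared} + (1-\lambda) w_i)\cdot fp$,
standardized per task, plus Gaussian noise (sd 0.3). $\lambda \in [0,1]$
tunes inter-task correlation the way protein-target similarity varies in
a docking-score matrix: `targetMaxCorrelation` rises monotonically with
$\lambda$. Molecules come from a built-in generator of valid drug-like
SMILES (chains, rings, substituents; a 200-molecule sample ships in
`inst/extdata/synthetic_smiles_library.txt`). Experiment drivers use
512-bit radius-2 fingerprints (256-bit for the sweep) to keep input
dimension proportionate to these library sizes; 1024/3 remains the
package default for real data. Study sizes: calibration — 500 molecules,
50 tasks ($\lambda = 0.7$), 40 meta-train / 10 meta-test, 60 epochs,
200 contexts per test task, 20 confidence percentiles; overfitting sweep
— 150 molecules, 20 tasks, 300 epochs per arm at $f = 0.05$ versus
$f = 1$ (with overlapping sets, the only way to reach $f > 0.5$), sized
so both arms train to convergence and the sampled fraction, not the step
count, separates them; Bayesian optimization — a 2000-candidate library
whose hidden objective is one held-out task of the same family, a CNP
meta-trained on the other 30 tasks, batches of 5 to a budget of 200 with
20 random initial evaluations, compared against random selection and a
Tanimoto-kernel GP.

What the generators do *not* emulate: real docking scores are nonlinear
in any fingerprint basis, scaffold-split rather than randomly split, and
task correlations are heterogeneous rather than exchangeable. Passing
tests therefore certify the machinery (objectives, invariances,
calibration mechanics, screening advantage under a correct prior), not
performance on real chemistry.

## Bayesian optimization

Objectives are minimized (docking-score convention); maximization
objectives are negated at ingestion, and LCB is $\mu - \kappa\sigma$ with
$\kappa = 1$ by default ($\kappa = 0$ is greedy). Initialization uses 20
random molecules (the package's choice). Ties in acquisition break by
lowest library index, making trajectories reproducible; best-so-far
curves are monotone by construction. The NP surrogate is conditioned on
all seen points as contexts at every iteration (re-fine-tuning per
iteration is available through the surrogate closure but off by default —
conditioning is the mechanism under study). Task augmentation from a
complete score matrix draws scalar multiples, two-target linear
combinations (weights $\sim U[0.1, 1]$), and min/max-with-median
transforms, each plus QED weighted $\sim U[0.5, 2]$; any transform
touching an excluded target is discarded. The Tanimoto-kernel GP is exact
(Cholesky with observation noise on the diagonal; one $10^{-8}$-jitter
retry), with prior variance $k(x,x) = 1$.

## Numerical conventions and edge cases

- Variance floors: predictive $10^{-4}$, latent $10^{-6}$.
- Softplus computed as $\max(x,0) + \log1p(e^{-|x|})$ (overflow-safe).
- Percentile grouping: stable tie-break by original index; when $T$ is
  not divisible by the group count, the last group absorbs the remainder.
- Calibration correlation drops groups with non-positive mean MSE or
  variance (their log is undefined) with a warning.
- Relative error excludes $y = 0$ points with a warning, never silently.
- Applicability-domain buckets are half-open $[0.05k, 0.05(k+1))$ with
  the final bucket closed at 1.
- Checkpoints round-trip weights bit-stably (`saveNPModel` /
  `loadNPModel`).
- Non-finite losses abort training with diagnostics rather than
  continuing.

## Known limitations

- The graph encoder is forward-only: the package does not backpropagate
  the NP objectives through the attention stack, so molecular NPs are
  trained on fingerprints or on *fixed* graph-encoder representations
  rather than end-to-end. Joint training is the natural extension.
- The LNP regularizer is the standard variational KL; other latent-path
  regularizations would slot into `lnpLoss`.
- No attentive or Gaussian NP variants, and no posterior correlation
  between targets.
- Scaffold splitting is consumed (as a split column), never computed;
  QED in synthetic mode is a bounded random column.
- The synthetic task family is linear in fingerprint space; see the
  generator caveats above for what that implies about external validity.
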