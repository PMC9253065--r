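---
title: "Learning successor-representation cognitive maps of space and language"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning successor-representation cognitive maps of space and language}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`cogmapsr` studies how a plain feed-forward network can acquire a *cognitive
map* — a predictive representation of a state space — purely from observed
transitions. The theoretical object is the successor representation (SR). For
a state space with row-stochastic one-step transition matrix $T$, discount
$\gamma \in [0, 1]$ and horizon $h$,

$$M \;=\; \sum_{t=0}^{h} \gamma^{t} T^{t},$$

so $M(s, s')$ is the discounted expected number of visits to $s'$ on a walk
started at $s$. Any reward vector $R$ is then read out linearly,
$V = M R$ — with $R \equiv 1$, $V$ is the total discounted occupancy. Rows of
$M$ rendered over a spatial environment look like hippocampal place-cell
firing fields; eigenvectors of $M$ reshaped over the environment look like
entorhinal grid-cell fields. `successor_matrix()` evaluates finite horizons
by Horner's scheme and the infinite horizon in closed form
$(I - \gamma T)^{-1}$ (requiring $\gamma < 1$);
`sr_partial_sum_oracle()` is a deliberately independent term-by-term
accumulation kept for cross-checks.

Three scenarios instantiate this idea:

1. **Spatial exploration** (supervised): a $10 \times 10$ open room, 100
   states. Transitions are a uniform random walk over the 8-connected
   neighborhood *including the current state* — interior cells have 9
   successor states, wall-adjacent cells 6, corners 4 (without
   self-inclusion: 8/5/3).
2. **Spatial navigation** (reinforcement): a $15 \times 15$ corridor maze of
   which 94 cells are traversable, with a $+10$ food-tray reward at each end
   of the main corridor.
3. **Linguistic structure inference** (supervised): a 40-word artificial
   language in five classes (10 adjectives, 10 verbs, 10 nouns, 5 pronouns,
   5 question words) with three construction rules — adjective→noun,
   pronoun→verb→adjective, question→pronoun→verb. Successor words are
   uniform within the successor class; nouns are rule-final and therefore
   never occur as inputs.

## The predictor network

`init_network()` builds a three-layer net: one-hot state input (size $N$),
ReLU hidden layer (size $\lfloor fN \rceil$, default $f = 1$), softmax
output over all $N$ states. Training (`train()`) minimizes the cross entropy
between the softmax output and one-hot sampled successors with the Adam
optimizer (learning rate 0.01 for the supervised tasks). The crucial
property is that the cross-entropy optimum for input $s$ is the *empirical
successor distribution* of $s$: the network converges to the transition
matrix row by row, not to any single one-hot target. Concatenating
predictions (`predicted_tp_matrix()`) therefore reconstructs $T$, and
feeding that reconstruction to `successor_matrix()` yields the learned SR.

Design choices that were genuinely open:

* **Batch regime.** Pairs are presented full-batch by default (one Adam
  update per epoch). Because inputs are one-hot, the exact full-batch
  gradient depends on the data only through the pair-count matrix, which
  makes an epoch a handful of $N \times N$ matrix products; the 10,000-pair
  spatial task reaches its loss plateau in a few seconds. A mini-batch path
  (`batch_size`) is provided and reaches the same plateau.
* **Initialization.** Fan-in-scaled Gaussian (He) weights with an explicit
  seed; biases zero. Any standard scheme works; the seed, not the scheme,
  carries the reproducibility contract.
* **Plateau detection.** With `early_stop = TRUE` training stops once the
  loss range over the last 50 epochs falls below $10^{-4}$. At the study
  conditions this triggers near epoch 430, far below the nominal 5000-epoch
  budget, with accuracy and RMSE indistinguishable from longer runs.
* **Validation.** 20% of the sampled pairs are held out per epoch for the
  validation accuracy curve.

### What "accuracy" can and cannot reach

The sampled label is *stochastic*: for an interior room state every one of
its 9 successors is equally likely. No predictor can beat the mean over
inputs of the largest conditional successor probability — the Bayes
ceiling, $\approx 0.1344$ for the room (brute force over all 100 cells) and
$\approx 0.1167$ for the language (question words have 5 successors, all
other input classes 10). Two consequences matter for interpretation:

* Reported plateau accuracy is measured on *held-out* pairs (a large freshly
  sampled test set). Its expectation is the Bayes ceiling. The accuracy on
  the training pairs themselves keeps creeping above the ceiling
  ($\approx 0.19$ at the spatial plateau) because the network also fits the
  multinomial sampling noise of the finite training sample — a
  finite-sample artifact, not learning.
* Chance level is $1/N$: 0.01 spatial, 0.025 language.

The predicted-vs-analytic transition-matrix RMSE decreases with sample size
(tested at 500 / 2,000 / 10,000 pairs) and is below 0.02 at the study's
10,000 pairs.

## The navigation agent

`train_agent()` implements a compact deep Q-network: one-hot state in, ReLU
hidden layer, one output per action. The action space is fixed at the 9
compass moves (8 directions + stay); choosing a wall or off-grid move ends
the episode with a penalty, which stands in for a variable-arity action set.
Defaults follow the study conditions: 10,000 environment steps, 300 uniform
random warmup steps, Adam at 0.001, 30 steps per episode, greedy policy
(exploration comes from random episode starts; an $\varepsilon$-greedy
option exists but is off). Values the study leaves open are set once and
exposed in `agent_config()`: $+10$ at the food trays, $-1$ for a wall
choice, 0 per step, Q-discount 0.9, replay buffer of 2,000 transitions,
batch 32, target-network refresh every 100 steps. Under these conditions the
mean episode reward climbs from about $-0.8$ (frequent wall hits) to a
steady $+10$ (reliable tray-finding) well before episode 600.

`action_distribution()` exposes the softmax (temperature 1) over the action
outputs; `extend_action_probs_to_states()` places those probabilities onto
the cells the actions reach. Mass directed at walls is masked and the row
renormalized by default, keeping the policy transition matrix row-stochastic
so it can be pushed through `successor_matrix()`. Both the policy-weighted
SR and the reward-free random-walk SR (`maze_ground_truth_sr()`) are
provided; which of the two a given figure treats as "ground truth" is a
modelling choice, so the package computes both and leaves the comparison to
the analyst.

## Analyses

**Eigenmaps.** `eigenmaps_of_sr()` eigendecomposes $M$, sorts by the real
part of the eigenvalue (descending by default — coarse maps first; the
ascending option exists) and reshapes the real parts of the eigenvectors
onto the lattice. Random-walk SR matrices are similar to symmetric matrices,
so the spectrum is real up to numerical noise; near-degenerate pairs can mix
within their eigenspace, which is visible as rotated versions of the same
grid pattern. On a ring (periodic domain) the eigenvectors are exactly the
discrete Fourier modes. On the bounded room they are half-cosine standing
waves, so spatial frequency is measured in the DCT basis
(`dominant_spatial_frequency(..., basis = "dct")`); the plain-FFT basis is
kept for periodic domains. Mesh size shrinks as the eigenvalue falls — a
strong rank trend (Spearman $\approx 0.996$ over the first 30 maps) — but it
is *not* strictly monotone: the walk's eigenvalue is a separable function of
the per-axis wave numbers, not of their radial frequency, and e.g. the
$(3,3)$ mode outranks the $(1,4)$ mode while carrying the larger radius.
The package asserts the trend, and documents the strict ordering as false.

**MDS.** `mds_embed()` offers classical (Torgerson) scaling — deterministic,
double-centered eigendecomposition — and a stress-minimizing refinement:
metric SMACOF majorization started from the classical solution, which
guarantees the final stress never exceeds the classical one. Duplicate rows
(the within-class-identical TP rows) are handled naturally by both. Two
caveats discovered by computation and worth knowing:

* The five distinct TP class rows are mutually orthogonal with nearly equal
  norms; the double-centered Gram spectrum is $(1, 1, 0.606, 0.206)$ and the
  degenerate principal plane maps the noun row (all zero) and the pronoun
  row to the *same* point. Classical MDS of the TP rows therefore shows 4
  locations, not 5; the stress refinement separates all five classes while
  keeping within-class spread at zero.
* SR rows at $\gamma = 1, h = 2$ are $e_w + (T + T^2)_w$: the identity term
  puts every same-class pair at distance $\sqrt 2$, comparable to the
  between-class distances ($\approx 1.4$). Word classes consequently overlap
  in any distance-faithful embedding of the ground-truth SR — k-means purity
  is about 0.5–0.65 in 2D (and 0.43 on the raw 40-D rows). The class
  structure is still fully recoverable (purity 1.0) from the classical
  embedding, which projects the isotropic identity component out. This is
  the quantitative face of "SR clusters are less dense and closer together
  than TP clusters".

**Purity.** `cluster_purity()` runs multi-restart k-means on the embedding
and reports the fraction of items whose cluster majority label matches their
own, ties breaking to the lexicographically smaller label. Coincident
points (up to a relative $10^{-6}$) are deduplicated first, since k-means
cannot seed distinct centers from them.

## The synthetic-data generators and their limits

All data are generated in code; the generators *are* the study conditions.
`sample_state_pairs()` draws input states uniformly over allowed cells
(walls excluded) and successors uniformly over the neighborhood — matching
the idealized uniform-walk $T$, with no path continuity between consecutive
pairs, no heading, no sensory noise. `sample_word_pairs()` draws a rule,
then an adjacent class pair, then words uniformly — transitions, not whole
sentences, so input-class frequencies are fixed by rule structure
(adjectives $\tfrac13$, pronouns $\tfrac13$, verbs $\tfrac16$, question
words $\tfrac16$); generating full sentences instead would shift these
weights slightly (and accuracy by $< 0.03$) without changing the support.
Passing tests on these data show that the architecture recovers transition
structure from clean categorical samples; they say nothing about continuous
space, egocentric motion, real grammar, or noisy observations.

Problem sizes throughout (100/225/40 states, 10,000/5,000 pairs, 10,000 RL
steps) are the study conditions themselves; the test suite reuses single
training runs where several properties are checked against the same fit.

## Numerical conventions

* States are 1-based, row-major over the full lattice; walls keep their
  indices so any length-$N$ vector reshapes directly onto the room
  (`state_matrix()`).
* Wall and terminal (noun) rows of $T$ are all-zero and propagate as zeros
  through the SR power series; nothing is renormalized.
* $\gamma = 1$ with a finite horizon (10 for the spatial maps, 2 for the
  language SR) is the default; the infinite horizon demands $\gamma < 1$
  and errors otherwise.
* Softmax is computed with the row-max subtracted; degenerate MDS input
  (all rows identical) warns and returns all points at the origin.
* Diagonal moves across wall corners are allowed (pure 8-connectivity); the
  maze topology makes this choice immaterial for reachability.

## Known limitations

* The fixed 9-action DQN head plus termination-on-wall is one of several
  reasonable readings of a variable-arity action space; policies that would
  exploit wall-adjacency structure differently are out of reach.
* Learned-SR eigenmaps inherit softmax noise; their fine-scale maps mix
  earlier than the analytic ones.
* No TD-style online SR updating, feature-based SR, or multi-scale SR
  hierarchies: the package computes SR matrices from learned or analytic
  transition models only.
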