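---
title: "Context-dependent HMM recognition of eye-motion sequences: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Context-dependent HMM recognition of eye-motion sequences: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eogdeco)
```

## The problem

People who retain only eye movement — late-stage ALS being the canonical
case — can communicate by moving their gaze in agreed patterns.
Electrooculography (EOG) measures gaze through the corneoretinal
potential: the eyeball is an electrical dipole (cornea positive), and
electrodes on the skin around the eyes pick up a voltage that tracks gaze
direction, roughly 290–1100 µV per radian of deflection depending on the
person and electrode contact, with signal energy essentially below 30 Hz.

`eogdeco` implements a full recognizer for *continuous* sequences of the
five gaze motions up, down, left, right and center, mapped to Kana
characters by a fixed input protocol (four motions per basic character,
mark + base code for voiced characters).  The difficulty is speed:
fluent users chain motions so quickly that adjacent motions fuse — the
gaze never settles, and the waveform of a motion depends heavily on what
preceded and follows it.  A context-independent model of each motion must
average over all of these shapes and loses the boundaries.

## The model

Each modeling unit is a 4-state left-to-right hidden Markov model with
diagonal-covariance Gaussian-mixture emissions over the six raw channel
values (or the 2-D horizontal/vertical projection for comparisons).  The
units come in three granularities, in the triphone notation `p-t+s`:

* **mono**: one model per motion `t`;
* **bi**: one model per (preceding motion, motion) pair `p-t`;
* **tri**: one model per triple `p-t+s`.

Because the protocol forbids immediate repeats, a tri system has
4·5·4 = 80 interior triples plus 20 + 20 one-sided boundary units; at 4
states per model that is the 480-state untied inventory that
`count_state_inventory(5, 4)` enumerates.

Tri systems are made estimable by decision-tree state tying
(`tie_states()`): for every (target motion, state position) the states of
all context variants are pooled at the root of a binary tree and greedily
split on context questions ("is the left context *down*?", "is the right
context horizontal?"), choosing at each node the question with the
largest gain in pooled single-Gaussian log-likelihood, until the best
gain falls below a threshold.  Unseen context combinations are later
routed through the same trees, which is how the decoder synthesizes
models for cross-character contexts that never occurred in training.
Growth is threshold-independent (the threshold only decides where to
stop), so the tied-state count is exactly monotone in the threshold; by
default the threshold is auto-chosen so that about one quarter of the
seen states survive, and a split must leave at least 100 frames of
occupancy on each side so every tied state remains estimable.

Training (`train_system()`) follows the standard context-dependent
recipe: flat-started context-independent models are trained by embedded
Baum–Welch over each sequence's concatenated unit chain (no
pre-segmentation), cloned to the context units seen in training,
re-trained, tied (tri), re-trained again, and finally mixtures are grown
by perturbed-mean binary splitting along a schedule ending, at full
scale, at 16 components.  All probability computation is in the log
domain; the forward, forward–backward and Viterbi recursions run in
compiled code over explicit arc-list graphs.

As a last step, every context-dependent state is MAP-smoothed toward the
corresponding state of its motion's context-independent model
(`smooth_context_models()`, prior weight 100 frames): a context state
observed in only a handful of sequences moves most of the way back to
the robust pooled Gaussian, while a well-observed state barely moves.
This is the standard regularizer for sparsely observed context models —
the same prior-interpolation formula used for MAP user adaptation — and
without it desk-scale tri systems over-fit their sharp per-context
models and hallucinate extra characters during decoding.

## Decoding

`build_decoding_graph()` composes the unit models with the protocol: each
character expands to its chain of motion units; the first and last units
of each character are expanded into variants so that, with tri units, the
last unit of one character receives the next character's first motion as
its succeeding context and vice versa.  A character *n*-gram (orders
0–3, where 0 means no language model) adds log-probabilities at character
boundaries, and every emitted character also collects an additive
insertion penalty.  The search is exact Viterbi over the composed graph
(token passing); beam pruning is available but off by default.
Tie-breaking between equal-scoring paths follows arc construction order,
in which characters are sorted lexicographically.

The insertion penalty matters more for context-dependent systems than for
mono systems: several hundred sharp context models give the search many
opportunities to explain a stretch of signal as a quilt of spurious extra
characters, each locally slightly better than the truth.  The experiment
harness therefore tunes the penalty per user and system on a small
held-out dev word set (never the test words), exactly as one tunes the
word insertion penalty of a speech recognizer.

## Language models

`train_ngram()` builds interpolated Witten–Bell character *n*-grams:

$$P(w \mid h) = \frac{c(h)}{c(h)+T(h)}\,\mathrm{ML}(w \mid h)
             + \frac{T(h)}{c(h)+T(h)}\,P(w \mid h^-),$$

with `c(h)` the history count, `T(h)` its distinct-continuation count,
and the recursion ending in the uniform distribution over the vocabulary
(70 Kana characters by default).  This form is exactly normalized and
maps directly onto the ARPA backoff format (`write_arpa()` /
`read_arpa()`), with back-off weight `T/(c+T)` and the unigram escape
mass carried by the conventional `<unk>` entry.  Perplexity is the
exponentiated mean negative log-probability per predicted symbol.  The
training text generator (`synthetic_kana_corpus()`) stands in for a large
licensed Kana corpus: it samples from a seeded Markov chain with
Zipf-weighted conditionals, so marginals are Zipf-like and higher-order
models have real structure to exploit.

## User adaptation

A user-independent model pools several users and degrades on a new user,
mainly through amplitude and speed differences.  Two standard remedies
are implemented.  Mean-MLLR (`mllr_adapt()`) estimates an affine
transform $\mu' = A\mu + b$ of all component means (one global regression
class by default) by maximum likelihood from forward–backward
occupancies; with diagonal covariances the solution decomposes row-wise
into $d$ small linear systems.  MAP adaptation (`map_adapt()`)
interpolates each component mean between its prior and the
occupancy-weighted adaptation-data mean with prior weight τ (default 10
frames): $\mu' = (\tau\mu_0 + \sum_t \gamma_t x_t)/(\tau + \sum_t
\gamma_t)$.  As τ → 0 this reaches the data means, as τ → ∞ it stays at
the prior, and in between each mean moves monotonically along that
segment.  Insertion-penalty tuning (`tune_insertion_penalty()`)
completes the adaptation suite, compensating for user-specific input
speed.

## Scoring

`align_and_count()` aligns hypothesis to reference by minimum edit
distance with unit costs and reports substitutions, deletions and
insertions; the character error rate is $\mathrm{CER} = 100\,(S+D+I)/N$
with $N$ the reference length, so insertion-heavy output can exceed
100%.  Corpus rates pool the counts over utterances (the speech-scoring
convention), never average per-utterance rates.  Ties in the alignment
are resolved substitution before deletion before insertion, which never
changes $S+D+I$.  Motion error rates use the same machinery over motion
labels.

## The synthetic world

No EOG recordings are distributed, so all experiments run on the
package's generator, which emulates the documented signal properties:

* a 2-D latent gaze state moving between unit-circle targets
  (up = (0, 1), left = (1, 0), ...) along logistic ramps;
* projection to six channels by the electrode geometry (CH1/CH6 above the
  eyes, CH3/CH4 below, CH2/CH5 at the temples), scaled by the user's
  amplitude (default 600 µV, constrained to the physiological
  290–1100 µV range);
* Gaussian measurement noise band-limited below 30 Hz (default 40 µV),
  plus an integrated random-walk electrode drift (default 20 µV/√s);
* sampling at 100 Hz, with 500 ms of "sil" (resting gaze) padding.

Three choices deserve justification because the sources state no values:

* **Saccade rise time 250 ms.**  At fast-input segment durations
  (~400 ms) the transition then spans most of a segment, so the shape of
  a motion carries its predecessor's imprint throughout — the documented
  behavior of real recordings of fast sequential input, where e.g. two
  "center" motions in different contexts have opposite gradients over
  their whole extent.  With a much shorter ramp the world degenerates:
  every motion settles to a clean hold, context becomes irrelevant, and
  context-independent models are unbeatable — a world without the
  phenomenon under study.
* **Per-motion endpoint jitter (15%) and speed jitter (20%).**
  Saccades under- and overshoot; without behavioral variability the
  synthetic task is solvable essentially perfectly by any model family.
* **Training units with designed coverage.**  One unit of training data
  is 22 sequences (4–8 motions each) built greedily to visit nearly all
  valid context triples, mirroring the recording protocol that makes
  context-dependent models estimable from few units.

What the generator does **not** emulate: eye blinks, muscle-potential
bursts, mains interference, electrode re-attachment offsets between
sessions, and the heavy-tailed artifact structure of real skin-electrode
recordings.  Synthetic error rates are therefore far lower than published
error rates on human data at comparable model granularity, and a green
ordering test establishes only that the *relative* behavior of the
systems (context beats no context, HMMs beat thresholding, adaptation
beats none) is reproduced, not any absolute accuracy.

## Numerical and design choices

* Diagonal covariances with a floor of 10⁻⁴ times the global per-channel
  variance; mixture splitting displaces means by ±0.2 standard
  deviations and halves weights, leaving the likelihood essentially
  unchanged at split time.
* Embedded training accepts partial-occupancy failure gracefully: a
  state starved below 10⁻² expected frames keeps its previous
  parameters with a warning, and advance probabilities are floored so no
  state can become absorbing.
* EM stops a mixture stage early when the per-frame corpus
  log-likelihood improves by less than 10⁻⁴.
* The tying gain uses pooled single-Gaussian sufficient statistics, the
  standard tractable surrogate for the exact mixture likelihood under
  re-clustering.
* Boundary units (with one context absent) answer "no" to every question
  about the missing side and ride the same trees.
* The desk-scale experiment defaults (5 users × 10 units, reduced
  character vocabularies, single-Gaussian emissions) keep a full
  reproduction within minutes on one CPU; every full-scale value (50
  units per user, 16-component mixtures, the complete 48 + 2 protocol)
  is a configuration away.

## Known limitations

* Cross-character context expansion assumes every protocol code starts
  with a non-center motion and ends in center (the default protocol's
  convention); loaded protocols violating it still decode, but boundary
  contexts then multiply.
* With very small training corpora, tri systems rely heavily on
  tying-tree synthesis for cross-boundary units and are sensitive to the
  insertion penalty; the harness's dev-set tuning addresses this but a
  severely mis-tuned penalty degrades context-dependent systems first.
* The decoder is offline and exact; the live partial-output behavior of
  the original interactive system is out of scope.
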