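# eogdeco

Recognition of continuous eye-motion sequences from electrooculography
(EOG), for eye-only text entry.

People who can move nothing but their eyes can write by moving their gaze
in agreed patterns.  EOG measures gaze through the corneoretinal
potential: skin electrodes around the eyes pick up roughly 290–1100 µV
per radian of gaze deflection (0–30 Hz), on six measurement channels.  An
input protocol maps each Kana character to a fixed code of four eye
motions over the alphabet {up, down, left, right, center} (voiced
characters prepend a four-motion modification mark).  The hard part is
speed: fluent users chain motions so fast that adjacent motions fuse, and
the waveform of a motion depends strongly on its neighbors.

`eogdeco` implements the full recognizer and its evaluation:

* **Context-dependent GMM-HMMs.**  Each unit is a 4-state left-to-right
  HMM with diagonal Gaussian-mixture emissions.  Units are
  context-independent (`t`), left-context (`p-t`), or full-context
  (`p-t+s`) — the eye-motion analogue of monophone/biphone/triphone
  modeling.  Tri-unit states (4 × (4·5·4 + 4·5 + 5·4) = 480 before
  tying) are shared by likelihood-driven decision trees over context
  questions, which also synthesize models for unseen contexts.
* **Training** by embedded Baum–Welch (flat start → clone → tie →
  re-estimate → mixture growth), with MAP smoothing of sparse context
  states toward their context-independent parents.
* **Decoding** by exact Viterbi over the protocol-composed graph with
  cross-character context expansion, an optional backoff character
  *n*-gram (interpolated Witten–Bell, ARPA I/O), a language-model weight
  and a per-character insertion penalty.
* **User adaptation**: mean-MLLR, MAP (`µ' = (τµ₀ + Σγx)/(τ + Σγ)`), and
  per-user insertion-penalty tuning.
* **A threshold baseline** (per-sample direction classification on the
  2-D horizontal/vertical signal, 1000 ms majority voting, event
  merging).
* **Scoring**: minimum-edit-distance alignment and the character/motion
  error rate `100·(S + D + I)/N`.
* **A synthetic EOG generator** (no recordings are distributed): latent
  2-D gaze with logistic saccade ramps, channel-geometry projection,
  band-limited noise, electrode drift, saccadic endpoint/speed
  variability, and designed-coverage training units of 22 sequences.

See the methods vignette (`vignettes/eogdeco-methods.Rmd`) for the models
and every calibration choice, with their rationale.

## A worked example

```r
library(eogdeco)

proto <- build_default_protocol(seed = 1)
proto
#> Kana input protocol: 48 basic characters, 2 marks, 25 derived (75 total)
char_to_motions("a", proto)
#> [1] "up"     "down"   "up"     "center"
char_to_motions("ga", proto)   # mark code + /ka/ code
#> [1] "right"  "left"   "down"   "center" "up"     "left"   "right"  "center"

# a synthetic user and three units of designed-coverage training data
profile <- eog_profile(amplitude_scale = 600, noise_std = 40)
set.seed(7)
train <- unlist(lapply(1:3, function(i) generate_training_unit(profile)),
                recursive = FALSE)

# train a tied tri-eye-motion system (single-Gaussian desk scale)
set <- train_system(train, "tri",
                    config = train_config(n_iterations = 3,
                                          mixture_schedule = 1))
set
#> HMM set: 125 units x 4 states, 100 pdfs (100 distinct), 6-dim, <=1 mixture components

# decode a two-character word from a fresh recording
word <- c("ga", "a")
rec <- generate_recording(word_to_motions(word, proto), profile, seed = 99)
graph <- build_decoding_graph(
  set, subset_protocol(proto, c("a", "ka", "e", "ko", "ga")), NULL, "tri")
hyp <- decode(six_channel_features(rec)$vectors, graph)
hyp
#> Hypothesis: ga a  (score -19077.48)

align_and_count(word, hyp$characters)
#> S=0 D=0 I=0 N=2  rate=0.0%
```

The recognizer recovered both characters of the 12-motion recording; the
error counts (substitutions, deletions, insertions over a reference of
N = 2 characters) pool across a corpus to give the character error rate.

The experiment harness reproduces the method comparisons at desk scale:
`run_baseline_comparison()` (threshold vs 2-/6-channel HMMs, motion error
rate), `run_unit_comparison()` (mono/bi/tri × n-gram order, CER), and
`run_adaptation_curve()` (no adaptation / MLLR / MAP / MAP + penalty
tuning on a user-independent model).

A thin command-line wrapper is installed as `exec/eogdeco`
(`simulate | train | decode | baseline | score | adapt | experiment`);
all artifacts are plain text (CSV/TSV/JSON/ARPA).

## Acceptance script

`scripts/acceptance.R` recomputes the package's externally checkable
quantity from scratch — the size of the untied context-dependent state
inventory for the five eye motions with 4-state models, by enumerating
the valid context units — and writes it as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
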