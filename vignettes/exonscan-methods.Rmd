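---
title: "Detecting exons from three-base periodicity: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting exons from three-base periodicity: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Protein-coding regions (exons) of eukaryotic genes show *three-base
periodicity* (TBP): because synonymous codons are not used uniformly
(codon bias), the nucleotide composition differs between the three codon
positions, which puts excess spectral power at period 3 inside coding
sequence and essentially none in introns. `exonscan` turns that physical
signal into a classifier: DNA is mapped to numeric tracks, a period-3
spectral-energy profile is computed, the profile is cut into fixed-size
frames, and a small convolutional network (CNN) labels each frame exonic
or intronic. The CNN's layer structure and hyperparameters are not chosen
by hand; they are found by the African Vulture Optimization Algorithm
(AVOA) minimizing the bit error rate (BER) on a validation split.

## Numeric mapping and the spectral front end

**Voss mapping.** A sequence over {A, C, G, T} becomes four binary
indicator tracks $u_\beta(x)$, $\beta \in \{A, C, G, T\}$; IUPAC ambiguity
codes become all-zero columns (kept strictly binary, tallied in the
result) rather than fractional mass.

**Gabor wavelet transform.** For each track, position $a$ and scale $b$:

$$U_\beta(a, b) = \sum_x u_\beta(x)\,
  e^{-\frac{(x-a)^2}{2b^2}}\, e^{j\omega_0 (x-a)},$$

a Gaussian window of width $b$ modulating a complex exponential at the
period-3 angular frequency $\omega_0 = 2\pi/3$ per sample. Evaluating one
fixed frequency across many scales is what frees the detector from the
fixed-window compromise of the classical short-time DFT: narrow scales
resolve short exons, wide scales integrate long ones. The per-position
spectrum sums $|U_\beta(a,b)|^2$ over the four tracks and then reduces
over scales.

Numerical choices, all config-exposed:

* **Envelope sign.** The decaying Gaussian $e^{-(x-a)^2/(2b^2)}$ is used;
  a positive exponent diverges and admits no transform.
* **Frequency convention.** $\omega_0 = 2\pi/3$ *per sample*, so period 3
  is targeted independent of sequence length (the DFT-bin phrasing
  "$N/3$" pins the same periodicity only for one fixed window length).
* **Scale grid.** 24 logarithmically spaced scales $b \in [9, 400]$
  samples — roughly the span of very short to very long exon widths.
* **Scale reduction.** `max` over scales by default (the best response
  across scales, the usual multiresolution read-out); `sum` pools instead.
* **Truncation.** Kernels are truncated at $\pm 4b$ (envelope mass beyond
  that is below $3\cdot10^{-4}$); positions beyond the sequence edge
  contribute zero (plain truncation, no renormalization).
* **Implementation.** Coefficients are computed by FFT cross-correlation
  and checked in the tests against a literal double-loop summation oracle
  to $10^{-9}$ relative error.

The classical **ST-DFT** baseline (rectangular window, default 351
samples, squared modulus at the period-3 bin, summed over tracks) is
included under the same profile interface for comparisons.

## From profiles to a dataset

Profiles are min-max normalized to $[0, 1]$ per sequence (a constant
profile maps to zeros). The normalized profile is then *separated by
class first*: the positions inside annotated exons form the periodic
stream, the rest the non-periodic stream, and each stream is cut
independently into frames of 256 samples with an overlap of 100 (hop
156), each reshaped row-major to a 16×16 image. Framing after separation
means every frame is class-pure; the alternative — sliding a window over
the whole profile and labeling each frame by 50% majority exon coverage —
is also provided (`extract_frames()`, `framing = "sliding"`). The
sliding variant is the more realistic deployment mode for scanning an
unannotated genome, but it necessarily creates boundary frames whose
label is ambiguous; in our experiments it caps held-out accuracy around
0.90, while per-class framing removes that ambiguity from the learning
task.

Frames are shuffled and split 80/20, stratified by class, with the
training size exactly $\lfloor 0.8 N \rfloor$ (this floor rule uniquely
reproduces the reference splits 8885 → 7108/1777 and
14164 → 11331/2833).

## The search space: genotypes and hyperparameters

A candidate network is an integer triple $(c, p, f)$ — counts of
convolutional, pooling and fully connected layers — with every count at
least 1 and total layer count in $[3, 11]$. Decoding places a convolution
first, the fully connected layers contiguously last (the output layer
fixed at 2 units), and interleaves the remaining conv blocks and poolings
at seeded-uniform random admissible positions. Every convolution carries
batch normalization and a ReLU, and counts as 3 layers; pooling and
fully connected layers count 1 each, so a decoded stack has $3c + p + f$
layers — the convention that reproduces the published 12-layer
$(3,1,2)$ and 17-layer $(4,3,2)$ reference architectures.

The free hyperparameters form a vector of length $m = 2c + p + h$ with
$h = f - 1$ (per convolution: filter count in {8, 16, 32} and filter size
in {3, 5, 7}; per pooling: kernel size in [2, 5]; per hidden FC layer:
units in [10, 1024]), plus two appended slots for the optimizer
(adam / sgdm / rmsprop) and the mini-batch size ({8, 16, 32, 64, 128}).
Continuous AVOA positions are clamped to their ranges and rounded to the
nearest admissible value (idempotent on admissible vectors).

Spatially invalid stacks (pooling below 1×1) are *repaired*, not
rejected: offending poolings are removed right-most first and logged.
Repair keeps the search space connected and the objective total; a
worst-fitness penalty would instead create plateaus of dead candidates.

## The optimizer

AVOA is a population metaheuristic governed by a "satiety" scalar

$$u = h\left(\sin^w\!\tfrac{\pi t}{2} + \cos\tfrac{\pi t}{2} - 1\right),
\qquad F = (2\,\mathrm{rand}_1 + 1)\, z_1 (1 - t) + u,$$

with $t$ the iteration fraction, $w = 2.5$, $h \sim U[-2, 2]$,
$z_1 \sim U[-1, 1]$. $|F| \ge 1$ triggers exploration (encircling a
roulette-selected group best, or a jump toward a random point of the
box); $0.5 \le |F| < 1$ a siege / rotating-flight phase; $|F| < 0.5$
accumulation around the two group bests or a Levy-flight scatter
(Mantegna's algorithm, stability 1.5). $F$ is exactly 0 at the final
iteration. Reference settings: population 10, 20 iterations,
$Q_1/Q_2/Q_3 = 0.6/0.4/0.6$, selection weights $L_1/L_2 = 0.8/0.2$.

Design points where the printed equations needed a decision:

* The printed selection rule compares a fitness ratio with $L_1, L_2$ in
  a way that does not type-check; the two group bests are selected by a
  two-arm roulette with weights $(L_1, L_2)$, with the fitness-share
  normalization $q_i = F_i / \sum_j F_j$ available as an alternative mode.
* The accumulation move
  $\tfrac12[BV_1 + BV_2 - (\frac{BV_1 Q}{BV_1 - Q^2} +
  \frac{BV_2 Q}{BV_2 - Q^2})F]$ is implemented as printed; note it fixes
  $Q$ only at $F = 0$. Non-finite components (degenerate denominators)
  fall back to the current position before clamping.
* The encircling coefficient $T$ is drawn per dimension from $U[0, 2]$.
* $|F| = 1$ exactly is assigned to exploration (the phases must
  partition).
* Positions are clamped (not reflected) to the box after every move.
* Candidates whose objective fails (e.g. an untrainable architecture)
  absorb the worst finite fitness seen so far, keeping the population
  size fixed.

Elitism is enforced through global-best bookkeeping, so the reported
best-fitness trace is non-increasing by construction.

## Training and the three-stage procedure

The CNN engine realizes a decoded plan layer-for-layer on 16×16×1 input:
"same"-padded stride-1 convolutions (only pooling changes the spatial
size, mirroring the repair rule's dimension model), per-channel batch
normalization (momentum 0.9, $\epsilon = 10^{-5}$), ReLU, max pooling
with kernel = stride, fully connected layers (hidden ones ReLU), softmax
cross-entropy. He-normal initialization, fixed learning rate 0.001,
10 epochs per stage at reference settings. Convolutions are evaluated as
im2col gathers plus one BLAS product; the optimizer updates (adam, SGD
with momentum 0.9, RMSprop) are fused single-pass kernels.

The fit proceeds in three stages, all minimizing BER
$= (FP + FN)/\text{total} = 1 - \text{accuracy}$:

1. **Architecture search** over genotypes, each candidate trained briefly
   with fixed defaults (8 filters of 3×3, pool 2, hidden 1024, adam,
   batch 32) and scored on a validation subset (a stratified 20% carve-out
   of the training split — never the held-out test set, which would leak).
2. **Hyperparameter search** over the winner's $m + 2$ vector, the
   incumbent defaults seeded into the initial population so stage 2 can
   only improve on stage 1.
3. **Final training** of the winning configuration on the full training
   split, evaluated once on the held-out 20%.

Candidate fitness is a *pure function of the candidate and the dataset*:
the validation carve-out, layer placement, weight initialization and
batch shuffling during evaluations are seeded from content hashes rather
than the run seed. This removes evaluation noise between identical
candidates (so the optimizer compares architectures, not lucky
initializations), and makes repeated evaluations cacheable — AVOA
revisits integer genotypes constantly. The stage-3 training is seeded by
the run seed, so repeating the fit under different seeds still measures
the variability of the whole procedure.

## What the synthetic generator emulates — and what it does not

Real benchmark corpora for this task are gene sets with curated exon
annotations; they are not redistributable here, so the package ships a
generator that reproduces the *mechanism* the detector exploits: exons
are concatenations of codons drawn from a 64-codon distribution
$(1 - s)\,\mathrm{uniform} + s\,\mathrm{uniform(preferred)}$ with one
fixed preferred codon per amino-acid class, introns are i.i.d.
nucleotides at a chosen GC content. The bias knob $s$ moves continuously
from no TBP ($s = 0$, exons statistically identical to introns) to
maximal TBP ($s = 1$).

Defaults, chosen once as the package's study conditions: bias 0.9,
GC 0.5, 3–5 exons per sequence, exon lengths 300–600 bp (multiples of 3,
so each exon spans at least one 256-sample frame), introns 600–1500 bp
(coding fraction ≈ 30%). Not emulated: splice-site motifs, isochore GC
structure, repeats, overlapping genes, sequencing noise. Passing tests on
this generator therefore show that the pipeline recovers TBP where it
exists by construction — they do not certify accuracy on real genomes,
where TBP strength varies along sequences and annotation itself is
imperfect.

## Problem sizes used by the tests and the acceptance script

Desk-scale experiments use ~48 synthetic sequences (≈ 2000 frames,
≈ 330 kb), searches with population 6 and 5 iterations at 2 training
epochs per candidate evaluation, and 10 final epochs; the optimizer
benchmark uses the 5-D sphere with population 20 and 100 iterations.
These sizes keep a full multi-seed experiment reproducible on a single
CPU while leaving every stage's logic identical to the reference
settings (population 10, 20 iterations, 10 epochs per stage), which are
the package defaults.

## Known limitations

* The per-class framing used for training assumes annotations; scanning
  an unannotated genome uses the sliding mode, whose boundary frames are
  intrinsically ambiguous near 50% coverage.
* Profiles are normalized per sequence; a sequence with no coding signal
  still maps its noise floor onto $[0, 1]$, so cross-sequence score
  calibration is not guaranteed.
* The CNN engine is deliberately minimal (no dropout, schedules, early
  stopping, skip connections) — faithful to the reference procedure, not
  a general deep-learning framework.
* The printed rotating-flight and accumulation moves are kept as printed
  for fidelity; the original-algorithm rotating form is available via
  `avoa_config(rotating = "original")`.
* An "approximation correlation" summary statistic seen in some reports
  of this task has no published formula and is deliberately not
  implemented; `metrics_report()` is the extension point for
  user-supplied metrics.
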