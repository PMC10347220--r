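---
title: "Multimodal CT + indicator fusion: model, assumptions and design choices"
author: "scanfuse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal CT + indicator fusion: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

A CT examination produces a variable-length stack of 150–400 grayscale
slices; alongside it a patient contributes a fixed vector of 14 clinical
indicators (two serology channels such as CRP and ESR, lesion site, sex,
age, and nine binary comorbidity flags), all normalized to $[0,1]$.  The
task is scan-level binary diagnosis.  The two modalities are badly
mismatched: the image stack is large and noisy, the indicator vector is
tiny and comparatively clean, so a naive bidirectional fusion overfits the
indicators and under-uses the images.  `scanfuse` implements a pipeline
built around three ideas: slice sampling, one-way cross-modal attention,
and graph-based aggregation of slice features.

# The model

## Slice sampling

A scan of $N$ slices is reduced to exactly $N_S$ slices.  The default
strategy partitions the index range $0..N-1$ into $N_S$ contiguous groups
(sizes differing by at most one; when $N \bmod N_S \ne 0$ the remainder
goes to the earliest groups, an arbitrary but fixed convention) and draws
one slice uniformly at random within each group.  Every slice has
inclusion probability $1/|\text{group}|>0$, so across training epochs the
whole stack is eventually seen, while each individual draw stays evenly
spread along the scan axis.  Three ablation baselines are provided:
equally spaced (`round(i*N/NS)`), equally spaced with one shared random
offset inside the first stride, and uniform sampling without replacement.
Stacks shorter than $N_S$ are rejected rather than padded — clinical
stacks (150+) are always far longer than the sample size.
At evaluation time the draw uses a fixed seed so that reported metrics
are reproducible; during training a fresh draw is taken every epoch.

## Image backbone and Unidirectional Selective Attention

Each sampled slice is split into square patches, linearly embedded, and
passed through four transformer stages.  Self-attention is restricted to
tokens of the same slice; between stages a $2\times2$ patch merge
quarters the token count and a linear map doubles the channel width
(widths 32/64/128/256 in the CPU-scale configuration, 64/128/256/512 in
the full one).  At the end of every stage each slice's tokens are
mean-pooled into one feature vector per slice.

The indicator vector is first encoded by a linear layer (kept at width
14, then lifted to the stage-1 width) into a "text" feature $F_T$.  At
each stage a Unidirectional Selective Attention (USA) block lets $F_T$
query the pooled slice features: the single query is built from $F_T$
alone, keys and values from the concatenation $[F_T, F^I_1..F^I_N]$, and
multi-head scaled-dot-product attention (scale $1/\sqrt{d_h}$) updates
$F_T$ through a pre-norm residual block with a 2-layer GeLU MLP.  The
image features are *never* written to: information flows one way, from
the image stream into the indicator stream.  This is an invariant the
test suite checks bit-for-bit by perturbing the indicators and diffing
the image stream at every stage.

The per-stage block layout (pre-norm residuals, one USA block per stage,
mean-pooling over tokens, an affine re-projection of $F_T$ between
stages) fills in details the architecture sketch leaves open; they are
the standard transformer conventions.

## GCN feature fusion

The stage-4 per-slice features $F^1 \in \mathbb{R}^{N\times d}$ become
nodes of a graph.  For every ordered pair the edge scorer
$\Omega$ — a 3-layer GeLU MLP — maps
$g_{ij} = [F_i, F_j, \lVert F_i - F_j\rVert^2]$ to a scalar $S_{ij}$.
The dense $S$ is sparsified by k-nearest neighbours *in slice-index
distance* (k = 2 by default): each node keeps its k index-closest
neighbours, ties toward the smaller index.  Reading the neighbourhood in
index space (adjacent slices) rather than feature space follows the
anatomical prior that neighbouring slices image the same structures; it
also keeps the graph topology stable across training.  Because
$\Omega(g_{ij}) \ne \Omega(g_{ji})$ in general but the graph is
undirected, the directed weights are symmetrized by the elementwise
maximum over the union of supports, so an edge proposed by either
endpoint survives.  The diagonal stays empty: the GCN residual plays the
self-connection role.

One fusion stage then computes

$$F_{mid} = \Gamma(A\,\mathrm{LN}(F))\,W + F,\qquad
  \Gamma(\cdot) = \mathrm{GeLU}(\mathrm{LN}(\cdot))$$

with a per-stage learned $d\times d$ matrix $W$ ($\Gamma$ itself carries
no affine map beyond the layer norm).  By default each adjacency row is
divided by its neighbour count before aggregation; the raw form is
available via `gcnNormalize = "none"`.  Normalization stabilizes the
aggregation scale when node degrees differ after symmetrization and is
the one deliberate departure from the plain formula, kept behind a flag.

Coarsening uses max-score feature sampling (FSA): a 2-layer GeLU MLP
$\Phi$ scores every node with a 2-vector; the node score is the maximum
entry; the $M = \lfloor n/2 \rfloor$ highest-scoring nodes are kept *in
their original slice order* (ties toward the smallest position), so
index-KNN stays meaningful at the next stage.  The max-entry score
follows the worst-slice logic of the diagnosis itself: a scan is positive
if any slice looks positive.  Three stages take 64 sampled slices through
node counts $64 \to 32 \to 16 \to 8$; the fused feature $f_{out}$ is the
mean of the survivors (the readout is not specified by the architecture
sketch; the mean is the symmetric default).  With odd counts
$M = \max(1, \lfloor n/2\rfloor)$, and the KNN k is capped at $n-1$ on
small graphs.

## Diagnosis head and loss

The diagnosis head is a linear 2-way classifier.  Its input is the
concatenation $[f_{out}, F_T]$ of the fused image feature with the final
text feature.  Feeding $f_{out}$ alone would make the prediction
provably independent of the indicators — the one-way flow guarantees the
image stream never absorbs them — which would contradict the observed
usefulness of the text modality in isolation; the concatenation is the
minimal head that lets both streams reach the output while preserving
one-way flow.

The training loss is

$$L = L_{CE}(A([f_{out}, F_T]), y) +
      \sum_{l} \sum_{j \in \text{selected}_l} L_{CE}(\Phi(F^l_{mid,j}), y)$$

the scan label applied to every *selected* node's score vector, summed
(not averaged) over nodes and stages, as the loss is written; an
`selectLoss = "all"` and a mean-reduction variant are config-gated.  The
select term supervises $\Phi$ to score label-consistent nodes highly and
simultaneously shapes the per-slice features.

## Optimization

AdamW (decoupled weight decay 0.01 applied to weight matrices only),
learning rate warmed up linearly to its peak over the first 5 epochs and
decayed to `1e-6` on a cosine schedule; the closed form is exposed as
`lrSchedule()` and its endpoint values are asserted in the tests.  The
full-size configuration is meant for long schedules (200 epochs at peak
`1e-4`, 64 slices per scan at 224×224); the CPU-scale runs in this
package use the toy configuration below with a peak of `5e-4` (a small
model trained few epochs needs a hotter peak) and global gradient-norm
clipping at 1.0.  Augmentation:
horizontal flip, rotation within ±10°, additive pixel noise, Gaussian
jitter on the continuous indicator channels and random flips of the
binary channels, plus dropout on the head input.  The indicator-side
augmentation matters on very small training sets: 14 clean numbers
uniquely identify a training scan, and without jitter the head happily
memorizes them instead of learning the class-conditional shift.

All forward/backward passes run on a small reverse-mode autodiff core
written for this package (dense base-R matrices, fused tape nodes for
attention); its gradients are validated against central finite
differences for every operator and for the complete model loss.

# The synthetic generator

Clinical scans cannot ship with the package, so `synthSpec()` +
`generateSyntheticScans()` emulate the data's *structure*: a smoothed
ellipse phantom with low-frequency texture and pixel noise
(sd 0.08); in positive scans a Gaussian blob (peak intensity 0.35,
radius 10–18% of the field) added over a contiguous window covering 30%
of the slices at a fixed in-plane position; two serology-like channels
shifted upward by 0.25 for positives (base 0.30, sd 0.12); nine binary
flags at rate 0.2 for negatives vs 0.5 for positives; age, sex and site
uninformative.  Slice counts are uniform in a configurable range
(default 150–400).  Setting every effect size to zero yields the null
generator: classes become statistically identical, and the generator
consumes the identical RNG stream for any effect sizes, so the null and
planted datasets differ exactly by the planted signal.

What the generator does *not* emulate: anatomy, Hounsfield calibration,
scanner artefacts, correlated indicator panels, class imbalance, or
lesions that change shape across slices.  A passing recovery test
therefore shows the *pipeline* can find a planted multimodal signal at
this size and noise level — not that it reaches clinical performance.

# Problem sizes used by the tests

The CPU-scale ("toy") configuration used by the end-to-end tests:
64×64 slices, patch 8, widths 32/64/128/256, depths 1/1/1/1, 16 slices
sampled per scan, 40 training and 20 held-out scans with slice counts
80–160, 30 epochs, batch 4.  These sizes were chosen so a full recovery
run (planted-signal training plus the matched null run) completes in
minutes on one CPU while leaving the architecture untouched.  Unit tests
run the same code at widths 4–16 on 16×16 images.

# Numerical choices

* GeLU is the exact $x\,\Phi(x)$ form (normal CDF), not the tanh
  approximation; its derivative $\Phi(x) + x\,\phi(x)$ is used in the
  backward pass.
* Layer norm uses $\varepsilon = 10^{-5}$ inside the square root.
* Softmax and cross-entropy subtract the row maximum before
  exponentiation.
* The symmetrization-by-maximum is implemented with a $-10^{30}$
  sentinel on non-edges so that the maximum over the support union is
  exact; gradients follow the argmax branch (ties to the first
  argument).
* Tie-breaks are deterministic everywhere: smallest slice index (KNN),
  smallest position (FSA top-M), stable order throughout.
* All randomness (weight init, sampling, augmentation, generator) is
  seeded; helpers restore the caller's RNG state.

# Known limitations

* The full-size configuration fixes the stage shape (widths doubling,
  tokens quartering) but leaves depths and widths as free choices; no
  particular parameter count is promised.
* Training in base R is CPU-bound; the package is sized for method
  study and testing, not for clinical-scale training.
* The FSA top-M selection is discrete: gradients reach only the selected
  nodes (plus all nodes through the edge scorer); differentiable
  relaxations are out of scope.
* AUC on 20 held-out scans has a granularity of 0.01 and a null standard
  deviation around 0.13; the stochastic end-to-end checks are therefore
  run under fixed seeds.
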