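# scanfuse

Scan-level binary diagnosis from two mismatched modalities: a
variable-length stack of CT slice images (150–400 per examination) and a
fixed 14-element vector of clinical indicators (serology, demographics,
comorbidity flags), all normalized to [0, 1]. The motivating use case is
periprosthetic joint infection, where CT evidence and biochemical results
must be read together, the image stack is large and noisy, and the
indicator vector is tiny and comparatively clean — a combination that
makes naive multimodal fusion overfit the indicators and ignore the
images.

`scanfuse` is an R implementation, self-contained down to the gradients
(a compact reverse-mode autodiff core over base-R matrices, validated
against finite differences), of a hierarchical fusion network with three
components:

1. **Grouped uniform-random slice sampling.** The `N` slice indices are
   split into `NS` contiguous groups (sizes differ by ≤ 1) and one slice
   is drawn uniformly per group — every draw is evenly spread along the
   scan, every slice has inclusion probability `1/|group|`, and fresh
   draws each epoch eventually use the whole stack. Equally-spaced,
   equally-spaced-random and plain random baselines are included.
2. **Unidirectional Selective Attention (USA).** At each backbone stage
   the indicator ("text") feature `F_T` issues a single multi-head
   attention query over `[F_T, F_I_1..F_I_N]`; only `F_T` is updated.
   Information flows one way — image → text — so no indicator
   perturbation can ever touch the image stream (asserted bit-for-bit in
   the tests).
3. **GCN feature fusion with max-score sampling (FSA).** Per-slice
   features become graph nodes; a 3-layer MLP Ω scores every ordered pair
   `g_ij = [F_i, F_j, ||F_i − F_j||²]`; the dense graph is sparsified to
   each node's k index-nearest neighbours (k = 2), symmetrized by
   elementwise maximum, and passed through a residual GCN block
   `F ← Γ(A·LN(F))·W + F` with `Γ = GeLU∘LN`. A 2-layer MLP Φ scores
   nodes; the `M = n/2` nodes with the highest max-entry survive each of
   three stages (64 → 32 → 16 → 8), and the survivors' mean is the fused
   feature `f_out`.

Training minimizes the joint loss
`L = CE(A([f_out, F_T]), y) + Σ_l Σ_{j∈selected} CE(Φ(F_mid,j^l), y)`
with AdamW, a 5-epoch linear warmup to the peak learning rate and cosine
decay to 1e-6. A synthetic phantom-scan generator (planted contiguous
lesion windows, class-shifted indicators, or a null variant with zero
effects) makes the whole pipeline testable without clinical data.

## Worked example

```r
library(scanfuse)

partitionGroups(10, 4)                 # contiguous groups, sizes 3,3,2,2
#> [[1]] 0 1 2   [[2]] 3 4 5   [[3]] 6 7   [[4]] 8 9
sampleSlices(12, 4, "equally_spaced")
#> [1] 0 3 6 9

spec <- synthSpec(nTrain = 8, nTest = 8, sliceRange = c(8L, 12L),
                  imageSize = 16L, seed = 3)
ds <- generateSyntheticScans(spec)
ds$train
#> ScanDataset: 8 scans (4 positive, 4 negative)

cfg <- hgtConfig(toy = TRUE, imageSize = 16L, patchSize = 2L,
                 widths = c(4L, 8L, 8L, 16L), depths = c(1L, 1L, 1L, 1L),
                 heads = c(2L, 2L, 2L, 2L), nSamples = 4L,
                 omegaHidden = c(8L, 6L), phiHidden = 8L)
model <- hgtModel(cfg, seed = 1)
model
#> HGTModel: 11743 parameters
#>   image 16x16, patch 2, widths 4/8/8/16, depths 1/1/1/1
#>   4 sampled slices, k=2, 3 fusion stages

fit <- trainHGT(model, ds$train, epochs = 8, batchSize = 4, lrMax = 2e-3,
                warmupEpochs = 2, seed = 1, evalData = ds$test)
fit$log[1:2, c("epoch", "lr", "loss", "diagnosisLoss", "selectLoss")]
#>   epoch    lr   loss diagnosisLoss selectLoss
#> 1     1 0.001 7.1113        1.3688     5.7425
#> 2     2 0.002 3.9881        0.7741     3.2140
fit$eval$acc; fit$eval$auc
#> [1] 0.625
#> [1] 0.5625
```

The log columns are the schedule's learning rate and the per-epoch mean
of the total, diagnosis and select loss components; `fit$eval` holds
held-out accuracy, AUC, confusion counts and throughput. (This miniature
16×16 run only demonstrates the interfaces; at the CPU-scale study
configuration — 64×64 slices, 16 sampled slices, 40 training scans, 30
epochs — the same pipeline reaches a held-out AUC above 0.9 on
planted-signal data, and chance on the matched null data.)

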