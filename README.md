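# dnnmapr

Tools for mapping the internal representations of artificial neural
networks onto measured neural responses, written for computational
neuroscientists who treat a network the way they treat a brain: present a
stimulus set, record the evoked activity, and ask what that activity
encodes.

Given (a) a layered feed-forward network, (b) an ordered stimulus set with
per-stimulus attributes, and (c) a response matrix **Y** (stimuli ×
measurement sites, e.g. image-evoked BOLD amplitudes per voxel), the
package supports the three standard analyses:

- **Encoding models** — for features **X** (summarized layer activations)
  and each site *y*, fit *y = Xβ + ε* with cross-validation (GLM/OLS,
  ridge, lasso per site; partial least squares jointly across sites).
  Held-out predictions are pooled over folds and each site is scored with
  the Pearson correlation *r*(y, ŷ) and explained variance. **Decoding
  models** run the same machinery in reverse (responses → labels or a
  continuous target), scored by accuracy or *r*.
- **Representational similarity analysis** — representational
  dissimilarity matrices *RDM(i, j) = d(xᵢ, xⱼ)* (Euclidean or 1 − Pearson
  *r*), compared across systems by Pearson/Spearman/Kendall correlation of
  their upper triangles, with stimulus-relabeling permutation tests. All
  permutation p-values use the add-one convention
  *p = (1 + #{null ≥ obs}) / (1 + n_perm)*.
- **Unit characterization** — top-stimulus ranking, input-gradient
  saliency maps (vanilla and guided), occlusion-based empirical receptive
  fields, channel/unit ablation, and optimal-stimulus synthesis by
  regularized gradient ascent.

The package also ships a deterministic fixture layer (toy networks with
known weights, synthetic stimuli, responses generated as *Y = F·W + ε*
with returned ground-truth *W*), file formats for every object (stimulus
CSV, mask CSV, activation HDF5, response matrices), and a command-line
interface. All channel and unit indices are **0-based** throughout the API
and the on-disk formats.

## Worked example

Scan a toy network for a stimulus set, generate linked synthetic responses
with known ground truth, fit a cross-validated encoding model, and compare
the two representational geometries:

```r
library(dnnmapr)

model <- makeToyNetwork(
  list(list(kind = "conv", out = 4, kernel = 3), list(kind = "relu"),
       list(kind = "pool", size = 2),
       list(kind = "conv", out = 3, kernel = 2), list(kind = "relu"),
       list(kind = "linear", out = 5)),
  inputShape = c(1L, 10L, 10L), seed = 3)
model
#> NetworkModel 'toynet', input [1 x 10 x 10]
#>   conv1 (conv) -> [4 x 8 x 8]
#>   relu1 (relu) -> [4 x 8 x 8]
#>   pool1 (pool) -> [4 x 4 x 4]
#>   conv2 (conv) -> [3 x 3 x 3]
#>   relu2 (relu) -> [3 x 3 x 3]
#>   fc1 (linear) -> [5]

stim  <- makeSyntheticStimuli(60, c(1, 10, 10), seed = 1, kind = "noise")
store <- extractActivations(model, stim, MaskSpec(fc1 = "all"))

## synthetic "brain": 4 sites, each a noisy linear readout of fc1 features
linked <- makeLinkedResponses(store, "fc1", nSites = 4, noiseSd = 0.2, seed = 2)
feats  <- summarizeActivation(store, "mean")$fc1
cv     <- makeFolds(60, "kfold", k = 10, seed = 7)
enc    <- fitUnivariateEncoding(feats, linked$responses, "glm", cv)
encodingScores(enc)
#>   site_id pearson_r explained_variance
#> 1 site001     0.547              0.280
#> 2 site002     0.481              0.212
#> 3 site003     0.896              0.802
#> 4 site004     0.874              0.764

rdmNet   <- computeRDM(feats, "correlation", stimIds = stimIds(store))
rdmBrain <- computeRDM(values(linked$responses), "correlation")
rdmPermutationTest(rdmNet, rdmBrain, "pearson", nPerm = 999, seed = 7)
#> PermutationResult: observed = 0.4412, p = 0.001 (999 permutations)
```

Per-site `pearson_r` is the pooled held-out correlation between measured
and predicted responses: sites 3–4 happen to draw strong linkage weights
relative to the noise and are predicted well, sites 1–2 less so. The RDM
comparison says the two systems share representational geometry
(*r* = 0.44) far beyond the stimulus-relabeling null (*p* = 0.001).

The same pipeline runs from the shell over files (see
`inst/scripts/dnnmap`):

```sh
dnnmap fixtures --out run --seed 7
dnnmap extract  --net run/net --stim run/stimuli.csv --mask run/mask.csv --out run/acts.h5
dnnmap summarize --act run/acts.h5 --method mean --out run
dnnmap encode   --x run/summary_conv2.csv --resp run/responses.csv --family glm --k 10 --seed 7 --out run/enc.json
```

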