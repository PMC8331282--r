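# ssfcm — semisupervised fuzzy c-means image segmentation

`ssfcm` is an R package for intensity-based segmentation of grayscale
images and volumes by fuzzy c-means clustering, aimed at medical-image
analysis settings (e.g. brain-tissue segmentation of MRI slices) where a
small number of pixels can be labeled in advance and should guide the
clustering of the rest.

## The model

Each of the *n* pixels *x<sub>k</sub>* holds a graded membership
*A<sub>ik</sub>* in each of *c* clusters (columns of the membership matrix
*U* sum to 1; fuzzifier fixed at *m* = 2).  With squared distances
*D²<sub>ik</sub>* = ‖*B<sub>i</sub>* − *x<sub>k</sub>*‖², the iteration
alternates

- membership update: *A<sub>ik</sub>* = 1 / Σ<sub>j</sub>
  (*D²<sub>ik</sub>* / *D²<sub>jk</sub>*)
- center update: *B<sub>i</sub>* = Σ<sub>k</sub> *A²<sub>ik</sub>*
  *x<sub>k</sub>* / Σ<sub>k</sub> *A²<sub>ik</sub>*

until ‖*U*<sup>(t)</sup> − *U*<sup>(t−1)</sup>‖ < ε (Chebyshev norm).
Partial labels enter through a labeled indicator *b<sub>k</sub>* and prior
memberships *f<sub>ik</sub>* with weight α.  Three modes are available:

| mode      | membership rule |
|-----------|-----------------|
| `fcm`     | plain FCM; supervision ignored |
| `ssfcm`   | *A′<sub>ik</sub>* = [*A<sub>ik</sub>* + α *f<sub>ik</sub> b<sub>k</sub>*] / (1+α), columns renormalized (default) |
| `pedrycz` | standard semisupervised closed form of Pedrycz & Waletzky, paired with its matching prototype update (monotone objective descent) |

The package also provides a seeded generator of ground-truthed brain-like
phantoms, permutation-matched accuracy and Dice evaluation, a benchmark
runner, and summary-statistic tests (pooled/Welch *t*, Pearson χ²) that
recompute a published clinical table from its printed group summaries.
See the methods vignette (`vignettes/ssfcm-methods.Rmd`) for the science
and the design choices.

## Worked example

```r
library(ssfcm)

spec <- phantom_spec(noise_sigma = 0.10, seed = 7)   # 128x128, 3 tissue classes
ph   <- generate_phantom(spec)
sup  <- sample_supervision(ph$truth, fraction = 0.05, seed = 7)
ex   <- extract_features(ph$image, mask = ph$truth > 0)

fit <- ssfcm(ex$features, 3L, mode = "ssfcm", supervision = sup,
             alpha = 1, seed = 7)
fit
#> Fuzzy c-means fit (mode = ssfcm )
#>   clusters:   3
#>   samples:    7972
#>   iterations: 54 (converged)
#>   centers:
#>        [,1]
#> [1,] 0.2602
#> [2,] 0.4889
#> [3,] 0.7470

map <- labels_to_map(hard_labels(fit$memberships), ex$index, ex$shape)
segmentation_accuracy(map, ph$truth)
#> [1] 78.02308

# plain FCM on the same input for comparison
fit0 <- ssfcm(ex$features, 3L, mode = "fcm", seed = 7)
map0 <- labels_to_map(hard_labels(fit0$memberships), ex$index, ex$shape)
segmentation_accuracy(map0, ph$truth)
#> [1] 74.19719
```

The three fitted centers sit near the nominal class intensities (0.30,
0.55, 0.80); labeling 5% of pixels lifts matched pixel accuracy by about 4
percentage points at this noise level.  The summary-statistic functions
work straight from published numbers:

```r
pooled_t(c(2721.42, 241.15, 38), c(2511.72, 203.36, 62))
#> t = 4.66057 ( pooled , df = 98 , p = 9.95e-06 )
chi2_2x2(1, 37, 13, 49)
#> chi2 = 6.57909 ( pearson-uncorrected , df = 1 , p = 0.01032 )
```

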