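# klfce

Fuzzy cluster ensembles via Kullback–Leibler divergence for noisy grayscale
image segmentation.

## What it does, and for whom

Noise makes single soft clusterers unreliable for image segmentation: fuzzy
c-means (FCM) ignores spatial context entirely, and each of its spatial
extensions has its own failure modes. `klfce` is for anyone segmenting noisy
grayscale images (synthetic phantoms, MR-like data) who wants the stability of
an *ensemble*: run several soft clusterers, then fuse their membership
matrices into one consensus partition.

The fusion treats each pixel's concatenated memberships as a discrete
probability vector and clusters those vectors by minimising

```
J = Σ_k Σ_i u_ik^m · D_KL( y_k ‖ o_i ),    Σ_i u_ik = 1,  Σ_j o_ij = 1,
```

where `y_k` is pixel *k*'s probability profile (the row-stochastic
concatenation of the `r` member partitions, divided by `r`), `o_i` are
consensus centers constrained to the probability simplex, `m > 1` is the
fuzzification coefficient, and `D_KL(p‖q) = Σ_j p_j log(p_j/q_j)`. Alternating
the two closed-form stationarity updates

```
o_ij = Σ_k u_ik^m y_kj / Σ_h Σ_k u_ik^m y_kh
u_ik = 1 / Σ_ℓ ( D_KL(y_k‖o_i) / D_KL(y_k‖o_ℓ) )^(1/(m−1))
```

gives the plain consensus (**FCE_KL**). The spatial variant (**FCE_sKL**)
additionally averages each pixel's membership with its neighbourhood mean on
every iteration (5×5 window by default), which suppresses isolated
noise-driven misclassifications. Hard labels come from per-pixel argmax,
scored against ground truth after optimal label alignment.

The package also provides the fully specified base clusterers (FCM and
spatial FCM at configurable windows), synthetic two-region and four-region
phantoms with Gaussian and Rician noise models, accuracy metrics (overall and
per-class Jaccard), file I/O for images/labels/memberships, a reproducible
experiment driver, and a small CLI (`inst/cli/klfce.R`).

## Worked example

Corrupt the 50×50 two-value phantom with 30% Gaussian noise and segment it
with the four-member spatial KL ensemble:

```r
library(klfce)

ph    <- make_two_value_phantom()                  # 50x50, intensities {0, 1}
noisy <- add_gaussian_noise(ph, 30, seed = 42)     # sigma = 0.30 x range
res   <- segment_ensemble(noisy, c = 2, method = "fce_skl", seed = 7)

rep <- evaluate_segmentation(res$labels, ph$labels)
rep$sa
#> [1] 0.9976
round(rep$per_class, 4)
#>      0      1
#> 0.9952 0.9952
sapply(res$partitions, function(U)
  segmentation_accuracy(align_labels(defuzzify(U, dim(noisy)), ph$labels), ph$labels))
#>   fcm_a   fcm_b sfcm_w3 sfcm_w5
#>  0.9544  0.9544  0.9892  0.9928
```

At this noise level the two plain FCM members misclassify ~4.6% of pixels and
the spatial members ~1%, while the consensus reaches SA = 0.9976 — the
ensemble beats every one of its members on the same image. `res$fit` carries
the soft memberships, the consensus centers and the objective trace (here 8
iterations to convergence).

For a whole benchmark grid use the experiment driver, which corrupts the
phantom once per cell and scores every method on the byte-identical image:

```r
cfg <- experiment_config(phantom = "two_value",
                         noise = list(gaussian = c(10, 20, 50)),
                         replicates = 5, seed = 1)
tab <- run_experiment(cfg)
attr(tab, "summary")   # mean ± sd accuracy per method and noise level
```

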