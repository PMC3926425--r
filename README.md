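# textsnake

Texture-guided active-contour segmentation and annotation of microscopy
images.

`textsnake` is for quantitative microscopy workflows — the motivating
application is kidney biopsy micrographs, where glomeruli and tubules must
be outlined, labeled (e.g. pathogenic vs. non-pathogenic) and measured —
in which a user supplies only a quick, rough outline of a structure and
the software must (i) refine the outline to the true boundary, (ii)
decide the structure's class, and (iii) measure its area in calibrated
units.

## Method

A closed parametric contour (snake) minimizes the classic energy

    E(v) = 1/2 ∫ ( α |∂v/∂s|² + β |∂²v/∂s²|² ) ds + ∫ P(v) ds

by greedy per-vertex window search. The external energy is composed as

    P(x) = −exp(−η·T(x)) · [ δ₁·e₁(x) + δ₂·e₂(x) ]

where `e₁` is the normalized gradient magnitude of the Gaussian-smoothed
image, `e₂` is an edge map derived from block-wise texture classification
(gray-level co-occurrence features → maximum-margin kernel classifier →
majority-vote denoising → binarization → Canny → Gaussian diffusion), and
`T` is the Euclidean distance transform of the user's rasterized initial
outline, so the snake is anchored near where the user pointed. The
classifier solves the soft-margin dual by a deterministic SMO; regions are
labeled by majority vote over the classified blocks inside the final mask.
Segmentation quality is scored by the Jaccard overlap ω = |A∩B| / |A∪B|.

Because no image corpus ships with the package, a synthetic phantom
generator produces deterministic benchmark images with compact
(glomerulus-like) and elongated (tubule-like) textured regions, faint
boundary arcs and background clutter — the regime in which texture
supervision matters. See the methods vignette
(`vignettes/textsnake-methods.Rmd`) for the model, parameters and design
rationale.

## Worked example

```r
library(textsnake)

cfg <- phantom_config()                      # benchmark-scale settings

# train a texture model on six annotated phantoms
training <- lapply(1:6, function(s) {
  p <- generate_phantom(phantom_preset("biopsy", seed = 1000 + s))
  list(image = p$image, annotations = p$annotations)
})
model <- train_model(training, cfg)

# a fresh phantom: rough outline -> refined, labeled, measured region
ph   <- generate_phantom(phantom_preset("biopsy", seed = 103))
init <- rough_contour(ph$masks[[1]], seed = 103)
reg  <- segment_supervised(ph$image, init, model, cfg)

jaccard(contour_to_mask(init, dim(ph$image)), ph$masks[[1]])
#> [1] 0.6822547
jaccard(reg$mask, ph$masks[[1]])
#> [1] 0.8770471
reg$label
#> [1] "tubulus_normal"
area(reg$mask, calibration(2))$physical    # µm², at 2 µm per pixel
#> [1] 17544
```

The rough outline overlaps the true region at ω ≈ 0.68; the supervised
snake refines it to ω ≈ 0.88 (on phantoms whose boundaries are deliberately
faint and cluttered) and labels it with the class that was planted in the
phantom. At 2 µm/px the measured area is ~17,500 µm².

## Command-line use

A thin CLI over the package functions is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "textsnake.R", package = "textsnake"))')" synth --n 3 --seed 7 --out phantoms/
```

Subcommands: `train`, `segment`, `evaluate`, `measure`, `synth`; run any
of them with `--help` for their options.
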