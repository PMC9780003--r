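# tonguetex

Tongue-texture classification for traditional Chinese medicine inspection:
is a tongue body **tough** (rough, firm texture), **tender** (delicate,
puffy) or **normal**? The texture signal lives on the tongue *body*, but
parts of the body are occluded by the whitish tongue *coating*, whose
edges and color break the continuity that texture classification relies
on. `tonguetex` implements the full pipeline that deals with this:

1. **Coating/body separation** — pixel colors on the tongue are modeled as
   a K-component Gaussian mixture, `p(x) = Σ_k ω_k N(x | μ_k, Σ_k)` with
   `Σ_k ω_k = 1`, fitted by EM; each tongue pixel is assigned by maximum
   posterior and the lighter (whitish) component becomes the coating mask.
2. **Body-patch harvesting** — sliding `n × n` windows (default 96) keep
   only crops whose body coverage strictly exceeds 80%, mirrored to double
   the corpus and split into training/validation sets.
3. **Coating inpainting** — a coarse-to-fine pair of convolutional
   generators fills the coating region: a coarse network makes a rough
   prediction; a refinement network combines a dilated-convolution branch
   with a **contextual attention** branch that copies feature patches from
   the known region by cosine-similarity softmax, trained with a spatially
   discounted L1 loss (`γ^l`, `γ = 0.99`, `l` = Chebyshev distance to the
   nearest known pixel).
4. **Classification** — a bottleneck residual network (depth 50/101 block
   plans; `1 + 3·(3+4+23+3) = 100` convolutional layers at depth 101)
   trained under a reduce-on-plateau schedule (lr 0.001, ×0.1 after 5
   stagnant epochs, early stop after 15), reporting per-class and overall
   accuracy `R/S`.

Clinical tongue datasets are private, so the package includes a
first-class synthetic generator: elliptical tongues whose body follows one
color Gaussian with class-conditional band-pass texture, whose coating
blobs follow a second, lighter Gaussian, and which emit ground-truth
body/coating masks — making every stage testable end to end.

The neural components (convolution kernels with im2col in C++, batch
normalization, residual blocks, the attention layer, Adam) are implemented
inside the package, so it runs with no deep-learning framework.

## Worked example

```r
library(tonguetex)

params <- synth_params(seed = 42)            # synthetic study conditions
sample <- generate_sample(params, "normal")  # image + ground-truth masks

sep <- separate_coating(sample$image, sample$tongue_mask, K = 2, seed = 1)
cat("estimated coating fraction:",
    round(sum(sep$coating_mask) / sum(sample$tongue_mask), 3), "\n")
cat("coating-mask IoU vs ground truth:",
    round(mask_iou(sep$coating_mask, sample$coating_mask), 3), "\n")
cat("EM iterations:", length(sep$model$log_likelihood_trace), "\n")

spec <- resnet_spec(depth = 101)
cat("conv layers (depth 101):", conv_layer_count(spec), "\n")
```

prints

```
estimated coating fraction: 0.2
coating-mask IoU vs ground truth: 1
EM iterations: 3
conv layers (depth 101): 100
```

The generator placed coating on 20% of the tongue; the two-component color
mixture recovered that mask exactly (IoU 1.0) in three EM iterations, and
the depth-101 block plan accounts for its 100 convolutional layers.

For the whole pipeline on a synthetic dataset:

```r
man <- generate_dataset(synth_params(image_size = c(96, 96),
                                     ellipse_axes = c(40, 34), seed = 9),
                        c(tough = 10, normal = 10, tender = 10), "data")
cfg <- pipeline_config(manifest = "data/manifest.csv", work_dir = "work",
                       seed = 1)
rec <- run_pipeline(cfg)       # separation -> patches -> inpainter ->
rec$report$overall_accuracy    # inpainting -> balance/split -> classifier
```

`compare_pretreatments(cfg)` trains two classifiers on the identical test
membership — one on the raw images, one on the inpainted ones — and
returns both accuracy reports side by side.

A thin command-line wrapper over these functions is installed at
`inst/scripts/tonguetex.R` (subcommands `separate`, `synth`, `run`,
`compare`).

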