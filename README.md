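# persal

Predicting *personal* interest from gaze and pupillometry in R.

Eye trackers report two things while a person views an image: where they
look and how wide their pupils are. Aggregated over many viewers, gaze
defines a **universal saliency map** (USM) — the parts of an image almost
everyone looks at. A single viewer's deviations from that consensus define
their **personalized saliency map** (PSM), and because pupils dilate when
people see something that interests them, pupil-diameter anomalies provide
per-image interest labels without asking the viewer anything. `persal`
implements this whole pipeline for researchers in visual attention,
pupillometry and gaze-based personalization:

- **Gaze I/O** — read/validate/write binocular eye-tracker CSV logs
  (timestamp, left/right gaze coordinates, left/right pupil diameter) and
  merge the two eyes into cyclopean samples.
- **Saliency maps** — fixation-count grids; separable truncated-Gaussian
  smoothing (reference parameters: 169×169 kernel, σ = 24 px at 1920×1080)
  normalized to [0, 1]; per-subject PSMs and aggregated USMs; bilinear
  resizing.
- **Interest vectors** — per-subject (optionally per-session-day)
  standardization of pupil diameters; a chi-squared(1) anomaly test on the
  squared Mahalanobis distance (for a scalar, z²) at significance α; a
  binary vector `I_n ∈ {0,1}^M` marking the images whose viewing dilated
  the subject's pupils.
- **Model** — a VGG16-style convolutional encoder (13 convs, 4 poolings)
  and mirrored decoder with a final 1-channel ReLU conv trained with MSE;
  the PSM variant inserts a user-encoding mechanism (Linear `M → C` plus a
  Transformer encoder over the single user token) and Transformer-decoder
  layers whose cross-attention uses the `(W·H) × C` image features as
  queries and the 1 × C user token as key/value. With one key the softmax
  saturates at 1, so attention broadcasts the value row — a property the
  tests pin down, along with its corollary that the query/key projections
  of a single-key block receive no gradient. A `channelScale` knob runs
  the identical graph from desk-scale widths up to the reference C = 512,
  M = 800, 4 encoder / 9 decoder layers, 256 heads. The network and its
  backpropagation are implemented in base R (im2col + BLAS).
- **Training** — Adam (lr 1e-5, batch 32) for the USM stage, AdamW
  (lr 1e-6, weight decay 0.05, batch 1) for the PSM stage, early stopping
  after 5 non-improving validation epochs, subject-stratified 6400/1600
  splits, and USM→PSM transfer initialization of the encoder/decoder.
- **Metrics** — NSS, CC, AUC-Borji (uniform-random negatives) and
  shuffled AUC (other-image fixation negatives, discounting central bias),
  plus map cosine similarity; all tested against brute-force oracles.
- **Synthetic data** — a seeded simulator with planted ground truth:
  central-bias gaze mixed with object pulls weighted by a subject ×
  category interest matrix, 300 samples per 5 s presentation, Gaussian
  baseline pupils with 2.5 SD dilation over a contiguous window on
  interesting images, and per-day baseline shifts for two-day subjects.

## Worked example

```r
library(persal)

world <- generateWorld(nSubjects = 3, nImages = 40, imageSize = c(160, 120), seed = 7)
log <- sampleGaze(world, subject = 1, image = 1)
log
#> GazeLog: subject s1, image img0001, day 1
#>   300 records (292 with at least one valid eye)

grid <- countFixations(mergeBinocular(log), 160, 120)
grid
#> CountGrid 160x120: 288 fixations (8 missing, 4 out of bounds dropped)
smoothToMap(grid, kernelSize = 21, sigma = 3)
#> SaliencyMap [PSM] 160x120, values in [0, 1]

pupils <- do.call(rbind, lapply(1:3, function(s)
  do.call(rbind, lapply(1:40, function(m) {
    lg <- sampleGaze(world, s, m)
    data.frame(subject_id = subjectId(lg), image_id = imageId(lg),
               day = sessionDay(lg), pupil = mergeBinocular(lg)$pupil)
  }))))
ivs <- buildInterestVector(pupils, alpha = 0.10, perDay = TRUE)
ivs[[1]]
#> InterestVector: subject s1, 40 images, 7 labelled interesting

which(interestedImages(world, 1))          # planted truth
#> [1]  2  4 11 12 24 32 35
which(interestEntries(ivs[[1]]) == 1)      # recovered from pupils alone
#> [1]  2  4 11 12 24 32 35
```

The three subjects were planted with disjoint interests, and their
recovered interest vectors are orthogonal (`similarityMatrix(ivs)` is the
identity); subjects sharing planted categories score high instead. The
interest vector then conditions the saliency model:

```r
cfg <- psmConfig(c(32, 32), channelScale = 1 / 8, encLayers = 1,
                 decLayers = 1, heads = 4, M = 40, seed = 1)
pm  <- psmModel(cfg)
map <- predictPsm(pm, stimulus, interestEntries(ivs[[1]]))  # 32x32, >= 0
```

`vignettes/personalized-saliency.Rmd` documents the model, the design
decisions and the simulator in detail. A command-line front end over the
same functions (`simulate`, `train-usm`, `train-psm`, `eval`, `describe`)
lives at `inst/cli/persal.R`.

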