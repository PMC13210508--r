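Package: persal
Title: Personalized Saliency Maps and Interest Inference from Gaze and Pupillometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for predicting personal interest from eye-tracking data.
    Reads binocular eye-tracker logs, builds fixation-count grids and
    Gaussian-smoothed saliency maps (personalized per subject and universal
    by aggregation), extracts binary per-image interest vectors from
    pupil-diameter anomalies via a chi-squared test on standardized
    (Mahalanobis) distances, and defines and trains a saliency-prediction
    model that fuses a VGG-style convolutional encoder/decoder with a
    Transformer-based user-encoding mechanism through single-token
    cross-attention. Includes shuffled-AUC, AUC-Borji, NSS and CC evaluation
    metrics and a synthetic gaze/pupil simulator with planted subject
    interests so the full pipeline is exercisable without human data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1), methods
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'persal-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'gaze-io.R'
    'utils.R'
    'interest.R'
    'saliency.R'
    'io-maps.R'
    'metrics.R'
    'nn-layers.R'
    'nn-transformer.R'
    'model.R'
    'train.R'
    'synthdata.R'
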