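Package: elegnn
Title: Edge-Inferring Graph Neural Networks for Whole-Brain Calcium Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies behavioral (motor action) states and predicts
    short-horizon neuron-level trajectories from whole-brain calcium-imaging
    recordings of C. elegans. Implements a graph neural network that infers a
    weighted adjacency between neurons from activity and uses it for message
    passing, alongside a structure-agnostic multi-layer perceptron baseline.
    Includes the field's preprocessing conventions (per-neuron unit-interval
    normalization over the full recording, derivative features, fixed-length
    windows, shuffled k-fold splits), per-individual training with
    individual-wise feature normalization, scheduled-sampling rollout training
    for trajectory prediction, cross-validation and unseen-individual
    evaluation protocols, and a synthetic-population generator emulating the
    statistical structure of multi-worm recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
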