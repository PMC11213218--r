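Package: pnmsDCE
Title: Probabilistic Nested Model Selection for DCE-MRI Pharmacokinetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Voxel-wise pharmacokinetic analysis of dynamic contrast-enhanced
    (DCE) MRI using a hierarchy of three nested Patlak-family models (plasma
    volume only; plus unidirectional leakage; plus leakage with back-flux).
    Implements conventional nested model selection (NMS) via sequential
    partial F-tests, a batch-trained Kohonen self-organizing map (SOM) on an
    8x8 hexagonal grid over normalized delta-R1 time profiles, per-voxel
    probabilities of each nested model from labeled SOM hit maps, and
    probability-weighted (model-averaged) permeability maps of plasma volume
    (vp), forward transfer constant (Ktrans) and interstitial volume fraction
    (ve). Includes a synthetic phantom generator with a gamma-variate arterial
    input function, a subject-level k-fold nested cross-validation harness
    with Dice similarity and mean-percent-difference evaluation, and a
    configurable end-to-end pipeline with NIfTI/CSV/JSON input and output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    pracma,
    RNifti,
    jsonlite,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'accessors.R'
    'constructors.R'
    'io.R'
    'ksom.R'
    'nms.R'
    'pipeline.R'
    'pk-models.R'
    'pnms.R'
    'pnmsDCE-package.R'
    'synthetic.R'
    'utils.R'
    'validation.R'
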