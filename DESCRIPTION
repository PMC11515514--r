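Package: molnp
Title: Neural Processes for Few-Shot Molecular Property Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Conditional and latent neural processes for meta-learning of
    molecular properties. Provides molecular featurization (binary circular
    fingerprints and attributed heavy-atom graphs with a graph-attention
    superatom encoder), randomized context/target meta-training with
    effective-epoch accounting, a fine-tuning procedure that adapts a trained
    model to divergent test tasks, calibration and applicability-domain
    diagnostics, batched Bayesian optimization over a fixed molecular library
    with a Tanimoto-kernel Gaussian-process baseline, and generators for
    synthetic sinusoid and molecular meta-datasets with tunable inter-task
    correlation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    ChemmineR,
    jsonlite,
    yaml
Suggests:
    ChemmineOB,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
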