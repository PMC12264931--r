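Package: molaudit
Title: Distributional Bias Audits for Generated Molecule Sets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies and localizes distributional bias between a reference
    ("training") set and a candidate ("generated") set of 3D organic
    molecules. Covers bond perception from coordinates, validity and
    duplicate filtering, composition/size/geometry distributions with
    Welch and Kolmogorov-Smirnov two-sample tests, functional-group and
    ring-class prevalence, an averaged power-spectrum (SOAP-style)
    structural descriptor and an engineered bonding descriptor, a 2D
    latent chemical space built from the first principal component of
    each descriptor with kernel density maps and two-stage clustering,
    two corrective resamplers (atom-count histogram matching and
    latent-grid flattening), and a decision-tree discriminator with
    depth selection and interpretable feature importances. A seeded
    synthetic molecule generator with controllable bias knobs supports
    end-to-end testing without external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    MASS,
    rpart,
    pracma,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
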