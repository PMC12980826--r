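Package: CapsidAdsorb
Title: Predicting Nonspecific Adsorption of rAAV Capsids onto Solid Surfaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Physicochemical modelling of nonspecific adsorption of
    recombinant adeno-associated virus (rAAV) particles onto solid surfaces.
    Computes outer-surface side-chain solvent-accessible surface area (SASA)
    of capsid viral proteins from PDB structures with biological-assembly
    transforms using a deterministic Shrake-Rupley engine, converts
    electrophoretic measurements to zeta potential (Smoluchowski) and net
    charge, summarises adsorption-ratio assays, and fits nested
    ordinary-least-squares models of the adsorption ratio on contact angle,
    sign-split zeta potential and residue-category SASA, with standardized
    coefficients and prediction under new formulation conditions. Includes
    a synthetic-data generator with analytic SASA ground truth and known
    regression coefficients for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    bio3d,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
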