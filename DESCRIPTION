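Package: bcl2dyn
Title: Src-Controlled Mitochondrial Apoptosis Dynamics in the Bcl-2 Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ordinary-differential-equation models of Bik turnover and of the
    mitochondrial (intrinsic) pathway of apoptosis in parental and
    Src-transformed fibroblasts. Implements Bik synthesis, spontaneous and
    Src-dependent ubiquitylation and proteasomal degradation with closed-form
    steady states; an eleven-species mass-action network of the Bcl-2 family
    (Bik, Bid/tBid, Bax activation and oligomerization, a lumped anti-apoptotic
    pool) coupled to a threshold-gated cell-population survival law; declarative
    drug treatments (staurosporine, Src inhibition, BH3-mimetic depletion of the
    anti-apoptotic pool, Bax down-regulation, tBid up-regulation); constrained
    least-squares calibration by a covariance-matrix-adaptation evolution
    strategy; in-silico optimization and exhaustive ranking of drug
    combinations under a healthy-cell toxicity cap; and synthetic-data
    generators with known ground truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    graphics,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
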