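Package: sepsiscues
Title: Nearest-Neighbor Reasoning Cues for Sepsis Treatment Decisions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A decision-support engine for sepsis treatment in the ICU.
    Patient stays are converted to four-hour state trajectories, embedded
    with a denoising autoencoder (a small causal self-attention encoder),
    and each query state is compared with its exact nearest neighbors in
    embedding space. From the neighbor pool the package computes eight
    "intelligent reasoning cues": consistent and unusual case features,
    neighbor-based risk scores for vasopressor use at twelve hours and for
    in-admission mortality, treatment-plan-conditional risk differences
    with an exact test, peer action frequencies, consensus actions, and
    plan recommendations. The cues are assembled into seven machine-readable
    interface payloads. A synthetic EHR simulator with closed-form ground
    truth (latent severity process, softmax treatment policy, logistic
    outcome model) makes every stage testable without access to restricted
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
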