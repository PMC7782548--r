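Package: hydrocv
Title: Water-Aware Machine-Learned Collective Variables for Host-Guest Binding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds water-describing collective variables for enhanced-sampling
    simulations of host-guest binding. Non-local water coordination descriptors
    (ligand-centred and binding-axis-centred coordination numbers) feed a deep
    linear discriminant analysis (Deep-LDA) neural collective variable trained
    by maximising Fisher's ratio between bound and unbound equilibrium
    fluctuations. The CV drives on-the-fly probability enhanced sampling (OPES)
    with a funnel restraint; free energy surfaces are recovered by
    umbrella-sampling-like reweighting with block-average errors, binding free
    energies receive the analytic funnel standard-state correction, and
    derivative-based ranking quantifies each descriptor's role per metastable
    state. Includes a seed-deterministic toy-system generator (two-class
    Gaussian descriptors, host + ligand + water-bead frames, a two-degree-of-
    freedom binding/hydration landscape with overdamped Langevin dynamics) with
    exact and quadrature references, plus SAMPL5-style accuracy metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    Rcpp,
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
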