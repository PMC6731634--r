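Package: pmstates
Title: Probabilistic Metastable Substates and Whole-Brain Hopf Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies brain states as probabilistic metastable substate
    (PMS) spaces from regional BOLD-like time series using leading
    eigenvector dynamics analysis (LEiDA): band-pass filtering, Hilbert
    phases, instantaneous phase-coherence matrices, leading eigenvectors,
    k-means substates, fractional occupancies and switching matrices.
    Simulates whole-brain dynamics as Stuart-Landau (Hopf) oscillators
    coupled through a structural connectome, fits the global coupling and
    the effective connectivity of the model to a PMS space (symmetrized
    Kullback-Leibler distance on substate probabilities, Kolmogorov-Smirnov
    distance on functional connectivity dynamics, Markov entropy rate on
    transition matrices), and perturbs the fitted model in silico -
    shifting local bifurcation parameters of homotopic region pairs - to
    discover stimulation sites and intensities that force a transition
    from a source brain state to a target brain state, including a greedy
    multisite search. A synthetic-data module generates connectomes and
    multi-subject two-condition datasets so the full pipeline is testable
    without empirical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    cluster,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
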