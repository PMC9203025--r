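Package: gabaregimes
Title: Regimes of GABAergic Action on Neuronal Firing in Conductance-Based Neuron Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytical and simulation tools for classifying the effect of
    GABAergic synaptic conductance on neuronal firing rate in conductance-based
    integrate-and-fire models. Implements the closed-form firing rate of the
    deterministic leaky integrate-and-fire (LIF) neuron with constant synaptic
    conductances, the first-passage-time (Ricciardi) firing rate under white
    input noise, a conductance-dependent (multiplicative) noise model derived
    from the diffusion approximation of Poisson synaptic input, and phase
    diagrams separating inhibitory, non-monotonic and excitatory regimes in the
    plane of GABA reversal potential and glutamatergic conductance. Also
    provides an exponential integrate-and-fire neuron with an inward-rectifier
    potassium current (EIF-Kir) for robustness checks, and a striatal
    microcircuit spiking-network model (fast-spiking interneurons plus direct-
    and indirect-pathway spiny projection neurons) with Poisson cortical drive,
    drive calibration, and population-level statistics of heterogeneous
    GABAergic effects.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
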