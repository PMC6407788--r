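Package: placedecode
Title: Position Decoding from Hippocampal Place-Cell Spike Trains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for decoding an animal's self-location from simultaneously
    recorded hippocampal single units. Provides windowed spike-count feature
    extraction, Poisson-likelihood Bayesian position decoders (flat prior, and
    an occupancy prior with a movement-continuity constraint), a many-to-one
    LSTM sequence regressor trained by backpropagation through time with
    RMSprop, leakage-safe blocked cross-validation for autocorrelated neural
    time series, error analytics including Z-track linearisation, and knockout
    and input-gradient sensitivity analyses. A synthetic place-cell session
    simulator (Gaussian tuning curves, inhomogeneous-Poisson spiking with
    optional gamma over-dispersion, open-field and Z-track behaviour) makes
    every stage testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), withr, jsonlite, optparse
Config/testthat/edition: 3
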