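Package: pinwheelEN
Title: Excitation-Normalization Model of Orientation Maps in Primary Visual Cortex
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates a steady-state rate model of the cat early visual
    pathway (photoreceptor compression, ON/OFF difference-of-Gaussians
    thalamic receptive fields, push-pull thalamocortical summation, expansive
    spiking nonlinearity) embedded in a cortical orientation-preference map,
    and the intra-cortical circuits that differentiate iso-orientation
    domains from pinwheel centres: surround excitation balanced by
    normalization from un-oriented inhibitory cells (the
    excitation-normalization model) and a divisive-normalization comparison
    model. Includes generators for sinusoidal grating and plaid stimulus
    batteries, synthetic pinwheel orientation maps and electrode-track
    recordings with Poisson spike counts, and the full measurement battery:
    Naka-Rushton contrast-response fits, Von Mises orientation-tuning fits,
    half-width at half-height, circular variance, suppression indices, local
    homogeneity indices (1D and 2D), and a nonlinearity index, together with
    experiment runners that reproduce the model's predicted regional
    differences as testable properties.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    optparse,
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
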