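Package: rdgeom
Title: Rate-Distortion Geometry of Latent Representations in Generative Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for studying how rate-distortion
    trade-offs distort the latent representations of generative models. Generates
    the synthetic 'Corridors' image dataset (13x13 binary grids with two
    orthogonal generative factors and optional frequency biases), trains
    capacity-annealed beta variational autoencoders with optional jointly
    trained classifier heads on four position-based classification tasks, and
    quantifies the resulting latent-space distortions (prototypization,
    specialization, orthogonalization) through distortion-ratio matrices,
    multidimensional-scaling projections, latent channel-activation maps and
    active-channel counts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    cluster,
    data.table,
    vegan,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
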