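Package: pelagimap
Title: Pelagic Habitat Mapping from Gridded Transect Sections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end mapping of pelagic macro-habitats from gridded
    oceanographic transect sections (temperature, salinity, oxygen,
    chlorophyll-a and plankton densities on a distance-by-depth lattice).
    Builds per-cell microhabitat feature vectors, embeds them with a
    tied-weight fully connected autoencoder, segments the 4-D latent space
    into macro-habitats with hierarchical density-based clustering
    (HDBSCAN), traces input-variable influence through the encoder weights,
    ranks latent dimensions by Sobol global sensitivity on a support-vector
    surrogate, and classifies plankton-habitat associations with a
    torus-translation randomization test. Includes a synthetic transect
    generator (tidal-mixing front, upwelling-downwelling dipole,
    zero-inflated plankton patches) with ground-truth labels for recovery
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
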