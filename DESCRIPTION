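Package: patchmc
Title: Gibbs-Ensemble Monte Carlo for Two-Component Patchy-Particle
    Phase Separation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Coarse-grained simulation of liquid-liquid phase separation in
    protein-regulator mixtures modelled as two species of Kern-Frenkel patchy
    particles: a four-patch "protein" (P) and a two-patch "regulator" (R) with
    tunable cross attraction. Implements Gibbs-ensemble Monte Carlo with
    particle displacement/rotation, inter-box particle exchange and volume
    exchange moves; computes coexistence densities, binodals, tie lines and
    threshold-concentration ratios; locates critical points by the law of
    rectilinear diameters with a fixed 3D-Ising width exponent; and analyses
    droplet-phase bond networks (bonds per particle, decomposition by species
    and partner type, connected bonding clusters). Sample streams and analysis
    results are tidy tibbles; fitted critical points support broom-style
    tidy()/glance() and ggplot2 autoplot().
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    minpack.lm,
    igraph,
    jsonlite,
    yaml,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
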