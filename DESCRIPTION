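Package: nichesim
Title: Physiologically Based Simulation of Mammalian Rest/Activity
    Patterns and Temporal Niche
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates mammalian sleep/wake and rest/activity patterns with a
    physiologically based model coupling the mutually inhibitory
    VLPO/monoaminergic sleep/wake switch, a homeostatic sleep drive, and a van
    der Pol circadian pacemaker entrained by light through a photoreceptor
    activation stage. Circadian output is modulated at the subparaventricular
    zone and relayed through the dorsomedial hypothalamus to both the VLPO and
    the lateral hypothalamus, and light additionally masks behavior directly.
    Includes species presets, light-schedule and parameter-override protocols
    (light/dark cycles, constant light or darkness, running-wheel inversions,
    SCN lesions), a stochastic fixed-step integrator, and analysis tools for
    sleep/wake scoring, actograms, circadian-binned wake profiles, amplitude
    spectra, and free-running period estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    graphics,
    grDevices,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
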