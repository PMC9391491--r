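Package: growthctrl
Title: Coarse-Grained Kinetic Submodels of Bacterial Growth Rate Control
Version: 0.1.0
Authors@R: person("Growth", "Control Maintainers", email = "maintainers@growthctrl.dev", role = c("aut", "cre"))
Description: Desk-scale kinetic submodels of growth rate control in
    Escherichia coli: a single-step amino-acid biosynthesis network with
    allosteric end-product inhibition, mechanistic amino-acid transport, a
    phenomenological supply alternative, tRNA aminoacylation and ribosome
    elongation kinetics, RelA/SpoT (p)ppGpp synthesis and hydrolysis,
    ppGpp-dependent partitioning of RNA polymerase output, charged-tRNA
    driven transcriptional attenuation, and topology-constrained network
    component analysis for regulator fold-change extraction.  All
    submodels are embedded in a reduced coarse-grained host cell able to
    run nutrient-shift and ppGpp-clamp experiments, and every parameter
    derivation (kcat fitting, transport calibration, RNAP binding fits,
    SpoT constants) is exposed as a standalone function with synthetic
    fixtures for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
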