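Package: locipair
Title: Inter-Allelic Distance Analysis of Tagged Homologous Loci in Plant Nuclei
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and quantitative analysis of fluorescently tagged
    homologous loci in plant root nuclei. Generates synthetic two-channel 3D
    image stacks with known ground truth (two diffraction-limited foci inside
    an ellipsoidal nucleus with a nucleolar exclusion zone), detects and
    localizes the foci to subvoxel precision, measures 3D inter-allelic
    distances and classifies paired (overlapping) loci, segments nuclei and
    estimates volumes, implements a Monte Carlo null model for two uniform
    random points in a nucleoplasm shell, quantifies DNA double-strand break
    load from comet-assay images (tail DNA percent, tail length, Olive tail
    moment), and orchestrates a full dose-response / time-course / genotype
    study with grouped statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tiff,
    jsonlite,
    yaml,
    zoo,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
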