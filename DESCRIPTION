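Package: fcglycoscope
Title: Glycopeptide-Centric Profiling of IgG Fc N-Glycosylation from
    Tandem Mass Spectrometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for characterising the Fc N-glycosylation of IgG
    antibodies from liquid chromatography tandem mass spectrometry data:
    in-silico Glu-C/trypsin digestion with N-glycosylation sequon
    discovery, oxonium-ion triage of HCD spectra, glycopeptide-spectrum
    matching with fragment annotation and glycosylation-site
    localization, MS1-based relative quantification of site-specific
    glycoform profiles, and quantification of glycosylation-site
    occupancy from PNGase F deglycosylation in heavy-oxygen (18O) water.
    Includes a seeded synthetic-run generator with presets emulating a
    plant-made and an mRNA-expressed antibody product, used for
    validation and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
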