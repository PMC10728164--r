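Package: ntdms
Title: Native Top-Down Mass Spectrometry of Metal-Bound Protein Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for native top-down mass spectrometry (nTDMS) of intact
    protein complexes and their metal-bound proteoforms. Provides exact-mass
    bookkeeping for proteoforms carrying post-translational modifications,
    calcium adducts, and terminal truncations; enumeration of candidate
    compositions from per-subunit grammars; isotope-envelope computation
    (elemental and averagine models) and isotopically resolved deconvolution
    of charge-envelope spectra; ppm-tolerance mass matching and complex-to-
    subunit ejection bookkeeping; b/y fragment-ion localization of
    non-covalent metal binding with acidic-residue interval trimming;
    Mason-Schamps conversion between reduced ion mobility and collision
    cross section with mobilogram conformer summarization; and seeded
    synthetic-data generators with ground-truth records for end-to-end
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    Biostrings,
    mzR,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
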