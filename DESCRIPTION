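Package: olimpr
Title: Oligosaccharide Mass Profiling of Xyloglucan by MALDI-ToF
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Annotation of MALDI-ToF mass spectra of xyloglucan
    oligosaccharides (XGOs) released by glycosidase digestion of plant and
    algal cell walls (oligosaccharide mass profiling, OLIMP). Implements the
    one-letter sidechain nomenclature for xyloglucan, theoretical mass and
    sodium-adduct m/z computation under monoisotopic, average and nominal
    mass conventions, brute-force enumeration of monosaccharide compositions
    and branching isomers consistent with an observed peak, in-silico models
    of endo-xyloglucanase, Driselase, alpha-fucosidase and beta-galactosidase
    digestion with predicted mass shifts, residue-mass ladder (series)
    detection, differential pre/post-enzyme spectrum analysis, tandem-MS
    neutral-loss fragment prediction and terminal-residue inference, and a
    seeded synthetic-spectrum generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
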