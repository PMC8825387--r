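Package: rgspect
Title: Detection and Component Annotation of Resin Glycoside Acylsugars from LC-MS/MS Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discovering and partially annotating resin glycoside
    (RG) acylsugars in negative-mode LC-MS/MS metabolomics data. Reads
    MS-DIAL-style MGF exports and peak-area alignment tables, detects RG-like
    features through signature hydroxyacyl/sugar fragment pairs and
    blank-subtraction filters, annotates MS/MS fragments against a curated
    moiety database with pairwise neutral-loss inference, enumerates candidate
    structural compositions (oligosaccharide core, hydroxyacyl chain,
    decorating acyls, adduct) consistent with the precursor mass, and computes
    fragment and organ co-occurrence statistics. A seeded synthetic-spectrum
    generator produces MGF and alignment-table fixtures with planted
    compositions for end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
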