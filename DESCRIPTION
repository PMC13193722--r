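Package: hgmod
Title: Discovery and Chirality Assignment of Protein O-2-Hydroxyglutarylation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational workflow for discovering and validating the
    2-hydroxyglutarate (2HG) ester modification of serine, threonine and
    tyrosine from mass-spectrometry data. Provides elemental-composition and
    monoisotopic mass arithmetic for the +130.0266 Da adduct and its
    diagnostic neutral losses, in silico trypsin/GluC (sequential) digestion,
    theoretical b/y fragmentation with neutral-loss channels and d4
    isotopologue ladders, spectrum matching with modification-site
    localization, heavy/light isotope-pair validation, TIC-normalized
    dose-response quantification with D- versus L-enantiomer assignment,
    retention-time shift analysis, and a seeded synthetic-data generator that
    emulates the assumed experimental structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    mzR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
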