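Package: aquaStoich
Title: Absolute Quantification of Histone H3K14 Acetylation Stoichiometry
    from Targeted MRM Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for AQUA-style absolute quantification of histone H3
    lysine-14 acetylation by multiple reaction monitoring (MRM) mass
    spectrometry. Computes monoisotopic masses and precursor/fragment m/z
    for propionyl-derivatized light and stable-isotope-labeled (heavy)
    peptides, builds and screens MRM transition sets against isobaric
    positional isomers, simulates calibration ladders and donor samples
    with realistic multiplicative noise, quantifies summed transition peak
    areas and light:heavy ratios, fits reverse calibration curves with the
    full set of figures of merit (LLOD, LLOQ, ULOQ, linearity, accuracy,
    precision, transition-ratio specificity, selectivity), and derives
    per-donor and per-condition K14Ac stoichiometry with Welch t-test
    comparisons.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
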