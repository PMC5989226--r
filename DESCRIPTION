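Package: hemebind
Title: Tight-Binding Analysis of Hemin Titrations and Heme-Protein UV-Vis Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative UV-Vis spectroscopy toolkit for heme-protein
    interaction studies. Fits spectrophotometric hemin titrations with a
    tight-binding (quadratic) isotherm that includes an active-hemin
    fraction, solves the underlying mass-action equilibrium, quantifies
    protein and heme content from dual-wavelength (280 nm / Soret)
    absorbances, extracts Soret and charge-transfer band features from
    absorption spectra to call the heme iron coordination and spin state,
    and simulates titration series and spectra for method validation and
    parameter-recovery studies. Includes delimited-text readers and writers,
    FASTA-based extinction-coefficient estimation, and a command-line
    interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    signal,
    jsonlite,
    yaml,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
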