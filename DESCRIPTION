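Package: albuminbind
Title: Ligand-Serum-Albumin Binding Characterization from Spectroscopic Titrations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for characterizing small-molecule binding to
    serum albumin from three spectroscopies. Fluorescence quenching titrations
    are processed with inner-filter correction, Stern-Volmer regression with
    static/dynamic mechanism classification, and double-logarithm binding
    regression yielding the association constant and binding-site number;
    binding constants across temperatures feed a van't Hoff analysis that
    classifies the dominant intermolecular forces, and site-marker
    (phenylbutazone/ibuprofen) competition locates the binding pocket.
    Circular dichroism spectra are converted to mean residue ellipticity and
    alpha-helix content at 208 nm; FT-IR amide-I bands are deconvolved into
    Gaussian components assigned to secondary-structure classes. A synthetic
    spectra generator with known ground truth makes every stage verifiable by
    parameter recovery. Druglikeness rules (Lipinski, Veber, TPSA) are
    evaluated over user-supplied descriptor tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    signal,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
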