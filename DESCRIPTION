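Package: molshots
Title: Automated Publication-Style Images of Macromolecular Structures
Version: 0.1.0
Authors@R: person("Molshots", "Developers", role = c("aut", "cre"),
    email = "molshots@example.org")
Description: A browserless command-line tool and library that generates
    standardized images of macromolecular structures from mmCIF files.
    Nine predefined scene types cover experimental entries (entry,
    assembly, entity, domain, ligand, modified residue, B-factor putty,
    validation) and predicted models (pLDDT confidence).  Structures are
    posed with a deterministic PCA-based canonical orientation with
    anti-flip rules, rendered with a built-in z-buffered software
    rasterizer, and saved as PNG images at several resolutions together
    with a caption file and a reloadable scene-state file, plus per-entry
    summary files.  A deterministic synthetic-fixture generator makes the
    whole pipeline testable fully offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
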