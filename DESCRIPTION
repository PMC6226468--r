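Package: depet
Title: Distance-Encoding Photoinduced Electron Transfer Spectroscopy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Toolkit for inferring protein atomic distances from steady-state
    tryptophan quenching of site-conjugated fluorophores (distance-encoding
    photoinduced electron transfer, DEPET). Builds quenching-probability
    versus distance (FDQ) functions from conformer ensembles via exact
    spherical-shell intersection geometry, preprocesses voltage-clamp
    fluorometry records into conductance-normalized fluorescence changes,
    and inverts multi-fluorophore quenching data into backbone and
    side-chain distances, side-chain orientations and displaced-atom
    coordinates with bootstrap confidence intervals. Includes a polyproline
    II length-standard pipeline, trilateration utilities and synthetic-data
    generators emulating every experimental input.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
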