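Package: nmjmorph
Title: Morphometric Analysis of Drosophila Neuromuscular Junction Image Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A scriptable re-implementation of a semi-automated pipeline for
    quantitative morphometry of Drosophila larval neuromuscular junctions
    (NMJs) from two-channel fluorescence z-stacks. From a terminal-marker
    channel (e.g. Dlg1, Hrp, Syt, Csp) and an active-zone channel (Brp) the
    pipeline derives the NMJ outline, a branch skeleton and 3D spot counts,
    and reports nine per-NMJ features: area, perimeter, bouton number, total
    length, longest branch length, islands, branches, branching points and
    active zones. Includes entropy- and moment-based automatic histogram
    thresholding (Renyi, Li, Huang, moments), rolling-ball background
    subtraction, distance-transform watershed bouton splitting, 3D
    local-maxima spot detection with prominence filtering, a vesicle-marker
    bouton-counting variant, method-agreement statistics (Lin's concordance
    correlation, percent deviation, object-level sensitivity/specificity)
    and a synthetic NMJ image generator with full ground truth for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    EBImage,
    tiff,
    stats,
    utils,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
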