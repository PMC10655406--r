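Package: lineageforest
Title: Cell Lineage Forests from Static Label Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs, edits, annotates and serializes cell-lineage
    forests over static 2D/3D label images, as produced when backtracking
    cell divisions in fixed plant tissue. Provides a strictly binary
    lineage-forest data model (link/unlink/tag), the two-array 'treeV'
    lineage file format and Newick export, label-image operations
    (generation rewind, sub-tree and tag-based extraction), per-cell volume
    summaries, a recursive-division simulator that produces ground-truth
    forests with consistent per-generation label images, and a command-line
    interface.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    tiff,
    utils
Suggests:
    ape,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
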