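#' Check a label image against a lineage forest
#'
#' An image and a forest are consistent when every strictly positive image
#' label is a leaf of the forest. The report also lists forest leaves absent
#' from the image (legal: a forest may cover several images or a crop) and
#' image labels that collide with reconstructed (internal) node labels,
#' which would make rewound views ambiguous.
#'
#' @param image A `label_image` (or bare array).
#' @param forest A `lineage_forest`.
#' @return A list of class `lineage_validation` with elements `ok`,
#'   `unknown_labels` (in image, not a forest leaf), `missing_leaves`
#'   (forest leaf, not in image) and `internal_collisions` (image labels
#'   equal to reconstructed node labels).
#' @export
validate_image <- function(image, forest) {
  image <- as_label_image(image)
  labs <- image_labels(image)
  leaves <- forest_leaves(forest)
  internal <- setdiff(forest_labels(forest), leaves)
  out <- list(
    unknown_labels = setdiff(labs, leaves),
    missing_leaves = setdiff(leaves, labs),
    internal_collisions = intersect(labs, internal)
  )
  out$ok <- length(out$unknown_labels) == 0L
  structure(out, class = "lineage_validation")
}

#' @export
print.lineage_validation <- function(x, ...) {
  cat(if (x$ok) "Image/forest check: pass\n" else "Image/forest check: FAIL\n")
  show <- function(what, v) {
    if (length(v)) cat(sprintf("  %s: %s\n", what, paste(v, collapse = " ")))
  }
  show("image labels not forest leaves", x$unknown_labels)
  show("forest leaves absent from image", x$missing_leaves)
  show("collides with reconstructed label", x$internal_collisions)
  invisible(x)
}

check_image_forest <- function(image, forest) {
  rep <- validate_image(image, forest)
  if (!rep$ok) {
    stop_lineage("image/forest mismatch: image labels not in forest leaves: %s",
                 paste(rep$unknown_labels, collapse = " "))
  }
  invisible(rep)
}

# Vectorized relabeling: map is a named integer vector old -> new; any
# unmapped foreground label maps to `default` (NA keeps it unchanged).
relabel <- function(image, map, default = 0L) {
  v <- image$voxels
  old <- as.integer(names(map))
  n <- max(max(v, 0L), old, 0L)
  if (is.na(default)) {
    lut <- 0:n
  } else {
    lut <- rep(as.integer(default), n + 1L)
    lut[1] <- 0L  # background stays background
  }
  lut[old + 1L] <- as.integer(map)
  out <- lut[v + 1L]
  dim(out) <- dim(v)
  label_image(out, spacing = image$spacing)
}

#' Rewind a label image to an earlier generation
#'
#' Produces an independent copy of the image in which each foreground voxel
#' with leaf label L is relabeled to L's ancestor at depth `g` below its
#' root ([generation_cut()]). `g = 0` yields the "current view" of a fully
#' merged forest — each voxel shows its root; `g` at or beyond the depth of
#' every leaf returns the input unchanged. Leaves shallower than `g` (cells
#' that stopped dividing, the generational gap of unbalanced lineages) keep
#' their own labels. The input image is not modified.
#'
#' @inheritParams validate_image
#' @param g Non-negative generation (depth from each root).
#' @return A new `label_image` with the same dimensions and spacing.
#' @export
render_generation <- function(image, forest, g) {
  image <- as_label_image(image)
  check_image_forest(image, forest)
  cut <- generation_cut(forest, g)
  relabel(image, cut, default = NA)
}

#' Extract the cells of a sub-tree
#'
#' Keeps exactly the voxels whose leaf label descends from the node `m`;
#' everything else becomes background. With `merged = TRUE` the extracted
#' voxels all take the label `m` (the sub-tree shown as its mother cell),
#' otherwise they keep their leaf labels.
#'
#' @inheritParams render_generation
#' @param m Label of the sub-tree's mother cell (any node; a leaf extracts
#'   that single cell).
#' @param merged Merge the sub-tree into one region labeled `m`?
#' @return A new `label_image`.
#' @export
extract_subtree <- function(image, forest, m, merged = FALSE) {
  image <- as_label_image(image)
  m <- as_label(m, "m")
  node_of(forest, m)
  check_image_forest(image, forest)
  leaves <- descendant_leaves(forest, m)
  map <- if (merged) rep(m, length(leaves)) else leaves
  names(map) <- leaves
  relabel(image, map, default = 0L)
}

#' Extract the cells sharing a tag
#'
#' Collects, over every node carrying `tag`, the voxels of its descendant
#' leaves. With `merged = TRUE` each voxel takes the label of its tagged
#' ancestor — when tagged nodes are nested on one root path, the deepest
#' tagged ancestor wins (finer annotations refine coarser ones); with
#' `merged = FALSE` leaf labels are kept. Voxels under no tagged node become
#' background.
#'
#' @inheritParams render_generation
#' @param tag The tag text (non-empty).
#' @param merged Relabel each cell to its tagged ancestor's label?
#' @return A new `label_image`.
#' @export
extract_tag <- function(image, forest, tag, merged = FALSE) {
  image <- as_label_image(image)
  if (!nzchar(check_tag(tag))) stop_lineage("unknown tag: empty tag")
  check_image_forest(image, forest)
  tags <- vapply(forest$nodes, `[[`, character(1), "tag")
  tagged <- forest_labels(forest)[tags == tag]
  if (!length(tagged)) stop_lineage("unknown tag: '%s'", tag)
  depths <- vapply(tagged, function(l) node_depth(forest, l), integer(1))
  map <- integer(0)
  for (t in tagged[order(depths)]) {  # deeper nodes overwrite shallower ones
    lv <- descendant_leaves(forest, t)
    map[as.character(lv)] <- if (merged) t else lv
  }
  relabel(image, map, default = 0L)
}
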