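#' Lineage forests over static label images
#'
#' A lineage forest is a set of disjoint, strictly binary rooted trees. Its
#' leaves are the cells observed in a segmented (label) image; internal nodes
#' are reconstructed mother cells, created one division at a time by pairing
#' two current roots ([link_cells()]). Every node carries a positive integer
#' label and an optional free-text tag. Label 0 is reserved for the image
#' background and for "no mother" in the treeV file format, so cell labels are
#' always >= 1.
#'
#' The structure is functional: editing operations return a modified copy.
#' Reconstructed mother cells receive the label `label_max + 1`, where
#' `label_max` is the highest label ever assigned in the forest (initially the
#' highest image label); retired labels are never reused, so `label_max` never
#' decreases.
#'
#' @param labels Positive integer labels of the cells present in the image.
#'   Gaps are allowed (segmentation labelings are often discontinuous).
#'
#' @return An object of class `lineage_forest` with fields `nodes` (map from
#'   label to node), `mother` (named integer vector: daughter label ->
#'   mother label), `label_max` and `initial_labels`.
#'
#' @examples
#' f <- forest_init(c(1, 2, 3, 4))
#' r <- link_cells(f, 1, 2)        # new mother labeled 5
#' r <- link_cells(r$forest, 3, 4) # new mother labeled 6
#' forest_roots(r$forest)
#' @export
forest_init <- function(labels) {
  if (length(labels) == 0L) stop_lineage("no cells: the label set is empty")
  labels <- vapply(labels, as_label, integer(1))
  if (any(labels <= 0L)) {
    stop_lineage("invalid label: labels must be >= 1 (0 is background)")
  }
  labels <- sort(unique(labels))
  nodes <- lapply(labels, function(l) list(label = l, tag = "", daughters = NULL))
  names(nodes) <- as.character(labels)
  structure(
    list(
      nodes = nodes,
      mother = structure(integer(0), names = character(0)),
      label_max = max(labels),
      initial_labels = labels
    ),
    class = "lineage_forest"
  )
}

node_of <- function(forest, label) {
  nd <- forest$nodes[[as.character(label)]]
  if (is.null(nd)) stop_lineage("no such cell: %d", label)
  nd
}

mother_of <- function(forest, label) {
  m <- forest$mother[as.character(label)]
  if (is.na(m)) NA_integer_ else unname(m)
}

#' Pair two root cells under a new mother
#'
#' The elementary lineage-reconstruction step: two sister cells, both
#' currently roots of the forest, are merged under a newly created mother
#' node labeled `label_max + 1`. The daughter order given here is preserved
#' (it affects Newick serialization only).
#'
#' @param forest A `lineage_forest`.
#' @param a,b Labels of the two sister cells; both must be roots and distinct.
#' @param tag Optional tag for the new mother (no tab/newline).
#' @return A list with `forest` (the updated forest) and `mother` (the label
#'   of the new node).
#' @export
link_cells <- function(forest, a, b, tag = "") {
  a <- as_label(a, "a")
  b <- as_label(b, "b")
  if (a == b) stop_lineage("self-pairing: cannot link cell %d with itself", a)
  node_of(forest, a)
  node_of(forest, b)
  check_tag(tag)
  for (l in c(a, b)) {
    if (!is.na(mother_of(forest, l))) {
      stop_lineage("already linked: cell %d has a mother", l)
    }
  }
  m <- forest$label_max + 1L
  forest$nodes[[as.character(m)]] <- list(label = m, tag = tag, daughters = c(a, b))
  forest$mother[as.character(c(a, b))] <- m
  forest$label_max <- m
  list(forest = forest, mother = m)
}

#' Undo a pairing by dissolving a mother cell
#'
#' Splits back the mother cell `m`: the node is deleted and its two daughters
#' become roots again. Because a strictly binary node cannot survive with a
#' single daughter, every ancestor of `m` is dissolved in cascade, its other
#' daughter branch becoming a root at each level. Deleted labels are retired,
#' never reused; `label_max` is unchanged.
#'
#' @param forest A `lineage_forest`.
#' @param m Label of a non-leaf node.
#' @return The updated forest.
#' @export
unlink_cell <- function(forest, m) {
  m <- as_label(m, "m")
  nd <- node_of(forest, m)
  if (is.null(nd$daughters)) {
    stop_lineage("cannot unlink a leaf: cell %d has no daughters", m)
  }
  chain <- m
  cur <- m
  while (!is.na(mm <- mother_of(forest, cur))) {
    chain <- c(chain, mm)
    cur <- mm
  }
  for (ch in as.character(chain)) forest$nodes[[ch]] <- NULL
  keep <- !(names(forest$mother) %in% as.character(chain)) &
    !(forest$mother %in% chain)
  forest$mother <- forest$mother[keep]
  forest
}

#' Tag a cell
#'
#' Attaches an arbitrary text identifier to any node, leaf or internal. The
#' same tag may be shared by any number of nodes, which is how anatomical
#' domains (e.g. protoderm `"Ext"` vs inner tissue `"Int"`) are delimited.
#' Setting the empty string clears the tag. Tab and newline are reserved as
#' treeV delimiters and rejected.
#'
#' @inheritParams unlink_cell
#' @param label Label of the node to tag.
#' @param tag The tag text.
#' @return The updated forest.
#' @export
set_tag <- function(forest, label, tag) {
  label <- as_label(label)
  node_of(forest, label)
  check_tag(tag)
  forest$nodes[[as.character(label)]]$tag <- tag
  forest
}

#' Query the tag of a cell
#' @inheritParams set_tag
#' @return The tag text ("" if untagged).
#' @export
get_tag <- function(forest, label) {
  node_of(forest, as_label(label))$tag
}

forest_labels <- function(forest) {
  as.integer(names(forest$nodes))
}

#' Roots and leaves of the forest
#'
#' Roots are nodes without a mother; leaves are nodes without daughters. For
#' a freshly initialized forest the two sets coincide.
#'
#' @inheritParams unlink_cell
#' @return A sorted integer vector of labels.
#' @export
forest_roots <- function(forest) {
  labs <- forest_labels(forest)
  sort(labs[!(as.character(labs) %in% names(forest$mother))])
}

#' @rdname forest_roots
#' @export
forest_leaves <- function(forest) {
  labs <- forest_labels(forest)
  is_leaf <- vapply(forest$nodes, function(nd) is.null(nd$daughters), logical(1))
  sort(labs[is_leaf])
}

# Path from the node's root down to the node (labels, root first).
root_path <- function(forest, label) {
  path <- label
  cur <- label
  n <- length(forest$nodes)
  while (!is.na(m <- mother_of(forest, cur))) {
    path <- c(m, path)
    cur <- m
    if (length(path) > n) stop_lineage("cyclic lineage")
  }
  path
}

#' Depth of a node below its root
#'
#' Depth is counted per tree: each root is at depth 0. This is distinct from
#' the biological generation counted from the zygote, which cannot be known
#' from a static image when the forest has several roots.
#'
#' @inheritParams set_tag
#' @return A non-negative integer.
#' @export
node_depth <- function(forest, label) {
  label <- as_label(label)
  node_of(forest, label)
  length(root_path(forest, label)) - 1L
}

#' Ancestor of a cell at a given generation
#'
#' Returns the ancestor of `label` located at depth `g` below its root
#' (root = depth 0). A node whose own depth is at most `g` is returned
#' unchanged, which is what keeps cells of shallow (stopped) branches
#' unmerged when a tissue is rewound.
#'
#' @inheritParams set_tag
#' @param g Non-negative generation (depth from the root).
#' @return The ancestor's label.
#' @export
ancestor_at_depth <- function(forest, label, g) {
  label <- as_label(label)
  node_of(forest, label)
  if (length(g) != 1L || is.na(g) || g < 0) stop_lineage("invalid generation")
  path <- root_path(forest, label)
  depth <- length(path) - 1L
  if (depth <= g) label else path[[g + 1L]]
}

#' Leaves of the sub-tree rooted at a cell
#'
#' @inheritParams set_tag
#' @return Sorted integer labels of the descendant leaves; a leaf returns the
#'   singleton of itself.
#' @export
descendant_leaves <- function(forest, label) {
  label <- as_label(label)
  node_of(forest, label)
  out <- integer(0)
  stack <- label
  while (length(stack)) {
    cur <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    nd <- forest$nodes[[as.character(cur)]]
    if (is.null(nd$daughters)) {
      out <- c(out, cur)
    } else {
      stack <- c(stack, nd$daughters)
    }
  }
  sort(out)
}

#' Map every leaf to its ancestor at generation g
#'
#' The generation cut behind rewound tissue views: at `g = 0` every leaf maps
#' to its root ("current view" of a fully merged forest); at `g` at least the
#' depth of every leaf the map is the identity. Leaves shallower than `g`
#' map to themselves, so unbalanced trees (a generational gap between
#' domains) keep their shallow cells unmerged.
#'
#' @inheritParams ancestor_at_depth
#' @return A named integer vector, names = leaf labels, values = ancestor
#'   labels.
#' @export
generation_cut <- function(forest, g) {
  if (length(g) != 1L || is.na(g) || g < 0) stop_lineage("invalid generation")
  leaves <- forest_leaves(forest)
  anc <- vapply(leaves, function(l) ancestor_at_depth(forest, l, g), integer(1))
  names(anc) <- leaves
  anc
}

#' Verify the structural invariants of a forest
#'
#' Checks that the mother relation is a function, acyclic, strictly binary,
#' consistent with the stored daughter pairs, and that `label_max` bounds all
#' labels. Used after file loading and in property tests.
#'
#' @inheritParams unlink_cell
#' @return Invisibly `TRUE`; otherwise an error describing the violation.
#' @export
forest_validate <- function(forest) {
  labs <- forest_labels(forest)
  if (any(labs < 1L)) stop_lineage("invalid label: labels must be >= 1")
  if (length(labs) && forest$label_max < max(labs)) {
    stop_lineage("label_max below an existing label")
  }
  seen_daughters <- integer(0)
  for (nd in forest$nodes) {
    d <- nd$daughters
    if (is.null(d)) next
    if (length(d) != 2L || d[1] == d[2] || any(d == nd$label)) {
      stop_lineage("non-binary record: node %d", nd$label)
    }
    for (dd in d) {
      if (is.null(forest$nodes[[as.character(dd)]])) {
        stop_lineage("no such cell: %d (daughter of %d)", dd, nd$label)
      }
      m <- mother_of(forest, dd)
      if (is.na(m) || m != nd$label) {
        stop_lineage("inconsistent mother map at cell %d", dd)
      }
    }
    seen_daughters <- c(seen_daughters, d)
  }
  if (anyDuplicated(seen_daughters)) {
    stop_lineage("a cell has more than one mother")
  }
  if (!setequal(names(forest$mother), as.character(seen_daughters))) {
    stop_lineage("mother map does not match daughter records")
  }
  for (l in labs) root_path(forest, l)  # errors on a cycle
  invisible(TRUE)
}

#' @export
print.lineage_forest <- function(x, ...) {
  n_leaves <- length(forest_leaves(x))
  n_roots <- length(forest_roots(x))
  cat(sprintf(
    "Lineage forest: %d nodes (%d leaves) in %d tree%s, label_max = %d\n",
    length(x$nodes), n_leaves, n_roots, if (n_roots == 1L) "" else "s",
    x$label_max
  ))
  tags <- vapply(x$nodes, `[[`, character(1), "tag")
  tags <- tags[nzchar(tags)]
  if (length(tags)) {
    cat("Tags:", paste(sprintf("%s=%s", names(tags), tags), collapse = ", "),
        "\n")
  }
  invisible(x)
}
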