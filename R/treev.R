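#' Write a lineage forest as a treeV file
#'
#' The treeV format stores a forest as two parallel arrays indexed by cell
#' label, from 1 up to `label_max`: the first array holds the label of each
#' cell's mother (0 for roots and for labels that were never instantiated —
#' gaps of a discontinuous labeling, or labels retired by [unlink_cell()]),
#' the second holds each cell's tag (empty when untagged). The on-disk
#' dialect is a two-line UTF-8 text file: line 1 the mother array as base-10
#' integers separated by single spaces, line 2 the tag array separated by
#' single tab characters, ending with one newline. Tags therefore cannot
#' contain tab or newline.
#'
#' @param forest A `lineage_forest`.
#' @param path Destination file path (conventional extension `.treeV`).
#' @return Invisibly, `path`.
#' @seealso [read_treev()]
#' @export
write_treev <- function(forest, path) {
  n <- forest$label_max
  mo <- integer(n)
  tg <- character(n)
  for (nd in forest$nodes) {
    m <- mother_of(forest, nd$label)
    mo[nd$label] <- if (is.na(m)) 0L else m
    tg[nd$label] <- nd$tag
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(paste(mo, collapse = " "), paste(tg, collapse = "\t")),
             con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

# Split a line into tab fields without dropping a trailing empty field.
split_fields <- function(line, sep) {
  parts <- strsplit(paste0(line, "\x01"), sep, fixed = TRUE)[[1]]
  parts[length(parts)] <- sub("\x01$", "", parts[length(parts)])
  parts
}

#' Read a treeV lineage file
#'
#' Reconstructs a forest from the two treeV arrays. Because the file indexes
#' every label up to `label_max` — including gaps of a discontinuous
#' labeling and retired labels, which are indistinguishable from plain
#' leaves in the arrays alone — membership is resolved against the label set
#' of the companion image: the node set is the image labels, every tagged
#' index and every index recording a mother (a cell the user linked),
#' closed upward under the mother array. When `image_labels`
#' is `NULL` (e.g. editing a lineage without its image at hand) every index
#' from 1 to `label_max` is taken as a cell.
#'
#' @param path Path to a treeV file (CRLF line endings tolerated).
#' @param image_labels Integer labels present in the companion label image,
#'   or `NULL`.
#' @return A `lineage_forest`; its `label_max` is the array length of the
#'   file, so labels retired before saving stay retired.
#' @export
read_treev <- function(path, image_labels = NULL) {
  lines <- tryCatch(readLines(path, warn = FALSE),
                    error = function(e) stop_parse("cannot read %s", path))
  lines <- sub("\r$", "", lines)
  if (length(lines) < 2L || any(nzchar(lines[-(1:2)]))) {
    stop_parse("malformed treeV: expected exactly two lines in %s", path)
  }
  mo <- suppressWarnings(as.integer(split_fields(lines[[1]], " ")))
  if (any(is.na(mo)) || length(mo) == 0L) {
    stop_parse("malformed treeV: mother array is not all integers in %s", path)
  }
  tg <- split_fields(lines[[2]], "\t")
  n <- length(mo)
  if (length(tg) != n) {
    stop_parse(paste0("malformed treeV: array length mismatch ",
                      "(%d mothers, %d tags) in %s"), n, length(tg), path)
  }
  if (any(mo < 0L | mo > n)) {
    stop_parse("malformed treeV: mother label outside 1..%d in %s", n, path)
  }
  if (any(mo == seq_len(n))) stop_parse("cyclic lineage: a cell is its own mother")
  vapply(tg, check_tag, character(1))

  resolve_all <- is.null(image_labels)
  if (resolve_all) {
    image_labels <- seq_len(n)
  } else {
    image_labels <- sort(unique(vapply(image_labels, as_label, integer(1))))
    if (any(image_labels > n)) {
      stop_parse("label outside treeV range: image label %d > %d",
                 max(image_labels), n)
    }
  }

  # Membership: image labels, tagged indices and indices recording a mother
  # (cells the user linked), closed upward under the mother map. Bare gaps —
  # mother 0, no tag, never referenced — stay non-nodes.
  member <- logical(n)
  member[image_labels] <- TRUE
  member[nzchar(tg)] <- TRUE
  member[mo != 0L] <- TRUE
  queue <- which(member)
  while (length(queue)) {
    mothers <- setdiff(unique(mo[queue]), 0L)
    mothers <- mothers[!member[mothers]]
    member[mothers] <- TRUE
    queue <- mothers
  }
  labs <- which(member)

  # Cycle check: walk each member's mother chain with a step bound.
  for (l in labs) {
    cur <- l
    steps <- 0L
    while (mo[cur] != 0L) {
      cur <- mo[cur]
      steps <- steps + 1L
      if (steps > n) stop_parse("cyclic lineage in %s", path)
    }
  }

  nodes <- lapply(labs, function(l) list(label = l, tag = tg[l], daughters = NULL))
  names(nodes) <- as.character(labs)
  mother <- structure(mo[labs], names = as.character(labs))
  mother <- mother[mother != 0L]
  for (m in unique(mother)) {
    d <- as.integer(names(mother)[mother == m])
    if (length(d) != 2L) {
      stop_parse("non-binary record: cell %d has %d daughter(s) in %s",
                 m, length(d), path)
    }
    nodes[[as.character(m)]]$daughters <- sort(d)
  }
  forest <- structure(
    list(nodes = nodes, mother = mother, label_max = n,
         initial_labels = image_labels),
    class = "lineage_forest"
  )
  if (resolve_all) forest$initial_labels <- forest_leaves(forest)
  forest_validate(forest)
  forest
}
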