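#' Export a forest to Newick
#'
#' One Newick statement per root, one per line, in ascending root-label
#' order. Node names are the bare integer labels (internal nodes included),
#' there are no branch lengths, and the daughter order given to
#' [link_cells()] is preserved. Tags are not carried by Newick — they travel
#' only in the treeV file.
#'
#' @param forest A `lineage_forest`.
#' @param path Optional destination file (conventional extension `.nwk`);
#'   when `NULL` the statements are returned as a character vector.
#' @return A character vector with one statement per root (invisibly when
#'   written to a file).
#' @export
write_newick <- function(forest, path = NULL) {
  render <- function(label) {
    nd <- forest$nodes[[as.character(label)]]
    if (is.null(nd$daughters)) {
      as.character(label)
    } else {
      sprintf("(%s,%s)%d", render(nd$daughters[1]), render(nd$daughters[2]),
              label)
    }
  }
  out <- vapply(forest_roots(forest), function(r) paste0(render(r), ";"),
                character(1))
  if (is.null(path)) return(out)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(out, con, sep = "\n", useBytes = TRUE)
  invisible(out)
}

#' Read a forest from Newick text
#'
#' Parses the dialect emitted by [write_newick()]: strictly binary clades,
#' integer node names on every node, no branch lengths, one tree per
#' statement. Intended for round-tripping exported lineages into other
#' tools and back; tags come back empty since Newick does not carry them.
#'
#' @param text Newick statements, as a character vector of lines and/or
#'   `;`-separated statements.
#' @return A `lineage_forest` whose `initial_labels` are the leaf labels.
#' @export
read_newick <- function(text) {
  src <- paste(text, collapse = "\n")
  src <- gsub("[ \t\r\n]", "", src)
  stmts <- strsplit(src, ";", fixed = TRUE)[[1]]
  stmts <- stmts[nzchar(stmts)]
  if (!length(stmts)) stop_parse("malformed Newick: no statement")

  nodes <- list()
  mother <- structure(integer(0), names = character(0))

  add_node <- function(label, daughters) {
    key <- as.character(label)
    if (!is.null(nodes[[key]])) {
      stop_parse("duplicate label: %d appears twice", label)
    }
    nodes[[key]] <<- list(label = label, tag = "", daughters = daughters)
  }

  for (stmt in stmts) {
    chars <- strsplit(stmt, "")[[1]]
    pos <- 1L

    peek <- function() if (pos <= length(chars)) chars[[pos]] else ""
    take_name <- function() {
      start <- pos
      while (pos <= length(chars) && grepl("[0-9]", chars[[pos]])) {
        pos <<- pos + 1L
      }
      if (pos == start) {
        if (peek() %in% c("(", ")", ",", "")) {
          stop_parse("unsupported name: every node needs an integer name")
        }
        stop_parse("unsupported name: '%s' is not an integer label", peek())
      }
      as.integer(paste(chars[start:(pos - 1L)], collapse = ""))
    }
    # Parses one clade, registers its nodes, returns the clade's root label.
    parse_clade <- function() {
      if (peek() != "(") {
        label <- take_name()
        add_node(label, NULL)
        return(label)
      }
      pos <<- pos + 1L  # "("
      children <- parse_clade()
      while (peek() == ",") {
        pos <<- pos + 1L
        children <- c(children, parse_clade())
      }
      if (peek() != ")") stop_parse("malformed Newick: expected ')'")
      pos <<- pos + 1L
      if (length(children) != 2L) {
        stop_parse("non-binary Newick: clade with %d children",
                   length(children))
      }
      label <- take_name()
      add_node(label, children)
      mother[as.character(children)] <<- label
      label
    }

    parse_clade()
    if (pos <= length(chars)) {
      stop_parse("malformed Newick: trailing characters '%s'",
                 paste(chars[pos:length(chars)], collapse = ""))
    }
  }

  labs <- as.integer(names(nodes))
  if (any(labs < 1L)) stop_parse("invalid label: 0 is reserved for background")
  forest <- structure(
    list(nodes = nodes, mother = mother, label_max = max(labs),
         initial_labels = integer(0)),
    class = "lineage_forest"
  )
  forest$initial_labels <- forest_leaves(forest)
  forest_validate(forest)
  forest
}
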