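# Condition helpers. User-level misuse (bad label, bad pairing, unknown tag)
# signals class "lineage_error"; a syntactically/structurally broken input
# file signals "lineage_parse_error". The CLI maps these to exit codes 1 / 2.

stop_lineage <- function(msg, ..., class = "lineage_error", call. = FALSE) {
  stop(structure(
    class = c(class, "lineage_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = NULL)
  ))
}

stop_parse <- function(msg, ...) {
  stop_lineage(msg, ..., class = "lineage_parse_error")
}

# Coerce a single label argument to a positive scalar integer.
as_label <- function(x, what = "label") {
  if (length(x) != 1L || is.na(suppressWarnings(xi <- as.integer(x))) ||
      (is.numeric(x) && x != xi)) {
    stop_lineage("invalid label: %s is not a single integer", what)
  }
  xi
}

check_tag <- function(tag) {
  if (length(tag) != 1L || !is.character(tag) || is.na(tag)) {
    stop_lineage("invalid tag")
  }
  if (grepl("[\t\n\r]", tag)) {
    stop_lineage("invalid tag: tab and newline are reserved treeV delimiters")
  }
  tag
}
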