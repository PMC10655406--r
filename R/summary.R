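#' Per-cell voxel counts and volumes
#'
#' One row per label present in the image (absent labels of a discontinuous
#' labeling are not listed). Volume is voxel count times the product of the
#' per-axis voxel spacing. When a forest is supplied, each cell's tag is
#' included.
#'
#' @param image A `label_image` (or bare array).
#' @param forest Optional `lineage_forest` supplying tags.
#' @return A data frame with columns `label`, `voxels`, `volume`, `tag`.
#' @export
region_volumes <- function(image, forest = NULL) {
  image <- as_label_image(image)
  v <- image$voxels
  fg <- v[v > 0L]
  if (!length(fg)) {
    return(data.frame(label = integer(0), voxels = integer(0),
                      volume = numeric(0), tag = character(0),
                      stringsAsFactors = FALSE))
  }
  counts <- table(fg)
  labels <- as.integer(names(counts))
  voxels <- as.integer(counts)
  tags <- rep("", length(labels))
  if (!is.null(forest)) {
    for (i in seq_along(labels)) {
      nd <- forest$nodes[[as.character(labels[i])]]
      if (!is.null(nd)) tags[i] <- nd$tag
    }
  }
  data.frame(label = labels, voxels = voxels,
             volume = voxels * prod(image$spacing), tag = tags,
             stringsAsFactors = FALSE)
}

# Cells (image leaves) assigned to a tag: the union of descendant leaves of
# every node carrying it.
tag_cells <- function(forest, tag) {
  tags <- vapply(forest$nodes, `[[`, character(1), "tag")
  tagged <- forest_labels(forest)[tags == tag]
  if (!length(tagged)) stop_lineage("unknown tag: '%s'", tag)
  sort(unique(unlist(lapply(tagged, descendant_leaves, forest = forest))))
}

#' Compare two tagged cell populations by volume
#'
#' The cells of a tag are the descendant leaves of every node carrying it
#' (cells reachable from several tagged ancestors count once). For each tag
#' the count, arithmetic mean and sample standard deviation (n - 1
#' denominator) of the cell volumes are computed over the cells present in
#' `volumes`; the ratio is `mean(tag_a) / mean(tag_b)`. A tag with a single
#' cell has an undefined (NA) standard deviation, not 0.
#'
#' @param volumes A volume table from [region_volumes()].
#' @param forest A `lineage_forest` carrying the tags.
#' @param tag_a,tag_b The two tags to compare.
#' @return A list of class `tag_summary`: `per_tag` (data frame `tag`,
#'   `count`, `mean_volume`, `sd_volume`) and `ratio`.
#' @export
group_summary <- function(volumes, forest, tag_a, tag_b) {
  check_tag(tag_a)
  check_tag(tag_b)
  one <- function(tag) {
    cells <- tag_cells(forest, tag)
    rows <- volumes[volumes$label %in% cells, , drop = FALSE]
    vol <- rows$volume
    data.frame(
      tag = tag, count = nrow(rows),
      mean_volume = if (nrow(rows)) mean(vol) else NA_real_,
      sd_volume = if (nrow(rows) > 1L) stats::sd(vol) else NA_real_,
      stringsAsFactors = FALSE
    )
  }
  a <- one(tag_a)
  b <- one(tag_b)
  structure(
    list(per_tag = rbind(a, b), ratio = a$mean_volume / b$mean_volume),
    class = "tag_summary"
  )
}

#' @export
print.tag_summary <- function(x, ...) {
  p <- x$per_tag
  for (i in seq_len(nrow(p))) {
    cat(sprintf("%s: %d cells, volume %.4g +/- %s\n", p$tag[i], p$count[i],
                p$mean_volume[i],
                if (is.na(p$sd_volume[i])) "NA" else sprintf("%.4g", p$sd_volume[i])))
  }
  cat(sprintf("mean-volume ratio %s / %s = %.6g\n", p$tag[1], p$tag[2], x$ratio))
  invisible(x)
}

# CSV writers. Tag fields are quoted only when they need it; numeric columns
# are written with full precision.
write_csv_plain <- function(df, path) {
  quote_field <- function(x) {
    needs <- grepl('[",]', x)
    x[needs] <- paste0('"', gsub('"', '""', x[needs]), '"')
    x
  }
  cols <- lapply(df, function(col) {
    if (is.character(col)) quote_field(col)
    else if (is.double(col)) {
      vapply(col, function(x) format(x, digits = 15, scientific = FALSE),
             character(1))
    } else as.character(col)
  })
  lines <- c(paste(names(df), collapse = ","),
             do.call(paste, c(cols, sep = ",")))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Write volume and summary tables as CSV
#'
#' `write_volumes_csv()` writes the per-cell table with header
#' `label,voxels,volume,tag`; `write_summary_csv()` writes the per-tag table
#' with header `tag,count,mean_volume,sd_volume`.
#'
#' @param volumes A table from [region_volumes()].
#' @param summary A `tag_summary` from [group_summary()].
#' @param path Destination file.
#' @return Invisibly, `path`.
#' @export
write_volumes_csv <- function(volumes, path) {
  write_csv_plain(volumes[, c("label", "voxels", "volume", "tag")], path)
}

#' @rdname write_volumes_csv
#' @export
write_summary_csv <- function(summary, path) {
  write_csv_plain(summary$per_tag, path)
}
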