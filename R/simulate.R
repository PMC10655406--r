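#' Simulate a tissue growing by recursive binary division
#'
#' Generates a synthetic tissue whose history is known exactly: starting
#' from a single axis-aligned foreground box (inset by one background voxel
#' from the image border), each round every active region is split into two
#' non-empty halves by a plane through its centroid with a random
#' orientation (falling back to an axis-aligned median split along the
#' region's longest axis whenever the drawn plane would empty a half). With
#' probability `stop_prob` a region permanently stops dividing at each
#' round, producing unbalanced trees — the generational gap seen in real
#' lineages. After the last round, a fraction `dropout_frac` of the final
#' labels is renumbered upward to non-consecutive values, emulating the
#' discontinuous labelings left by segmentation post-processing.
#'
#' The output is the full stack of per-generation label images plus the true
#' lineage forest: `images[[g + 1]]` is the tissue after `g` rounds, every
#' region of generation g is the exact union of its two daughters at g + 1,
#' the foreground voxel set never changes, and the labels of the last image
#' are exactly the leaves of the forest. Internal labels are assigned
#' bottom-up from `max(leaf labels) + 1`, so replaying them in ascending
#' order through [link_cells()] reproduces the ground truth. Everything is
#' deterministic given `seed`; the caller's RNG state is left untouched.
#'
#' @param shape Image dimensions (2 or 3 values, each >= 4).
#' @param generations Number of division rounds (>= 0).
#' @param stop_prob Per-round probability that a region stops dividing
#'   (0 <= stop_prob < 1).
#' @param dropout_frac Fraction of final labels renumbered to create gaps
#'   (0 <= dropout_frac < 1).
#' @param seed Integer seed (required).
#' @param spacing Per-axis voxel spacing for the generated images.
#' @return An object of class `generation_stack`: list with `images` (list
#'   of `label_image`, index g + 1 = generation g), `forest` (the true
#'   `lineage_forest`) and `params`.
#' @export
simulate_divisions <- function(shape, generations, stop_prob = 0,
                               dropout_frac = 0, seed, spacing = NULL) {
  shape <- as.integer(shape)
  nd <- length(shape)
  if (nd < 2L || nd > 3L || any(shape < 4L)) {
    stop_lineage("invalid shape: need 2 or 3 axes, each >= 4")
  }
  if (length(generations) != 1L || is.na(generations) || generations < 0) {
    stop_lineage("invalid generations")
  }
  generations <- as.integer(generations)
  if (stop_prob < 0 || stop_prob >= 1) stop_lineage("invalid stop_prob")
  if (dropout_frac < 0 || dropout_frac >= 1) stop_lineage("invalid dropout_frac")
  if (missing(seed)) stop_lineage("seed is required")

  old_seed <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))

  # Foreground: the box inset by one voxel on every face; coords as a matrix.
  grids <- lapply(shape, function(s) 2:(s - 1L))
  coords <- as.matrix(expand.grid(grids, KEEP.OUT.ATTRS = FALSE))
  colnames(coords) <- NULL
  lin <- as.vector(coords %*% c(1, cumprod(shape)[-nd])) -
    sum(c(1, cumprod(shape)[-nd]))  # 0-based linear index
  lin <- lin + 1L

  # Division tree over provisional node ids.
  vox <- list(seq_len(nrow(coords)))  # per-node rows of `coords`
  parent <- c(NA_integer_)
  children <- list(NULL)
  depth <- c(0L)
  active <- c(TRUE)

  split_region <- function(rows) {
    if (length(rows) < 2L) {
      stop_lineage("cannot realize generations: a region of 1 voxel must split")
    }
    rc <- coords[rows, , drop = FALSE]
    ctr <- colMeans(rc)
    normal <- stats::rnorm(nd)
    normal <- normal / sqrt(sum(normal^2))
    side <- as.vector(sweep(rc, 2, ctr) %*% normal) > 0
    if (all(side) || !any(side)) {
      ext <- apply(rc, 2, function(x) diff(range(x)))
      ax <- which.max(ext)
      v <- rc[, ax]
      side <- v > stats::median(v)
      if (!any(side)) side <- v > min(v)
    }
    list(a = rows[!side], b = rows[side])
  }

  for (g in seq_len(generations)) {
    frontier <- which(active & depth == g - 1L)
    for (id in frontier) {
      if (stop_prob > 0 && stats::runif(1) < stop_prob) {
        active[id] <- FALSE
        next
      }
      halves <- split_region(vox[[id]])
      for (h in list(halves$a, halves$b)) {
        vox[[length(vox) + 1L]] <- h
        parent[length(parent) + 1L] <- id
        depth[length(depth) + 1L] <- g
        active[length(active) + 1L] <- TRUE
      }
      children[[id]] <- c(length(vox) - 1L, length(vox))
      length(children) <- length(vox)  # pads the new nodes with NULL
      active[id] <- FALSE
    }
  }

  n_nodes <- length(vox)
  is_leaf <- vapply(seq_len(n_nodes), function(i) is.null(children[[i]]),
                    logical(1))
  leaf_ids <- which(is_leaf)

  # Leaf labels 1..L, then dropout renumbers a sample upward with gaps.
  final_label <- integer(n_nodes)
  final_label[leaf_ids] <- seq_along(leaf_ids)
  n_leaves <- length(leaf_ids)
  k <- floor(dropout_frac * n_leaves)
  if (k > 0) {
    moved <- sort(sample.int(n_leaves, k))
    steps <- sample(2:4, k, replace = TRUE)
    final_label[leaf_ids[moved]] <- n_leaves + cumsum(steps)
  }

  # Internal labels: deepest first, so children always precede their mother.
  internal_ids <- which(!is_leaf)
  internal_ids <- internal_ids[order(-depth[internal_ids], internal_ids)]
  nxt <- max(final_label) + 1L
  for (id in internal_ids) {
    final_label[id] <- nxt
    nxt <- nxt + 1L
  }

  forest <- forest_init(final_label[leaf_ids])
  for (id in internal_ids) {  # ascending label order (deepest first)
    d <- children[[id]]
    res <- link_cells(forest, final_label[d[1]], final_label[d[2]])
    stopifnot(res$mother == final_label[id])
    forest <- res$forest
  }

  images <- vector("list", generations + 1L)
  for (g in 0:generations) {
    frontier <- which((!is_leaf & depth == g) | (is_leaf & depth <= g))
    arr <- integer(prod(shape))
    for (id in frontier) arr[lin[vox[[id]]]] <- final_label[id]
    dim(arr) <- shape
    images[[g + 1L]] <- label_image(arr, spacing = spacing)
  }

  structure(
    list(
      images = images,
      forest = forest,
      params = list(shape = shape, generations = generations,
                    stop_prob = stop_prob, dropout_frac = dropout_frac,
                    seed = as.integer(seed))
    ),
    class = "generation_stack"
  )
}

#' @export
print.generation_stack <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "Generation stack: shape %s, %d generation%s, %d final cells (seed %d)\n",
    paste(p$shape, collapse = "x"), p$generations,
    if (p$generations == 1L) "" else "s",
    length(forest_leaves(x$forest)), p$seed
  ))
  invisible(x)
}
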