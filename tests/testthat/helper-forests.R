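# Shared generators and oracles. All randomized tests seed the RNG
# explicitly, so suites are reproducible.

# A random forest: leaves with possible label gaps, a random number of
# pairings among current roots, random shared tags.
random_forest <- function(max_leaves = 16, tag_prob = 0.2) {
  n <- sample(2:max_leaves, 1)
  labels <- sort(sample.int(ceiling(n * 1.5), n))
  f <- forest_init(labels)
  n_links <- sample(0:(n - 1), 1)
  for (i in seq_len(n_links)) {
    ab <- sample(forest_roots(f), 2)
    f <- link_cells(f, ab[1], ab[2])$forest
  }
  labs <- forest_labels(f)
  for (l in labs[stats::runif(length(labs)) < tag_prob]) {
    f <- set_tag(f, l, paste0("t", sample(5, 1)))
  }
  f
}

# Structural equality: same node set, same mother map, same tags.
forest_equal <- function(a, b, tags = TRUE) {
  la <- sort(forest_labels(a))
  lb <- sort(forest_labels(b))
  if (!identical(la, lb)) return(FALSE)
  ma <- a$mother[order(as.integer(names(a$mother)))]
  mb <- b$mother[order(as.integer(names(b$mother)))]
  if (!identical(unname(as.integer(ma)), unname(as.integer(mb))) ||
      !identical(names(ma), names(mb))) {
    return(FALSE)
  }
  if (tags) {
    for (l in la) if (get_tag(a, l) != get_tag(b, l)) return(FALSE)
  }
  TRUE
}

# Independent path oracle: root-to-node paths by descending the daughter
# pairs from every root, never consulting the mother map.
bf_paths <- function(f) {
  paths <- list()
  walk <- function(lab, path) {
    path <- c(path, lab)
    paths[[as.character(lab)]] <<- path
    for (x in f$nodes[[as.character(lab)]]$daughters) walk(x, path)
  }
  for (r in forest_roots(f)) walk(r, integer(0))
  paths
}

forest_labels <- function(f) as.integer(names(f$nodes))

# Rebuild a forest from a simulator stack's leaf image by replaying the
# ground-truth pairings through link_cells, ascending internal label order.
replay_from_stack <- function(stack) {
  last <- stack$images[[length(stack$images)]]
  f <- forest_init(image_labels(last))
  ints <- sort(setdiff(forest_labels(stack$forest), forest_leaves(stack$forest)))
  for (m in ints) {
    d <- stack$forest$nodes[[as.character(m)]]$daughters
    f <- link_cells(f, d[1], d[2])$forest
  }
  f
}

# The worked example used across format tests: ((1,2)9,(3,4)10)11 over
# leaves 1..8, i.e. three pairings on a fresh 8-cell forest.
example_forest <- function() {
  f <- forest_init(1:8)
  f <- link_cells(f, 1, 2)$forest   # 9
  f <- link_cells(f, 3, 4)$forest   # 10
  f <- link_cells(f, 9, 10)$forest  # 11
  f
}

# A small 2D image whose labels are the given leaves, one horizontal band
# per leaf, with a one-voxel background border.
band_image <- function(leaves, rows_per_band = 2, cols = 6, spacing = NULL) {
  n <- length(leaves)
  v <- matrix(0L, n * rows_per_band + 2L, cols)
  for (i in seq_len(n)) {
    rows <- 1L + (i - 1L) * rows_per_band + seq_len(rows_per_band)
    v[rows, 2:(cols - 1L)] <- leaves[i]
  }
  label_image(v, spacing = spacing)
}
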