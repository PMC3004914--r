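# Shared fixtures and independent oracles used across test files.

# canonical noiseless four-state parameter set used in worked examples:
# strongly state-dependent drug (Kr 600, Ki 6 uM) at 100 uM
noiseless_params <- function(...) {
  args <- list(V_half_mV = -65, k_mV = 8, Kr_uM = 600, Ki_uM = 6,
               drug_concentration_uM = 100, noise_cv = 0, seed = 11)
  over <- list(...)
  args[names(over)] <- over
  do.call(four_state_params, args)
}

fixture_train <- function() {
  utils::read.csv(sciblock_example("table2_train.csv"), stringsAsFactors = FALSE)
}

fixture_avail <- function() {
  utils::read.csv(sciblock_example("table3_availability.csv"), stringsAsFactors = FALSE)
}

# decimal places a printed number was rounded to
printed_decimals <- function(x) {
  s <- sub("0+$", "", format(x, scientific = FALSE, trim = TRUE))
  ifelse(grepl("\\.", s), nchar(sub(".*\\.", "", s)), 0L)
}

# does `calc` match the printed value within its rounding, with the
# rounding of printed inputs propagated?
agrees_with_printed <- function(calc, printed, inputs = list()) {
  tol <- 0.5 * 10^(-printed_decimals(printed))
  for (inp in inputs) tol <- tol + abs(printed) * 0.5 * 10^(-printed_decimals(inp)) / abs(inp)
  abs(calc - printed) <= tol + 1e-12
}

# --- independent clustering oracles (O(n^3), from definitions) ---------

# WPGMA: merge the closest pair; distance of the merged cluster to any
# third cluster is the plain mean of the two constituents' distances.
bf_wpgma <- function(x) {
  D <- as.matrix(stats::dist(x))
  clusters <- as.list(seq_len(nrow(x)))
  heights <- numeric(0)
  partitions <- list()
  while (length(clusters) > 1L) {
    nc <- length(clusters)
    best <- c(Inf, NA, NA)
    for (i in seq_len(nc - 1L)) for (j in (i + 1L):nc)
      if (D[i, j] < best[1]) best <- c(D[i, j], i, j)
    i <- best[2]; j <- best[3]
    newd <- (D[i, ] + D[j, ]) / 2
    keep <- setdiff(seq_len(nc), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], newd[keep]), c(newd[keep], 0))
    clusters <- c(clusters[keep], list(sort(c(clusters[[i]], clusters[[j]]))))
    heights <- c(heights, best[1])
    partitions <- c(partitions, list(clusters))
  }
  list(heights = heights, partitions = partitions)
}

# Ward: merge the pair minimizing the Ward distance computed directly
# from cluster members, d(A,B) = sqrt(2|A||B|/(|A|+|B|)) * ||cA - cB||
bf_ward <- function(x) {
  clusters <- as.list(seq_len(nrow(x)))
  heights <- numeric(0)
  partitions <- list()
  wd <- function(a, b) {
    ca <- colMeans(x[a, , drop = FALSE]); cb <- colMeans(x[b, , drop = FALSE])
    sqrt(2 * length(a) * length(b) / (length(a) + length(b))) *
      sqrt(sum((ca - cb)^2))
  }
  while (length(clusters) > 1L) {
    nc <- length(clusters)
    best <- c(Inf, NA, NA)
    for (i in seq_len(nc - 1L)) for (j in (i + 1L):nc) {
      d <- wd(clusters[[i]], clusters[[j]])
      if (d < best[1]) best <- c(d, i, j)
    }
    i <- best[2]; j <- best[3]
    merged <- sort(c(clusters[[i]], clusters[[j]]))
    clusters <- c(clusters[setdiff(seq_len(nc), c(i, j))], list(merged))
    heights <- c(heights, best[1])
    partitions <- c(partitions, list(clusters))
  }
  list(heights = heights, partitions = partitions)
}

# canonical form of a partition: sorted list of sorted member vectors
canon <- function(p) {
  p <- lapply(p, sort)
  p[order(vapply(p, `[`, numeric(1), 1L))]
}

# partition from cutree labels to canonical form
canon_from_labels <- function(labels) {
  canon(unname(split(seq_along(labels), labels)))
}

# does an hclust tree agree with a brute-force oracle on heights and on
# the flat partition after every merge?
tree_agrees_with_oracle <- function(tree, oracle, tol = 1e-8) {
  if (max(abs(sort(tree$height) - sort(oracle$heights))) > tol) return(FALSE)
  n <- length(tree$labels)
  for (step in seq_len(n - 1L)) {
    k <- n - step
    got <- canon_from_labels(stats::cutree(tree, k = k))
    want <- canon(oracle$partitions[[step]])
    if (!identical(got, want)) return(FALSE)
  }
  TRUE
}
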