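# Shared loaders for the packaged study fixtures and small oracles.

fixture <- function(name) {
  system.file("extdata", name, package = "coastrisk", mustWork = TRUE)
}

load_metals <- function() read_survey(fixture("table1_metals.csv"), "metals")

load_pahs <- function(policy = "zero") {
  substitute_nondetects(read_survey(fixture("table2_pahs.csv"), "pahs"), policy)
}

load_toc <- function() read_survey(fixture("table3_toc.csv"), "toc")

# Greedy Ward clustering recomputed from first principles: at every step merge
# the pair of clusters whose fusion least increases the total within-cluster
# sum of squares; heights on the ward.D2 scale, sqrt(2 * delta SS). Returns
# the merge heights and the partition after every step (as membership lists).
brute_force_ward <- function(x) {
  n <- nrow(x)
  clusters <- as.list(seq_len(n))
  height <- numeric(n - 1)
  partitions <- vector("list", n - 1)
  css <- function(rows) {
    m <- x[rows, , drop = FALSE]
    sum(sweep(m, 2, colMeans(m))^2)
  }
  for (step in seq_len(n - 1)) {
    best <- NULL
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        d_ss <- css(c(clusters[[i]], clusters[[j]])) -
          css(clusters[[i]]) - css(clusters[[j]])
        if (is.null(best) || d_ss < best$d) best <- list(i = i, j = j, d = d_ss)
      }
    }
    height[step] <- sqrt(2 * best$d)
    clusters[[best$i]] <- sort(c(clusters[[best$i]], clusters[[best$j]]))
    clusters[[best$j]] <- NULL
    partitions[[step]] <- clusters
  }
  list(height = height, partitions = partitions)
}

# Canonical form of a partition given as integer labels: list of sorted
# member sets, ordered by smallest member.
canonical_partition <- function(labels) {
  sets <- split(seq_along(labels), labels)
  sets <- lapply(sets, sort)
  unname(sets[order(vapply(sets, min, numeric(1)))])
}

canonical_sets <- function(sets) {
  sets <- lapply(sets, sort)
  unname(sets[order(vapply(sets, min, numeric(1)))])
}
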