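# Independent brute-force evaluators of the split-criterion formulas, written
# directly from their definitions. These never call package internals beyond
# plain arithmetic, and serve as the oracle for equivalence tests.

oracle_entropy <- function(counts) {
  n <- sum(counts)
  acc <- 0
  for (r in counts) {
    p <- r / n
    if (p > 0) acc <- acc - p * log(p) / log(2)
  }
  acc
}

# counts_matrix: classes x subsets
oracle_conditional_entropy <- function(counts_matrix) {
  n <- sum(counts_matrix)
  acc <- 0
  for (j in seq_len(ncol(counts_matrix))) {
    sj <- sum(counts_matrix[, j])
    acc <- acc + (sj / n) * oracle_entropy(counts_matrix[, j])
  }
  acc
}

oracle_gain <- function(counts, counts_matrix) {
  oracle_entropy(counts) - oracle_conditional_entropy(counts_matrix)
}

oracle_split_info <- function(sizes) oracle_entropy(sizes)

oracle_gain_ratio <- function(counts, counts_matrix) {
  si <- oracle_split_info(colSums(counts_matrix))
  if (si == 0) return(NA_real_)
  oracle_gain(counts, counts_matrix) / si
}

oracle_class_weights <- function(cost_mat, counts) {
  C <- apply(cost_mat, 1, sum)
  n <- sum(counts)
  C * n / sum(C * counts)
}

# All class-count vectors with m classes summing to total, total >= 1.
enumerate_distributions <- function(m, total) {
  if (m == 1L) return(list(total))
  out <- list()
  for (r1 in 0:total) {
    for (rest in enumerate_distributions(m - 1L, total - r1)) {
      out[[length(out) + 1L]] <- c(r1, rest)
    }
  }
  out
}

# All ways to split a count vector into two non-empty subsets (a, counts - a).
enumerate_binary_splits <- function(counts) {
  grids <- lapply(counts, function(r) 0:r)
  grid <- do.call(expand.grid, grids)
  out <- list()
  for (i in seq_len(nrow(grid))) {
    a <- as.numeric(grid[i, ])
    b <- counts - a
    if (sum(a) > 0 && sum(b) > 0) {
      out[[length(out) + 1L]] <- cbind(a, b)
    }
  }
  out
}

# Small random labelled dataset with one continuous and one categorical
# attribute, for tree-equivalence fixtures.
random_fixture <- function(n = 40, seed = 1) {
  withr::with_seed(seed, {
    data.frame(
      x = round(stats::runif(n, 0, 10), 1),
      g = sample(c("p", "q", "r"), n, replace = TRUE),
      y = sample(c("a", "b", "c"), n, replace = TRUE,
                 prob = c(0.6, 0.3, 0.1))
    )
  })
}
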