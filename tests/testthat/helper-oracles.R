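# Independent oracles used across the suite. Each reimplements the quantity
# from its definition, without calling the package's own computation path.

# Node-count depth of every tip: climb the edge matrix from tip to root.
oracle_root_distances <- function(tree) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  vapply(seq_len(ntip), function(tip) {
    d <- 0L
    node <- tip
    while (node != root) {
      row <- which(tree$edge[, 2L] == node)
      node <- tree$edge[row, 1L]
      d <- d + 1L
    }
    d
  }, integer(1L)) |> stats::setNames(tree$tip.label)
}

# VIF by explicit auxiliary regressions of each column on the others.
oracle_vif <- function(x) {
  x <- as.matrix(x)
  vapply(seq_len(ncol(x)), function(j) {
    r2 <- summary(stats::lm(x[, j] ~ x[, -j, drop = FALSE]))$r.squared
    1 / (1 - r2)
  }, numeric(1L))
}

# Moran's I by the naive double loop over all ordered pairs, binary weights
# given as a full matrix.
oracle_morans_i <- function(values, w) {
  n <- length(values)
  z <- values - mean(values)
  num <- 0
  s0 <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      num <- num + w[i, j] * z[i] * z[j]
      s0 <- s0 + w[i, j]
    }
  }
  (n / s0) * num / sum(z^2)
}

# Random assemblage over a tree's tips: species names sp1..spk, orders drawn
# with replacement from the tips.
random_assemblage <- function(tree, k, id = "r1") {
  orders <- sample(tree$tip.label, k, replace = TRUE)
  assemblage(id, paste0("sp", seq_len(k)), orders)
}
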