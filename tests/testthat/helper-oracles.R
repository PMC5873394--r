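# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive so they are not the code paths they check.

# Exhaustive HPD: scan every window of k consecutive order statistics.
brute_hpd <- function(x, level = 0.95) {
  x <- sort(x)
  n <- length(x)
  k <- ceiling(level * n)
  best <- c(NA_real_, NA_real_)
  best_w <- Inf
  for (i in seq_len(n - k + 1L)) {
    w <- x[i + k - 1L] - x[i]
    if (w < best_w) {           # strict <: first minimum = lowest lower bound
      best_w <- w
      best <- c(x[i], x[i + k - 1L])
    }
  }
  best
}

# MRCA by intersecting root paths of all tips in the set.
brute_mrca <- function(phy, tips) {
  path_to_root <- function(tip) {
    v <- match(tip, phy$tip.label)
    out <- v
    repeat {
      i <- match(v, phy$edge[, 2L])
      if (is.na(i)) break
      v <- phy$edge[i, 1L]
      out <- c(out, v)
    }
    out
  }
  common <- Reduce(intersect, lapply(tips, path_to_root))
  depth <- ape::node.depth.edgelength(phy)
  common[which.max(depth[common])]
}

# A chronogram built directly from explicit node ages on a fixed 4-tip
# topology ((A,B),(C,D)); handy for constructing exact constraint scenarios.
# ages: named c(ab = , cd = , root = ).
quartet_chronogram <- function(ab, cd, root) {
  phy <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  # node numbering: tips A,B,C,D = 1..4; root = 5; (A,B) = 6; (C,D) = 7
  hgtclock:::new_chronogram(phy, c(0, 0, 0, 0, root, ab, cd))
}

clade_ab <- function(selector = "crown")
  clade_definition("AB", c("A", "B"), selector)
clade_cd <- function(selector = "crown")
  clade_definition("CD", c("C", "D"), selector)

# Random ultrametric chronogram via the jitter simulator on a random topology.
random_chronogram <- function(n_tips, seed, height = 3000, sd = 150) {
  phy <- yule_topology(n_tips, seed = seed)
  nn <- ape::Ntip(phy) + phy$Nnode
  depth <- ape::node.depth.edgelength(hgtclock:::compute_unit_lengths(phy))
  ages <- numeric(nn)
  internal <- (ape::Ntip(phy) + 1L):nn
  # ages shrink geometrically with topological depth: always parent > child
  ages[internal] <- height * 0.7^depth[internal]
  truth <- hgtclock:::new_chronogram(phy, ages)
  simulate_posterior_trace(truth, sd = sd, n = 1, seed = seed + 1)$trace$samples[[1L]]
}
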