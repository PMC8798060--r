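# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: compositions are enumerated exhaustively, and
# lineage counts are recomputed from raw branch time intervals.

# All ordered compositions of N into k positive parts, as a matrix with
# one composition per row (enumerated via cut positions).
enumCompositions <- function(N, k) {
  if (k == 1L) return(matrix(N, 1, 1))
  cuts <- utils::combn(N - 1L, k - 1L)
  t(apply(cuts, 2L, function(cc) diff(c(0L, sort(cc), N))))
}

# Exact P(first j parts sum to exactly f) by enumeration.
oracleDescendantPmf <- function(N, k, j, f) {
  comp <- enumCompositions(N, k)
  mean(rowSums(comp[, seq_len(j), drop = FALSE]) == f)
}

# Exact one-sided tail P(first j parts sum to >= fN) by enumeration.
oracleDescendantTail <- function(N, k, j, fN) {
  comp <- enumCompositions(N, k)
  mean(rowSums(comp[, seq_len(j), drop = FALSE]) >= fN)
}

# Brute-force lineage counts at time t from raw branch intervals of an
# ape phylo: a branch [child_time, parent_time) crosses t; resistance is
# decided by listing the branch's descendant tips directly with
# ape::extract.clade-free traversal.
oracleLineagesAtTime <- function(tree, t, carriers) {
  phy <- tree@phy
  depth <- ape::node.depth.edgelength(phy)
  ntip <- length(phy$tip.label)
  height <- max(depth[seq_len(ntip)])
  times <- height - depth
  kR <- 0L; kS <- 0L
  for (e in seq_len(nrow(phy$edge))) {
    ct <- times[phy$edge[e, 2L]]
    pt <- times[phy$edge[e, 1L]]
    if (ct <= t && t < pt) {
      node <- phy$edge[e, 2L]
      if (node <= ntip) tips <- phy$tip.label[node]
      else {
        sub <- ape::extract.clade(phy, node)
        tips <- sub$tip.label
      }
      if (all(tips %in% carriers)) kR <- kR + 1L else kS <- kS + 1L
    }
  }
  c(k_R = kR, k_S = kS)
}

# Hand-rolled pairwise-difference pi (per site) for a 0/1 matrix,
# independent of the frequency-based implementation.
oraclePi <- function(geno) {
  n <- ncol(geno)
  pairs <- utils::combn(n, 2L)
  diffs <- apply(pairs, 2L, function(pr) sum(geno[, pr[1]] != geno[, pr[2]]))
  mean(diffs) / nrow(geno)
}
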