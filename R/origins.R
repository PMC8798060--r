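# Clustering carrier haplotypes into independent mutational origins,
# monophyly support across genealogy samples, allele ages, and the
# geographic-stratification permutation test.

#' Cluster carrier haplotypes into independent mutational origins
#'
#' Origins are the maximal clades whose descendant leaves are all
#' carriers: every carrier belongs to exactly one cluster, isolated
#' carrier leaves form singleton clusters (MRCA time 0), and clustering
#' depends only on topology, not branch lengths. Clusters are indexed in
#' decreasing size order.
#'
#' @param tree a [LabeledTree-class]
#' @param carriers non-empty character vector of carrier leaf IDs.
#' @param variant variant name recorded in the clusters.
#' @return list of [OriginCluster-class] objects with disjoint leaf sets
#'   whose union is \code{carriers}
#' @export
clusterOrigins <- function(tree, carriers, variant = "variant") {
  stopifnot(is(tree, "LabeledTree"))
  carriers <- unique(as.character(carriers))
  if (!length(carriers)) stop("carriers must be non-empty")
  labs <- leafLabels(tree)
  if (!all(carriers %in% labs)) stop("carriers must be leaves of the tree")
  phy <- tree@phy
  ntip <- length(labs)
  flag <- .allCarrierFlags(tree, carriers)
  root <- ntip + 1L
  parent <- integer(ntip + phy$Nnode)
  parent[phy$edge[, 2L]] <- phy$edge[, 1L]
  parent[root] <- root   # sentinel: the root is its own parent
  maximal <- which(flag & (seq_along(flag) == root | !flag[parent]))
  clusters <- lapply(maximal, function(node) {
    leaves <- .cladeLeaves(tree, node)
    ptime <- if (node == root) Inf else tree@times[parent[node]]
    new("OriginCluster", variantName = variant, originIndex = NA_integer_,
        leafIds = leaves, mrcaTime = unname(tree@times[node]),
        parentTime = unname(ptime), support = NA_real_,
        ageMean = NA_real_, ageCiLow = NA_real_, ageCiHigh = NA_real_)
  })
  sizes <- vapply(clusters, function(cl) length(cl@leafIds), integer(1))
  clusters <- clusters[order(-sizes)]
  for (i in seq_along(clusters)) clusters[[i]]@originIndex <- i
  stopifnot(setequal(unlist(lapply(clusters, originLeaves)), carriers))
  clusters
}

#' Summarise a list of origin clusters as a data.frame
#'
#' @param origins list of [OriginCluster-class]
#' @return data.frame with one row per origin
#' @export
originTable <- function(origins) {
  do.call(rbind, lapply(origins, function(o) data.frame(
    variant = o@variantName, origin = o@originIndex,
    n_haplotypes = length(o@leafIds),
    mrca_time = o@mrcaTime, parent_time = o@parentTime,
    support = o@support, age_mean = o@ageMean,
    age_ci_low = o@ageCiLow, age_ci_high = o@ageCiHigh,
    leaf_ids = paste(o@leafIds, collapse = ","),
    stringsAsFactors = FALSE)))
}

.isClade <- function(tree, leaves) {
  if (length(leaves) <= 1L) return(TRUE)
  mrca <- .mrcaNode(tree, leaves)
  .cladeLeafCount(tree, mrca) == length(leaves)
}

#' Monophyly support of an origin across genealogy samples
#'
#' Fraction of the supplied trees (e.g. MCMC samples of an ancestral
#' recombination graph) in which the cluster's leaf set is exactly a
#' clade.
#'
#' @param trees list of [LabeledTree-class] sharing one leaf universe
#'   (at least 2 trees).
#' @param cluster an [OriginCluster-class] or character vector of leaf IDs.
#' @return numeric fraction in [0, 1]
#' @export
monophylySupport <- function(trees, cluster) {
  leaves <- if (is(cluster, "OriginCluster")) originLeaves(cluster)
            else as.character(cluster)
  if (length(trees) < 2L) stop("need at least 2 genealogy samples")
  universe <- sort(leafLabels(trees[[1]]))
  for (tr in trees) {
    if (!identical(sort(leafLabels(tr)), universe))
      stop("trees do not share the same leaf universe")
  }
  if (!all(leaves %in% universe)) stop("cluster leaves missing from trees")
  mean(vapply(trees, .isClade, logical(1), leaves = leaves))
}

# Bracketing interval [mrca, parent] for the carriers' subtending branch on
# one tree; falls back to the smallest containing clade when the carriers
# are not monophyletic (counted by the caller).
.ageBracket <- function(tree, carriers) {
  mrca <- .mrcaNode(tree, carriers)
  is_clade <- .cladeLeafCount(tree, mrca) == length(carriers)
  phy <- tree@phy
  ntip <- length(phy$tip.label)
  root <- ntip + 1L
  if (mrca == root) {
    list(lo = tree@times[mrca], hi = tree@times[mrca], clade = is_clade)
  } else {
    parent <- phy$edge[match(mrca, phy$edge[, 2L]), 1L]
    list(lo = unname(tree@times[mrca]), hi = unname(tree@times[parent]),
         clade = is_clade)
  }
}

#' Allele age of a mutational origin across genealogy samples
#'
#' Per tree, the mutation that defines the origin lies on the branch
#' between the carrier-clade MRCA and the node above it, and is modelled
#' as uniformly placed on that branch. The per-tree point estimate is the
#' branch midpoint; the aggregate point estimate is the mean of the
#' midpoints, and the 95\% interval is the percentile interval of one
#' seeded uniform placement draw per tree, which propagates both
#' across-sample tree variation and the placement uncertainty. With a
#' single tree the interval degenerates to the midpoint. Trees in which
#' the carriers are not monophyletic contribute the smallest clade
#' containing all carriers, and are counted in \code{n_nonclade}.
#'
#' Other origins of the same variant should be pruned from the trees
#' before calling (the oldest origin otherwise dominates).
#'
#' @param trees list of [LabeledTree-class] samples.
#' @param carriers character vector of the origin's leaf IDs, or a list
#'   of such vectors (one per tree).
#' @param conf confidence level for the percentile interval.
#' @param seed integer seed for the placement draws.
#' @return list with \code{mean}, \code{ci} (length-2), \code{ages}
#'   (per-tree midpoints), \code{n_nonclade}
#' @export
alleleAge <- function(trees, carriers, conf = 0.95, seed = 1L) {
  if (is(trees, "LabeledTree")) trees <- list(trees)
  per_tree <- if (is.list(carriers) && !is.character(carriers)) carriers
              else rep(list(as.character(carriers)), length(trees))
  if (length(per_tree) != length(trees))
    stop("carriers list must match the number of trees")
  brackets <- Map(.ageBracket, trees, per_tree)
  lo <- vapply(brackets, `[[`, numeric(1), "lo")
  hi <- vapply(brackets, `[[`, numeric(1), "hi")
  nonclade <- sum(!vapply(brackets, `[[`, logical(1), "clade"))
  if (nonclade > 0)
    warning(sprintf("carriers not monophyletic in %d of %d trees; used the smallest containing clade",
                    nonclade, length(trees)))
  mids <- (lo + hi) / 2
  if (length(trees) == 1L) {
    ci <- c(mids, mids)
  } else {
    set.seed(seed)
    draws <- lo + runif(length(trees)) * (hi - lo)
    a <- (1 - conf) / 2
    ci <- unname(quantile(draws, c(a, 1 - a)))
  }
  list(mean = mean(mids), ci = ci, ages = mids, n_nonclade = nonclade)
}

#' Rescale an allele age to a different effective population size
#'
#' Genealogy-based ages inferred under an assumed (historical) Ne scale
#' linearly with Ne; an age estimated under \code{ne_assumed} is converted
#' to the contemporary timescale by dividing by
#' \code{ne_contemporary / ne_assumed}.
#'
#' @param raw_age age (same units as the genealogy) under \code{ne_assumed}.
#' @param ne_assumed Ne assumed during genealogy inference (> 0).
#' @param ne_contemporary contemporary Ne estimate (> 0).
#' @return rescaled age, \code{raw_age / (ne_contemporary / ne_assumed)}
#' @examples
#' rescaleAge(6163.8, 5e5, 83294700)  # ~37 years
#' @export
rescaleAge <- function(raw_age, ne_assumed, ne_contemporary) {
  if (any(ne_assumed <= 0) || any(ne_contemporary <= 0))
    stop("effective population sizes must be positive")
  raw_age / (ne_contemporary / ne_assumed)
}

#' Permutation test for geographic stratification of an origin
#'
#' Tests panmixia between two regions: haplotype region labels are
#' shuffled across the two-region universe and the proportion of the
#' origin's haplotypes mapping to \code{regions[1]} is recomputed
#' \code{n_perm} times. The origin is flagged as geographically
#' stratified when the observed proportion falls outside the percentile
#' interval of the permuted proportions.
#'
#' @param origin an [OriginCluster-class] or character vector of leaf IDs.
#' @param meta haplotype metadata (see [readHaplotypeMetadata()]); every
#'   origin leaf must have a region among \code{regions}.
#' @param regions length-2 character vector naming the two-region
#'   partition.
#' @param n_perm number of permutations (>= 100 recommended).
#' @param seed integer RNG seed (mandatory).
#' @param conf confidence level of the null percentile interval.
#' @return list with \code{observed}, \code{ci}, \code{stratified},
#'   \code{region}, \code{n_perm}
#' @export
geoPermutation <- function(origin, meta, regions, n_perm = 1000, seed,
                           conf = 0.95) {
  if (missing(seed)) stop("seed is mandatory")
  leaves <- if (is(origin, "OriginCluster")) originLeaves(origin)
            else as.character(origin)
  if (length(regions) != 2L) stop("regions must name a two-region partition")
  if (n_perm < 100) warning("n_perm < 100: the null interval will be coarse")
  universe <- meta[meta$region %in% regions, , drop = FALSE]
  idx <- match(leaves, universe$haplotype_id)
  if (anyNA(idx))
    stop("origin leaves without a region in the two-region partition: ",
         paste(head(leaves[is.na(idx)], 5), collapse = ", "))
  labels <- universe$region
  observed <- mean(labels[idx] == regions[1])
  set.seed(seed)
  perms <- vapply(seq_len(n_perm), function(i) {
    mean(sample(labels)[idx] == regions[1])
  }, numeric(1))
  a <- (1 - conf) / 2
  ci <- unname(quantile(perms, c(a, 1 - a)))
  list(observed = observed, ci = ci,
       stratified = observed < ci[1] || observed > ci[2],
       region = regions[1], n_perm = n_perm)
}
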