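# Order-of-coalescence tests of non-neutral allele-frequency change.
#
# Under the neutral coalescent the descendant counts of the k lineages
# present at any past time are exchangeable: the vector of counts is a
# uniform ordered composition of N into k positive parts. The probability
# that j marked lineages leave exactly f present-day descendants is then
#
#   P(f | N, k, j) = C(f-1, j-1) C(N-f-1, k-j-1) / C(N-1, k-1),
#
# a (shifted) hypergeometric in the "stars and bars" cut positions. All
# arithmetic is in log-space (log-gamma / log-sum-exp): sample sizes of
# several hundred overflow binomial coefficients in doubles.

.logSumExp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  m <- max(x)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(x - m)))
}

#' Descendant-count null distribution for marked ancestral lineages
#'
#' Probability that \code{j} marked of \code{k} exchangeable ancestral
#' lineages leave exactly \code{f} of \code{N} present-day descendants
#' under the neutral coalescent. The support is
#' \code{j <= f <= N - (k - j)}; values of \code{f} outside it return 0.
#'
#' @param N present-day sample size (leaf count).
#' @param k number of ancestral lineages, \code{2 <= k <= N}.
#' @param j number of marked ancestral lineages, \code{1 <= j < k}.
#' @param f descendant count(s); vectorized.
#' @param log return log-probabilities.
#' @return numeric vector of probabilities, same length as \code{f}
#' @examples
#' descendantCountPmf(5, 3, 1, 1:3)  # 1/2, 1/3, 1/6
#' @export
descendantCountPmf <- function(N, k, j, f, log = FALSE) {
  stopifnot(length(N) == 1L, length(k) == 1L, length(j) == 1L)
  if (k > N) stop("k must not exceed N")
  if (j < 1L || j >= k) stop("need 1 <= j < k")
  lp <- lchoose(f - 1, j - 1) + lchoose(N - f - 1, k - j - 1) -
    lchoose(N - 1, k - 1)
  lp[f < j | f > N - (k - j)] <- -Inf
  if (log) lp else exp(lp)
}

# One-sided upper tail P(F >= fN) for the descendant-count null, log-space.
.descendantTailLogP <- function(N, k, j, fN) {
  upper <- N - (k - j)
  if (fN <= j) return(0)             # log(1): the bound is always met
  if (fN > upper) return(-Inf)
  .logSumExp(descendantCountPmf(N, k, j, fN:upper, log = TRUE))
}

.mrcaNode <- function(tree, leaves) {
  phy <- tree@phy
  idx <- match(leaves, phy$tip.label)
  if (length(idx) == 1L) return(idx)
  ape::getMRCA(phy, idx)
}

.cladeLeafCount <- function(tree, node) {
  ntip <- length(tree@phy$tip.label)
  if (node <= ntip) return(1L)
  length(.cladeLeaves(tree, node))
}

.cladeLeaves <- function(tree, node) {
  phy <- tree@phy
  ntip <- length(phy$tip.label)
  if (node <= ntip) return(phy$tip.label[node])
  kids <- phangornFreeDescendants(phy, node)
  phy$tip.label[kids]
}

# descendant tips of an internal node (iterative stack walk; no extra deps)
phangornFreeDescendants <- function(phy, node) {
  ntip <- length(phy$tip.label)
  out <- integer(0)
  stack <- node
  children <- split(phy$edge[, 2L], phy$edge[, 1L])
  while (length(stack)) {
    nd <- stack[[1L]]; stack <- stack[-1L]
    if (nd <= ntip) out <- c(out, nd)
    else stack <- c(children[[as.character(nd)]], stack)
  }
  out
}

.checkMonophyletic <- function(tree, carriers) {
  mrca <- .mrcaNode(tree, carriers)
  clade <- .cladeLeaves(tree, mrca)
  if (!setequal(clade, carriers))
    stop("carriers are not monophyletic on this tree; cluster them into ",
         "independent origins first (clusterOrigins) and test per origin")
  mrca
}

.testResultRow <- function(origin_id, test_kind, f_N, N, k_S = NA_integer_,
                           k_R_t = NA_integer_, k_S_t = NA_integer_,
                           t = NA_real_, p_value, flag = "") {
  data.frame(origin_id = origin_id, test_kind = test_kind,
             f_N = f_N, N = N, k_S = k_S, k_R_t = k_R_t, k_S_t = k_S_t,
             t = t, p_value = p_value, q_value = NA_real_, flag = flag,
             stringsAsFactors = FALSE)
}

#' Test for selection since a mutation arose de novo
#'
#' One-sided test of whether the focal carriers' present-day count is too
#' large to be explained by drift since the mutation's 1-to-2 event. The
#' carrier-clade MRCA marks that event; \code{k_S} is the susceptible
#' lineage count just above it (at \code{MRCA + eps}). The p-value is the
#' upper tail of the descendant-count null with \code{j = 2} marked among
#' \code{k_S + 2} lineages. Depends only on the order of coalescent
#' events, not branch lengths.
#'
#' @param tree a [LabeledTree-class], already pruned of carriers from any
#'   other origin of the same variant.
#' @param carriers character vector of carrier leaf IDs forming one
#'   monophyletic clade; a singleton yields p = 1 with a flag (the test is
#'   undefined for one carrier).
#' @param origin_id identifier copied into the result.
#' @return one-row data.frame: \code{origin_id, test_kind, f_N, N, k_S,
#'   k_R_t, k_S_t, t, p_value, q_value, flag}
#' @export
testDenovo <- function(tree, carriers, origin_id = "origin") {
  stopifnot(is(tree, "LabeledTree"))
  labs <- leafLabels(tree)
  if (!all(carriers %in% labs)) stop("carriers must be leaves of the tree")
  N <- length(labs)
  f_N <- length(carriers)
  if (f_N < 1L) stop("no carriers supplied")
  if (f_N == 1L)
    return(.testResultRow(origin_id, "denovo", f_N, N, p_value = 1,
                          flag = "singleton: test undefined"))
  if (f_N >= N) stop("carriers must be a proper subset of the leaves")
  mrca <- .checkMonophyletic(tree, carriers)
  mrca_time <- tree@times[mrca]
  eps <- 1e-9 * rootTime(tree)
  counts <- lineagesAtTime(tree, mrca_time + eps, carriers)
  k_S <- unname(counts["k_S"])
  if (k_S < 1L) stop("no susceptible lineages above the carrier MRCA")
  p <- exp(.descendantTailLogP(N, k_S + 2L, 2L, f_N))
  p <- min(p, 1)
  .testResultRow(origin_id, "denovo", f_N, N, k_S = k_S,
                 t = mrca_time, p_value = p)
}

#' Test for selection over a recent timescale (standing variation)
#'
#' One-sided test of non-neutral frequency change between a recent cutoff
#' time \code{t} and the present: given \code{k_R(t)} resistant and
#' \code{k_S(t)} susceptible lineages at \code{t}, the p-value is the
#' upper tail of the descendant-count null with \code{j = k_R(t)} marked
#' among \code{k_R(t) + k_S(t)} lineages.
#'
#' @inheritParams testDenovo
#' @param t cutoff time before present, \code{0 < t <} the carrier-clade
#'   MRCA time (older cutoffs are the de novo test's regime).
#' @return one-row data.frame as in [testDenovo()]
#' @export
testRecent <- function(tree, carriers, t, origin_id = "origin") {
  stopifnot(is(tree, "LabeledTree"))
  labs <- leafLabels(tree)
  if (!all(carriers %in% labs)) stop("carriers must be leaves of the tree")
  N <- length(labs)
  f_N <- length(carriers)
  if (f_N < 2L)
    return(.testResultRow(origin_id, "recent", f_N, N, t = t, p_value = 1,
                          flag = "singleton: test undefined"))
  mrca <- .checkMonophyletic(tree, carriers)
  mrca_time <- tree@times[mrca]
  if (t <= 0) stop("t must be positive")
  if (t >= mrca_time)
    stop("t is older than the carrier-clade MRCA; use testDenovo instead")
  counts <- lineagesAtTime(tree, t, carriers)
  k_R <- unname(counts["k_R"])
  k_S <- unname(counts["k_S"])
  if (k_R < 1L || k_R > f_N) stop("inconsistent resistant lineage count")
  p <- exp(.descendantTailLogP(N, k_R + k_S, k_R, f_N))
  p <- min(p, 1)
  .testResultRow(origin_id, "recent", f_N, N, k_R_t = k_R, k_S_t = k_S,
                 t = t, p_value = p)
}

#' Run both selection tests across the origins of a variant
#'
#' For each origin, all other origins' carrier leaves are pruned from the
#' tree so the focal lineage is compared against susceptible haplotypes
#' only; the de novo test always runs, and the recent-timescale test runs
#' when the carrier-clade MRCA predates the cutoff
#' \code{recent_fraction * tree height} (height of the pruned tree).
#' Benjamini-Hochberg q-values are attached within each test family.
#'
#' @param tree a [LabeledTree-class] carrying all origins' leaves.
#' @param origins a list of [OriginCluster-class] objects (or bare
#'   character vectors of leaf IDs) with pairwise-disjoint leaf sets.
#' @param recent_fraction recent-timescale cutoff as a fraction of tree
#'   height (default 0.01, i.e. the most recent 1\% of the tree).
#' @param alpha FDR level used for the significance flags.
#' @return data.frame with one row per origin x test family
#' @export
runOriginTests <- function(tree, origins, recent_fraction = 0.01,
                           alpha = 0.05) {
  stopifnot(is(tree, "LabeledTree"))
  if (recent_fraction <= 0 || recent_fraction >= 1)
    stop("recent_fraction must be in (0, 1)")
  leafsets <- lapply(origins, function(o)
    if (is(o, "OriginCluster")) originLeaves(o) else as.character(o))
  ids <- vapply(seq_along(origins), function(i) {
    o <- origins[[i]]
    if (is(o, "OriginCluster"))
      sprintf("%s#%d", o@variantName, o@originIndex)
    else sprintf("origin#%d", i)
  }, character(1))
  all_carriers <- unlist(leafsets)
  if (anyDuplicated(all_carriers))
    stop("origin leaf sets overlap; origins of one variant must be disjoint")
  if (!all(all_carriers %in% leafLabels(tree)))
    stop("origin leaves missing from the tree")
  rows <- list()
  for (i in seq_along(leafsets)) {
    other <- setdiff(all_carriers, leafsets[[i]])
    tr_i <- if (length(other)) pruneLeaves(tree, other) else tree
    rows[[length(rows) + 1L]] <-
      testDenovo(tr_i, leafsets[[i]], origin_id = ids[i])
    if (length(leafsets[[i]]) >= 2L) {
      cutoff <- recent_fraction * rootTime(tr_i)
      mrca_time <- tr_i@times[.mrcaNode(tr_i, leafsets[[i]])]
      if (mrca_time > cutoff)
        rows[[length(rows) + 1L]] <-
          testRecent(tr_i, leafsets[[i]], t = cutoff, origin_id = ids[i])
    }
  }
  res <- do.call(rbind, rows)
  for (fam in unique(res$test_kind)) {
    sel <- res$test_kind == fam
    res$q_value[sel] <- p.adjust(res$p_value[sel], method = "BH")
  }
  res$significant <- res$q_value <= alpha
  rownames(res) <- NULL
  res
}

#' Monte-Carlo oracle for the descendant-count tail probability
#'
#' Draws uniform ordered compositions of \code{N} into \code{k} positive
#' parts and reports the fraction whose first \code{j} parts sum to at
#' least \code{f_N}, with a binomial standard error. Used as an
#' implementation-independent check of the analytic tail.
#'
#' @inheritParams descendantCountPmf
#' @param f_N lower bound on the marked lineages' descendant total.
#' @param n_draws number of Monte-Carlo draws (>= 1e4 recommended).
#' @param seed integer RNG seed (mandatory).
#' @return list with \code{estimate}, \code{se}, \code{n_draws}
#' @export
neutralLabellingOracle <- function(N, k, j, f_N, n_draws = 1e4, seed) {
  stopifnot(k >= 2, k <= N, j >= 1, j < k)
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  hits <- 0L
  for (i in seq_len(n_draws)) {
    cuts <- sort(sample.int(N - 1L, k - 1L))
    parts <- diff(c(0L, cuts, N))
    if (sum(parts[seq_len(j)]) >= f_N) hits <- hits + 1L
  }
  est <- hits / n_draws
  list(estimate = est, se = sqrt(est * (1 - est) / n_draws),
       n_draws = n_draws)
}
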