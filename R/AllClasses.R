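#' @import methods
#' @importFrom stats cor sd quantile approx rexp runif rnorm rpois rbinom
#'   p.adjust pchisq weighted.mean setNames
#' @importFrom utils read.table write.table head tail
NULL

setOldClass("phylo")

#' Rooted ultrametric genealogy with node times
#'
#' An S4 container for a rooted, binary, ultrametric genealogy whose leaves
#' are present-day haplotypes. Node times are measured backwards from the
#' present (leaves at time 0, the root oldest), in generations or years;
#' the unit tag is opaque metadata carried along by the object. The
#' underlying topology and branch lengths are stored as an \code{ape}
#' \code{phylo}; \code{times} holds one entry per node (tips first, then
#' internal nodes, in \code{phylo} node numbering).
#'
#' @slot phy an \code{ape::phylo} object, rooted and binary.
#' @slot times numeric vector of node times before present, indexed by
#'   \code{phylo} node number (tips \code{1..n}, internals \code{n+1..}).
#' @slot units character, \code{"generations"} or \code{"years"} (opaque).
#' @slot tol numeric absolute tolerance used when the object was validated.
#'
#' @seealso [parseNewick()], [lineagesAtTime()], [pruneLeaves()]
#' @export
setClass("LabeledTree",
  slots = c(phy = "phylo", times = "numeric", units = "character",
            tol = "numeric"))

setValidity("LabeledTree", function(object) {
  phy <- object@phy
  msgs <- character()
  ntip <- length(phy$tip.label)
  if (ntip < 2) msgs <- c(msgs, "tree must have at least 2 leaves")
  if (anyDuplicated(phy$tip.label) || any(!nzchar(phy$tip.label)))
    msgs <- c(msgs, "leaf labels must be unique and non-empty")
  if (!ape::is.binary(phy))
    msgs <- c(msgs, "tree contains polytomies; only binary genealogies are supported")
  if (length(object@times) != ntip + phy$Nnode)
    msgs <- c(msgs, "times must have one entry per node")
  tol <- object@tol
  leaf_t <- object@times[seq_len(ntip)]
  if (any(abs(leaf_t) > tol)) {
    worst <- which.max(abs(leaf_t))
    msgs <- c(msgs, sprintf(
      "tree is not ultrametric: leaf '%s' is at time %.3g (tolerance %.3g)",
      phy$tip.label[worst], leaf_t[worst], tol))
  }
  # parent strictly older than child, up to tolerance ties
  pt <- object@times[phy$edge[, 1]]
  ct <- object@times[phy$edge[, 2]]
  if (any(pt - ct < -tol))
    msgs <- c(msgs, "an internal node is younger than its child")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "LabeledTree", function(object) {
  cat(sprintf("LabeledTree: %d leaves, root time %.6g %s\n",
              length(object@phy$tip.label), rootTime(object), object@units))
})

#' Piecewise-constant effective population size trajectory
#'
#' Epochs are half-open intervals \code{[start, end)} in years (or
#' generations) before present, each with a constant diploid effective
#' population size. Epochs must be non-overlapping and in increasing time
#' order; the last epoch may extend to \code{Inf}.
#'
#' @slot epochs data.frame with columns \code{start}, \code{end}, \code{ne}.
#' @slot units character time unit tag (opaque metadata).
#'
#' @seealso [readCoal()], [geometricMeanNe()], [harmonicMeanNe()]
#' @export
setClass("NeTrajectory",
  slots = c(epochs = "data.frame", units = "character"))

setValidity("NeTrajectory", function(object) {
  e <- object@epochs
  msgs <- character()
  if (!all(c("start", "end", "ne") %in% names(e)))
    msgs <- c(msgs, "epochs must have columns start, end, ne")
  else {
    if (nrow(e) == 0) msgs <- c(msgs, "trajectory has no epochs")
    if (any(e$start >= e$end)) msgs <- c(msgs, "epoch start must be < end")
    if (any(!is.finite(e$ne) | e$ne <= 0))
      msgs <- c(msgs, "Ne must be positive and finite in every epoch")
    if (nrow(e) > 1 && any(e$start[-1] < e$end[-nrow(e)] - 1e-9))
      msgs <- c(msgs, "epochs overlap or are out of order")
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "NeTrajectory", function(object) {
  e <- object@epochs
  cat(sprintf("NeTrajectory: %d epochs over [%.4g, %.4g] %s, Ne range [%.4g, %.4g]\n",
              nrow(e), min(e$start), max(e$end), object@units,
              min(e$ne), max(e$ne)))
})

#' Phased biallelic haplotype (or genotype dosage) matrix
#'
#' Sites are rows, samples are columns. In \code{"haplotype"} mode the
#' entries are phased 0/1 allele indicators per haplotype; in
#' \code{"genotype"} mode they are 0/1/2 alternate-allele dosages per
#' individual. Site metadata carries 1-based positions (strictly
#' increasing within each chromosome) and a functional class
#' (\code{missense}, \code{synonymous} or \code{other}) used to filter
#' linkage-disequilibrium scans.
#'
#' @slot geno integer matrix, sites x samples, NA for missing.
#' @slot sites data.frame with columns \code{chrom}, \code{pos},
#'   \code{ref}, \code{alt}, \code{class}.
#' @slot mode character, \code{"haplotype"} or \code{"genotype"}.
#'
#' @seealso [readHaplotypeVcf()], [signedR()], [windowedMeanR()]
#' @export
setClass("HaplotypeMatrix",
  slots = c(geno = "matrix", sites = "data.frame", mode = "character"))

setValidity("HaplotypeMatrix", function(object) {
  msgs <- character()
  g <- object@geno
  s <- object@sites
  if (!object@mode %in% c("haplotype", "genotype"))
    msgs <- c(msgs, "mode must be 'haplotype' or 'genotype'")
  if (nrow(g) != nrow(s))
    msgs <- c(msgs, "geno and sites must have the same number of rows")
  if (!all(c("chrom", "pos", "ref", "alt", "class") %in% names(s)))
    msgs <- c(msgs, "sites must have columns chrom, pos, ref, alt, class")
  maxval <- if (identical(object@mode, "genotype")) 2L else 1L
  v <- g[!is.na(g)]
  if (length(v) && (any(v < 0L) || any(v > maxval)))
    msgs <- c(msgs, sprintf("entries must be integers in 0..%d (biallelic)", maxval))
  if (nrow(s) > 1) {
    bad <- unlist(lapply(split(s$pos, s$chrom), function(p) any(diff(p) <= 0)))
    if (any(bad))
      msgs <- c(msgs, "positions must be strictly increasing within chromosome")
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "HaplotypeMatrix", function(object) {
  cat(sprintf("HaplotypeMatrix (%s mode): %d sites x %d samples on %d chromosome(s)\n",
              object@mode, nrow(object@geno), ncol(object@geno),
              length(unique(object@sites$chrom))))
})

#' One independent mutational origin of a resistance variant
#'
#' A maximal clade of present-day haplotypes all carrying the same focal
#' variant, interpreted as descending from one independent occurrence of
#' the mutation. The mutation lies on the branch between the clade MRCA
#' and the node above it, so its age is bracketed by
#' \code{[mrcaTime, parentTime]}.
#'
#' @slot variantName character name of the resistance variant.
#' @slot originIndex integer index among the origins of this variant.
#' @slot leafIds character vector of member haplotype IDs.
#' @slot mrcaTime numeric time of the clade MRCA (0 for singletons).
#' @slot parentTime numeric time of the node above the clade MRCA
#'   (\code{Inf} when the clade is the whole tree).
#' @slot support numeric fraction of genealogy samples in which the leaf
#'   set is monophyletic (NA until computed).
#' @slot ageMean,ageCiLow,ageCiHigh numeric allele-age summaries in tree
#'   units (NA until computed).
#'
#' @seealso [clusterOrigins()], [monophylySupport()], [alleleAge()]
#' @export
setClass("OriginCluster",
  slots = c(variantName = "character", originIndex = "integer",
            leafIds = "character", mrcaTime = "numeric",
            parentTime = "numeric", support = "numeric",
            ageMean = "numeric", ageCiLow = "numeric", ageCiHigh = "numeric"))

setValidity("OriginCluster", function(object) {
  msgs <- character()
  if (length(object@leafIds) < 1) msgs <- c(msgs, "origin must contain at least one leaf")
  if (anyDuplicated(object@leafIds)) msgs <- c(msgs, "duplicate leaf ids")
  if (!is.na(object@mrcaTime) && !is.na(object@parentTime) &&
      object@mrcaTime > object@parentTime)
    msgs <- c(msgs, "mrcaTime must be <= parentTime")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "OriginCluster", function(object) {
  cat(sprintf("OriginCluster %s #%d: %d haplotype(s), MRCA %.4g, support %s\n",
              object@variantName, object@originIndex, length(object@leafIds),
              object@mrcaTime,
              if (is.na(object@support)) "NA" else sprintf("%.2f", object@support)))
})

# ---- generics ----------------------------------------------------------

#' Number of leaves of a genealogy
#' @param x a [LabeledTree-class]
#' @return integer leaf count
#' @export
setGeneric("nLeaves", function(x) standardGeneric("nLeaves"))

#' @rdname nLeaves
setMethod("nLeaves", "LabeledTree", function(x) length(x@phy$tip.label))

#' Leaf (haplotype) labels of a genealogy
#' @param x a [LabeledTree-class]
#' @return character vector of haplotype IDs
#' @export
setGeneric("leafLabels", function(x) standardGeneric("leafLabels"))

#' @rdname leafLabels
setMethod("leafLabels", "LabeledTree", function(x) x@phy$tip.label)

#' Root time (tree height) of a genealogy
#' @param x a [LabeledTree-class]
#' @return numeric time of the root before present
#' @export
setGeneric("rootTime", function(x) standardGeneric("rootTime"))

#' @rdname rootTime
setMethod("rootTime", "LabeledTree", function(x) {
  x@times[length(x@phy$tip.label) + 1L]
})

#' Node times of a genealogy
#' @param x a [LabeledTree-class]
#' @return numeric vector of times before present in phylo node order
#' @export
setGeneric("nodeTimes", function(x) standardGeneric("nodeTimes"))

#' @rdname nodeTimes
setMethod("nodeTimes", "LabeledTree", function(x) x@times)

#' Epoch table of an Ne trajectory
#' @param x a [NeTrajectory-class]
#' @return data.frame with columns start, end, ne
#' @export
setGeneric("epochs", function(x) standardGeneric("epochs"))

#' @rdname epochs
setMethod("epochs", "NeTrajectory", function(x) x@epochs)

#' Site metadata of a haplotype matrix
#' @param x a [HaplotypeMatrix-class]
#' @return data.frame of site records
#' @export
setGeneric("siteInfo", function(x) standardGeneric("siteInfo"))

#' @rdname siteInfo
setMethod("siteInfo", "HaplotypeMatrix", function(x) x@sites)

#' Sample (haplotype or individual) IDs of a haplotype matrix
#' @param x a [HaplotypeMatrix-class]
#' @return character vector of column IDs
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname sampleIds
setMethod("sampleIds", "HaplotypeMatrix", function(x) colnames(x@geno))

#' Genotype / haplotype matrix values
#' @param x a [HaplotypeMatrix-class]
#' @return integer matrix, sites x samples
#' @export
setGeneric("genoMatrix", function(x) standardGeneric("genoMatrix"))

#' @rdname genoMatrix
setMethod("genoMatrix", "HaplotypeMatrix", function(x) x@geno)

#' Leaf ids of an origin cluster
#' @param x an [OriginCluster-class]
#' @return character vector of haplotype IDs
#' @export
setGeneric("originLeaves", function(x) standardGeneric("originLeaves"))

#' @rdname originLeaves
setMethod("originLeaves", "OriginCluster", function(x) x@leafIds)
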