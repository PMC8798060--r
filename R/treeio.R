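# Genealogy I/O and lineage-counting primitives.
#
# Time convention: continuous time before present, leaves at 0. A branch
# with child time c and parent time p "crosses" time t when c <= t < p
# (half-open on the older end), so a node at exactly t counts as already
# coalesced; this makes lineage counts unambiguous at event times.

.default_tol <- function(height) max(1e-9, 1e-9 * height)

# Construct a LabeledTree from an ape phylo with branch lengths.
.labeledTree <- function(phy, units = "generations", tol = NULL,
                         resolve.polytomies = FALSE) {
  if (is.null(phy$edge.length))
    stop("newick tree must carry branch lengths")
  if (!ape::is.binary(phy) || !ape::is.rooted(phy)) {
    if (resolve.polytomies) {
      phy <- ape::multi2di(phy, random = FALSE)
      phy$edge.length[is.na(phy$edge.length)] <- 0
    } else {
      stop("tree contains polytomies; set resolve.polytomies = TRUE to ",
           "resolve them with zero-length branches")
    }
  }
  depth <- ape::node.depth.edgelength(phy)   # root-to-node path lengths
  ntip <- length(phy$tip.label)
  height <- max(depth[seq_len(ntip)])
  times <- height - depth
  if (is.null(tol)) tol <- .default_tol(height)
  leaf_t <- times[seq_len(ntip)]
  if (any(abs(leaf_t) > tol)) {
    worst <- which.max(abs(leaf_t))
    stop(sprintf(
      "tree is not ultrametric within tolerance %.3g: worst leaf '%s' at time %.6g",
      tol, phy$tip.label[worst], leaf_t[worst]))
  }
  times[seq_len(ntip)] <- 0
  new("LabeledTree", phy = phy, times = times, units = units, tol = tol)
}

#' Parse a newick string into a labelled ultrametric genealogy
#'
#' Node times are reconstructed from root-to-leaf path lengths (leaves at
#' time 0, root oldest). The tree must be binary and ultrametric within
#' tolerance; scientific-notation branch lengths and labelled internal
#' nodes are tolerated.
#'
#' @param text a single newick string (terminated by \code{;}).
#' @param units time unit tag carried as opaque metadata.
#' @param tol absolute ultrametricity tolerance; default
#'   \code{max(1e-9, 1e-9 * height)}.
#' @param resolve.polytomies resolve polytomies with zero-length branches
#'   instead of rejecting them (off by default; genealogies extracted from
#'   an ancestral recombination graph are binary).
#' @return a [LabeledTree-class]
#' @examples
#' tr <- parseNewick("((A:1,B:1):1,C:2);")
#' nLeaves(tr)   # 3
#' rootTime(tr)  # 2
#' @export
parseNewick <- function(text, units = "generations", tol = NULL,
                        resolve.polytomies = FALSE) {
  stopifnot(is.character(text), length(text) == 1L)
  off <- .newickSyntaxOffset(text)
  if (!is.na(off))
    stop(sprintf("malformed newick at character offset %d", off))
  phy <- tryCatch(ape::read.tree(text = text), error = function(e) NULL,
                  warning = function(w) NULL)
  if (is.null(phy) || inherits(phy, "multiPhylo"))
    phy <- tryCatch(ape::read.tree(text = text)[[1]], error = function(e) NULL)
  if (is.null(phy))
    stop(sprintf("malformed newick at character offset %d", nchar(text)))
  .labeledTree(phy, units = units, tol = tol,
               resolve.polytomies = resolve.polytomies)
}

# Best-effort syntax check returning the offset of the first defect, NA if ok.
.newickSyntaxOffset <- function(text) {
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    else if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) return(i)
    }
  }
  if (depth != 0L) return(length(chars))
  if (!any(chars == ";")) return(length(chars))
  NA_integer_
}

#' Read one genealogy per line from a newick file
#'
#' Multi-line files are treated as MCMC genealogy samples over the same
#' leaf set.
#'
#' @param path path to a newick file (one tree per line).
#' @inheritParams parseNewick
#' @return a list of [LabeledTree-class] objects
#' @export
readNewickTrees <- function(path, units = "generations", tol = NULL,
                            resolve.polytomies = FALSE) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("no trees found in ", path)
  lapply(lines, parseNewick, units = units, tol = tol,
         resolve.polytomies = resolve.polytomies)
}

#' Serialize a labelled genealogy to newick
#'
#' @param tree a [LabeledTree-class]
#' @param digits significant digits for branch lengths (default 12, enough
#'   to round-trip node times at 1e-9 relative precision).
#' @return a newick string
#' @export
writeNewick <- function(tree, digits = 12) {
  stopifnot(is(tree, "LabeledTree"))
  ape::write.tree(tree@phy, digits = digits)
}

# Logical flag per node: are all descendant leaves carriers?
.allCarrierFlags <- function(tree, carriers) {
  phy <- tree@phy
  ntip <- length(phy$tip.label)
  nn <- ntip + phy$Nnode
  flag <- logical(nn)
  flag[seq_len(ntip)] <- phy$tip.label %in% carriers
  # edges in ape cladewise order: traverse children before parents by
  # processing edges in reverse postorder
  ord <- ape::reorder.phylo(phy, "postorder")$edge
  flag[(ntip + 1L):nn] <- TRUE
  for (i in seq_len(nrow(ord))) {
    p <- ord[i, 1L]; ch <- ord[i, 2L]
    flag[p] <- flag[p] && flag[ch]
  }
  flag
}

#' Count resistant and susceptible lineages crossing a time
#'
#' A branch crosses time \code{t} when \code{child_time <= t < parent_time}
#' (half-open on the older end: a node at exactly \code{t} counts as
#' already coalesced). A lineage is resistant iff all its descendant
#' leaves are carriers, susceptible otherwise; the two counts always sum
#' to the total number of lineages crossing \code{t}.
#'
#' @param tree a [LabeledTree-class]
#' @param t time before present, \code{0 <= t < rootTime(tree)}.
#' @param carriers character vector of carrier leaf IDs (subset of the
#'   leaf labels).
#' @return named integer vector \code{c(k_R = ..., k_S = ...)}
#' @examples
#' tr <- parseNewick("((A:1,B:1):1,C:2);")
#' lineagesAtTime(tr, 1.5, carriers = c("A", "B"))  # k_R = 1, k_S = 1
#' @export
lineagesAtTime <- function(tree, t, carriers = character()) {
  stopifnot(is(tree, "LabeledTree"))
  if (!all(carriers %in% leafLabels(tree)))
    stop("carriers must be a subset of the leaf labels")
  rt <- rootTime(tree)
  if (t < 0) stop("t must be non-negative")
  if (t >= rt) stop("t must be strictly below the root time (no lineages above the root)")
  phy <- tree@phy
  times <- tree@times
  flag <- .allCarrierFlags(tree, carriers)
  ct <- times[phy$edge[, 2L]]
  pt <- times[phy$edge[, 1L]]
  crossing <- ct <= t & t < pt
  res <- flag[phy$edge[crossing, 2L]]
  c(k_R = sum(res), k_S = sum(!res))
}

#' Drop leaves from a genealogy, suppressing unary nodes
#'
#' Surviving node times are unchanged (pairwise path lengths among the
#' remaining leaves are preserved); the root becomes the MRCA of the
#' survivors.
#'
#' @param tree a [LabeledTree-class]
#' @param drop character vector of leaf IDs to remove (a proper subset of
#'   the leaves; dropping none returns the tree unchanged).
#' @return a [LabeledTree-class] with \code{nLeaves(tree) - length(drop)} leaves
#' @export
pruneLeaves <- function(tree, drop) {
  stopifnot(is(tree, "LabeledTree"))
  drop <- unique(drop)
  labs <- leafLabels(tree)
  if (!all(drop %in% labs)) stop("drop contains unknown leaf IDs")
  if (length(drop) == 0L) return(tree)
  if (length(drop) >= length(labs)) stop("cannot drop all leaves")
  if (length(labs) - length(drop) < 2L)
    stop("pruned tree would have fewer than 2 leaves")
  phy <- ape::drop.tip(tree@phy, drop)
  .labeledTree(phy, units = tree@units, tol = tree@tol)
}

# ---- leaf metadata -----------------------------------------------------

#' Read haplotype leaf metadata from a TSV file
#'
#' Expected header: \code{haplotype_id}, \code{individual_id},
#' \code{population}, \code{region}, then one logical (TRUE/FALSE or 0/1)
#' column per resistance-variant name giving carrier status.
#'
#' @param path path to the tab-separated metadata file.
#' @return a validated data.frame (see [validateHaplotypeMetadata()])
#' @export
readHaplotypeMetadata <- function(path) {
  meta <- read.table(path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE, check.names = FALSE)
  validateHaplotypeMetadata(meta)
}

#' Validate a haplotype metadata table
#'
#' Checks the required columns, uniqueness of haplotype IDs, and that each
#' individual contributes exactly two haplotypes (diploid phased data; a
#' warning is emitted otherwise). Variant carrier columns are coerced to
#' logical.
#'
#' @param meta a data.frame with columns \code{haplotype_id},
#'   \code{individual_id}, \code{population}, \code{region} and one
#'   logical column per variant.
#' @return the validated (coerced) data.frame, invisibly classed
#'   \code{"HaplotypeMetadata"}
#' @export
validateHaplotypeMetadata <- function(meta) {
  required <- c("haplotype_id", "individual_id", "population", "region")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols))
    stop("metadata is missing columns: ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(meta$haplotype_id))
    stop("haplotype_id values must be unique")
  counts <- table(meta$individual_id)
  if (any(counts != 2L))
    warning(sprintf("%d individual(s) do not contribute exactly 2 haplotypes",
                    sum(counts != 2L)))
  varcols <- setdiff(names(meta), required)
  for (v in varcols) {
    x <- meta[[v]]
    if (is.character(x)) x <- toupper(trimws(x)) %in% c("TRUE", "T", "1", "YES")
    meta[[v]] <- as.logical(x)
  }
  class(meta) <- c("HaplotypeMetadata", "data.frame")
  meta
}

#' Variant names carried by a metadata table
#' @param meta a metadata data.frame from [readHaplotypeMetadata()]
#' @return character vector of variant column names
#' @export
variantNames <- function(meta) {
  setdiff(names(meta), c("haplotype_id", "individual_id", "population", "region"))
}

#' Carrier haplotype IDs for a named variant
#'
#' @param meta a metadata data.frame from [readHaplotypeMetadata()]
#' @param variant name of a carrier-flag column.
#' @return character vector of carrier haplotype IDs
#' @export
carrierSet <- function(meta, variant) {
  if (!variant %in% names(meta))
    stop("unknown variant '", variant, "'; available: ",
         paste(variantNames(meta), collapse = ", "))
  meta$haplotype_id[meta[[variant]] %in% TRUE]
}

#' Check that every tree leaf resolves to one metadata record
#'
#' @param tree a [LabeledTree-class]
#' @param meta a metadata data.frame
#' @return invisibly TRUE; errors when leaves are unmatched
#' @export
joinTreeMetadata <- function(tree, meta) {
  labs <- leafLabels(tree)
  missing_ids <- setdiff(labs, meta$haplotype_id)
  if (length(missing_ids))
    stop("tree leaves without metadata records: ",
         paste(head(missing_ids, 5), collapse = ", "),
         if (length(missing_ids) > 5) " ..." else "")
  invisible(TRUE)
}
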