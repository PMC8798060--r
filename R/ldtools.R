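# Signed linkage disequilibrium with focal resistance variants: windowed
# summaries, matched-pair nulls, individual-label permutation tests, FDR.
#
# "Signed" means r keeps its sign under a fixed allele polarization; by
# default each site is polarized by rarity (minor allele coded 1), so
# minor alleles segregating on the same haplotypes give positive r.

#' Construct a HaplotypeMatrix
#'
#' @param geno integer matrix, sites x samples; 0/1 in haplotype mode,
#'   0/1/2 dosages in genotype mode; NA for missing.
#' @param sites data.frame with columns \code{chrom}, \code{pos},
#'   \code{ref}, \code{alt}, \code{class} (rows sorted by chrom, pos).
#' @param mode \code{"haplotype"} or \code{"genotype"}.
#' @return a [HaplotypeMatrix-class]
#' @export
haplotypeMatrix <- function(geno, sites, mode = c("haplotype", "genotype")) {
  mode <- match.arg(mode)
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (is.null(colnames(geno)))
    colnames(geno) <- paste0(if (mode == "haplotype") "hap" else "ind",
                             seq_len(ncol(geno)))
  for (col in c("ref", "alt", "class"))
    if (is.null(sites[[col]])) sites[[col]] <- if (col == "class") "other" else "N"
  ord <- order(sites$chrom, sites$pos)
  new("HaplotypeMatrix", geno = geno[ord, , drop = FALSE],
      sites = sites[ord, , drop = FALSE], mode = mode)
}

#' Collapse a phased haplotype matrix to genotype dosages
#'
#' Haplotype columns named \code{<individual>_1} / \code{<individual>_2}
#' are summed into one 0/1/2 dosage column per individual.
#'
#' @param hm a [HaplotypeMatrix-class] in haplotype mode.
#' @return a [HaplotypeMatrix-class] in genotype mode
#' @export
asGenotypeMatrix <- function(hm) {
  stopifnot(is(hm, "HaplotypeMatrix"))
  if (hm@mode == "genotype") return(hm)
  ids <- sub("_[12]$", "", colnames(hm@geno))
  inds <- unique(ids)
  g <- vapply(inds, function(i)
    rowSums(hm@geno[, ids == i, drop = FALSE]), numeric(nrow(hm@geno)))
  g <- matrix(as.integer(g), nrow = nrow(hm@geno),
              dimnames = list(NULL, inds))
  haplotypeMatrix(g, hm@sites, mode = "genotype")
}

# Resolve a site reference ("chrom:pos" string or row index) to a row index.
.siteIndex <- function(hm, site) {
  if (is.character(site)) {
    parts <- strsplit(site, ":", fixed = TRUE)[[1]]
    idx <- which(hm@sites$chrom == parts[1] &
                 hm@sites$pos == as.numeric(parts[2]))
    if (length(idx) != 1L) stop("site not found (or ambiguous): ", site)
    idx
  } else {
    site <- as.integer(site)
    if (site < 1L || site > nrow(hm@geno)) stop("site index out of range")
    site
  }
}

# Polarize a site vector by rarity: code the minor allele as 1 (dosages
# flipped to 2 - x in genotype mode); an exact 0.5 frequency keeps the
# alternate-allele coding, making ties deterministic.
.polarize <- function(x, maxval) {
  freq <- mean(x, na.rm = TRUE) / maxval
  if (!is.na(freq) && freq > 0.5) maxval - x else x
}

#' Signed linkage disequilibrium (r) between two sites
#'
#' Pearson correlation of allele indicators (haplotype mode) or dosages
#' (genotype mode) over pairwise-complete samples. With
#' \code{polarize = "rarity"} each site's minor allele is coded 1 before
#' correlating (ties at frequency 0.5 keep the alternate-allele coding);
#' \code{polarize = "given"} correlates the stored codings as-is.
#'
#' @param hm a [HaplotypeMatrix-class]
#' @param site_a,site_b site references: row indices or
#'   \code{"chrom:pos"} strings.
#' @param polarize \code{"rarity"} (default) or \code{"given"}.
#' @return numeric r in [-1, 1], or NA when either site is monomorphic
#'   over the complete pairs
#' @export
signedR <- function(hm, site_a, site_b, polarize = c("rarity", "given")) {
  polarize <- match.arg(polarize)
  ia <- .siteIndex(hm, site_a)
  ib <- .siteIndex(hm, site_b)
  maxval <- if (hm@mode == "genotype") 2L else 1L
  x <- hm@geno[ia, ]
  y <- hm@geno[ib, ]
  if (polarize == "rarity") {
    x <- .polarize(x, maxval)
    y <- .polarize(y, maxval)
  }
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2L) return(NA_real_)
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) return(NA_real_)
  cor(x[ok], y[ok])
}

# Signed r of one (polarized) focal vector against polarized site rows;
# vectorized Pearson over shared non-missing entries. Rows and focal are
# polarized by the caller.
.rowR <- function(focal, rows) {
  apply(rows, 1L, function(y) {
    ok <- !is.na(focal) & !is.na(y)
    if (sum(ok) < 2L) return(NA_real_)
    if (stats::sd(focal[ok]) == 0 || stats::sd(y[ok]) == 0) return(NA_real_)
    cor(focal[ok], y[ok])
  })
}

#' Windowed mean signed LD with a focal site
#'
#' Splits each chromosome into non-overlapping windows
#' \code{[k*w + 1, (k+1)*w + 1)} (1-based, anchored at position 1) and
#' averages the defined signed-r values between the focal site and all
#' class-filtered sites in each window. The focal site itself is always
#' excluded; optionally the focal site's whole chromosome is excluded
#' (genome-wide interaction scans).
#'
#' @param hm a [HaplotypeMatrix-class]
#' @param focal_site focal site reference (index or \code{"chrom:pos"}).
#' @param window_size window width in bp (> 0).
#' @param class_filter site classes to include (default \code{"missense"});
#'   NULL for all classes.
#' @param exclude_focal_chrom drop all windows on the focal site's
#'   chromosome.
#' @param polarize passed to the r computation.
#' @return data.frame with columns \code{chromosome}, \code{window_start},
#'   \code{window_end} (half-open), \code{n_sites}, \code{mean_r}
#' @export
windowedMeanR <- function(hm, focal_site, window_size,
                          class_filter = "missense",
                          exclude_focal_chrom = FALSE,
                          polarize = c("rarity", "given")) {
  polarize <- match.arg(polarize)
  stopifnot(window_size > 0)
  fi <- .siteIndex(hm, focal_site)
  maxval <- if (hm@mode == "genotype") 2L else 1L
  focal <- hm@geno[fi, ]
  keep <- seq_len(nrow(hm@geno)) != fi
  if (!is.null(class_filter)) keep <- keep & hm@sites$class %in% class_filter
  if (exclude_focal_chrom) keep <- keep & hm@sites$chrom != hm@sites$chrom[fi]
  if (!any(keep))
    return(data.frame(chromosome = character(), window_start = numeric(),
                      window_end = numeric(), n_sites = integer(),
                      mean_r = numeric()))
  rows <- hm@geno[keep, , drop = FALSE]
  if (polarize == "rarity") {
    focal <- .polarize(focal, maxval)
    rows <- t(apply(rows, 1L, .polarize, maxval = maxval))
  }
  rvals <- .rowR(focal, rows)
  s <- hm@sites[keep, , drop = FALSE]
  win <- (s$pos - 1) %/% window_size
  key <- paste(s$chrom, win, sep = "\r")
  agg_n <- tapply(!is.na(rvals), key, sum)
  agg_r <- tapply(rvals, key, mean, na.rm = TRUE)
  parts <- strsplit(names(agg_r), "\r", fixed = TRUE)
  out <- data.frame(
    chromosome = vapply(parts, `[`, character(1), 1L),
    window_start = vapply(parts, function(p) as.numeric(p[2]), numeric(1)) *
      window_size + 1,
    n_sites = as.integer(agg_n),
    mean_r = ifelse(agg_n > 0, as.numeric(agg_r), NA_real_),
    stringsAsFactors = FALSE)
  out$window_end <- out$window_start + window_size
  out <- out[out$n_sites > 0, c("chromosome", "window_start", "window_end",
                                "n_sites", "mean_r")]
  out <- out[order(out$chromosome, out$window_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select the extreme-LD outlier windows of a windowed scan
#'
#' Takes the \code{tail_frac} upper and lower tails of windows ranked by
#' mean signed r (\code{ceiling(tail_frac * n)} windows in each tail).
#'
#' @param windows data.frame from [windowedMeanR()] (or a union of scans).
#' @param tail_frac tail fraction per side (default 0.01).
#' @return the outlier subset, with a \code{tail} column (\code{"upper"} /
#'   \code{"lower"})
#' @export
outlierWindows <- function(windows, tail_frac = 0.01) {
  stopifnot(tail_frac > 0, tail_frac < 0.5)
  n <- nrow(windows)
  k <- ceiling(tail_frac * n)
  ord <- order(windows$mean_r)
  lower <- head(ord, k)
  upper <- tail(ord, k)
  out <- windows[c(lower, upper), , drop = FALSE]
  out$tail <- rep(c("lower", "upper"), each = k)
  out
}

#' Matched-pair empirical null for the LD of a focal site pair
#'
#' Builds the empirical distribution of signed r over all same-chromosome
#' site pairs matched to the focal pair by frequency (minor allele
#' frequency above \code{maf_min}) and physical proximity (within
#' \code{max_dist} bp), excluding the focal pair itself, and returns the
#' one-tailed empirical probability of an LD value as extreme as the
#' focal pair's.
#'
#' @param hm a [HaplotypeMatrix-class]
#' @param focal_pair length-2 vector of site references.
#' @param maf_min minor-allele-frequency floor for matched sites.
#' @param max_dist maximum pair distance in bp.
#' @param tail \code{"lower"} (repulsion; default) or \code{"upper"}.
#' @param class_filter optional site classes for the matched pairs.
#' @return list with \code{r_observed}, \code{p}, \code{n_pairs},
#'   \code{null_r}
#' @export
matchedPairNull <- function(hm, focal_pair, maf_min = 0.20, max_dist = 500,
                            tail = c("lower", "upper"), class_filter = NULL) {
  tail <- match.arg(tail)
  stopifnot(length(focal_pair) == 2L)
  ia <- .siteIndex(hm, focal_pair[[1]])
  ib <- .siteIndex(hm, focal_pair[[2]])
  r_obs <- signedR(hm, ia, ib)
  if (is.na(r_obs)) stop("focal pair LD is undefined (monomorphic site)")
  maxval <- if (hm@mode == "genotype") 2L else 1L
  freq <- rowMeans(hm@geno, na.rm = TRUE) / maxval
  maf <- pmin(freq, 1 - freq)
  cand <- which(maf > maf_min)
  if (!is.null(class_filter))
    cand <- cand[hm@sites$class[cand] %in% class_filter]
  cand <- setdiff(cand, c(ia, ib))
  null_r <- numeric(0)
  for (chrom in unique(hm@sites$chrom[cand])) {
    idx <- cand[hm@sites$chrom[cand] == chrom]
    if (length(idx) < 2L) next
    pos <- hm@sites$pos[idx]
    for (a in seq_len(length(idx) - 1L)) {
      b <- a + 1L
      while (b <= length(idx) && pos[b] - pos[a] <= max_dist) {
        null_r <- c(null_r, signedR(hm, idx[a], idx[b]))
        b <- b + 1L
      }
    }
  }
  null_r <- null_r[!is.na(null_r)]
  if (!length(null_r)) stop("no matched pairs pass the MAF/distance filters")
  if (length(null_r) < 20L)
    warning("fewer than 20 matched pairs; empirical p will be coarse")
  n <- length(null_r)
  p <- if (tail == "lower") (sum(null_r <= r_obs) + 1) / (n + 1)
       else (sum(null_r >= r_obs) + 1) / (n + 1)
  list(r_observed = r_obs, p = p, n_pairs = n, null_r = null_r)
}

#' Individual-label permutation test for windowed LD with a focal variant
#'
#' Shuffles the focal variant's genotype vector across individuals
#' (window genotypes fixed), recomputing the window's mean signed r each
#' time; the two-tailed p-value is
#' \code{(\#\{|mean r_perm| >= |mean r_obs|\} + 1) / (n_perm + 1)}, so the
#' smallest reportable p is \code{1 / (n_perm + 1)}.
#'
#' @param hm a [HaplotypeMatrix-class] (genotype mode; haplotype input is
#'   collapsed to dosages first so labels are permuted across individuals).
#' @param focal_site focal site reference.
#' @param chromosome,window_start,window_end half-open window whose
#'   class-filtered sites are tested.
#' @param class_filter site classes included in the window mean.
#' @param n_perm number of permutations.
#' @param seed integer RNG seed (mandatory).
#' @return list with \code{mean_r_observed}, \code{p}, \code{n_sites},
#'   \code{n_perm}
#' @export
windowPermutationTest <- function(hm, focal_site, chromosome, window_start,
                                  window_end, class_filter = "missense",
                                  n_perm = 1000, seed) {
  if (missing(seed)) stop("seed is mandatory")
  fi_site <- .siteIndex(hm, focal_site)
  key <- paste0(hm@sites$chrom[fi_site], ":", hm@sites$pos[fi_site])
  hm <- asGenotypeMatrix(hm)
  fi <- .siteIndex(hm, key)
  sel <- which(hm@sites$chrom == chromosome &
               hm@sites$pos >= window_start & hm@sites$pos < window_end &
               seq_len(nrow(hm@geno)) != fi)
  if (!is.null(class_filter)) sel <- sel[hm@sites$class[sel] %in% class_filter]
  if (!length(sel)) stop("no sites in the requested window")
  rows <- t(apply(hm@geno[sel, , drop = FALSE], 1L, .polarize, maxval = 2L))
  focal <- .polarize(hm@geno[fi, ], 2L)
  obs <- mean(.rowR(focal, rows), na.rm = TRUE)
  set.seed(seed)
  perm_stats <- vapply(seq_len(n_perm), function(i) {
    mean(.rowR(sample(focal), rows), na.rm = TRUE)
  }, numeric(1))
  p <- (sum(abs(perm_stats) >= abs(obs), na.rm = TRUE) + 1) / (n_perm + 1)
  list(mean_r_observed = obs, p = p, n_sites = length(sel), n_perm = n_perm)
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up adjusted q-values with significance flags at level
#' \code{alpha}; flags are monotone in the p-value ranks.
#'
#' @param p_values numeric vector of p-values in [0, 1].
#' @param alpha FDR level.
#' @return list with \code{q_values} and logical \code{significant}
#' @export
bhFdr <- function(p_values, alpha = 0.05) {
  if (!length(p_values))
    return(list(q_values = numeric(0), significant = logical(0)))
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  q <- p.adjust(p_values, method = "BH")
  list(q_values = q, significant = q <= alpha)
}
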