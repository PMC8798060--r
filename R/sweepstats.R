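# Haplotype-based selective-sweep summaries contrasted between carrier
# and susceptible haplotype sets: EHH / iHH / XPEHH, windowed pairwise
# diversity, and H12.

#' Convert population recombination rates (rho) to a genetic map
#'
#' Per-bp recombination fraction is \code{r = rho / (4 Ne)} per
#' generation, i.e. \code{100 * rho / (4 Ne)} cM per bp; cumulative
#' distances are accumulated monotonically over the segments and
#' interpolated piecewise-linearly between anchors (clamped beyond them).
#'
#' @param segments data.frame with columns \code{chrom}, \code{start},
#'   \code{end} (bp, half-open) and \code{rho} (per bp, >= 0).
#' @param ne diploid effective population size used in the rho estimate.
#' @return a genetic map: data.frame with columns \code{chrom},
#'   \code{pos}, \code{cm} (anchors at segment boundaries), classed
#'   \code{"GeneticMap"}
#' @export
rhoToCm <- function(segments, ne) {
  stopifnot(all(c("chrom", "start", "end", "rho") %in% names(segments)),
            ne > 0)
  if (any(segments$rho < 0)) stop("rho must be non-negative")
  out <- lapply(split(segments, segments$chrom), function(s) {
    s <- s[order(s$start), , drop = FALSE]
    if (any(s$start[-1] < s$end[-nrow(s)] - 1e-9))
      stop("rho segments overlap within a chromosome")
    cm_per_bp <- 100 * s$rho / (4 * ne)
    cum <- cumsum(c(0, cm_per_bp * (s$end - s$start)))
    data.frame(chrom = s$chrom[1], pos = c(s$start[1], s$end),
               cm = cum, stringsAsFactors = FALSE)
  })
  map <- do.call(rbind, out)
  rownames(map) <- NULL
  class(map) <- c("GeneticMap", "data.frame")
  map
}

#' Build a genetic map directly from anchor points
#'
#' @param chrom,pos,cm anchor vectors; positions strictly increasing and
#'   cumulative cM non-decreasing within each chromosome.
#' @return a \code{"GeneticMap"} data.frame
#' @export
geneticMap <- function(chrom, pos, cm) {
  map <- data.frame(chrom = chrom, pos = pos, cm = cm,
                    stringsAsFactors = FALSE)
  for (s in split(map, map$chrom)) {
    if (any(diff(s$pos) <= 0)) stop("map positions must be strictly increasing")
    if (any(diff(s$cm) < 0)) stop("cumulative cM must be non-decreasing")
  }
  class(map) <- c("GeneticMap", "data.frame")
  map
}

#' Interpolate genetic-map positions
#'
#' Piecewise-linear interpolation of cumulative cM at arbitrary bp
#' positions, clamped to the terminal anchors beyond the map span.
#'
#' @param map a \code{"GeneticMap"} data.frame.
#' @param chrom chromosome name.
#' @param pos bp positions (vectorized).
#' @return numeric cumulative cM
#' @export
interpolateCm <- function(map, chrom, pos) {
  s <- map[map$chrom == chrom, , drop = FALSE]
  if (nrow(s) == 0) stop("chromosome not in map: ", chrom)
  if (nrow(s) == 1) return(rep(s$cm, length(pos)))
  stats::approx(s$pos, s$cm, xout = pos, rule = 2)$y
}

# EHH curve on one side of the core: sites ordered outward from the core,
# haplotype groups refined site by site; ehh = sum C(n_g,2) / C(n,2).
.ehhSide <- function(geno, site_order, cm_dist) {
  n <- ncol(geno)
  npairs <- n * (n - 1) / 2
  grp <- rep(1L, n)
  ehh <- numeric(length(site_order))
  for (i in seq_along(site_order)) {
    grp <- as.integer(factor(paste(grp, geno[site_order[i], ])))
    cnt <- tabulate(grp)
    ehh[i] <- sum(cnt * (cnt - 1) / 2) / npairs
    if (ehh[i] == 0) { ehh[i:length(site_order)] <- 0; break }
  }
  data.frame(distance_cm = cm_dist, ehh = ehh)
}

# Truncated trapezoidal integral of an EHH curve over cM distance,
# starting from (0, 1); integration stops at the segment that first drops
# below the cutoff (that segment is included, later ones are not).
.ihh <- function(curve, cutoff) {
  d <- c(0, curve$distance_cm)
  e <- c(1, curve$ehh)
  total <- 0
  for (i in seq_len(length(d) - 1L)) {
    if (e[i] < cutoff) break
    total <- total + 0.5 * (e[i] + e[i + 1L]) * (d[i + 1L] - d[i])
  }
  total
}

#' EHH, iHH and XPEHH between two haplotype sets at a core site
#'
#' Extended haplotype homozygosity at distance x from the core is the
#' fraction of haplotype pairs within a set that are identical over all
#' sites from the core out to x; it starts at 1 and is non-increasing
#' outward. iHH is the trapezoidal integral of the EHH curve over genetic
#' distance (both directions summed), truncated once EHH falls below
#' \code{ehh_cutoff}; XPEHH is \code{log(iHH_A / iHH_B)}, positive when
#' set A (carriers) has the longer haplotype homozygosity.
#'
#' @param hm a [HaplotypeMatrix-class] in haplotype mode.
#' @param set_a,set_b character vectors of haplotype column IDs (each of
#'   size >= 2), e.g. carriers and susceptibles.
#' @param core_site core site reference (index or \code{"chrom:pos"}).
#' @param map optional \code{"GeneticMap"}; by default a uniform
#'   1 cM / Mb map over the core chromosome is assumed.
#' @param ehh_cutoff truncation level for the iHH integral (default 0.05).
#' @return list with \code{ehh_a}, \code{ehh_b} (data.frames: direction,
#'   pos, distance_cm, ehh), \code{ihh_a}, \code{ihh_b}, \code{xpehh}
#'   (NA sentinel when \code{ihh_b} is 0)
#' @export
xpehh <- function(hm, set_a, set_b, core_site, map = NULL,
                  ehh_cutoff = 0.05) {
  stopifnot(is(hm, "HaplotypeMatrix"), hm@mode == "haplotype")
  if (length(set_a) < 2L || length(set_b) < 2L)
    stop("each haplotype set needs at least 2 haplotypes")
  missing_ids <- setdiff(c(set_a, set_b), colnames(hm@geno))
  if (length(missing_ids))
    stop("unknown haplotype IDs: ", paste(head(missing_ids, 5), collapse = ", "))
  ci <- .siteIndex(hm, core_site)
  chrom <- hm@sites$chrom[ci]
  on_chrom <- which(hm@sites$chrom == chrom)
  pos <- hm@sites$pos[on_chrom]
  cm <- if (is.null(map)) pos / 1e6  # uniform 1 cM per Mb
        else interpolateCm(map, chrom, pos)
  core_local <- match(ci, on_chrom)
  oneSet <- function(ids) {
    g <- hm@geno[on_chrom, ids, drop = FALSE]
    sides <- list()
    for (dir in c("left", "right")) {
      ord <- if (dir == "right") seq(core_local, length(on_chrom))
             else seq(core_local, 1L)
      dist <- abs(cm[ord] - cm[core_local])
      curve <- .ehhSide(g, ord, dist)
      curve$direction <- dir
      curve$pos <- pos[ord]
      sides[[dir]] <- curve
    }
    curve <- rbind(sides$left, sides$right)
    ihh <- .ihh(sides$left, ehh_cutoff) + .ihh(sides$right, ehh_cutoff)
    list(curve = curve[, c("direction", "pos", "distance_cm", "ehh")],
         ihh = ihh)
  }
  a <- oneSet(set_a)
  b <- oneSet(set_b)
  xp <- if (b$ihh == 0 || a$ihh == 0) NA_real_ else log(a$ihh / b$ihh)
  list(ehh_a = a$curve, ehh_b = b$curve,
       ihh_a = a$ihh, ihh_b = b$ihh, xpehh = xp)
}

.windowSiteIdx <- function(hm, chrom, start, end) {
  which(hm@sites$chrom == chrom & hm@sites$pos >= start & hm@sites$pos < end)
}

# per-site mean pairwise difference summed over window sites, divided by
# the number of sites (unbiased 2p(1-p) n/(n-1) per site).
.piOfSites <- function(geno) {
  n <- ncol(geno)
  if (n < 2L || nrow(geno) == 0L) return(0)
  p <- rowMeans(geno, na.rm = TRUE)
  mean(2 * p * (1 - p) * n / (n - 1))
}

#' Pairwise nucleotide diversity per window
#'
#' Per window, the mean number of pairwise differences per site over all
#' haplotype pairs, computed over the sites present in the matrix (the
#' denominator is the site count of the window, matching matrices that
#' carry segregating sites only).
#'
#' @param hm a [HaplotypeMatrix-class] in haplotype mode.
#' @param windows data.frame with columns \code{chrom}, \code{start},
#'   \code{end} (half-open bp windows).
#' @param haplotypes optional subset of haplotype column IDs.
#' @return the windows data.frame with added \code{n_sites} and \code{pi}
#' @export
piWindows <- function(hm, windows, haplotypes = NULL) {
  stopifnot(is(hm, "HaplotypeMatrix"), hm@mode == "haplotype")
  ids <- if (is.null(haplotypes)) colnames(hm@geno) else haplotypes
  out <- windows
  out$n_sites <- NA_integer_
  out$pi <- NA_real_
  for (i in seq_len(nrow(windows))) {
    idx <- .windowSiteIdx(hm, windows$chrom[i], windows$start[i],
                          windows$end[i])
    out$n_sites[i] <- length(idx)
    out$pi[i] <- if (length(idx))
      .piOfSites(hm@geno[idx, ids, drop = FALSE]) else NA_real_
  }
  out
}

#' Carrier-minus-susceptible diversity difference per window
#'
#' @inheritParams piWindows
#' @param carriers,susceptibles haplotype ID sets to contrast.
#' @return the windows data.frame with \code{pi_carrier},
#'   \code{pi_susceptible} and \code{delta_pi} columns
#' @export
piDiff <- function(hm, windows, carriers, susceptibles) {
  a <- piWindows(hm, windows, carriers)
  b <- piWindows(hm, windows, susceptibles)
  out <- windows
  out$n_sites <- a$n_sites
  out$pi_carrier <- a$pi
  out$pi_susceptible <- b$pi
  out$delta_pi <- a$pi - b$pi
  out
}

#' H12 haplotype homozygosity in a site window
#'
#' With sorted window-haplotype frequencies p1 >= p2 >= ..., H12 pools the
#' two most frequent haplotypes: \code{(p1 + p2)^2 + sum_{i>2} p_i^2};
#' H1 is the plain haplotype homozygosity \code{sum p_i^2}. Sensitive to
#' both hard and soft sweeps.
#'
#' @param hm a [HaplotypeMatrix-class] in haplotype mode.
#' @param sites integer vector of site row indices defining the window
#'   (default: all sites).
#' @param haplotypes optional subset of haplotype column IDs.
#' @return list with \code{h12}, \code{h1}, \code{frequencies} (sorted)
#' @export
h12 <- function(hm, sites = seq_len(nrow(genoMatrix(hm))),
                haplotypes = NULL) {
  stopifnot(is(hm, "HaplotypeMatrix"), hm@mode == "haplotype")
  ids <- if (is.null(haplotypes)) colnames(hm@geno) else haplotypes
  if (length(ids) < 2L) stop("need at least 2 haplotypes")
  g <- hm@geno[sites, ids, drop = FALSE]
  keys <- apply(g, 2L, paste, collapse = "")
  p <- sort(as.numeric(table(keys)) / length(keys), decreasing = TRUE)
  h1 <- sum(p^2)
  h12v <- if (length(p) >= 2L) (p[1] + p[2])^2 + sum(p[-(1:2)]^2) else h1
  list(h12 = h12v, h1 = h1, frequencies = p)
}

#' Sliding H12 scan in fixed SNP-count windows
#'
#' Windows are defined by a fixed number of consecutive sites (not bp)
#' with a stride, the convention under which H12 was introduced.
#'
#' @param hm a [HaplotypeMatrix-class] in haplotype mode.
#' @param snp_window number of sites per window (default 200).
#' @param stride step between window starts in sites (default
#'   \code{snp_window}, i.e. non-overlapping).
#' @param haplotypes optional subset of haplotype column IDs.
#' @return data.frame with window site ranges, bp midpoints, h12 and h1
#' @export
h12Scan <- function(hm, snp_window = 200, stride = snp_window,
                    haplotypes = NULL) {
  ns <- nrow(hm@geno)
  starts <- seq(1L, max(1L, ns - snp_window + 1L), by = stride)
  rows <- lapply(starts, function(s) {
    idx <- s:min(ns, s + snp_window - 1L)
    res <- h12(hm, sites = idx, haplotypes = haplotypes)
    data.frame(first_site = s, last_site = max(idx),
               chrom = hm@sites$chrom[s],
               mid_pos = mean(range(hm@sites$pos[idx])),
               h12 = res$h12, h1 = res$h1)
  })
  do.call(rbind, rows)
}
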