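# Closed-form worked calculations: resistance-frequency tabulation,
# mutational-supply arithmetic, expected recombinant rates, and the
# 2x2 haplotype-independence test.

#' Tabulate resistant individuals and mutation copies per variant
#'
#' From diploid dosages (0/1/2 alternate copies per individual) and a
#' region label per individual, counts carriers (dosage >= 1) and
#' mutation copies for each variant, in total and per region, with
#' relative frequencies: individual frequency = carriers / individuals
#' sampled, copy frequency = copies / (2 x individuals sampled). An empty
#' cohort yields zero counts and NA frequencies.
#'
#' @param genotypes matrix or data.frame, individuals x variants, dosage
#'   0/1/2 (NA treated as susceptible for counting).
#' @param regions character vector of region labels, one per individual.
#' @param variants variant (column) names to tabulate; defaults to all.
#' @param any_of optional character vector of variant names: additionally
#'   reports the fraction of individuals carrying at least one of them.
#' @return list with \code{table} (one row per region x variant plus
#'   totals), \code{n_individuals} (per region and total), and
#'   \code{any_of} (list with count and frequency, or NULL)
#' @export
tabulateTsr <- function(genotypes, regions, variants = colnames(genotypes),
                        any_of = NULL) {
  genotypes <- as.matrix(genotypes)
  if (is.null(colnames(genotypes))) stop("genotypes must have variant column names")
  unknown <- setdiff(c(variants, any_of), colnames(genotypes))
  if (length(unknown)) stop("unknown variant(s): ", paste(unknown, collapse = ", "))
  if (nrow(genotypes) != length(regions))
    stop("regions must have one label per individual")
  g <- genotypes[, variants, drop = FALSE]
  g[is.na(g)] <- 0
  if (any(g < 0 | g > 2)) stop("dosages must be 0, 1 or 2")
  scopes <- c(list(Total = seq_len(nrow(g))),
              split(seq_len(nrow(g)), regions))
  rows <- list()
  for (sc in names(scopes)) {
    idx <- scopes[[sc]]
    n <- length(idx)
    for (v in variants) {
      carriers <- sum(g[idx, v] >= 1)
      copies <- sum(g[idx, v])
      rows[[length(rows) + 1L]] <- data.frame(
        scope = sc, variant = v, n_individuals = n,
        individuals_with_mutation = carriers, mutation_copies = copies,
        individual_frequency = if (n > 0) carriers / n else NA_real_,
        copy_frequency = if (n > 0) copies / (2 * n) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  any_res <- NULL
  if (!is.null(any_of)) {
    ga <- genotypes[, any_of, drop = FALSE]
    ga[is.na(ga)] <- 0
    n <- nrow(ga)
    cnt <- sum(apply(ga >= 1, 1, any))
    any_res <- list(variants = any_of, count = cnt,
                    frequency = if (n > 0) cnt / n else NA_real_)
  }
  list(table = do.call(rbind, rows),
       n_individuals = vapply(scopes, length, integer(1)),
       any_of = any_res)
}

#' Mutational supply at a set of target codons
#'
#' Under the infinite-sites model a new mutation at any one target site
#' arises at rate \eqn{\Theta_\pi / 2} per generation, so across
#' \code{n_target_codons} exchangeable target codons the supply is
#' \code{(theta_pi / 2) * n_target_codons}, with waiting time its
#' reciprocal.
#'
#' @param theta_pi pairwise-diversity estimate of the population-scaled
#'   mutation rate (4 Ne mu) per site.
#' @param n_target_codons number of resistance-conferring target codons.
#' @return list with \code{rate} (mutations per generation) and
#'   \code{waiting_time} (generations; Inf when the rate is 0)
#' @examples
#' mutationalSupply(0.041, 8)  # rate 0.164, waiting time ~6.1 generations
#' @export
mutationalSupply <- function(theta_pi, n_target_codons) {
  stopifnot(theta_pi >= 0, n_target_codons >= 0)
  rate <- (theta_pi / 2) * n_target_codons
  list(rate = rate, waiting_time = if (rate > 0) 1 / rate else Inf)
}

#' Population-scaled mutation rate Theta = 4 Ne mu
#'
#' @param ne diploid effective population size (>= 0).
#' @param mu per-site per-generation mutation rate (>= 0).
#' @return numeric Theta
#' @examples
#' thetaFourNeMu(8e8, 7e-9)  # 22.4
#' @export
thetaFourNeMu <- function(ne, mu) {
  stopifnot(ne >= 0, mu >= 0)
  4 * ne * mu
}

#' Expected recombination events per generation between two sites
#'
#' With a population-scaled recombination rate \code{rho = 4 Ne r} per bp,
#' the per-generation recombinant production between sites
#' \code{distance_bp} apart is \code{distance_bp * rho / 4}, optionally
#' weighted by the two allele frequencies to count double-mutant-producing
#' events.
#'
#' @param distance_bp physical distance in bp (>= 0).
#' @param rho_per_bp population recombination rate per bp (>= 0).
#' @param p1,p2 allele frequencies weighting the event rate (in [0, 1]).
#' @return expected events per generation
#' @examples
#' expectedRecombinants(237, 0.057)             # ~3.4
#' expectedRecombinants(237, 0.057, 0.29, 0.44) # ~0.43
#' @export
expectedRecombinants <- function(distance_bp, rho_per_bp, p1 = 1, p2 = 1) {
  stopifnot(distance_bp >= 0, rho_per_bp >= 0,
            p1 >= 0, p1 <= 1, p2 >= 0, p2 <= 1)
  distance_bp * (rho_per_bp / 4) * p1 * p2
}

#' Pearson chi-squared test of haplotype independence (2x2)
#'
#' Standard Pearson chi-squared on a 2x2 table of haplotype counts, df = 1,
#' without continuity correction by default (Yates' correction available).
#' A zero marginal yields an undefined-result sentinel (all NA).
#'
#' Note: published analyses of two-locus haplotype independence sometimes
#' report statistics that cannot be reproduced from the printed marginal
#' counts by this standard computation (the exact table or correction used
#' being unstated); this function is the textbook test and makes no
#' attempt to match such values.
#'
#' @param counts 2x2 matrix (or length-4 vector, filled column-wise) of
#'   non-negative counts.
#' @param correct apply Yates' continuity correction.
#' @return list with \code{chi2}, \code{df}, \code{p}
#' @export
haplotypeIndependenceChisq <- function(counts, correct = FALSE) {
  m <- matrix(as.numeric(counts), 2, 2)
  if (any(m < 0)) stop("counts must be non-negative")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    return(list(chi2 = NA_real_, df = 1L, p = NA_real_))
  n <- sum(m)
  expd <- outer(rowSums(m), colSums(m)) / n
  dev <- abs(m - expd)
  if (correct) dev <- pmax(dev - 0.5, 0)
  chi2 <- sum(dev^2 / expd)
  list(chi2 = chi2, df = 1L, p = pchisq(chi2, df = 1, lower.tail = FALSE))
}
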