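# Seeded generators for every input the pipeline consumes: neutral and
# sweep genealogies, multi-origin carrier regions, infinite-sites
# haplotype matrices, phase noise, Ne trajectories, and a fixture writer.
#
# Conventions: diploid coalescent scaling (pair rate 1/(2Ne), so k
# lineages wait an exponential with rate k(k-1)/(4Ne)); all times in
# generations; every generator takes an explicit seed (NULL continues the
# caller's RNG stream, for use inside seeded replicate loops).

.maybeSeed <- function(seed) if (!is.null(seed)) set.seed(seed)

#' Simulate a neutral Kingman coalescent genealogy
#'
#' With k lineages the waiting time to the next coalescence is
#' exponential with rate \code{k (k - 1) / (4 Ne)} and a uniformly random
#' pair merges; the result is an ultrametric binary tree with exactly
#' \code{n - 1} internal nodes. E[TMRCA] = \code{4 Ne (1 - 1/n)}.
#'
#' @param n number of sampled haplotypes (leaves), >= 2.
#' @param ne diploid effective population size (> 0).
#' @param seed integer RNG seed; NULL uses the current RNG state.
#' @param labels leaf labels (default \code{h1..hn}).
#' @param units time unit tag.
#' @return a [LabeledTree-class]
#' @export
simNeutralTree <- function(n, ne, seed = NULL,
                           labels = sprintf("h%d", seq_len(n)),
                           units = "generations") {
  stopifnot(n >= 2, ne > 0, length(labels) == n)
  .maybeSeed(seed)
  sub <- labels
  tm <- numeric(n)
  t <- 0
  k <- n
  while (k > 1L) {
    t <- t + rexp(1, rate = k * (k - 1) / (4 * ne))
    pair <- sample.int(k, 2L)
    i <- pair[1L]; j <- pair[2L]
    sub[i] <- sprintf("(%s:%.12g,%s:%.12g)", sub[i], t - tm[i],
                      sub[j], t - tm[j])
    tm[i] <- t
    sub <- sub[-j]; tm <- tm[-j]
    k <- k - 1L
  }
  parseNewick(paste0(sub, ";"), units = units)
}

# Carriers defined by a neutral mutation dropped uniformly on the tree
# (branch-length weighted); used for null calibration and the s = 0 sweep.
.dropNeutralCarrierSet <- function(tree, min_carriers = 1L,
                                   max_carriers = nLeaves(tree) - 1L) {
  phy <- tree@phy
  sizes <- vapply(phy$edge[, 2L], function(nd) .cladeLeafCount(tree, nd),
                  integer(1))
  ok <- sizes >= min_carriers & sizes <= max_carriers
  if (!any(ok)) stop("no branch subtends a carrier set of the requested size")
  w <- phy$edge.length * ok
  e <- sample.int(nrow(phy$edge), 1L, prob = w)
  child <- phy$edge[e, 2L]
  parent <- phy$edge[e, 1L]
  list(carriers = .cladeLeaves(tree, child),
       origin_time = runif(1, tree@times[child], tree@times[parent]))
}

#' Simulate a genealogy under a selective sweep
#'
#' The carrier frequency follows a deterministic logistic trajectory with
#' selection coefficient \code{s} backwards from \code{final_frequency}
#' at the present; the sample coalesces in a structured coalescent whose
#' carrier / non-carrier classes have within-class pair rates
#' \code{1 / (2 Ne x(t))} and \code{1 / (2 Ne (1 - x(t)))}, stepped on a
#' grid that keeps the per-step event probability below 0.05. The origin
#' generation is where the trajectory hits frequency \code{1 / (2 Ne)}
#' (deterministic given \code{s} and \code{final_frequency}); carrier
#' lineages still separate there are merged at the origin, after which
#' the single mutant ancestor coalesces neutrally with the susceptible
#' lineages. Carriers are monophyletic by construction.
#'
#' With \code{s = 0} the model nests the neutral coalescent: the tree is
#' a plain Kingman genealogy and the carriers are the leaves under a
#' branch-length-weighted random branch (a neutral mutation), with the
#' origin drawn uniformly on that branch.
#'
#' @param n number of sampled haplotypes.
#' @param ne diploid effective population size.
#' @param s selection coefficient (>= 0).
#' @param final_frequency present-day carrier frequency in (0, 1]; must
#'   exceed \code{1 / (2 Ne)} or the trajectory never reaches the
#'   origin.
#' @param n_carriers number of sampled carriers (default
#'   \code{round(n * final_frequency)}, at least 1).
#' @param min_carriers for \code{s = 0} only: condition the neutral
#'   mutation on subtending at least this many leaves (e.g. 2 for a
#'   testable origin); ignored when \code{s > 0}.
#' @param seed integer RNG seed; NULL uses the current RNG state.
#' @param units time unit tag.
#' @return list with \code{tree} ([LabeledTree-class]), \code{carriers}
#'   (leaf IDs), \code{origin_time} (generations)
#' @export
simSweepTree <- function(n, ne, s, final_frequency, n_carriers = NULL,
                         min_carriers = 1L, seed = NULL,
                         units = "generations") {
  stopifnot(n >= 2, ne > 0, s >= 0,
            final_frequency > 0, final_frequency <= 1)
  .maybeSeed(seed)
  labels <- sprintf("h%d", seq_len(n))
  if (s == 0) {
    tree <- simNeutralTree(n, ne, seed = NULL, labels = labels,
                           units = units)
    drop <- .dropNeutralCarrierSet(tree, min_carriers = min_carriers)
    return(list(tree = tree, carriers = drop$carriers,
                origin_time = drop$origin_time))
  }
  x0 <- final_frequency
  xstar <- 1 / (2 * ne)
  if (x0 <= xstar)
    stop(sprintf(paste0(
      "trajectory never reaches the origin: final frequency %.3g does not ",
      "exceed the single-copy frequency 1/(2Ne) = %.3g"), x0, xstar))
  t_origin <- (1 / s) * log(x0 * (1 - xstar) / (xstar * (1 - x0)))
  xfun <- function(t) x0 / (x0 + (1 - x0) * exp(s * t))
  nc <- if (is.null(n_carriers)) max(1L, round(n * x0)) else as.integer(n_carriers)
  stopifnot(nc >= 1L, nc <= n)
  carriers <- labels[seq_len(nc)]
  # lineage state: newick fragments + their times, per class
  subR <- labels[seq_len(nc)]; tmR <- numeric(nc)
  subS <- labels[setdiff(seq_len(n), seq_len(nc))]; tmS <- numeric(n - nc)
  t <- 0
  merge2 <- function(sub, tm, t) {
    pair <- sample.int(length(sub), 2L)
    i <- pair[1L]; j <- pair[2L]
    sub[i] <- sprintf("(%s:%.12g,%s:%.12g)", sub[i], t - tm[i],
                      sub[j], t - tm[j])
    tm[i] <- t
    list(sub = sub[-j], tm = tm[-j])
  }
  while (t < t_origin && (length(subR) > 1L || length(subS) > 1L)) {
    x <- xfun(t)
    cR <- length(subR) * (length(subR) - 1) / (4 * ne * x)
    cS <- length(subS) * (length(subS) - 1) / (4 * ne * (1 - x))
    rate <- cR + cS
    dt <- if (rate > 0) 0.05 / rate else t_origin - t
    dt <- min(dt, t_origin - t, t_origin / 200)
    t2 <- t + dt
    if (rate > 0 && runif(1) < rate * dt) {
      if (runif(1) < cR / rate) {
        st <- merge2(subR, tmR, t2); subR <- st$sub; tmR <- st$tm
      } else {
        st <- merge2(subS, tmS, t2); subS <- st$sub; tmS <- st$tm
      }
    }
    t <- t2
  }
  # any carrier lineages still separate coalesce at the origin
  eps <- max(t_origin, 1) * 1e-9
  while (length(subR) > 1L) {
    t <- t + eps
    st <- merge2(subR, tmR, t); subR <- st$sub; tmR <- st$tm
  }
  # the mutant ancestor joins the susceptible background, then neutral
  sub <- c(subR, subS); tm <- c(tmR, tmS)
  t <- max(t, t_origin)
  k <- length(sub)
  while (k > 1L) {
    t <- t + rexp(1, rate = k * (k - 1) / (4 * ne))
    st <- merge2(sub, tm, t); sub <- st$sub; tm <- st$tm
    k <- k - 1L
  }
  tree <- parseNewick(paste0(sub, ";"), units = units)
  list(tree = tree, carriers = carriers, origin_time = t_origin)
}

#' Simulate a region with multiple independent carrier origins
#'
#' Plants \code{n_origins} disjoint carrier clades for one variant on a
#' neutral base genealogy, assigns each haplotype to one of two regions
#' (uniformly under panmixia, or concentrated in an origin-specific home
#' region when \code{stratify} is on, emulating restricted gene flow),
#' and records the ground truth: the planted leaf sets and the true
#' mutation time of each origin, drawn uniformly on the branch subtending
#' its clade.
#'
#' @param n number of haplotypes (leaves; paired into \code{n/2}
#'   diploid individuals, so \code{n} should be even).
#' @param ne diploid effective population size of the base genealogy.
#' @param n_origins number of independent origins to plant (>= 1).
#' @param variant variant name used for the carrier-flag column.
#' @param min_size,max_size clade-size range for planted origins.
#' @param regions length-2 region labels.
#' @param region_probs sampling probabilities of the two regions under
#'   panmixia.
#' @param stratify concentrate each origin in a home region.
#' @param mixing fraction of an origin's haplotypes assigned away from
#'   the home region when stratified (gene flow).
#' @param seed integer RNG seed; NULL uses the current RNG state.
#' @return list with \code{tree}, \code{meta} (haplotype metadata
#'   data.frame), \code{origins} (list of leaf-ID sets), \code{true_ages},
#'   \code{origin_nodes}, \code{params}
#' @export
simMultioriginRegion <- function(n, ne, n_origins, variant = "TSR_variant",
                                 min_size = 2L,
                                 max_size = max(2L, floor(n / 4)),
                                 regions = c("Ontario", "Midwest"),
                                 region_probs = c(0.5, 0.5),
                                 stratify = FALSE, mixing = 0.1,
                                 seed = NULL) {
  stopifnot(n_origins >= 1, length(regions) == 2L)
  if (n_origins * min_size > n)
    stop("infeasible: n_origins * min_size exceeds the sample size")
  .maybeSeed(seed)
  ind <- rep(seq_len(ceiling(n / 2)), each = 2L)[seq_len(n)]
  labels <- sprintf("I%d_%d", ind, rep(1:2, length.out = n))
  tree <- simNeutralTree(n, ne, seed = NULL, labels = labels)
  phy <- tree@phy
  ntip <- n
  internal <- (ntip + 2L):(ntip + phy$Nnode)   # exclude the root
  sizes <- vapply(internal, function(nd) .cladeLeafCount(tree, nd), integer(1))
  cand <- internal[sizes >= min_size & sizes <= max_size]
  if (min_size <= 1L) cand <- c(cand, seq_len(ntip))
  cand <- sample(cand)
  chosen <- integer(0)
  used <- character(0)
  for (nd in cand) {
    lv <- .cladeLeaves(tree, nd)
    if (!length(intersect(lv, used))) {
      chosen <- c(chosen, nd)
      used <- c(used, lv)
      if (length(chosen) == n_origins) break
    }
  }
  if (length(chosen) < n_origins)
    stop("infeasible clade sizes: could not place ", n_origins,
         " disjoint origins of size ", min_size, "..", max_size)
  parent <- integer(ntip + phy$Nnode)
  parent[phy$edge[, 2L]] <- phy$edge[, 1L]
  origins <- lapply(chosen, function(nd) .cladeLeaves(tree, nd))
  true_ages <- vapply(chosen, function(nd)
    runif(1, tree@times[nd], tree@times[parent[nd]]), numeric(1))
  carriers <- unlist(origins)
  region <- sample(regions, n, replace = TRUE, prob = region_probs)
  names(region) <- labels
  if (stratify) {
    for (i in seq_along(origins)) {
      home <- regions[(i - 1L) %% 2L + 1L]
      away <- setdiff(regions, home)
      region[origins[[i]]] <- ifelse(runif(length(origins[[i]])) < mixing,
                                     away, home)
    }
  }
  meta <- data.frame(haplotype_id = labels,
                     individual_id = sprintf("I%d", ind),
                     population = paste0(region[labels], "_pop",
                                         1L + (ind %% 3L)),
                     region = region[labels],
                     stringsAsFactors = FALSE)
  meta[[variant]] <- meta$haplotype_id %in% carriers
  meta <- validateHaplotypeMetadata(meta)
  list(tree = tree, meta = meta, origins = origins, true_ages = true_ages,
       origin_nodes = chosen,
       params = list(n = n, ne = ne, n_origins = n_origins,
                     variant = variant, regions = regions,
                     stratify = stratify, mixing = mixing))
}

#' Perturbed genealogy samples emulating MCMC output
#'
#' Produces \code{m} copies of a genealogy, each independently perturbed:
#' with probability \code{regraft_prob} one random leaf is pruned and
#' re-attached at a uniformly chosen height on a random branch, and all
#' node times are scaled by a lognormal factor with log-sd
#' \code{time_jitter_sd}. Emulates the topology and branch-length
#' variation across MCMC samples of an ancestral recombination graph.
#'
#' @param tree a [LabeledTree-class]
#' @param m number of samples.
#' @param regraft_prob per-sample probability of one leaf regraft.
#' @param time_jitter_sd log-sd of the per-sample time scaling (0 = none).
#' @param seed integer RNG seed; NULL uses the current RNG state.
#' @return list of \code{m} [LabeledTree-class] objects
#' @export
jitterTrees <- function(tree, m, regraft_prob = 0.1, time_jitter_sd = 0.05,
                        seed = NULL) {
  stopifnot(is(tree, "LabeledTree"), m >= 1)
  .maybeSeed(seed)
  lapply(seq_len(m), function(i) {
    phy <- tree@phy
    if (runif(1) < regraft_prob && length(phy$tip.label) > 3L) {
      leaf <- sample(phy$tip.label, 1L)
      pruned <- pruneLeaves(tree, leaf)
      p2 <- pruned@phy
      e <- sample.int(nrow(p2$edge), 1L)
      child <- p2$edge[e, 2L]
      ta <- runif(1, pruned@times[child], pruned@times[p2$edge[e, 1L]])
      p2 <- phytools::bind.tip(p2, leaf, edge.length = ta, where = child,
                               position = ta - pruned@times[child])
      phy <- p2
    }
    if (time_jitter_sd > 0)
      phy$edge.length <- phy$edge.length * exp(rnorm(1, 0, time_jitter_sd))
    .labeledTree(phy, units = tree@units)
  })
}

#' Drop infinite-sites mutations on a genealogy
#'
#' Each branch receives \code{Poisson(length * mu * L)} mutations; each
#' mutation is a new biallelic site carried by exactly the leaves under
#' its branch, at a distinct position uniform on \code{[1, L]}.
#'
#' @param tree a [LabeledTree-class]
#' @param mu per-site per-generation mutation rate (> 0).
#' @param L sequence length in bp (> 0).
#' @param seed integer RNG seed; NULL uses the current RNG state.
#' @param chrom chromosome name for the site records.
#' @param class_probs sampling probabilities of the site functional
#'   classes (named: missense, synonymous, other).
#' @return a [HaplotypeMatrix-class] in haplotype mode (0 rows when no
#'   mutation falls on the tree)
#' @export
dropMutations <- function(tree, mu, L, seed = NULL, chrom = "chr1",
                          class_probs = c(missense = 0.1, synonymous = 0.1,
                                          other = 0.8)) {
  stopifnot(is(tree, "LabeledTree"), mu >= 0, L > 0)
  .maybeSeed(seed)
  phy <- tree@phy
  labs <- leafLabels(tree)
  counts <- rpois(nrow(phy$edge), phy$edge.length * mu * L)
  total <- sum(counts)
  empty_sites <- data.frame(chrom = character(), pos = numeric(),
                            ref = character(), alt = character(),
                            class = character(), stringsAsFactors = FALSE)
  if (total == 0L)
    return(haplotypeMatrix(
      matrix(integer(0), 0L, length(labs), dimnames = list(NULL, labs)),
      empty_sites, mode = "haplotype"))
  if (total > L)
    stop("more mutations than sites: increase L or decrease mu")
  pos <- sort(sample.int(L, total))
  pos <- sample(pos)   # decouple position order from branch order
  geno <- matrix(0L, total, length(labs), dimnames = list(NULL, labs))
  row <- 1L
  for (e in which(counts > 0L)) {
    lv <- .cladeLeaves(tree, phy$edge[e, 2L])
    for (r in seq_len(counts[e])) {
      geno[row, match(lv, labs)] <- 1L
      row <- row + 1L
    }
  }
  sites <- data.frame(chrom = chrom, pos = pos, ref = "A", alt = "T",
                      class = sample(names(class_probs), total,
                                     replace = TRUE, prob = class_probs),
                      stringsAsFactors = FALSE)
  haplotypeMatrix(geno, sites, mode = "haplotype")
}

#' Add phase-switch noise to a phased haplotype matrix
#'
#' Emulates phasing error: for each diploid individual (haplotype columns
#' \code{<ind>_1} / \code{<ind>_2}), switch points are drawn per site
#' with the given rate and the two haplotypes are swapped from each
#' switch position onward.
#'
#' @param hm a [HaplotypeMatrix-class] in haplotype mode.
#' @param rate per-site switch probability (>= 0).
#' @param seed integer RNG seed; NULL uses the current RNG state.
#' @return a [HaplotypeMatrix-class] with the same sites and IDs
#' @export
phaseSwitchNoise <- function(hm, rate, seed = NULL) {
  stopifnot(is(hm, "HaplotypeMatrix"), hm@mode == "haplotype", rate >= 0)
  .maybeSeed(seed)
  g <- hm@geno
  ns <- nrow(g)
  if (ns == 0L || rate == 0) return(hm)
  ids <- sub("_[12]$", "", colnames(g))
  for (i in unique(ids)) {
    cols <- which(ids == i)
    if (length(cols) != 2L) next
    swapped <- cumsum(rbinom(ns, 1L, rate)) %% 2L == 1L
    if (any(swapped)) {
      tmp <- g[swapped, cols[1L]]
      g[swapped, cols[1L]] <- g[swapped, cols[2L]]
      g[swapped, cols[2L]] <- tmp
    }
  }
  haplotypeMatrix(g, hm@sites, mode = "haplotype")
}

#' Simulate a piecewise-constant Ne trajectory
#'
#' Epochs are log-spaced in time (steps of \code{10^step_log10} years,
#' matching coalescence-rate trajectories estimated on fine recent
#' timescales). The \code{"expansion"} kind jumps from an ancient to a
#' much larger recent Ne at \code{t_expand}, emulating a massive recent
#' population expansion; \code{"constant"} holds one value throughout.
#'
#' @param kind \code{"expansion"} or \code{"constant"}.
#' @param ne_recent,ne_ancient recent / ancient Ne for the expansion kind.
#' @param t_expand expansion time (years before present).
#' @param ne constant Ne for the constant kind.
#' @param t_max oldest epoch boundary.
#' @param step_log10 log10 width of the epoch grid.
#' @return a [NeTrajectory-class]
#' @export
simNeTrajectory <- function(kind = c("expansion", "constant"),
                            ne_recent = 8.3e7, ne_ancient = 6.3e4,
                            t_expand = 100, ne = 1e4, t_max = 1e7,
                            step_log10 = 0.25) {
  kind <- match.arg(kind)
  bounds <- c(0, 10^seq(0, log10(t_max), by = step_log10))
  start <- bounds[-length(bounds)]
  end <- bounds[-1L]
  nev <- if (kind == "constant") rep(ne, length(start))
         else ifelse(start < t_expand, ne_recent, ne_ancient)
  neTrajectory(start, end, nev, units = "years")
}

#' Write a complete synthetic fixture set for the pipeline
#'
#' Generates a multi-origin region with genealogy samples, an
#' infinite-sites haplotype matrix, a genetic map, and an
#' expansion-shaped Ne trajectory, and writes every file the pipeline
#' consumes: \code{tree.nwk} (the base genealogy), \code{mcmc_trees.nwk}
#' (perturbed samples), \code{haplotypes.vcf}, \code{meta.tsv},
#' \code{map.tsv}, \code{ne.coal.tsv}, and \code{manifest.json} carrying
#' the generator parameters, seed, and ground truth (planted origin leaf
#' sets and true mutation ages). All outputs are plain text.
#'
#' @param outdir output directory (created if absent).
#' @param seed integer RNG seed (mandatory; recorded in the manifest).
#' @param n,ne,n_origins,variant,stratify passed to
#'   [simMultioriginRegion()].
#' @param mu,L mutation rate and sequence length for [dropMutations()].
#' @param n_mcmc number of perturbed genealogy samples.
#' @param rho_per_bp uniform population recombination rate for the map.
#' @return named list of written file paths, invisibly
#' @export
writeFixtureSet <- function(outdir, seed, n = 40, ne = 1e4, n_origins = 2,
                            variant = "TSR_variant", stratify = FALSE,
                            mu = 1e-6, L = 50000L, n_mcmc = 20,
                            rho_per_bp = 0.01) {
  if (missing(seed)) stop("seed is mandatory")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  sim <- simMultioriginRegion(n = n, ne = ne, n_origins = n_origins,
                              variant = variant, stratify = stratify,
                              seed = NULL)
  hm <- dropMutations(sim$tree, mu = mu, L = L, seed = NULL)
  trees <- jitterTrees(sim$tree, n_mcmc, seed = NULL)
  map <- rhoToCm(data.frame(chrom = "chr1", start = 1, end = L,
                            rho = rho_per_bp), ne = ne)
  traj <- simNeTrajectory("expansion")
  paths <- list(
    tree = file.path(outdir, "tree.nwk"),
    mcmc_trees = file.path(outdir, "mcmc_trees.nwk"),
    vcf = file.path(outdir, "haplotypes.vcf"),
    meta = file.path(outdir, "meta.tsv"),
    map = file.path(outdir, "map.tsv"),
    coal = file.path(outdir, "ne.coal.tsv"),
    manifest = file.path(outdir, "manifest.json"))
  writeLines(writeNewick(sim$tree), paths$tree)
  writeLines(vapply(trees, writeNewick, character(1)), paths$mcmc_trees)
  if (nrow(genoMatrix(hm)) > 0) writeHaplotypeVcf(hm, paths$vcf)
  write.table(as.data.frame(sim$meta), paths$meta, sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeGeneticMap(map, paths$map)
  writeCoalTsv(traj, paths$coal)
  manifest <- list(seed = seed, params = sim$params,
                   mu = mu, L = L, n_mcmc = n_mcmc,
                   rho_per_bp = rho_per_bp,
                   n_sites = nrow(genoMatrix(hm)),
                   origins = lapply(sim$origins, identity),
                   true_ages = sim$true_ages)
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
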