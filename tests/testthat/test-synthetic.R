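test_that("neutral coalescent matches closed-form TMRCA expectations", {
  set.seed(81)
  # n = 2: E[TMRCA] = 2 Ne
  ne <- 500
  t2 <- replicate(4000, rootTime(simNeutralTree(2, ne)))
  se <- sd(t2) / sqrt(length(t2))
  expect_lt(abs(mean(t2) - 2 * ne), 3 * se)
  # n = 50: E[TMRCA] = 4 Ne (1 - 1/n); also exactly n - 1 internal nodes
  t50 <- replicate(800, {
    tr <- simNeutralTree(50, ne)
    expect_equal(tr@phy$Nnode, 49L)
    rootTime(tr)
  })
  se50 <- sd(t50) / sqrt(length(t50))
  expect_lt(abs(mean(t50) - 4 * ne * (1 - 1 / 50)), 3 * se50)
})

test_that("sweep genealogies are monophyletic, dated, and nest the neutral model", {
  set.seed(82)
  sw <- simSweepTree(30, 1000, 0.3, final_frequency = 0.5, n_carriers = 15)
  expect_length(clusterOrigins(sw$tree, sw$carriers), 1L)
  expect_gt(sw$origin_time, 0)
  # the origin lies on the carrier clade's subtending branch
  cl <- clusterOrigins(sw$tree, sw$carriers)[[1]]
  expect_gte(sw$origin_time, cl@mrcaTime)
  expect_lte(sw$origin_time, cl@parentTime)
  # deterministic origin time given (s, x0, Ne)
  expect_equal(sw$origin_time,
               (1 / 0.3) * log(0.5 * (1 - 1 / 2000) / ((1 / 2000) * 0.5)))

  # strong selection: carrier clade far younger than the neutral TMRCA scale
  strong <- replicate(60, {
    swi <- simSweepTree(20, 1000, 2, final_frequency = 0.5, n_carriers = 10)
    clusterOrigins(swi$tree, swi$carriers)[[1]]@mrcaTime
  })
  expect_lt(median(strong) / (4 * 1000 * (1 - 1 / 10)), 0.1)

  # s = 0 reduces to the neutral coalescent (TMRCA distribution)
  set.seed(83)
  t_neutral <- replicate(300, rootTime(simNeutralTree(15, 800)))
  t_s0 <- replicate(300, rootTime(simSweepTree(15, 800, 0,
                                               final_frequency = 0.5)$tree))
  expect_gt(suppressWarnings(ks.test(t_neutral, t_s0))$p.value, 0.01)

  # unreachable origin frequency is a diagnostic error
  expect_error(simSweepTree(10, 50, 0.1, final_frequency = 1 / 200),
               "never reaches")
})

test_that("multi-origin planting is recovered exactly by clustering", {
  set.seed(84)
  for (k in 1:3) {
    mo <- simMultioriginRegion(40, 1e3, k)
    cl <- clusterOrigins(mo$tree, unlist(mo$origins))
    expect_length(cl, k)
    expect_setequal(lapply(cl, function(o) sort(originLeaves(o))),
                    lapply(mo$origins, sort))
  }
  # planted true ages sit on the subtending branch
  mo <- simMultioriginRegion(40, 1e3, 2, seed = 85)
  for (i in 1:2) {
    cl <- clusterOrigins(mo$tree, mo$origins[[i]])[[1]]
    expect_gte(mo$true_ages[i], cl@mrcaTime)
    expect_lte(mo$true_ages[i], cl@parentTime)
  }
  expect_error(simMultioriginRegion(10, 1e3, 4, min_size = 4),
               "infeasible")
})

test_that("stratified regions are flagged and panmictic ones are not", {
  set.seed(86)
  mo <- simMultioriginRegion(60, 1e3, 1, min_size = 10, max_size = 20,
                             stratify = TRUE, mixing = 0.05)
  res <- geoPermutation(mo$origins[[1]], mo$meta, c("Ontario", "Midwest"),
                        n_perm = 300, seed = 7)
  expect_true(res$stratified)
  mo2 <- simMultioriginRegion(60, 1e3, 1, min_size = 10, max_size = 20,
                              stratify = FALSE, seed = 87)
  res2 <- geoPermutation(mo2$origins[[1]], mo2$meta, c("Ontario", "Midwest"),
                         n_perm = 300, seed = 8)
  expect_false(res2$stratified)
})

test_that("infinite-sites mutations follow Watterson and form clades", {
  # mu = 0: empty matrix
  tr <- simNeutralTree(10, 500, seed = 88)
  expect_equal(nrow(genoMatrix(dropMutations(tr, 0, 1000))), 0L)
  # segregating sites near theta L sum(1/k)
  set.seed(89)
  ne <- 500; mu <- 2e-6; L <- 1e4; n <- 10
  S <- replicate(250, {
    tri <- simNeutralTree(n, ne)
    nrow(genoMatrix(dropMutations(tri, mu, L)))
  })
  expected <- 4 * ne * mu * L * sum(1 / seq_len(n - 1))
  se <- sd(S) / sqrt(length(S))
  expect_lt(abs(mean(S) - expected), 3 * se)
  # every site's carrier set is a clade before phase noise
  hm <- dropMutations(tr, 1e-5, 1e4, seed = 90)
  g <- genoMatrix(hm)
  for (i in seq_len(min(nrow(g), 25))) {
    carriers <- colnames(g)[g[i, ] == 1L]
    if (length(carriers) >= 1 && length(carriers) < ncol(g))
      expect_length(clusterOrigins(tr, carriers), 1L)
  }
})

test_that("phase-switch noise swaps haplotypes but keeps dosages", {
  set.seed(91)
  mo <- simMultioriginRegion(20, 500, 1)
  hm <- dropMutations(mo$tree, 5e-6, 1e4)
  expect_identical(phaseSwitchNoise(hm, 0), hm)
  noisy <- phaseSwitchNoise(hm, 0.05, seed = 92)
  expect_false(identical(genoMatrix(noisy), genoMatrix(hm)))
  # per-individual dosages are invariant under phase switching
  expect_equal(genoMatrix(asGenotypeMatrix(noisy)),
               genoMatrix(asGenotypeMatrix(hm)))
})

test_that("simulated Ne trajectories have the stated epoch structure", {
  const <- simNeTrajectory("constant", ne = 1e4)
  expect_equal(geometricMeanNe(const, c(0, 1e6)), 1e4)
  expect_equal(harmonicMeanNe(const, c(0, 1e6)), 1e4)
  exp_traj <- simNeTrajectory("expansion", ne_recent = 8.3e7,
                              ne_ancient = 6.3e4, t_expand = 100)
  # window inside the recent epoch: GM equals the recent value
  expect_equal(geometricMeanNe(exp_traj, c(0, 50)), 8.3e7)
  expect_equal(geometricMeanNe(exp_traj, c(1e3, 1e6)), 6.3e4)
  # log-spaced epochs at 10^0.25 steps
  e <- epochs(exp_traj)
  mids <- log10(e$start[-(1:2)])
  expect_equal(diff(mids), rep(0.25, length(mids) - 1), tolerance = 1e-9)
})

test_that("generators are bit-reproducible under a fixed seed", {
  a <- simNeutralTree(15, 700, seed = 93)
  b <- simNeutralTree(15, 700, seed = 93)
  expect_identical(writeNewick(a), writeNewick(b))
  swa <- simSweepTree(15, 700, 0.2, final_frequency = 0.5, seed = 94)
  swb <- simSweepTree(15, 700, 0.2, final_frequency = 0.5, seed = 94)
  expect_identical(writeNewick(swa$tree), writeNewick(swb$tree))
  expect_identical(swa$carriers, swb$carriers)
  ma <- dropMutations(a, 1e-5, 1e4, seed = 95)
  mb <- dropMutations(b, 1e-5, 1e4, seed = 95)
  expect_identical(genoMatrix(ma), genoMatrix(mb))
  expect_identical(siteInfo(ma), siteInfo(mb))
})

test_that("fixture sets round-trip through every reader", {
  outdir <- withr::local_tempdir()
  paths <- writeFixtureSet(outdir, seed = 96, n = 20, ne = 1e3,
                           n_origins = 2, mu = 2e-7, L = 2e4, n_mcmc = 5)
  expect_true(all(file.exists(unlist(paths))))
  tree <- readNewickTrees(paths$tree)[[1]]
  trees <- readNewickTrees(paths$mcmc_trees)
  meta <- readHaplotypeMetadata(paths$meta)
  hm <- readHaplotypeVcf(paths$vcf)
  map <- readGeneticMap(paths$map)
  traj <- readCoal(paths$coal)
  manifest <- jsonlite::read_json(paths$manifest, simplifyVector = TRUE)
  expect_equal(nLeaves(tree), 20L)
  expect_length(trees, 5L)
  expect_true(joinTreeMetadata(tree, meta))
  expect_setequal(sub("_[12]$", "", sampleIds(hm)),
                  unique(meta$individual_id))
  expect_s4_class(traj, "NeTrajectory")
  expect_equal(manifest$seed, 96L)
  carriers <- carrierSet(meta, "TSR_variant")
  expect_length(clusterOrigins(tree, carriers), 2L)
  # ground truth recorded for every planted origin
  expect_length(manifest$true_ages, 2L)
})
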