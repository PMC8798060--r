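test_that("signed r reproduces direct-correlation worked examples", {
  # haplotype counts AB=1, Ab=4, aB=4, ab=1 under minor-allele coding
  g <- rbind(c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0),
             c(1, 0, 0, 0, 0, 1, 1, 1, 1, 0))
  hm <- haplotypeMatrix(g, data.frame(chrom = "c", pos = c(10, 20),
                                      ref = "A", alt = "T",
                                      class = "missense"))
  expect_equal(signedR(hm, 1, 2), -0.6)
  expect_equal(signedR(hm, 1, 1), 1)
  # symmetry
  expect_equal(signedR(hm, 2, 1), signedR(hm, 1, 2))
  # perfect repulsion: complementary alleles at frequency one half
  g2 <- rbind(c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0),
              c(0, 0, 0, 0, 0, 1, 1, 1, 1, 1))
  hm2 <- haplotypeMatrix(g2, data.frame(chrom = "c", pos = c(10, 20),
                                        ref = "A", alt = "T",
                                        class = "missense"))
  expect_equal(signedR(hm2, 1, 2), -1)
  # monomorphic site -> undefined sentinel
  g3 <- rbind(c(1, 1, 1, 1), c(0, 0, 0, 0))
  hm3 <- haplotypeMatrix(g3, data.frame(chrom = "c", pos = c(1, 2),
                                        ref = "A", alt = "T",
                                        class = "other"))
  expect_true(is.na(signedR(hm3, 1, 2)))
})

test_that("rarity polarization flips majorities and is swap-invariant", {
  set.seed(61)
  g <- matrix(rbinom(6 * 30, 1, 0.35), 6, 30)
  hm <- haplotypeMatrix(g, data.frame(chrom = "c", pos = 1:6 * 10,
                                      ref = "A", alt = "T",
                                      class = "missense"))
  r0 <- signedR(hm, 1, 2)
  # swapping BOTH sites' allele labels leaves rarity-polarized r unchanged
  g_both <- g; g_both[1, ] <- 1L - g_both[1, ]; g_both[2, ] <- 1L - g_both[2, ]
  hm_both <- haplotypeMatrix(g_both, siteInfo(hm))
  expect_equal(signedR(hm_both, 1, 2), r0)
  # swapping ONE site's labels flips the sign under 'given' polarization
  g_one <- g; g_one[1, ] <- 1L - g_one[1, ]
  hm_one <- haplotypeMatrix(g_one, siteInfo(hm))
  expect_equal(signedR(hm_one, 1, 2, polarize = "given"),
               -signedR(hm, 1, 2, polarize = "given"))
})

test_that("haplotype and genotype mode agree on doubled haplotypes", {
  set.seed(62)
  g <- matrix(rbinom(8 * 15, 1, 0.4), 8, 15)
  # each individual's two haplotypes identical
  gh <- g[, rep(seq_len(15), each = 2)]
  colnames(gh) <- paste0("I", rep(1:15, each = 2), "_", 1:2)
  sites <- data.frame(chrom = "c", pos = 1:8 * 5, ref = "A", alt = "T",
                      class = "missense")
  hm_h <- haplotypeMatrix(gh, sites)
  hm_g <- asGenotypeMatrix(hm_h)
  for (pair in list(c(1, 2), c(3, 7), c(4, 8))) {
    expect_equal(signedR(hm_g, pair[1], pair[2]),
                 signedR(hm_h, pair[1], pair[2]), tolerance = 1e-12)
  }
})

test_that("windowed means match a naive per-window loop", {
  set.seed(63)
  hm <- makeNullHaplotypeMatrix(60, 30, spacing = 137)
  w <- windowedMeanR(hm, 1, window_size = 1000, class_filter = "missense")
  # naive loop oracle
  for (i in seq_len(nrow(w))) {
    idx <- which(siteInfo(hm)$pos >= w$window_start[i] &
                 siteInfo(hm)$pos < w$window_end[i])
    idx <- setdiff(idx, 1L)
    rs <- vapply(idx, function(jj) signedR(hm, 1, jj), numeric(1))
    expect_equal(w$mean_r[i], mean(rs, na.rm = TRUE), tolerance = 1e-12)
    expect_equal(w$n_sites[i], sum(!is.na(rs)))
  }
  # single site per window: the window mean is that site's r
  hm1 <- makeNullHaplotypeMatrix(5, 20, spacing = 5000)
  w1 <- windowedMeanR(hm1, 1, window_size = 1000)
  expect_true(all(w1$n_sites == 1))
  expect_equal(w1$mean_r[1], signedR(hm1, 1, 2))
  # excluding the focal chromosome removes all its windows
  w2 <- windowedMeanR(hm, 1, 1000, exclude_focal_chrom = TRUE)
  expect_equal(nrow(w2), 0L)
})

test_that("tail selection takes ceiling(frac * n) windows per side", {
  set.seed(64)
  fake <- data.frame(chromosome = "c", window_start = seq_len(1156),
                     window_end = seq_len(1156) + 1, n_sites = 1,
                     mean_r = rnorm(1156))
  out <- outlierWindows(fake, 0.01)
  expect_equal(nrow(out), 24L)   # 12 per tail from 1156 windows
  expect_setequal(unique(out$tail), c("lower", "upper"))
  expect_true(max(out$mean_r[out$tail == "lower"]) <=
              min(fake$mean_r[!seq_len(1156) %in%
                              which(rank(fake$mean_r) <= 12)]))
})

test_that("matched-pair null centers and calibrates on null data", {
  set.seed(65)
  hm <- makeNullHaplotypeMatrix(60, 40, p = 0.4, spacing = 120)
  res <- matchedPairNull(hm, c(30, 31), maf_min = 0.2, max_dist = 400)
  expect_true(res$n_pairs >= 20)
  expect_true(res$p > 0 && res$p <= 1)
  # p over repeated null draws is approximately uniform
  ps <- replicate(120, {
    hm_i <- makeNullHaplotypeMatrix(40, 40, p = 0.4, spacing = 120)
    matchedPairNull(hm_i, c(20, 21), maf_min = 0.2, max_dist = 400)$p
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
  # a focal r at the null median gives p near one half
  expect_equal(mean(ps), 0.5, tolerance = 0.12)
  expect_error(matchedPairNull(hm, c(1, 2), maf_min = 0.49, max_dist = 1),
               "no matched pairs")
})

test_that("window permutation p has 1/(n_perm+1) floor and calibrates", {
  set.seed(66)
  # a window made of copies of the focal site: observed |mean r| maximal
  g <- matrix(rbinom(20, 2, 0.5), 1, 20)
  g <- rbind(g, g, g, g)
  hm <- haplotypeMatrix(g, data.frame(chrom = "c", pos = c(10, 20, 30, 40),
                                      ref = "A", alt = "T",
                                      class = "missense"),
                        mode = "genotype")
  res <- windowPermutationTest(hm, 1, "c", 15, 45, n_perm = 99, seed = 7)
  expect_equal(res$mean_r_observed, 1)
  expect_equal(res$p, 1 / 100)
  # reproducible under a fixed seed
  res2 <- windowPermutationTest(hm, 1, "c", 15, 45, n_perm = 99, seed = 7)
  expect_identical(res, res2)
  # independent focal and window: p uniform over generator replicates
  ps <- replicate(100, {
    gg <- matrix(rbinom(15 * 25, 2, 0.3), 15, 25)
    hmx <- haplotypeMatrix(gg, data.frame(
      chrom = "c", pos = seq(10, by = 10, length.out = 15),
      ref = "A", alt = "T", class = "missense"), mode = "genotype")
    windowPermutationTest(hmx, 1, "c", 20, 1000, n_perm = 49,
                          seed = sample.int(1e6, 1))$p
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("BH step-up reproduces the hand-applied example", {
  res <- bhFdr(c(0.01, 0.02, 0.03, 0.5), alpha = 0.05)
  expect_equal(res$q_values, c(0.04, 0.04, 0.04, 0.5))
  expect_equal(res$significant, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(bhFdr(1)$q_values, 1)
  expect_false(bhFdr(1)$significant)
  res1 <- bhFdr(0.04)
  expect_equal(res1$q_values, 0.04)
  expect_true(res1$significant)
  expect_length(bhFdr(numeric(0))$q_values, 0L)
  # all p = 1 -> none significant
  expect_false(any(bhFdr(rep(1, 10))$significant))
})
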