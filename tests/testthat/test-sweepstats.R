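test_that("rho-to-cM conversion accumulates 100 rho / (4 Ne) per bp", {
  # rho = 0 everywhere: flat map
  flat <- rhoToCm(data.frame(chrom = "c", start = 1, end = 1e5, rho = 0),
                  ne = 5e5)
  expect_equal(interpolateCm(flat, "c", c(1, 5e4, 1e5)), c(0, 0, 0))
  # constant rho: linear cumulative distance
  lin <- rhoToCm(data.frame(chrom = "c", start = 0, end = 1e6, rho = 0.02),
                 ne = 5e5)
  expect_equal(interpolateCm(lin, "c", 1e6), 100 * 0.02 / (4 * 5e5) * 1e6)
  expect_equal(interpolateCm(lin, "c", 5e5), 100 * 0.02 / (4 * 5e5) * 5e5)
  # piecewise map: interpolated values bracketed by neighbouring anchors
  set.seed(71)
  seg <- data.frame(chrom = "c", start = seq(0, 900, by = 100),
                    end = seq(100, 1000, by = 100),
                    rho = runif(10, 0, 0.1))
  map <- rhoToCm(seg, ne = 1e4)
  q <- runif(50, 0, 1000)
  v <- interpolateCm(map, "c", q)
  lo <- interpolateCm(map, "c", floor(q / 100) * 100)
  hi <- interpolateCm(map, "c", pmin(ceiling(q / 100) * 100, 1000))
  expect_true(all(v >= lo - 1e-12 & v <= hi + 1e-12))
  # monotone in position
  expect_true(all(diff(interpolateCm(map, "c", sort(q))) >= -1e-12))
  expect_error(rhoToCm(data.frame(chrom = "c", start = 0, end = 1,
                                  rho = -0.1), 1e4), "non-negative")
})

test_that("xpehh matches a hand-computed six-haplotype example", {
  # 3 identical carriers (all ancestral), 3 distinct susceptibles,
  # 5 sites on a unit map (1 cM per bp), core at site 3
  g <- cbind(c1 = c(0, 0, 0, 0, 0), c2 = c(0, 0, 0, 0, 0),
             c3 = c(0, 0, 0, 0, 0),
             s1 = c(0, 0, 0, 0, 0), s2 = c(1, 0, 0, 0, 1),
             s3 = c(1, 1, 0, 1, 1))
  hm <- haplotypeMatrix(g, data.frame(chrom = "c", pos = 1:5, ref = "A",
                                      alt = "T", class = "other"))
  map <- geneticMap(rep("c", 5), 1:5, 1:5)
  res <- xpehh(hm, c("c1", "c2", "c3"), c("s1", "s2", "s3"), 3, map = map)
  expect_equal(res$ihh_a, 4)                     # EHH = 1 out to both ends
  expect_equal(res$ihh_b, 5 / 3)                 # 5/6 per side, trapezoids
  expect_equal(res$xpehh, log(4 / (5 / 3)))
  # EHH curves are non-increasing outward
  for (curve in list(res$ehh_a, res$ehh_b)) {
    for (d in c("left", "right")) {
      e <- curve$ehh[curve$direction == d]
      expect_true(all(diff(e) <= 1e-12))
    }
  }
})

test_that("xpehh is zero on identical sets and antisymmetric", {
  set.seed(72)
  hm <- makeNullHaplotypeMatrix(30, 20, spacing = 500)
  ids <- sampleIds(hm)
  same <- xpehh(hm, ids[1:6], ids[1:6], 15)
  expect_equal(same$xpehh, 0)
  ab <- xpehh(hm, ids[1:6], ids[7:14], 15)
  ba <- xpehh(hm, ids[7:14], ids[1:6], 15)
  expect_equal(ab$xpehh, -ba$xpehh, tolerance = 1e-12)
  # monomorphic region in both sets: EHH identically 1, xpehh 0
  gmono <- matrix(0L, 4, 8)
  hmono <- haplotypeMatrix(gmono, data.frame(chrom = "c", pos = 1:4 * 10,
                                             ref = "A", alt = "T",
                                             class = "other"))
  colnames(gmono) <- sampleIds(hmono)
  resm <- xpehh(hmono, sampleIds(hmono)[1:4], sampleIds(hmono)[5:8], 2)
  expect_true(all(resm$ehh_a$ehh == 1), all(resm$ehh_b$ehh == 1))
  expect_equal(resm$xpehh, 0)
})

test_that("pairwise diversity follows its definition and the coalescent mean", {
  # identical haplotypes: pi = 0
  g0 <- matrix(0L, 10, 4)
  hm0 <- haplotypeMatrix(g0, data.frame(chrom = "c", pos = 1:10, ref = "A",
                                        alt = "T", class = "other"))
  expect_equal(piWindows(hm0, data.frame(chrom = "c", start = 1,
                                         end = 11))$pi, 0)
  # two haplotypes differing at 3 of 100 sites: pi = 0.03
  gp <- matrix(0L, 100, 2)
  gp[1:3, 2] <- 1L
  hp <- haplotypeMatrix(gp, data.frame(chrom = "c", pos = 1:100, ref = "A",
                                       alt = "T", class = "other"))
  expect_equal(piWindows(hp, data.frame(chrom = "c", start = 1,
                                        end = 101))$pi, 0.03)
  # agreement with a brute-force pairwise-difference oracle
  set.seed(73)
  hm <- makeNullHaplotypeMatrix(25, 12)
  pw <- piWindows(hm, data.frame(chrom = "c1", start = 1, end = 1e5))
  expect_equal(pw$pi, oraclePi(genoMatrix(hm)), tolerance = 1e-12)

  # neutral simulator: mean per-bp pi across reps near theta = 4 Ne mu
  set.seed(74)
  ne <- 1000; mu <- 1e-6; L <- 2e4
  reps <- 120
  pis <- replicate(reps, {
    tr <- simNeutralTree(12, ne)
    hmx <- dropMutations(tr, mu, L)
    if (nrow(genoMatrix(hmx)) == 0) return(0)
    w <- piWindows(hmx, data.frame(chrom = "chr1", start = 1, end = L + 1))
    w$pi * w$n_sites / L
  })
  theta <- 4 * ne * mu
  se <- sd(pis) / sqrt(reps)
  expect_lt(abs(mean(pis) - theta), 3 * se)
})

test_that("h12 matches closed forms and pools the top two haplotypes", {
  # all identical -> 1
  g1 <- matrix(0L, 3, 6)
  hm1 <- haplotypeMatrix(g1, data.frame(chrom = "c", pos = 1:3, ref = "A",
                                        alt = "T", class = "other"))
  expect_equal(h12(hm1)$h12, 1)
  # frequencies (0.4, 0.3, 0.2, 0.1) -> 0.54
  g2 <- rbind(c(0, 0, 0, 0, 1, 1, 1, 0, 0, 1),
              c(0, 0, 0, 0, 0, 0, 0, 1, 1, 1))
  hm2 <- haplotypeMatrix(g2, data.frame(chrom = "c", pos = 1:2, ref = "A",
                                        alt = "T", class = "other"))
  res <- h12(hm2)
  expect_equal(res$frequencies, c(0.4, 0.3, 0.2, 0.1))
  expect_equal(res$h12, 0.7^2 + 0.2^2 + 0.1^2)
  expect_gte(res$h12, res$h1)
  # n distinct haplotypes -> (2/n)^2 + (n-2)/n^2
  n <- 8
  g3 <- matrix(0L, n - 1, n)
  for (i in seq_len(n - 1)) g3[i, i] <- 1L
  hm3 <- haplotypeMatrix(g3, data.frame(chrom = "c", pos = seq_len(n - 1),
                                        ref = "A", alt = "T",
                                        class = "other"))
  res3 <- h12(hm3)
  expect_equal(res3$h12, (2 / n)^2 + (n - 2) / n^2)
  expect_equal(res3$h1, n * (1 / n)^2)
  # invariant to haplotype order
  perm <- sample(ncol(g2))
  hm2p <- haplotypeMatrix(g2[, perm], siteInfo(hm2))
  expect_equal(h12(hm2p)$h12, res$h12)
  # SNP-count windows
  sc <- h12Scan(hm3, snp_window = 3, stride = 2)
  expect_true(all(sc$h12 >= sc$h1))
})

test_that("strong sweeps depress carrier diversity and extend homozygosity", {
  set.seed(75)
  reps <- 20
  hits_pi <- 0; hits_xp <- 0; used <- 0
  for (i in seq_len(reps)) {
    sw <- simSweepTree(30, 2000, s = 0.5, final_frequency = 0.5,
                       n_carriers = 12)
    hm <- dropMutations(sw$tree, 5e-7, 2e4)
    if (nrow(genoMatrix(hm)) < 10) next
    used <- used + 1
    sus <- setdiff(leafLabels(sw$tree), sw$carriers)
    d <- piDiff(hm, data.frame(chrom = "chr1", start = 1, end = 2e4 + 1),
                sw$carriers, sus)
    core <- which.min(abs(siteInfo(hm)$pos - 1e4))
    xp <- xpehh(hm, sw$carriers, sus, core)
    if (!is.na(d$delta_pi) && d$delta_pi < 0) hits_pi <- hits_pi + 1
    if (!is.na(xp$xpehh) && xp$xpehh > 0) hits_xp <- hits_xp + 1
  }
  expect_gt(hits_pi / used, 0.5)
  expect_gt(hits_xp / used, 0.5)
})
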