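test_that("the volume law predicts copies per cell", {
  expect_equal(rcFromVolume(1), 9.58)
  expect_equal(rcFromVolume(1000), 9.58 * exp(0.66 * log(1000)))
  expect_equal(rcFromVolume(1000), 914.9, tolerance = 1e-4)
  expect_equal(rcFromVolume(7, allometricModel(1, 1)), 7)
  expect_error(rcFromVolume(0), "positive")
  expect_error(rcFromVolume(-3), "positive")
})

test_that("the diameter law is the volume law at the sphere volume", {
  dl <- diameterLaw()
  expect_equal(round(unname(dl["prefactor"]), 2), 6.25)
  expect_equal(unname(dl["exponent"]), 1.98)
  expect_equal(rcFromDiameter(1), 6.25, tolerance = 1e-3)
  expect_equal(rcFromDiameter(2), 6.2499 * 2^1.98, tolerance = 1e-4)
  for (d in c(0.2, 1, 16.4))
    expect_equal(rcFromDiameter(d), rcFromVolume(sphereVolume(d)))
  expect_error(rcFromDiameter(0), "positive")
})

test_that("cell fractions invert the copy-number weighting", {
  p <- communityProfile(c("small", "large"), freq = c(0.5, 0.5),
                        volume = c(1, 1000))
  fc <- cellFrac(cellFractions(p))
  oracle <- oracleCorrect(c(0.5, 0.5), c(1, 1000))
  expect_equal(unname(fc), oracle$fc, tolerance = 1e-12)
  expect_equal(round(unname(fc), 3), c(0.990, 0.010))
  # shared volume: copy-number weighting cancels, F_c = F_r
  p2 <- communityProfile(letters[1:3], freq = c(0.2, 0.3, 0.5),
                         volume = rep(4, 3))
  expect_equal(unname(cellFrac(cellFractions(p2))), c(0.2, 0.3, 0.5))
  # single taxon
  p3 <- communityProfile("only", freq = 1, volume = 12)
  expect_equal(unname(cellFrac(cellFractions(p3))), 1)
})

test_that("biovolume fractions weight cell fractions by volume", {
  p <- communityProfile(c("small", "large"), freq = c(0.5, 0.5),
                        volume = c(1, 1000))
  corr <- biovolumeFractions(cellFractions(p))
  oracle <- oracleCorrect(c(0.5, 0.5), c(1, 1000))
  expect_equal(unname(biovolFrac(corr)), oracle$fv, tolerance = 1e-12)
  expect_equal(round(unname(biovolFrac(corr)), 3), c(0.087, 0.913))
  # equal volumes: F_v = F_c; single taxon: F_v = 1
  p2 <- communityProfile(letters[1:3], freq = c(0.2, 0.3, 0.5),
                         volume = rep(4, 3))
  corr2 <- biovolumeFractions(cellFractions(p2))
  expect_equal(biovolFrac(corr2), cellFrac(corr2))
  p3 <- communityProfile("only", freq = 1, volume = 12)
  expect_equal(unname(biovolFrac(biovolumeFractions(cellFractions(p3)))), 1)
})

test_that("absolutize anchors the profile to the qPCR total", {
  p <- communityProfile("only", freq = 1, volume = 1, qpcrTotal = 9.58e6)
  abs1 <- absolutize(p)
  expect_equal(abs1@totalCells, 1e6)
  expect_equal(abs1@totalBiovol, 1e6)
  # conservation and consistency with the fractions
  p2 <- communityProfile(c("s", "l"), freq = c(0.5, 0.5),
                         volume = c(1, 1000), qpcrTotal = 1000)
  a2 <- absolutize(p2)
  expect_equal(sum(a2@copies), 1000)
  expect_equal(unname(a2@cells / a2@totalCells), unname(cellFrac(a2)),
               tolerance = 1e-9)
  expect_equal(unname(a2@biovol / a2@totalBiovol), unname(biovolFrac(a2)),
               tolerance = 1e-9)
  # doubling R_s doubles absolutes, leaves fractions unchanged
  a3 <- absolutize(p2, qpcrTotal = 2000)
  expect_equal(a3@cells, 2 * a2@cells)
  expect_equal(a3@biovol, 2 * a2@biovol)
  expect_equal(cellFrac(a3), cellFrac(a2))
  expect_equal(biovolFrac(a3), biovolFrac(a2))
  # R_s is mandatory
  p4 <- communityProfile("x", freq = 1, volume = 1)
  expect_error(absolutize(p4), "qPCR total")
  expect_error(absolutize(p4, qpcrTotal = -5), "qPCR total")
})

test_that("profiles validate their structure", {
  expect_error(communityProfile(c("a", "a"), c(0.5, 0.5), volume = c(1, 2)),
               "unique")
  expect_error(communityProfile(c("a", "b"), c(0, 0), volume = c(1, 2)),
               "zero")
  expect_error(communityProfile(c("a", "b"), c(0.5, -0.1),
                                volume = c(1, 2)), "non-negative")
  expect_error(communityProfile("a", 1), "exactly one")
  expect_error(communityProfile("a", 1, volume = -2), "positive")
  expect_error(communityProfile("a", 1, volume = 1, qpcrTotal = 0),
               "positive")
})

test_that("frequencies not summing to one are renormalized with a warning", {
  p <- communityProfile(c("a", "b"), freq = c(30, 70), volume = c(1, 1))
  expect_warning(corr <- cellFractions(p), "renormalizing")
  expect_equal(unname(relFreq(corr)), c(0.3, 0.7))
  # zero-frequency taxa are carried through, not dropped
  p2 <- communityProfile(c("a", "b", "c"), freq = c(0.5, 0.5, 0),
                         volume = c(1, 10, 100))
  corr2 <- biovolumeFractions(cellFractions(p2))
  expect_equal(length(corr2), 3L)
  expect_equal(unname(cellFrac(corr2))[3], 0)
  expect_equal(unname(biovolFrac(corr2))[3], 0)
})

test_that("diameter bins follow the half-open convention", {
  sch <- sizeBinScheme()
  expect_equal(nBins(sch), 13L)
  expect_equal(binAssign(1.0), 5L)           # the 0.9-1.2 um bin
  expect_equal(binAssign(1.2), 6L)           # boundary joins the upper bin
  expect_equal(binAssign(0.2), 1L)
  expect_equal(binAssign(16.4), 13L)         # top edge closes the last bin
  expect_equal(binAssign(pi / 6, what = "volume"), 5L)
  expect_error(binAssign(0.1), "nearest bin")
  expect_error(binAssign(17), "nearest bin")
  expect_error(sizeBinScheme(c(1, 1, 2)), "increasing")
})

test_that("bin representatives average the edge values", {
  # 0.9-1.2 um bin: mean of 9.58 V(0.9)^0.66 = 5.07 and
  # 9.58 V(1.2)^0.66 = 8.97 is about 7.02
  lo <- 9.58 * sphereVolume(0.9)^0.66
  hi <- 9.58 * sphereVolume(1.2)^0.66
  expect_equal(round(lo, 2), 5.07)
  expect_equal(round(hi, 2), 8.97)
  expect_equal(binRc(5), (lo + hi) / 2)
  expect_equal(round(binRc(5), 2), 7.02)
  expect_equal(binRc(1),
               (rcFromVolume(sphereVolume(0.2)) +
                  rcFromVolume(sphereVolume(0.3))) / 2)
  expect_equal(binRepVolume(5), (sphereVolume(0.9) + sphereVolume(1.2)) / 2)
  expect_error(binRc(14), "1..13")
  expect_error(binRepVolume(0), "1..13")
})

test_that("within-bin variation stays below 8% in every bin", {
  tab <- binTable()
  expect_equal(nrow(tab), 13)
  expect_true(all(tab$variation_pct <= 8))
  expect_true(all(diff(tab$lo) > 0))
  expect_equal(tab$hi[-13], tab$lo[-1])      # contiguous bins
})

test_that("binned profiles use representative volumes and copy numbers", {
  p <- communityProfile(c("binned", "exact"), freq = c(0.5, 0.5),
                        diameter = c(1.0, NA), volume = c(NA, 1000))
  corr <- biovolumeFractions(cellFractions(p))
  expect_equal(corr@rc[1], binRc(5))
  expect_equal(corr@volume[1], binRepVolume(5))
  expect_equal(corr@rc[2], rcFromVolume(1000))
})

test_that("fraction sums, bias direction and permutation invariance hold", {
  set.seed(99)
  for (r in 1:50) {
    n <- sample(2:25, 1)
    p <- communityProfile(sprintf("t%02d", 1:n),
                          freq = runif(n),
                          volume = exp(runif(n, log(1e-2), log(1e7))))
    corr <- suppressWarnings(correctProfile(p, qpcrTotal = runif(1, 1, 1e9)))
    expect_equal(sum(cellFrac(corr)), 1, tolerance = 1e-9)
    expect_equal(sum(biovolFrac(corr)), 1, tolerance = 1e-9)
    expect_equal(sum(corr@copies), corr@qpcrTotal, tolerance = 1e-9)
  }
  # equal read frequencies: the larger cell always contributes fewer
  # cells and more biovolume
  p <- communityProfile(c("small", "big"), freq = c(0.5, 0.5),
                        volume = c(3, 900))
  corr <- biovolumeFractions(cellFractions(p))
  expect_lt(cellFrac(corr)["big"], cellFrac(corr)["small"])
  expect_gt(biovolFrac(corr)["big"], biovolFrac(corr)["small"])
  # permutation invariance
  set.seed(42)
  n <- 12
  fr <- runif(n); fr <- fr / sum(fr)
  v <- exp(runif(n, -2, 10))
  ord <- sample(n)
  c1 <- correctProfile(communityProfile(sprintf("t%02d", 1:n), fr,
                                        volume = v))
  c2 <- correctProfile(communityProfile(sprintf("t%02d", (1:n)[ord]),
                                        fr[ord], volume = v[ord]))
  expect_equal(cellFrac(c2)[names(cellFrac(c1))], cellFrac(c1),
               tolerance = 1e-12)
  expect_equal(biovolFrac(c2)[names(biovolFrac(c1))], biovolFrac(c1),
               tolerance = 1e-12)
})

test_that("forward-simulated communities are inverted exactly", {
  # volumes spanning more than 6 decades
  counts <- c(1e6, 5e4, 2e3, 50, 3)
  volumes <- c(0.05, 1.2, 40, 2.1e3, 8e5)
  sim <- simulateCommunity(counts, volumes)
  corr <- biovolumeFractions(cellFractions(sim$profile))
  expect_equal(unname(cellFrac(corr)), sim$truth$cell_frac,
               tolerance = 1e-9)
  expect_equal(unname(biovolFrac(corr)), sim$truth$biovol_frac,
               tolerance = 1e-9)
})
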