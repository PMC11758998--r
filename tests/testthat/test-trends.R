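test_that("binning takes arithmetic means in half-open anchored bins", {
  x <- makeToyExperiment(nMol = 2, nSamp = 2, seed = 30,
                         years = c(1801, 1803))
  intensityMatrix(x)[1, ] <- c(10, 30)
  b <- binIntensities(x, binWidth = 5, anchor = 1800)
  expect_equal(binYears(b), 1800)
  expect_equal(binMatrix(b)[1, 1], 20)

  # boundary year belongs to the bin starting there
  x2 <- makeToyExperiment(nMol = 2, nSamp = 3, seed = 31,
                          years = c(1801, 1804.9, 1805))
  b2 <- binIntensities(x2)
  expect_equal(binYears(b2), c(1800, 1805))
  expect_equal(b2@sampleCount, c(2L, 1L))

  # empty interior bins are missing, not zero
  x3 <- makeToyExperiment(nMol = 2, nSamp = 2, seed = 32,
                          years = c(1801, 1816))
  b3 <- binIntensities(x3)
  expect_true(all(is.na(binMatrix(b3)[, 2])))

  # a 53-sample 1800-1980 record fits in at most 37 five-year bins
  x4 <- makeToyExperiment(nMol = 3, nSamp = 53, seed = 33,
                          years = sort(runif(53, 1800, 1980)))
  expect_lte(length(binYears(binIntensities(x4))), 37)
})

test_that("class series conserve intensity and form probability shares", {
  x <- makeToyExperiment(nMol = 2, nSamp = 2, seed = 34,
                         years = c(1801, 1803))
  intensityMatrix(x)[1, ] <- 95; intensityMatrix(x)[2, ] <- 5
  b <- binIntensities(x)
  cs <- classSeries(b, c("CHO", "CHNO"))
  expect_equal(unname(cs$share[, 1]), c(95, 5))
  expect_equal(unname(cs$recordShare), c(95, 5))

  x2 <- makeToyExperiment(nMol = 10, nSamp = 12, seed = 35)
  cs2 <- classSeries(binIntensities(x2), sample(c("CHO", "CHNO", "other"),
                                                10, replace = TRUE))
  expect_equal(unname(colSums(cs2$share)), rep(100, ncol(cs2$share)))
  expect_equal(sum(cs2$recordShare), 100)
})

test_that("weighted descriptor series are intensity-weighted means", {
  x <- makeToyExperiment(nMol = 2, nSamp = 1, seed = 36, years = 1801)
  intensityMatrix(x)[] <- c(10, 30)
  b <- binIntensities(x)
  vals <- setNames(c(0.5, 1.0), rownames(x))
  expect_equal(weightedDescriptor(b, vals)$value, 0.875)

  # equal weights reduce to the plain mean; single-molecule subset is identity
  intensityMatrix(x)[] <- c(7, 7)
  b2 <- binIntensities(x)
  expect_equal(weightedDescriptor(b2, vals)$value, 0.75)
  expect_equal(weightedDescriptor(b2, vals, subset = rownames(x)[2])$value, 1.0)

  # invariant to rescaling all intensities in a bin
  x3 <- makeToyExperiment(nMol = 4, nSamp = 6, seed = 37)
  b3 <- binIntensities(x3)
  v3 <- setNames(runif(4), rownames(x3))
  w1 <- weightedDescriptor(b3, v3)$value
  x3b <- x3; intensityMatrix(x3b) <- intensityMatrix(x3) * 17.3
  w2 <- weightedDescriptor(binIntensities(x3b), v3)$value
  expect_equal(w1, w2)
  # value bounded by the descriptor range (empty bins stay missing)
  expect_true(all(w1 >= min(v3) & w1 <= max(v3), na.rm = TRUE))
})

test_that("change-point scan is exact on steps and matches brute force", {
  cp <- detectChangePoint(c(1, 1, 1, 1, 2, 2, 2), seq(1800, 1830, 5))
  expect_equal(cp$year, 1820)
  expect_true(cp$significant)

  flat <- detectChangePoint(rep(3, 8), seq(1800, 1835, 5))
  expect_equal(flat$sseDrop, 0)
  expect_false(flat$significant)

  # cumulative-sum implementation == explicit brute-force scan
  set.seed(38)
  for (rep in 1:50) {
    v <- rnorm(sample(4:40, 1))
    got <- detectChangePoint(v)
    oracle <- bruteChangePoint(v)
    expect_equal(got$index, oracle$index)
    expect_equal(got$sseDrop, oracle$sseDrop, tolerance = 1e-9)
  }
  expect_error(detectChangePoint(c(1, 2, 3)), "at least 4")
})

test_that("fold change divides post- by pre-change means", {
  yrs <- seq(1800, 1835, 5)
  v <- c(10, 10, 10, 10, 14, 14, 14, 14)
  expect_equal(foldChange(v, yrs, 1820)$fold, 1.4)
  expect_equal(foldChange(rep(5, 8), yrs, 1820)$fold, 1)
  expect_warning(fc <- foldChange(c(0, 0, 0, 0, 1, 1, 1, 1), yrs, 1820),
                 "zero")
  expect_true(is.na(fc$fold))
})

test_that("trend test recovers exact lines and flags degeneracy", {
  yrs <- 1:20
  tt <- trendTest(2 * yrs, yrs)
  expect_equal(tt$slope, 2)
  expect_lt(tt$pValue, 1e-12)
  flat <- trendTest(rep(4, 10), 1:10)
  expect_equal(flat$slope, 0)
  expect_true(is.na(flat$pValue))
  expect_false(flat$significant)
})

test_that("proxy correlation interpolates the proxy onto the bins", {
  yrs <- seq(1800, 1900, 5)
  v <- sin(yrs / 20)
  proxy <- data.frame(year = yrs, value = v)
  expect_equal(proxyCorrelation(v, yrs, proxy), 1)
  proxy$value <- -v
  expect_equal(proxyCorrelation(v, yrs, proxy), -1)
  # interpolation: proxy on a coarser grid still correlates strongly
  coarse <- data.frame(year = seq(1800, 1900, 20),
                       value = sin(seq(1800, 1900, 20) / 20))
  expect_gt(proxyCorrelation(v, yrs, coarse), 0.97)
  expect_error(proxyCorrelation(v[1:2], yrs[1:2], proxy[1:2, ]), "3")
})

test_that("group comparison is a symmetric Welch test", {
  set.seed(39)
  a <- rnorm(30)
  expect_equal(compareGroups(a, a)$pValue, 1)
  b <- rnorm(40, 1, 2)
  expect_equal(compareGroups(a, b)$pValue, compareGroups(b, a)$pValue)
  expect_lt(compareGroups(rnorm(50), rnorm(50, 3))$pValue, 1e-6)
  expect_error(compareGroups(1, c(1, 2)), ">= 2")
})
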