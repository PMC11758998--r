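test_that("z-scoring standardises rows and flags degenerate ones", {
  m <- rbind(a = c(1, 2, 3), b = c(5, 5, 5), c = c(10, 0, 20))
  z <- zscoreRows(m)
  expect_equal(mean(z["a", ]), 0)
  expect_equal(sd(z["a", ]), 1)
  expect_equal(unname(z["b", ]), c(0, 0, 0))
  expect_equal(unname(attr(z, "degenerate")), c(FALSE, TRUE, FALSE))
  # invariance to affine rescaling of a raw row
  z2 <- zscoreRows(rbind(a = 100 + 42 * m["a", ], c = m["c", ]))
  expect_equal(unname(z2["a", ]), unname(z["a", ]))
})

test_that("planted flat versus step populations are perfectly separated", {
  set.seed(50)
  nb <- 20
  flat <- t(replicate(20, rnorm(nb, 0, 0.3)))
  step <- t(replicate(20, c(rep(0, 12), rep(2, 8)) + rnorm(nb, 0, 0.3)))
  m <- rbind(flat, step)
  rownames(m) <- sprintf("M%02d", 1:40)
  cl <- clusterMolecules(zscoreRows(m))
  lab <- clusterLabels(cl)
  truthTop <- rep(c("2", "1"), each = 20)
  got <- ifelse(lab == "2", "2", "1")
  expect_equal(mclust::adjustedRandIndex(got, truthTop), 1.0)
  # the rising population is the one called anthropogenic
  expect_true(all(got[21:40] == "1"))
})

test_that("anthropogenic branch splits into ramping versus absent-early", {
  aris <- vapply(1:25, function(s) {
    set.seed(400 + s)
    nb <- 30
    flat <- t(replicate(25, 100 * (1 + rnorm(nb, 0, 0.15))))
    ramp <- t(replicate(20, 100 * (1 + 0.8 * seq(0, 1, length.out = nb) +
                                     rnorm(nb, 0, 0.15))))
    zero <- t(replicate(12, c(rep(0, 20), 100 * (1 + rnorm(10, 0, 0.15)))))
    m <- rbind(flat, ramp, zero)
    rownames(m) <- sprintf("M%02d", seq_len(nrow(m)))
    lab <- clusterLabels(clusterMolecules(zscoreRows(m)))
    truth <- rep(c("2", "1A", "1B"), c(25, 20, 12))
    mclust::adjustedRandIndex(lab, truth)
  }, numeric(1))
  expect_gte(mean(aris >= 0.9), 0.95)
})

test_that("identical rows merge at distance zero", {
  m <- matrix(rep(c(1, 3, 2, 5), each = 6), nrow = 6, byrow = FALSE)
  rownames(m) <- sprintf("M%d", 1:6)
  cl <- clusterMolecules(zscoreRows(m))
  expect_equal(max(cl@tree$height), 0)
})

test_that("cluster summaries aggregate descriptors and conserve tallies", {
  set.seed(51)
  x <- makeToyExperiment(nMol = 14, nSamp = 12, seed = 52)
  b <- binIntensities(x)
  cl <- clusterMolecules(zscoreRows(b), binYears = binYears(b))
  forms <- setNames(formulas(x), rownames(x))
  desc <- computeDescriptors(forms)
  s <- summarizeClusters(cl, desc)
  expect_equal(sum(vapply(s, `[[`, numeric(1), "n")),
               length(clusterLabels(cl)))
  global <- table(factor(desc$compound_class,
                         levels = c("CHO", "CHNO", "CHNOS", "CHOS", "other")))
  summed <- Reduce(`+`, lapply(s, `[[`, "classCounts"))
  expect_equal(as.integer(summed), as.integer(global))

  # hand case: mean +/- sd of two members
  d2 <- data.frame(id = c("m1", "m2"), formula = c("C4H6O4", "C5H8O4"),
                   nC = c(4, 5), oc_ratio = c(0.4, 0.8), hc_ratio = c(1.5, 1.6),
                   dbe = c(2, 2), chi_c = c(0, 0), osc = c(-0.7, 0),
                   compound_class = "CHO", stringsAsFactors = FALSE)
  fake <- new("MoleculeClustering", tree = cl@tree,
              labels = setNames(c("1A", "1A"), c("m1", "m2")),
              meanSeries = matrix(0, 1, 2, dimnames = list("1A", NULL)),
              binYears = c(1800, 1805), excluded = character(0))
  s2 <- summarizeClusters(fake, d2)
  expect_equal(unname(s2$`1A`$descriptors["mean", "oc_ratio"]), 0.6)
  expect_equal(unname(s2$`1A`$descriptors["sd", "oc_ratio"]), 0.2828, tolerance = 1e-3)
})

test_that("cluster shares are percent splits summing to 100 per bin", {
  x <- makeToyExperiment(nMol = 6, nSamp = 8, seed = 53)
  intensityMatrix(x)[] <- 1e7 * matrix(rep(seq(1, 2, length.out = 8), each = 6), 6)
  b <- binIntensities(x)
  cl <- clusterMolecules(zscoreRows(b), binYears = binYears(b))
  sh <- clusterShare(cl, b)
  filled <- colSums(is.na(sh)) == 0   # bins containing samples
  expect_true(any(filled))
  expect_equal(unname(colSums(sh[, filled, drop = FALSE])),
               rep(100, sum(filled)))
})

test_that("Ward merge heights are monotone and labels follow molecules", {
  set.seed(54)
  x <- makeToyExperiment(nMol = 20, nSamp = 16, seed = 55)
  b <- binIntensities(x)
  z <- zscoreRows(b)
  cl <- clusterMolecules(z, binYears = binYears(b))
  expect_true(all(diff(cl@tree$height) >= -1e-9))

  perm <- sample(nrow(z))
  zp <- z[perm, , drop = FALSE]
  attr(zp, "degenerate") <- attr(z, "degenerate")[perm]
  clp <- clusterMolecules(zp, binYears = binYears(b))
  ids <- names(clusterLabels(cl))
  # same partition up to the 1A/1B/2 naming, checked via ARI = 1
  expect_equal(mclust::adjustedRandIndex(clusterLabels(cl)[ids],
                                         clusterLabels(clp)[ids]), 1.0)
})
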