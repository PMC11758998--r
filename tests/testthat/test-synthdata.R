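test_that("generation is deterministic under a fixed seed", {
  cfg <- generatorConfig(seed = 77)
  s1 <- simulateIceCore(cfg)
  s2 <- simulateIceCore(cfg)
  expect_identical(intensityMatrix(s1$features), intensityMatrix(s2$features))
  expect_identical(formulas(s1$features), formulas(s2$features))
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$proxies, s2$proxies)
})

test_that("class counts match the configured proportions", {
  sim <- simulateIceCore(generatorConfig(seed = 78))
  counts <- as.integer(sim$truth$classCounts)
  expect_true(all(abs(counts - c(298, 72, 12, 8, 8)) <= 3))
  expect_equal(sum(counts), 398L)
})

test_that("purely industrial molecules are absent before their onset", {
  sim <- simulateIceCore(generatorConfig(seed = 79))
  im <- intensityMatrix(sim$features)
  yrs <- sampleYears(sim$features)
  lab <- sim$truth$labels
  cls <- sim$truth$classes
  for (id in names(lab)[lab == "1B"]) {
    onset <- if (cls[[id]] == "CHNOS") 1960 else 1950
    expect_true(all(im[id, yrs < onset] == 0))
    expect_true(any(im[id, yrs >= onset] > 0))
  }
})

test_that("generated formulas are chemically valid and descriptor-clean", {
  sim <- simulateIceCore(generatorConfig(seed = 80, nRejects = 0))
  fs <- formulas(sim$features)
  d <- computeDescriptors(setNames(fs, rownames(sim$features)))
  expect_true(all(d$chi_c >= 0))
  expect_true(all(d$dbe >= 0))
  expect_equal(d$osc, 2 * d$oc_ratio - d$hc_ratio, tolerance = 1e-12)
  ec <- elementCounts(fs)
  expect_true(all(ec[, "H"] + ec[, "X"] <= 2 * ec[, "C"] + 2 + ec[, "N"]))
  # generated class labels agree with the classifier
  expect_equal(unname(compoundClass(fs)), unname(sim$truth$classes))
  # most CHO molecules sit in the 0.25 <= O/C < 0.75 band
  cho <- d$compound_class == "CHO"
  expect_gte(mean(d$oc_ratio[cho] >= 0.25 & d$oc_ratio[cho] < 0.75), 0.70)
})

test_that("QC filter separates planted molecules from planted rejects", {
  sim <- simulateIceCore(generatorConfig(seed = 81))
  res <- applyQcFilters(sim$features)
  expect_setequal(rownames(res$kept), names(sim$truth$labels))
  expect_equal(sum(res$tally), length(sim$truth$rejects))
  # every predicate is exercised by the reject set
  expect_true(all(res$tally >= 1))
})

test_that("CHO intensity share converges to its target at large n", {
  sim <- simulateIceCore(generatorConfig(nMolecules = 5000, nRejects = 0,
                                         seed = 82))
  res <- applyQcFilters(sim$features)
  b <- binIntensities(res$kept)
  cs <- classSeries(b, compoundClass(formulas(res$kept)))
  expect_lt(abs(cs$recordShare[["CHO"]] - 95), 2)
})

test_that("written datasets read back into an equivalent pipeline input", {
  sim <- simulateIceCore(generatorConfig(seed = 83, nRejects = 6))
  dir <- file.path(tempdir(), "simout")
  writeSyntheticData(sim, dir)
  sam <- readSampleMeta(file.path(dir, "samples.csv"))
  suppressMessages(x <- readFeatureTable(file.path(dir, "features.csv"), sam))
  expect_equal(dim(x), dim(sim$features))
  expect_equal(intensityMatrix(x), intensityMatrix(sim$features),
               tolerance = 1e-6)
  p <- readProxy(file.path(dir, "proxies", "nitrate.csv"))
  expect_equal(p$value, sim$proxies$nitrate$value, tolerance = 1e-6)
  lib <- readSpectralLibrary(file.path(dir, "library.msp"))
  expect_length(lib, length(sim$speclib))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(length(truth$labels), 398L)
})

test_that("recovery scoring hits the ceiling without noise and floors on nulls", {
  sim <- simulateIceCore(generatorConfig(seed = 84, noiseCV = 0))
  rep <- runPipeline(sim$features, proxies = sim$proxies, verbose = FALSE)
  rec <- recoveryReport(rep, sim$truth)
  expect_equal(rec$ariTop, 1.0)
  expect_equal(rec$cpErrorCHNO, 0)
  expect_equal(rec$cpErrorCHNOS, 0)
  # shuffled labels baseline: ARI near zero
  set.seed(85)
  shuffled <- rep; shuffled$clusterLabels <- setNames(
    sample(rep$clusterLabels), names(rep$clusterLabels))
  expect_lt(abs(recoveryReport(shuffled, sim$truth)$ariTop), 0.1)
})
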