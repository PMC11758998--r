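test_that("Hill-notation parsing reads counts and round-trips", {
  expect_equal(parseFormula("C8H8O3"), c(C = 8L, H = 8L, O = 3L))
  expect_equal(parseFormula("C6H5NO3"), c(C = 6L, H = 5L, N = 1L, O = 3L))
  expect_equal(parseFormula("CH4"), c(C = 1L, H = 4L))
  # explicit "1" counts and unknown symbols survive
  expect_equal(parseFormula("C6H5N1O3"), parseFormula("C6H5NO3"))
  expect_true("Se" %in% names(parseFormula("C2H6Se")))
  # parse -> format -> parse is idempotent
  set.seed(1)
  for (f in replicate(50, randomFormula())) {
    expect_identical(formatFormula(parseFormula(f)), f)
  }
  expect_error(parseFormula("C6h6"), "position")
  expect_error(parseFormula("8CH"), "position")
  expect_error(parseFormula(""), "non-empty")
})

test_that("compound classes follow the exact element-set rules", {
  expect_equal(compoundClass(c("C4H6O4", "C6H5NO3", "C10H15NO7S",
                               "C8H14O4S", "C6H7N", "C6H4ClNO2", "C5H12")),
               c("CHO", "CHNO", "CHNOS", "CHOS", "other", "other", "other"))
  # class assignment partitions any formula set
  set.seed(2)
  fs <- replicate(200, randomFormula())
  cls <- compoundClass(fs)
  expect_true(all(cls %in% c("CHO", "CHNO", "CHNOS", "CHOS", "other")))
  expect_equal(sum(table(cls)), length(fs))
})

test_that("DBE counts rings plus double bonds, halogens counted with H", {
  expect_equal(dbe("C4H6O4"), 2)
  expect_equal(dbe("C6H5NO3"), 5)
  expect_equal(dbe("C6H4ClNO2"), 5)   # Cl counted with hydrogen
  expect_equal(dbe("C6H6"), 4)
  # parity rule: integer iff H+halogens and N have equal parity
  set.seed(3)
  for (f in replicate(300, randomFormula())) {
    ec <- elementCounts(f)
    d <- dbe(f)
    if ((ec[, "H"] + ec[, "X"] + ec[, "N"]) %% 2 == 0) {
      expect_equal(d, round(d))
    } else {
      expect_equal(abs(d - floor(d)), 0.5)
    }
  }
})

test_that("aromaticity equivalent matches its definition and clamps", {
  expect_equal(aromaticityEquivalent("C8H8O3"), 2.428571, tolerance = 1e-6)
  expect_equal(round(aromaticityEquivalent("C8H8O3"), 1), 2.4)
  expect_equal(aromaticityEquivalent("C5H8O3"), 0)  # raw value negative
  expect_equal(aromaticityEquivalent("C4H6O4"), 0)  # degenerate denominator
  expect_equal(aromaticityEquivalent("C6H6"), 2.5)  # aromatic at threshold
  # non-default pi-bond fractions shift the correction
  cfgCarbonyl <- descriptorConfig(m = 1, n = 1)
  expect_lt(aromaticityEquivalent("C8H8O3", cfgCarbonyl),
            aromaticityEquivalent("C8H8O3"))
  # brute-force re-evaluation on random formulas; always >= 0
  set.seed(4)
  for (f in replicate(300, randomFormula())) {
    chi <- aromaticityEquivalent(f)
    expect_gte(chi, 0)
    ec <- elementCounts(f)
    d <- dbe(f) - 0.5 * ec[, "O"] - 0.5 * ec[, "S"]
    raw <- (3 * d - 2) / d
    if (d > 0 && raw > 0) expect_equal(chi, unname(raw))
  }
})

test_that("carbon oxidation state equals 2 O/C - H/C", {
  expect_equal(carbonOxidationState("C8H8O3"), -0.25)
  expect_equal(carbonOxidationState("CH4"), -4)
  expect_equal(carbonOxidationState("C4H6O4"), 0.5)
  expect_error(carbonOxidationState("H2O"), "zero-carbon")
  # alkane closed form: OSc(CnH2n+2) = -(2n+2)/n < -2
  for (n in 1:12) {
    f <- formatFormula(c(C = n, H = 2 * n + 2))
    expect_equal(carbonOxidationState(f), -(2 * n + 2) / n)
    expect_lt(carbonOxidationState(f), -2)
  }
})

test_that("Van Krevelen and Kroll regions annotate by interval membership", {
  r <- annotateRegions(osc = c(-0.3, 0.5, -1.65, -0.75), hc = c(1.8, 1, 2, 1.2))
  expect_equal(r$vk_region,
               c("aliphatic", "unsaturated/aromatic-leaning", "aliphatic",
                 "unsaturated/aromatic-leaning"))
  expect_true(all(c("isoprene-OH", "SVOC") %in% r$kroll_regions[[1]]))
  expect_equal(r$kroll_regions[[2]], "LVOC")
  expect_equal(r$kroll_regions[[3]], "hydrocarbon-like")
  # overlapping bands: -0.75 sits in both precursor intervals
  expect_setequal(r$kroll_regions[[4]], c("monoterpene-oxidation",
                                          "isoprene-OH"))
})

test_that("descriptor table keeps internal identities and exports cleanly", {
  set.seed(5)
  fs <- replicate(40, randomFormula())
  names(fs) <- sprintf("X%02d", seq_along(fs))
  d <- computeDescriptors(fs)
  expect_equal(d$osc, 2 * d$oc_ratio - d$hc_ratio, tolerance = 1e-12)
  expect_equal(d$is_aromatic, d$chi_c >= 2.5)
  expect_equal(nrow(d), 40)
  tf <- tempfile(fileext = ".csv")
  writeDescriptors(d, tf)
  back <- read.csv(tf)
  expect_equal(back$chi_c, d$chi_c, tolerance = 1e-9)
  expect_equal(back$id, d$id)
})
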