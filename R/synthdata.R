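# Synthetic ice-core NTS generator. Emulates the statistical structure the
# pipeline assumes: a dated 1800-1980 CE record with a dominant natural
# (stationary-to-declining) molecule population, an anthropogenic population
# ramping after the industrialisation onset with a purely industrial
# subpopulation absent before it, class-level step increases, and proxy
# series coupled to the anthropogenic cluster mean. Calibrations (class
# counts, intensity shares, fold changes, proxy correlations) are applied
# deterministically per realisation so the planted values are exact at the
# template level; lognormal multiplicative noise sits on top.

MONO_MASS <- c(C = 12, H = 1.0078250319, N = 14.0030740052,
               O = 15.9949146221, S = 31.97207069, Cl = 34.96885271,
               P = 30.97376151)
PROTON_MASS <- 1.00727646688

# largest-remainder allocation of n into round(n * p) with exact total
.allocate <- function(n, p) {
  raw <- n * p / sum(p)
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1L
  }
  as.integer(base)
}

#' Generator configuration
#'
#' Defaults encode the study conditions the generator emulates: 398
#' molecules at class proportions 75/18/3/2/2 percent, CHO carrying 95
#' percent of the record-total intensity, 53 unevenly spaced samples over
#' 1800-1980 CE, an anthropogenic ramp starting 1925 with a 1.4-fold
#' cluster-1A increase, purely industrial (1B) molecules appearing at the
#' class onset (1950; 1960 for CHNOS), class-aggregate fold increases of
#' 1.4 (CHNO, 1950) and 1.9 (CHNOS, 1960), a declining natural cluster,
#' 15 percent multiplicative noise, and nitrate/sulfate proxies coupled to
#' the anthropogenic cluster mean at r = 0.70/0.72.
#'
#' @param nMolecules number of true molecular profiles (post-QC).
#' @param classProportions named numeric, molecule-count proportions.
#' @param choIntensityShare CHO share of record-total intensity.
#' @param recordStart,recordEnd record span, years CE.
#' @param nSamples number of dated samples.
#' @param rampStart1A year the cluster-1A ramp begins.
#' @param onset1B year purely industrial molecules appear (CHNOS members
#'   follow `onsetCHNOS`).
#' @param onsetCHNO,onsetCHNOS class-aggregate step years.
#' @param fold1A cluster-1A aggregate post/pre fold at `onset1B`.
#' @param foldCHNO,foldCHNOS class-aggregate post/pre folds.
#' @param naturalTrend fractional change of the natural cluster over the
#'   record (negative = decline).
#' @param noiseCV multiplicative (lognormal) noise coefficient of variation.
#' @param blankLevel blank intensity as a fraction of the profile maximum.
#' @param proxyCoupling named numeric, target Pearson r of each coupled
#'   proxy with the anthropogenic cluster mean.
#' @param nRejects extra profiles constructed to fail exactly one QC
#'   predicate each (exercises the filter).
#' @param seed integer RNG seed.
#' @return list with class `GeneratorConfig`.
#' @export
generatorConfig <- function(nMolecules = 398,
                            classProportions = c(CHO = 0.75, CHNO = 0.18,
                                                 CHNOS = 0.03, CHOS = 0.02,
                                                 other = 0.02),
                            choIntensityShare = 0.95,
                            recordStart = 1800, recordEnd = 1980,
                            nSamples = 53,
                            rampStart1A = 1925, onset1B = 1950,
                            onsetCHNO = 1950, onsetCHNOS = 1960,
                            fold1A = 1.4, foldCHNO = 1.4, foldCHNOS = 1.9,
                            naturalTrend = -0.35, noiseCV = 0.15,
                            blankLevel = 0.02,
                            proxyCoupling = c(nitrate = 0.70, sulfate = 0.72,
                                              ozone = 0.66),
                            nRejects = 40, seed = 1L) {
  stopifnot(abs(sum(classProportions) - 1) < 1e-8,
            all(c(fold1A, foldCHNO, foldCHNOS) > 0),
            noiseCV >= 0, nMolecules >= 20, nSamples >= 10)
  structure(as.list(environment()), class = "GeneratorConfig")
}

# intensity shares of record-total per class (count shares 75/18/3/2/2)
.classIntensityShares <- function(choShare) {
  rest <- 1 - choShare
  c(CHO = choShare, CHNO = rest * 0.80, CHNOS = rest * 0.08,
    CHOS = rest * 0.06, other = rest * 0.06)
}

# cluster mix within each class, derived from the cross table of an alpine
# ice-core record (1A / 1B / 2)
CLUSTER_MIX <- rbind(
  CHO   = c(93, 9, 195),
  CHNO  = c(27, 21, 24),
  CHNOS = c(0, 7, 4),
  CHOS  = c(3, 3, 2),
  other = c(2, 6, 2))
colnames(CLUSTER_MIX) <- c("1A", "1B", "2")

# draw one chemically valid formula for a class/cluster pair; clusters differ
# in oxidation (1A most oxidised, 2 intermediate, 1B least) and chain length
.sampleFormula <- function(class, cluster) {
  par <- switch(cluster,
    "1A" = list(nc = 4:10, p = 0.30, ocMu = 0.65, ocSd = 0.15,
                oscMu = -0.3, oscSd = 0.5),
    "2"  = list(nc = 5:18, p = 0.18, ocMu = 0.50, ocSd = 0.15,
                oscMu = -0.6, oscSd = 0.5),
    "1B" = list(nc = 5:20, p = 0.20, ocMu = 0.40, ocSd = 0.20,
                oscMu = -1.0, oscSd = 0.6))
  ncw <- stats::dgeom(seq_along(par$nc) - 1, prob = par$p) + 0.01
  for (try in 1:200) {
    C <- sample(par$nc, 1, prob = ncw)
    N <- switch(class,
                CHO = 0L, CHOS = 0L,
                CHNO = sample(1:2, 1, prob = c(0.8, 0.2)),
                CHNOS = 1L,
                other = sample(0:1, 1))
    S <- if (class %in% c("CHNOS", "CHOS")) 1L else 0L
    Cl <- 0L
    P <- 0L
    hasO <- TRUE
    if (class == "other") {
      kind <- sample(c("CHN", "CHNS", "CHOCl", "CHOP"), 1)
      if (kind == "CHN") { N <- max(N, 1L); hasO <- FALSE }
      if (kind == "CHNS") { N <- max(N, 1L); S <- 1L; hasO <- FALSE }
      if (kind == "CHOCl") { N <- 0L; Cl <- 1L }
      if (kind == "CHOP") { N <- 0L; P <- 1L }
    }
    O <- if (hasO) max(1L, round(stats::rnorm(1, par$ocMu, par$ocSd) * C))
         else 0L
    if (O > 2 * C) next
    hc <- 2 * O / C - stats::rnorm(1, par$oscMu, par$oscSd)
    H <- round(hc * C)
    # DBE integer: H + halogens must share N's parity
    if ((H + Cl + N) %% 2 != 0) H <- H + 1L
    if (H < 1 || H + Cl > 2 * C + 2 + N) next
    ct <- c(C = C, H = as.integer(H), N = N, O = O, S = S, Cl = Cl, P = P)
    ct <- ct[ct > 0]
    f <- formatFormula(ct)
    if (dbe(f) < 0) next
    return(f)
  }
  stop("could not draw a valid formula for class ", class)
}

.mzFromFormula <- function(f) {
  ct <- parseFormula(f)
  m <- sum(vapply(names(ct), function(s) {
    if (!s %in% names(MONO_MASS)) stop("no mass for element ", s)
    MONO_MASS[[s]] * ct[[s]]
  }, numeric(1)))
  m - PROTON_MASS   # [M-H]- in negative-mode ESI
}

#' Generate a synthetic ice-core NTS dataset
#'
#' Draws molecules (class, cluster, formula, base intensity), builds
#' deterministic temporal templates per cluster (natural decline,
#' anthropogenic ramp from `rampStart1A`, purely industrial step at the
#' class onset), calibrates intensities so the planted quantities are exact
#' at the template level (class counts by largest remainder; within-class
#' cluster intensity balance; class record-total intensity shares;
#' closed-form ramp amplitude and class step multipliers for the target
#' folds), rescales so every true profile clears the QC intensity floor,
#' then applies lognormal noise. Proxy series are built on the 5-year bin
#' grid as affine images of the planted anthropogenic cluster mean plus
#' noise rescaled so the sample correlation equals the coupling target
#' exactly. `nRejects` additional profiles each violate exactly one QC
#' predicate. A handful of molecules get reference standards, MS2 spectra
#' and spectral-library entries so the identification stage can run.
#'
#' @param config a [generatorConfig()].
#' @return list with `features` (an [NTSExperiment] including reject
#'   profiles), `samples` (metadata `data.frame`), `proxies` (named list of
#'   year/value `data.frame`s), `standards`, `speclib`, `ms2` (named list of
#'   spectra), and `truth` (planted labels, onsets, folds, shares,
#'   couplings, reject ids).
#' @export
simulateIceCore <- function(config = generatorConfig()) {
  stopifnot(inherits(config, "GeneratorConfig"))
  set.seed(config$seed)
  cfg <- config
  span <- cfg$recordEnd - cfg$recordStart

  ## ---- samples: uneven dates, monotone depth, enrichment ----
  grid <- seq(cfg$recordStart, cfg$recordEnd, length.out = cfg$nSamples)
  years <- sort(pmin(cfg$recordEnd, pmax(cfg$recordStart,
    grid + stats::runif(cfg$nSamples, -1.7, 1.7))))
  samples <- data.frame(
    sample_id = sprintf("S%02d", seq_len(cfg$nSamples)),
    depth_m = round(62.87 - (years - cfg$recordStart) / span *
                      (62.87 - 26.55), 2),
    year_ce = round(years, 1),
    enrichment_factor = round(stats::rnorm(cfg$nSamples, 92, 3), 1))
  years <- samples$year_ce

  ## ---- molecule population ----
  classes <- rep(names(cfg$classProportions),
                 .allocate(cfg$nMolecules, cfg$classProportions))
  clusters <- unlist(lapply(names(cfg$classProportions), function(cl) {
    n <- sum(classes == cl)
    rep(colnames(CLUSTER_MIX), .allocate(n, CLUSTER_MIX[cl, ]))
  }))
  nM <- length(classes)
  ids <- sprintf("M%04d", seq_len(nM))
  forms <- mapply(.sampleFormula, classes, clusters)
  names(forms) <- ids

  ## ---- deterministic temporal templates ----
  onsetOf <- function(cl) if (cl == "CHNOS") cfg$onsetCHNOS else cfg$onset1B
  ramp <- pmax(0, (years - cfg$rampStart1A) /
                    (cfg$recordEnd - cfg$rampStart1A))
  tfrac <- (years - cfg$recordStart) / span
  A <- stats::rlnorm(nM, meanlog = 0, sdlog = 1.0)
  slopeJit <- stats::runif(nM, 0.7, 1.3)   # natural decline heterogeneity
  rampJit <- stats::runif(nM, 0.8, 1.2)    # ramp heterogeneity

  # cluster-1A ramp amplitude: closed-form so the intensity-weighted 1A
  # aggregate has the target post/pre fold around onset1B
  i1A <- clusters == "1A"
  uBar <- sum(A[i1A] * rampJit[i1A]) / sum(A[i1A])
  pre <- years < cfg$onset1B
  rPre <- mean(ramp[pre]); rPost <- mean(ramp[!pre])
  f <- cfg$fold1A
  denom <- uBar * (rPost - f * rPre)
  if (denom <= 0) stop("infeasible cluster-1A fold for this ramp geometry")
  aAmp <- (f - 1) / denom

  template <- matrix(0, nM, cfg$nSamples, dimnames = list(ids, samples$sample_id))
  for (i in seq_len(nM)) {
    template[i, ] <- switch(clusters[i],
      "2"  = A[i] * (1 + cfg$naturalTrend * slopeJit[i] * tfrac),
      "1A" = A[i] * (1 + aAmp * rampJit[i] * ramp),
      "1B" = A[i] * as.numeric(years >= onsetOf(classes[i])))
  }
  if (any(template < 0)) stop("infeasible natural trend: negative template")

  ## ---- within-class cluster intensity balance (pre-onset 1A:2 = 41:57.5,
  ##      1B post-onset at 5% of the class) ----
  for (cl in unique(classes)) {
    m <- classes == cl
    on <- onsetOf(cl)
    preW <- years < on
    s1A <- sum(template[m & i1A, preW, drop = FALSE])
    s2  <- sum(template[m & clusters == "2", preW, drop = FALSE])
    if (s1A > 0 && s2 > 0) {
      sc <- (41 / 57.5) * s2 / s1A
      template[m & i1A, ] <- template[m & i1A, , drop = FALSE] * sc
    }
    i1Bm <- m & clusters == "1B"
    post12 <- sum(template[m & !i1Bm, !preW, drop = FALSE])
    s1B <- sum(template[i1Bm, !preW, drop = FALSE])
    if (s1B > 0 && post12 > 0)
      template[i1Bm, ] <- template[i1Bm, , drop = FALSE] * 0.05 * post12 / s1B
  }

  ## ---- class-aggregate step multipliers (exact template folds) ----
  stepYear <- rep(NA_real_, nM)
  for (cl in c("CHNO", "CHNOS")) {
    on <- if (cl == "CHNO") cfg$onsetCHNO else cfg$onsetCHNOS
    fTar <- if (cl == "CHNO") cfg$foldCHNO else cfg$foldCHNOS
    m <- classes == cl
    anth <- m & clusters != "2"
    preW <- years < on
    preAll <- mean(colSums(template[m, preW, drop = FALSE]))
    post2 <- mean(colSums(template[m & clusters == "2", !preW, drop = FALSE]))
    post1 <- mean(colSums(template[anth, !preW, drop = FALSE]))
    u <- (fTar * preAll - post2) / post1
    if (!is.finite(u) || u <= 0)
      stop("infeasible class fold for ", cl)
    template[anth, !preW] <- template[anth, !preW, drop = FALSE] * u
    stepYear[anth] <- on
  }

  ## ---- class intensity shares (one-pass exact) ----
  shares <- .classIntensityShares(cfg$choIntensityShare)
  tot <- vapply(names(shares), function(cl) {
    sum(template[classes == cl, , drop = FALSE])
  }, numeric(1))
  for (cl in names(shares)) {
    template[classes == cl, ] <- template[classes == cl, , drop = FALSE] *
      (shares[[cl]] / (tot[[cl]] / sum(tot)))
  }

  ## ---- global scale: every true profile clears the QC intensity floor ----
  maxT <- apply(template, 1, max)
  template <- template * (4 * 5e6 / min(maxT))

  ## ---- truth (template-level planted values) ----
  cls <- stats::setNames(clusters, ids)
  fold1Areal <- {
    agg <- colSums(template[i1A, , drop = FALSE])
    mean(agg[!pre]) / mean(agg[pre])
  }
  truth <- list(
    labels = cls,
    classes = stats::setNames(classes, ids),
    classCounts = table(factor(classes, levels = names(cfg$classProportions))),
    onsets = c(CHNO = cfg$onsetCHNO, CHNOS = cfg$onsetCHNOS,
               `1B` = cfg$onset1B),
    folds = c(CHNO = cfg$foldCHNO, CHNOS = cfg$foldCHNOS,
              `1A` = fold1Areal),
    choShare = 100 * cfg$choIntensityShare,
    proxyCoupling = cfg$proxyCoupling,
    rejects = character(0))

  ## ---- noise ----
  sdlog <- sqrt(log(1 + cfg$noiseCV^2))
  noise <- matrix(stats::rlnorm(nM * cfg$nSamples, -sdlog^2 / 2, sdlog),
                  nM, cfg$nSamples)
  intens <- template * noise

  ## ---- proxies: exact-correlation construction on the 5-yr bin grid ----
  binGrid <- seq(cfg$recordStart, cfg$recordEnd, by = 5)
  binIdx <- findInterval(years, binGrid)
  anthAgg <- colSums(template[clusters != "2", , drop = FALSE])
  sig <- vapply(seq_along(binGrid), function(j) {
    sel <- binIdx == j
    if (any(sel)) mean(anthAgg[sel]) else NA_real_
  }, numeric(1))
  sig[is.na(sig)] <- stats::approx(binGrid[!is.na(sig)], sig[!is.na(sig)],
                                   binGrid[is.na(sig)], rule = 2)$y
  sigZ <- as.numeric(scale(sig))
  mkProxy <- function(r, base, amp) {
    e <- stats::rnorm(length(sigZ))
    eres <- stats::residuals(stats::lm(e ~ sigZ))
    lam <- stats::sd(sigZ) / stats::sd(eres) * sqrt(1 / r^2 - 1)
    z <- sigZ + lam * eres
    data.frame(year = binGrid, value = base + amp * z / stats::sd(z))
  }
  proxies <- list(
    nitrate = mkProxy(cfg$proxyCoupling[["nitrate"]], 120, 45),
    sulfate = mkProxy(cfg$proxyCoupling[["sulfate"]], 250, 90),
    ozone   = mkProxy(cfg$proxyCoupling[["ozone"]], 32, 5),
    OH      = data.frame(year = binGrid,
                         value = 9e5 * (1 + 0.01 * (binGrid >= 1930) *
                                          (binGrid - 1930) / 50) *
                           (1 + stats::rnorm(length(binGrid), 0, 0.003))))

  ## ---- per-profile QC fields (all true profiles pass) ----
  maxI <- apply(intens, 1, max)
  rowdat <- data.frame(
    mz = round(vapply(forms, .mzFromFormula, numeric(1)), 5),
    rt = round(stats::runif(nM, 1, 14), 2),
    formula = unname(forms),
    peak_rating = round(stats::runif(nM, 7.5, 10), 1),
    group_cv = round(stats::runif(nM, 2, 12), 1),
    is_background = FALSE,
    blank_max = cfg$blankLevel * maxI / 3,   # sample/blank ratio >> 3
    row.names = ids, stringsAsFactors = FALSE)

  ## ---- reject profiles: one violated predicate each ----
  if (cfg$nRejects > 0) {
    kinds <- rep(c("background", "rating", "cv", "formula", "intensity",
                   "blank"), length.out = cfg$nRejects)
    rid <- sprintf("R%03d", seq_len(cfg$nRejects))
    rInt <- matrix(stats::rlnorm(cfg$nRejects * cfg$nSamples,
                                 log(2e7), 0.5),
                   cfg$nRejects, cfg$nSamples,
                   dimnames = list(rid, samples$sample_id))
    rForms <- vapply(seq_len(cfg$nRejects), function(i)
      .sampleFormula("CHO", "2"), character(1))
    rd <- data.frame(
      mz = round(vapply(rForms, .mzFromFormula, numeric(1)), 5),
      rt = round(stats::runif(cfg$nRejects, 1, 14), 2),
      formula = rForms,
      peak_rating = round(stats::runif(cfg$nRejects, 7.5, 10), 1),
      group_cv = round(stats::runif(cfg$nRejects, 2, 12), 1),
      is_background = FALSE,
      blank_max = 0,
      row.names = rid, stringsAsFactors = FALSE)
    for (i in seq_len(cfg$nRejects)) {
      switch(kinds[i],
        background = { rd$is_background[i] <- TRUE },
        rating     = { rd$peak_rating[i] <- round(stats::runif(1, 3, 6.9), 1) },
        cv         = { rd$group_cv[i] <- round(stats::runif(1, 16, 40), 1) },
        formula    = { rd$formula[i] <- NA_character_ },
        intensity  = { rInt[i, ] <- rInt[i, ] * 1e5 / max(rInt[i, ]) },
        blank      = { rd$blank_max[i] <- max(rInt[i, ]) / 2 })
    }
    intens <- rbind(intens, rInt)
    rowdat <- rbind(rowdat, rd)
    truth$rejects <- rid
  }

  ## ---- identification artifacts for a handful of molecules ----
  nStd <- 5L; nLib <- 8L; nMs2 <- 12L
  pick <- sample(which(classes %in% c("CHO", "CHNO")), nMs2)
  ms2 <- lapply(pick, function(i) {
    M <- rowdat$mz[i] + PROTON_MASS
    nf <- sample(4:8, 1)
    mzs <- sort(stats::runif(nf, 40, M - 1))
    ints <- stats::runif(nf, 0.05, 1)
    cbind(mz = round(mzs, 4), intensity = round(100 * ints / max(ints), 1))
  })
  names(ms2) <- ids[pick]
  speclib <- lapply(seq_len(nLib), function(k) {
    list(name = sprintf("library-compound-%02d", k),
         formula = forms[[pick[k]]],
         peaks = ms2[[k]])
  })
  stdIdx <- pick[seq_len(nStd)]
  standards <- data.frame(
    name = sprintf("standard-%02d", seq_len(nStd)),
    formula = unname(forms[stdIdx]),
    rt_min = round(rowdat$rt[stdIdx] + stats::rnorm(nStd, 0, 0.02), 3))

  rownames(samples) <- samples$sample_id
  features <- NTSExperiment(intens, rowdat, samples,
                            metadata = list(generator = cfg))
  list(features = features, samples = samples, proxies = proxies,
       standards = standards, speclib = speclib, ms2 = ms2, truth = truth)
}

#' Write a synthetic dataset to a directory
#'
#' Emits `features.csv`, `samples.csv`, `standards.csv`, `library.msp`,
#' `proxies/<name>.csv` and `truth.json` in the formats the pipeline reads.
#'
#' @param sim output of [simulateIceCore()].
#' @param dir output directory (created if needed).
#' @return invisibly, `dir`.
#' @export
writeSyntheticData <- function(sim, dir) {
  dir.create(file.path(dir, "proxies"), recursive = TRUE, showWarnings = FALSE)
  writeFeatureTable(sim$features, file.path(dir, "features.csv"))
  writeSampleMeta(sim$samples, file.path(dir, "samples.csv"))
  utils::write.csv(sim$standards, file.path(dir, "standards.csv"),
                   row.names = FALSE)
  con <- file(file.path(dir, "library.msp"), "w")
  for (e in sim$speclib) {
    writeLines(c(sprintf("Name: %s", e$name),
                 sprintf("Formula: %s", e$formula),
                 sprintf("Num Peaks: %d", nrow(e$peaks)),
                 apply(e$peaks, 1, function(p) sprintf("%.4f %.1f", p[1], p[2])),
                 ""), con)
  }
  close(con)
  for (nm in names(sim$proxies))
    utils::write.csv(sim$proxies[[nm]],
                     file.path(dir, "proxies", paste0(nm, ".csv")),
                     row.names = FALSE)
  tr <- sim$truth
  tr$classCounts <- as.list(tr$classCounts)
  jsonlite::write_json(tr, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Score pipeline outputs against the planted truth
#'
#' Compares a [runPipeline()] report with the generator's planted structure:
#' adjusted Rand index of the cluster labels (top-level natural versus
#' anthropogenic, and the full 1A/1B/2 partition), change-point year errors
#' for the CHNO and CHNOS class aggregates, relative fold-change errors,
#' proxy-correlation errors and the CHO intensity-share error.
#'
#' @param report a [runPipeline()] report.
#' @param truth the `truth` element of [simulateIceCore()] output.
#' @return list of recovery metrics.
#' @export
recoveryReport <- function(report, truth) {
  est <- report$clusterLabels
  common <- intersect(names(est), names(truth$labels))
  tl <- truth$labels[common]; el <- est[common]
  top <- function(x) ifelse(x == "2", "2", "1")
  list(
    ariTop = mclust::adjustedRandIndex(top(tl), top(el)),
    ariFull = mclust::adjustedRandIndex(tl, el),
    cpErrorCHNO = report$classChangePoints[["CHNO"]]$year -
      truth$onsets[["CHNO"]],
    cpErrorCHNOS = report$classChangePoints[["CHNOS"]]$year -
      truth$onsets[["CHNOS"]],
    foldRelErrCHNO = abs(report$classFolds[["CHNO"]] /
                           truth$folds[["CHNO"]] - 1),
    foldRelErrCHNOS = abs(report$classFolds[["CHNOS"]] /
                            truth$folds[["CHNOS"]] - 1),
    proxyErrNitrate = abs(report$proxyCorrelations[["nitrate"]] -
                            truth$proxyCoupling[["nitrate"]]),
    choShareErr = abs(report$recordShare[["CHO"]] - truth$choShare))
}
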