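# Fixture builders and independent oracles shared across the test files.
# Everything is generated in code; no stored data.

# random chemically plausible formula (sometimes with halogens/exotics)
randomFormula <- function() {
  C <- sample(1:20, 1)
  N <- sample(0:2, 1, prob = c(0.6, 0.3, 0.1))
  O <- sample(0:10, 1)
  S <- sample(0:1, 1, prob = c(0.9, 0.1))
  Cl <- sample(0:1, 1, prob = c(0.95, 0.05))
  H <- sample(1:(2 * C + 2 + N), 1)
  ct <- c(C = C, H = H, N = N, O = O, S = S, Cl = Cl)
  formatFormula(ct[ct > 0])
}

# a small NTSExperiment built in code; all profiles pass the QC filter
makeToyExperiment <- function(nMol = 12, nSamp = 10, seed = 42,
                              years = NULL) {
  set.seed(seed)
  if (is.null(years)) years <- seq(1800, 1845, length.out = nSamp)
  ids <- sprintf("M%02d", seq_len(nMol))
  sam <- data.frame(
    sample_id = sprintf("S%02d", seq_len(nSamp)),
    depth_m = seq(60, 30, length.out = nSamp),
    year_ce = years,
    enrichment_factor = rep(92, nSamp))
  rownames(sam) <- sam$sample_id
  forms <- replicate(nMol, randomFormula())
  intens <- matrix(rlnorm(nMol * nSamp, log(2e7), 0.4), nMol, nSamp,
                   dimnames = list(ids, sam$sample_id))
  rd <- data.frame(
    mz = runif(nMol, 100, 400), rt = runif(nMol, 1, 14), formula = forms,
    peak_rating = runif(nMol, 8, 10), group_cv = runif(nMol, 2, 10),
    is_background = FALSE, blank_max = 0,
    row.names = ids, stringsAsFactors = FALSE)
  NTSExperiment(intens, rd, sam)
}

# brute-force homolog oracle: connected components of the graph joining
# formulas that differ by exactly j CH2 units (j >= 1)
bruteHomologGroups <- function(formulas, minMembers) {
  formulas <- unique(formulas)
  n <- length(formulas)
  ec <- elementCounts(formulas)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    dC <- ec[j, "C"] - ec[i, "C"]
    same <- all(ec[i, c("N", "O", "S", "X", "other")] ==
                  ec[j, c("N", "O", "S", "X", "other")])
    adj[i, j] <- same && dC != 0 && ec[j, "H"] - ec[i, "H"] == 2 * dC
  }
  comp <- rep(0L, n); cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s]) next
    cur <- cur + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (comp[v]) next
      comp[v] <- cur
      queue <- c(queue, which(adj[v, ] & comp == 0L))
    }
  }
  groups <- split(formulas, comp)
  groups <- groups[lengths(groups) >= minMembers]
  # canonical form: sorted members, sorted groups
  unname(lapply(groups, sort))[order(vapply(lapply(groups, sort), paste,
                                            character(1), collapse = "|"))]
}

# brute-force single change point: explicit loop over all splits
bruteChangePoint <- function(v) {
  n <- length(v)
  sse <- vapply(1:(n - 1), function(j) {
    sum((v[1:j] - mean(v[1:j]))^2) + sum((v[(j + 1):n] - mean(v[(j + 1):n]))^2)
  }, numeric(1))
  best <- which.min(sse)
  list(index = best + 1L, sseDrop = sum((v - mean(v))^2) - sse[best])
}

# the hand-traced 4-row QC fixture: exactly one profile passes; the others
# fail (ii) rating, (vi) blank ratio and (v) max intensity respectively
makeFilterFixture <- function() {
  sam <- data.frame(sample_id = c("S1", "S2"), depth_m = c(50, 40),
                    year_ce = c(1900, 1950), enrichment_factor = c(92, 92))
  rownames(sam) <- sam$sample_id
  intens <- rbind(
    P1 = c(8e6, 1e7),    # passes everything
    P2 = c(8e6, 1e7),    # peak rating 6.5 < 7
    P3 = c(8e6, 1e7),    # blank 5e6 -> ratio 2 < 3
    P4 = c(1e6, 5e5))    # max intensity 1e6 < 5e6
  colnames(intens) <- sam$sample_id
  rd <- data.frame(
    mz = c(187.1, 201.2, 215.3, 229.4), rt = c(5, 6, 7, 8),
    formula = c("C4H6O4", "C5H8O4", "C6H10O4", "C7H12O4"),
    peak_rating = c(9, 6.5, 9, 9), group_cv = c(5, 5, 5, 5),
    is_background = FALSE, blank_max = c(0, 0, 5e6, 0),
    row.names = rownames(intens), stringsAsFactors = FALSE)
  NTSExperiment(intens, rd, sam)
}
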