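# Independent oracles, deliberately written without reusing package internals.

# Spreadsheet-style monoisotopic arithmetic: literal residue masses, plain
# cumulative sums. Used to cross-check the package's mass/fragment math.
oracleResidues <- c(
  K = 128.09496, S = 87.03203, T = 101.04768, G = 57.02146,
  A = 71.03711, P = 97.05276, R = 156.10111
)
ORACLE_WATER <- 18.0105646863
ORACLE_PROTON <- 1.00727646688
ORACLE_POY <- 56.026215
ORACLE_AC <- 42.010565
ORACLE_HEAVY_R <- 6 * 1.0033548378 + 4 * 0.9970349

# mods: named numeric vector position -> delta; heavy adds to last residue
oracleResidueVec <- function(seq, mods = numeric(), heavy = FALSE) {
  m <- unname(oracleResidues[strsplit(seq, "")[[1]]])
  if (length(mods)) m[as.integer(names(mods))] <- m[as.integer(names(mods))] + mods
  if (heavy) m[length(m)] <- m[length(m)] + ORACLE_HEAVY_R
  m
}

oracleNeutral <- function(seq, mods = numeric(), heavy = FALSE) {
  sum(oracleResidueVec(seq, mods, heavy)) + ORACLE_WATER
}

oracleFragment <- function(seq, mods, heavy, type, idx, charge = 1) {
  m <- oracleResidueVec(seq, mods, heavy)
  L <- length(m)
  raw <- if (type == "y") sum(rev(m)[1:idx]) + ORACLE_WATER
         else sum(m[1:idx])
  (raw + charge * ORACLE_PROTON) / charge
}

# All b and y singly charged fragments of a peptide, as a data.frame.
oracleAllFragments <- function(seq, mods, heavy = FALSE, charge = 1) {
  L <- nchar(seq)
  do.call(rbind, lapply(c("y", "b"), function(tp)
    data.frame(ion_type = tp, ion_index = 1:(L - 1),
               mz = vapply(1:(L - 1), function(i)
                 oracleFragment(seq, mods, heavy, tp, i, charge), 0))))
}

# Hand-coded Welch/Satterthwaite formulas.
oracleWelch <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- var(a); vb <- var(b)
  se2 <- va / na + vb / nb
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Reference implementation of the LLOQ/ULOQ contiguity rule: walk down from
# the ULOQ through the contiguous strictly-passing block, then extend one
# level if that level passes the relaxed LLOQ band.
oracleLloqUloq <- function(strict, loose) {
  if (!any(strict)) return(list(lloq = NA_integer_, uloq = NA_integer_))
  u <- max(which(strict))
  start <- u
  while (start > 1 && strict[start - 1]) start <- start - 1
  lloq <- if (start > 1 && loose[start - 1]) start - 1 else start
  list(lloq = lloq, uloq = u)
}

# Minimal CalibrationFit for unit tests that need a known line.
identityFit <- function(slope = 1, intercept = 0) {
  new("CalibrationFit", peptidePair = "test", slope = slope,
      intercept = intercept, rSquared = 1, levelsUsed = c(1, 10, 100),
      points = data.frame())
}

noiselessNoise <- function() {
  noiseModel(areaCv = 0, baselineSd = 0, blankAreaSd = 0, rtJitterSd = 0)
}
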