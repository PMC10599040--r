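#' Fit the reversed calibration curve
#'
#' Unweighted ordinary least squares of log10(heavy:light area ratio) on
#' log10(nominal heavy concentration), over the calibration injections of
#' one peptide pair. Blanks and QC injections are excluded from the fit.
#' Non-positive or flagged ratios at calibration levels are dropped with a
#' warning; fewer than three surviving levels is fatal. R-squared is the
#' squared Pearson correlation on the log-log points.
#'
#' @param ratios ratio table from [computeRatios()].
#' @param manifest run manifest (injection_id, role, nominal_conc, ...).
#' @param pair peptide pair to fit; default the first pair present.
#' @return a [CalibrationFit-class] object.
#' @export
fitReverseCalibration <- function(ratios, manifest, pair = NULL) {
  if (is.null(pair)) pair <- ratios$peptide_pair[1L]
  rr <- ratios[ratios$peptide_pair == pair, , drop = FALSE]
  rr <- merge(rr, manifest[, c("injection_id", "role", "nominal_conc")],
              by = "injection_id")
  rr <- rr[rr$role == "cal", , drop = FALSE]
  bad <- !is.finite(rr$heavy_to_light) | rr$heavy_to_light <= 0 | rr$flagged
  if (any(bad)) {
    warning(sprintf("%d calibration point(s) dropped (non-positive or flagged ratio)",
                    sum(bad)), call. = FALSE)
    rr <- rr[!bad, , drop = FALSE]
  }
  levels <- sort(unique(rr$nominal_conc))
  if (length(levels) < 3L)
    stop("fewer than 3 calibration levels with usable ratios", call. = FALSE)
  lx <- log10(rr$nominal_conc)
  ly <- log10(rr$heavy_to_light)
  fit <- stats::lm(ly ~ lx)
  co <- stats::coef(fit)
  r2 <- if (stats::var(ly) == 0) 1 else stats::cor(lx, ly)^2
  pts <- data.frame(injection_id = rr$injection_id,
                    nominal_conc = rr$nominal_conc,
                    ratio = rr$heavy_to_light,
                    log_conc = lx, log_ratio = ly,
                    residual = unname(stats::residuals(fit)),
                    stringsAsFactors = FALSE)
  new("CalibrationFit", peptidePair = pair,
      slope = unname(co[2L]), intercept = unname(co[1L]),
      rSquared = min(max(r2, 0), 1), levelsUsed = levels, points = pts)
}

#' Back-calculate concentration from a ratio
#'
#' Inverts the log-log calibration line:
#' conc = 10^((log10(ratio) - intercept) / slope). Non-positive ratios are
#' undefined and return `NA`.
#'
#' @param fit a [CalibrationFit-class].
#' @param ratio heavy:light area ratio(s).
#' @return concentration(s), fmol/uL.
#' @export
backCalculate <- function(fit, ratio) {
  out <- rep(NA_real_, length(ratio))
  ok <- is.finite(ratio) & ratio > 0
  out[ok] <- 10^((log10(ratio[ok]) - fit@intercept) / fit@slope)
  out
}

#' Per-level accuracy and precision
#'
#' For every calibration level: accuracy = mean back-calculated
#' concentration as a percentage of nominal; precision = percent CV of the
#' back-calculated replicates (sample SD, n-1). Pass flags follow the
#' acceptance bands: 85-115% of nominal in general, relaxed to 80-120% at
#' a candidate LLOQ level; CV must be below `cvMax` for either flag.
#'
#' @param fit a [CalibrationFit-class].
#' @param ratios ratio table from [computeRatios()].
#' @param manifest run manifest.
#' @param cvMax CV threshold in percent (default 20).
#' @param accStrict,accLloq accuracy bands in percent.
#' @return data.frame per level: nominal_conc, n, mean_backcalc,
#'   accuracy_pct, precision_cv, pass_strict, pass_lloq.
#' @export
accuracyPrecision <- function(fit, ratios, manifest, cvMax = 20,
                              accStrict = c(85, 115), accLloq = c(80, 120)) {
  rr <- ratios[ratios$peptide_pair == fit@peptidePair, , drop = FALSE]
  rr <- merge(rr, manifest[, c("injection_id", "role", "nominal_conc")],
              by = "injection_id")
  rr <- rr[rr$role == "cal", , drop = FALSE]
  rr$backcalc <- backCalculate(fit, rr$heavy_to_light)
  out <- do.call(rbind, lapply(split(rr, rr$nominal_conc), function(g) {
    bc <- g$backcalc[is.finite(g$backcalc)]
    n <- length(bc)
    mn <- mean(bc)
    acc <- 100 * mn / g$nominal_conc[1L]
    cv <- if (n >= 2L) 100 * stats::sd(bc) / mn else NA_real_
    data.frame(nominal_conc = g$nominal_conc[1L], n = n,
               mean_backcalc = mn, accuracy_pct = acc, precision_cv = cv,
               pass_strict = is.finite(cv) && cv < cvMax &&
                 acc >= accStrict[1L] && acc <= accStrict[2L],
               pass_lloq = is.finite(cv) && cv < cvMax &&
                 acc >= accLloq[1L] && acc <= accLloq[2L],
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$nominal_conc), ]
  rownames(out) <- NULL
  out
}

#' Estimate the lower limit of detection
#'
#' LLOD signal = mean(blank) + 3 x SD(blank) (sample SD), computed on the
#' blank injections' heavy:light ratios (or any signal on the calibration
#' axis); `rule = "3sd"` uses 3 x SD alone. When a calibration fit is
#' supplied the LLOD signal is converted to a concentration through the
#' curve; otherwise the signal itself is returned. All-zero blanks give 0.
#'
#' @param blankSignals numeric vector of blank signals (>= 3 required).
#' @param fit optional [CalibrationFit-class] for conversion to fmol/uL.
#' @param rule `"mean_plus_3sd"` (default) or `"3sd"`.
#' @return LLOD as a concentration (with `fit`) or on the signal scale.
#' @export
estimateLlod <- function(blankSignals, fit = NULL,
                         rule = c("mean_plus_3sd", "3sd")) {
  rule <- match.arg(rule)
  blankSignals <- blankSignals[is.finite(blankSignals)]
  if (length(blankSignals) < 3L)
    stop("at least 3 blank injections are required", call. = FALSE)
  sig <- switch(rule,
    mean_plus_3sd = mean(blankSignals) + 3 * stats::sd(blankSignals),
    `3sd` = 3 * stats::sd(blankSignals))
  if (sig <= 0) return(0)
  if (is.null(fit)) sig else backCalculate(fit, sig)
}

#' Determine LLOQ, ULOQ and the linear range
#'
#' ULOQ is the highest level passing the strict criteria (accuracy
#' 85-115%, CV < 20%). The LLOQ is the lowest level that itself passes the
#' relaxed LLOQ band (accuracy 80-120%, CV < 20%) such that every level
#' between it and the ULOQ passes strictly — the linear range must be
#' contiguous. With a non-contiguous pass pattern the LLOQ lands above the
#' last interior failure and a warning is issued. No passing level flags
#' the assay as failed.
#'
#' @param apTable per-level table from [accuracyPrecision()].
#' @return list: `lloq`, `uloq`, `linear_range` (length-2), `pass`
#'   (logical), `contiguous` (logical).
#' @export
determineLloqUloq <- function(apTable) {
  ap <- apTable[order(apTable$nominal_conc), , drop = FALSE]
  strict <- ap$pass_strict
  loose <- ap$pass_lloq
  if (!any(strict))
    return(list(lloq = NA_real_, uloq = NA_real_,
                linear_range = c(NA_real_, NA_real_),
                pass = FALSE, contiguous = NA))
  u <- max(which(strict))
  lloqIdx <- NA_integer_
  for (l in seq_len(u)) {
    interiorOk <- l == u || all(strict[(l + 1L):u])
    if (loose[l] && interiorOk) { lloqIdx <- l; break }
  }
  if (is.na(lloqIdx))
    return(list(lloq = NA_real_, uloq = ap$nominal_conc[u],
                linear_range = c(NA_real_, NA_real_),
                pass = FALSE, contiguous = NA))
  skipped <- any(!strict[seq_len(u)] & seq_len(u) < lloqIdx)
  if (skipped)
    warning("non-contiguous pass pattern; LLOQ set above the last interior failure",
            call. = FALSE)
  list(lloq = ap$nominal_conc[lloqIdx], uloq = ap$nominal_conc[u],
       linear_range = c(ap$nominal_conc[lloqIdx], ap$nominal_conc[u]),
       pass = TRUE, contiguous = !skipped)
}

#' Transition-ratio specificity QC
#'
#' Normalizes each transition's peak area to the analyte's total area per
#' injection (percentage peak areas), builds a reference profile as the
#' mean percentage per transition over calibration standards at or above
#' the LLOQ, and flags any injection whose transition deviates from the
#' reference by more than `threshold` percent (relative). Injections with
#' zero total area are excluded with a warning.
#'
#' @param peaks long peak table.
#' @param manifest run manifest.
#' @param peptide analyte peptide name (one `peptide_name` of `peaks`).
#' @param lloq LLOQ concentration; standards below it are not used for the
#'   reference profile.
#' @param threshold relative deviation threshold in percent (default 30).
#' @param includeRoles roles whose injections are checked (default
#'   calibration, QC and donor samples).
#' @return list: `reference` (named mean percentages), `table`
#'   (injection_id, transition_label, pct_area, deviation_pct, flag),
#'   `flagged` (injection ids with any flag).
#' @export
transitionRatioQc <- function(peaks, manifest, peptide, lloq = 0,
                              threshold = 30,
                              includeRoles = c("cal", "qc", "donor")) {
  pk <- peaks[peaks$peptide_name == peptide, , drop = FALSE]
  if (!nrow(pk)) stop("no rows for peptide ", peptide, call. = FALSE)
  pk <- merge(pk, manifest[, c("injection_id", "role", "nominal_conc")],
              by = "injection_id")
  tot <- tapply(pk$area, pk$injection_id, sum)
  zero <- names(tot)[tot <= 0]
  if (length(zero)) {
    warning(sprintf("%d injection(s) with zero total area excluded",
                    length(zero)), call. = FALSE)
    pk <- pk[!pk$injection_id %in% zero, , drop = FALSE]
    tot <- tot[!names(tot) %in% zero]
  }
  pk$pct_area <- 100 * pk$area / tot[pk$injection_id]
  refRows <- pk$role == "cal" & pk$nominal_conc >= lloq
  if (!any(refRows))
    stop("no calibration standards at or above the LLOQ for the reference profile",
         call. = FALSE)
  reference <- tapply(pk$pct_area[refRows], pk$transition_label[refRows], mean)
  chk <- pk[pk$role %in% includeRoles, , drop = FALSE]
  chk$deviation_pct <- 100 * abs(chk$pct_area -
                                 reference[chk$transition_label]) /
                       reference[chk$transition_label]
  chk$flag <- chk$deviation_pct > threshold
  tab <- chk[, c("injection_id", "transition_label", "pct_area",
                 "deviation_pct", "flag")]
  rownames(tab) <- NULL
  list(reference = reference, table = tab,
       flagged = unique(tab$injection_id[tab$flag]))
}

#' Selectivity check on matrix blanks
#'
#' Automated surrogate for visual blank inspection: a transition fails
#' when the blank's signal in the analyte retention-time region exceeds
#' the LLOD signal. Operates on blank peak-table rows (fast path) whose
#' areas are compared directly against `llodSignal` on the same scale.
#'
#' @param blankPeaks peak-table rows of blank injections for the analyte.
#' @param llodSignal LLOD on the area (signal) scale.
#' @return data.frame per blank injection x transition: injection_id,
#'   transition_label, area, pass.
#' @export
selectivityCheck <- function(blankPeaks, llodSignal) {
  out <- data.frame(injection_id = blankPeaks$injection_id,
                    transition_label = blankPeaks$transition_label,
                    area = blankPeaks$area,
                    pass = blankPeaks$area <= llodSignal,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Full validation report for one peptide pair
#'
#' Runs the calibration fit, accuracy/precision tables, LLOD (from blank
#' heavy:light ratios through the curve), LLOQ/ULOQ determination and
#' transition-ratio QC, assembling the assay's figures of merit.
#'
#' @param peaks long peak table of the calibration experiment.
#' @param manifest run manifest.
#' @param pair light peptide name of the pair to validate.
#' @param heavySuffix suffix of the heavy partner.
#' @param llodRule passed to [estimateLlod()].
#' @return list: `fit` ([CalibrationFit-class]), `accuracy_precision`
#'   (per-level table), `llod`, `lloq`, `uloq`, `linear_range`,
#'   `r_squared`, `transition_qc`.
#' @export
validationReport <- function(peaks, manifest, pair = "K9[Poy]K14[Ac]",
                             heavySuffix = "-heavy",
                             llodRule = "mean_plus_3sd") {
  ratios <- computeRatios(peaks, heavySuffix = heavySuffix)
  fit <- fitReverseCalibration(ratios, manifest, pair = pair)
  ap <- accuracyPrecision(fit, ratios, manifest)
  lim <- determineLloqUloq(ap)
  blankIds <- manifest$injection_id[manifest$role == "blank"]
  blanks <- ratios[ratios$injection_id %in% blankIds &
                   ratios$peptide_pair == pair, , drop = FALSE]
  llod <- if (nrow(blanks) >= 3L)
    estimateLlod(blanks$heavy_to_light, fit, rule = llodRule)
  else NA_real_
  qc <- transitionRatioQc(peaks, manifest, paste0(pair, heavySuffix),
                          lloq = if (lim$pass) lim$lloq else 0)
  list(fit = fit, accuracy_precision = ap, llod = llod,
       lloq = lim$lloq, uloq = lim$uloq, linear_range = lim$linear_range,
       r_squared = fit@rSquared, transition_qc = qc)
}
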