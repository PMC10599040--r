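#' Assay design parameters
#'
#' Describes the sample roles the assay uses: a reversed calibration ladder
#' of heavy-standard concentrations spiked into matrix carrying a constant
#' light internal standard, matrix blanks, a QC level, and donor samples
#' spiked with heavy standard at a fixed concentration. Defaults are the
#' validated assay's conditions: seven levels 0.5-2500 fmol/uL in five
#' replicates, nine blanks, QC at 12.5 fmol/uL, 100 fmol light internal
#' standard, and a 50 fmol/uL heavy spike in donor samples.
#'
#' @param calibrationLevels strictly increasing heavy concentrations (fmol/uL).
#' @param replicatesPerLevel injections per calibration level.
#' @param blankReplicates matrix-blank injections.
#' @param qcLevel QC concentration (fmol/uL).
#' @param lightIsAmount constant light internal-standard amount (fmol) in
#'   calibration runs.
#' @param heavySpikeDonor heavy-standard concentration (fmol/uL) in donor runs.
#' @param injectionVolume injected volume (uL); with the 1 uL default the
#'   light internal standard is equivalent to `lightIsAmount` fmol/uL.
#'
#' @return validated list of class `"AssayDesign"`.
#' @export
assayDesign <- function(calibrationLevels = c(0.5, 1.25, 5, 50, 500, 1250, 2500),
                        replicatesPerLevel = 5L,
                        blankReplicates = 9L,
                        qcLevel = 12.5,
                        lightIsAmount = 100,
                        heavySpikeDonor = 50,
                        injectionVolume = 1) {
  stopifnot(all(calibrationLevels > 0),
            !is.unsorted(calibrationLevels, strictly = TRUE),
            replicatesPerLevel >= 1, blankReplicates >= 0,
            qcLevel >= 0, lightIsAmount > 0, heavySpikeDonor > 0,
            injectionVolume > 0)
  structure(list(calibrationLevels = calibrationLevels,
                 replicatesPerLevel = as.integer(replicatesPerLevel),
                 blankReplicates = as.integer(blankReplicates),
                 qcLevel = qcLevel,
                 lightIsAmount = lightIsAmount,
                 heavySpikeDonor = heavySpikeDonor,
                 injectionVolume = injectionVolume),
            class = "AssayDesign")
}

#' Measurement noise model
#'
#' Peak areas carry multiplicative lognormal noise, the standard model for
#' MS intensity data; the lognormal is parameterized to have mean exactly 1
#' (\eqn{\sigma^2 = \log(1 + cv^2)}, \eqn{\mu = -\sigma^2/2}) so that
#' estimators stay unbiased in expectation. A peptide-level area is split
#' across transitions by fixed fractions, then each transition receives
#' independent lognormal noise at half the peptide-level CV, giving
#' transition-ratio QC realistic structure. Chromatographic peaks are
#' Gaussian with jittered retention time and additive baseline noise.
#'
#' @param areaCv fractional CV of peptide-level area noise (default 0.05,
#'   matching the assay's reported precision envelope of a few percent).
#' @param baselineSd additive baseline noise SD (intensity units) for
#'   simulated traces.
#' @param blankAreaSd SD (area units) of residual blank signal in the fast
#'   peak-table path; default 50 places blank-derived detection limits at
#'   the ~0.1-0.2 fmol/uL order with the default response.
#' @param rtMean,rtJitterSd,peakSigma retention-time mean, per-injection
#'   jitter SD, and Gaussian peak width, all minutes.
#' @param transitionFractions named fractions of peptide area per
#'   transition; must sum to 1.
#' @param samplingInterval trace sampling interval (minutes).
#'
#' @return validated list of class `"NoiseModel"`.
#' @export
noiseModel <- function(areaCv = 0.05,
                       baselineSd = 0,
                       blankAreaSd = 50,
                       rtMean = 15,
                       rtJitterSd = 0.02,
                       peakSigma = 0.05,
                       transitionFractions = c(y7 = 0.45, y8 = 0.30, y6 = 0.25),
                       samplingInterval = 0.005) {
  stopifnot(areaCv >= 0, baselineSd >= 0, blankAreaSd >= 0,
            peakSigma > 0, samplingInterval > 0,
            abs(sum(transitionFractions) - 1) <= 1e-9)
  structure(list(areaCv = areaCv, baselineSd = baselineSd,
                 blankAreaSd = blankAreaSd, rtMean = rtMean,
                 rtJitterSd = rtJitterSd, peakSigma = peakSigma,
                 transitionFractions = transitionFractions,
                 samplingInterval = samplingInterval),
            class = "NoiseModel")
}

#' Mean-one lognormal deviates
#'
#' Multiplicative noise factors with E[X] = 1 and CV `cv`
#' (sdlog = sqrt(log(1 + cv^2)), meanlog = -sdlog^2/2). `cv = 0` returns
#' exact ones.
#'
#' @param n number of deviates
#' @param cv fractional coefficient of variation
#' @return numeric vector of length `n`
#' @export
rlnormMean1 <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  stats::rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2))
}

# One injection's transition areas for one peptide: peptide-level lognormal
# noise, split by fractions, independent half-CV noise per transition.
.transitionAreas <- function(trueArea, noise) {
  fr <- noise$transitionFractions
  realized <- trueArea * rlnormMean1(1L, noise$areaCv)
  realized * fr * rlnormMean1(length(fr), noise$areaCv / 2)
}

.blankAreas <- function(noise) {
  fr <- noise$transitionFractions
  abs(stats::rnorm(1L, 0, noise$blankAreaSd)) * fr *
    rlnormMean1(length(fr), noise$areaCv / 2)
}

#' Simulate one MRM chromatogram
#'
#' intensity(t) = realized_area x Normal density(t; rt, peakSigma) +
#' baseline noise, where realized_area = trueArea x lognormal(mean 1,
#' `areaCv`) and rt = rtMean + Normal(0, rtJitterSd). The grid spans
#' rt +/- 8 peak sigmas at `samplingInterval` spacing.
#'
#' @param trueArea non-negative true peak area (signal units x minutes).
#' @param noise a [noiseModel()].
#' @param seed optional integer seed for reproducibility.
#' @return data.frame with columns `time` (minutes) and `intensity`, with
#'   attributes `rt` (realized apex) and `realized_area`.
#' @export
simulateChromatogram <- function(trueArea, noise = noiseModel(), seed = NULL) {
  if (trueArea < 0) stop("true area must be non-negative", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  rt <- noise$rtMean + stats::rnorm(1L, 0, noise$rtJitterSd)
  area <- trueArea * rlnormMean1(1L, noise$areaCv)
  half <- 8 * noise$peakSigma
  tgrid <- seq(noise$rtMean - half, noise$rtMean + half,
               by = noise$samplingInterval)
  y <- area * stats::dnorm(tgrid, rt, noise$peakSigma)
  if (noise$baselineSd > 0)
    y <- y + stats::rnorm(length(tgrid), 0, noise$baselineSd)
  out <- data.frame(time = tgrid, intensity = y)
  attr(out, "rt") <- rt
  attr(out, "realized_area") <- area
  out
}

.peakRows <- function(injection_id, role, peptide_name, label_state,
                      areas, rt) {
  data.frame(injection_id = injection_id, sample_role = role,
             peptide_name = peptide_name, label_state = label_state,
             transition_label = names(areas), area = unname(areas),
             retention_time = rt, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Simulate the reversed calibration series
#'
#' Generates peak tables for the calibration design: at each level the
#' heavy peptide's true area is `response x level` and the light internal
#' standard's is `response x lightIsAmount / injectionVolume`, each with
#' independent multiplicative noise; matrix blanks carry baseline-only
#' heavy signal plus the normal light internal standard. QC injections are
#' generated at the design's QC level. All label states of one injection
#' share a retention time (co-elution of light and heavy).
#'
#' @param design an [assayDesign()].
#' @param noise a [noiseModel()].
#' @param response signal area units per fmol/uL (default 1000).
#' @param peptidePairs named character vector mapping light peptide name to
#'   heavy peptide name; default the two assay pairs.
#' @param seed integer seed (mandatory; recorded in the output attributes).
#'
#' @return list with `peaks` (long peak table: injection_id, sample_role,
#'   peptide_name, label_state, transition_label, area, retention_time) and
#'   `manifest` (injection_id, role, nominal_conc, donor_id, condition,
#'   replicate).
#' @export
simulateCalibrationSeries <- function(design = assayDesign(),
                                      noise = noiseModel(),
                                      response = 1000,
                                      peptidePairs = c(
                                        "K9[Poy]K14[Ac]"  = "K9[Poy]K14[Ac]-heavy",
                                        "K9[Poy]K14[Poy]" = "K9[Poy]K14[Poy]-heavy"),
                                      seed) {
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  stopifnot(response > 0)
  set.seed(seed)
  lightConc <- design$lightIsAmount / design$injectionVolume
  inj <- list(); man <- list(); k <- 0L
  addInjection <- function(id, role, conc, rep) {
    k <<- k + 1L
    rt <- noise$rtMean + stats::rnorm(1L, 0, noise$rtJitterSd)
    rows <- list()
    for (lp in names(peptidePairs)) {
      hv <- peptidePairs[[lp]]
      heavyAreas <- if (conc > 0) .transitionAreas(response * conc, noise)
                    else .blankAreas(noise)
      lightAreas <- .transitionAreas(response * lightConc, noise)
      rows[[length(rows) + 1L]] <- .peakRows(id, role, lp, "light",
                                             lightAreas, rt)
      rows[[length(rows) + 1L]] <- .peakRows(id, role, hv, "heavy",
                                             heavyAreas, rt)
    }
    inj[[k]] <<- do.call(rbind, rows)
    man[[k]] <<- data.frame(injection_id = id, role = role,
                            nominal_conc = conc, donor_id = NA_character_,
                            condition = NA_character_,
                            replicate = as.integer(rep),
                            stringsAsFactors = FALSE)
  }
  for (r in seq_len(design$blankReplicates))
    addInjection(sprintf("blank_r%02d", r), "blank", 0, r)
  for (lv in design$calibrationLevels)
    for (r in seq_len(design$replicatesPerLevel))
      addInjection(sprintf("cal_%g_r%d", lv, r), "cal", lv, r)
  for (r in seq_len(design$replicatesPerLevel))
    addInjection(sprintf("qc_r%d", r), "qc", design$qcLevel, r)
  peaks <- do.call(rbind, inj)
  manifest <- do.call(rbind, man)
  rownames(peaks) <- rownames(manifest) <- NULL
  attr(peaks, "seed") <- seed
  list(peaks = peaks, manifest = manifest)
}

#' Donor scenarios
#'
#' One row per donor x condition with the ground-truth K14Ac stoichiometry
#' (modified fraction) and the total concentration of the K14-containing
#' peptide (acetylated + propionylated forms). `defaultDonorScenarios()`
#' emulates the study's cohort structure: six donors in three conditions
#' (CIC, CIM, MIM) with three technical replicates, heterogeneous baseline
#' stoichiometries, three donors responding to Meth exposure with an
#' increase and three with a decrease.
#'
#' @param donorIds donor identifiers.
#' @param baseStoichiometry per-donor baseline (CIC) modified fraction.
#' @param totalPeptide per-donor total peptide concentration (fmol/uL).
#' @param technicalReplicates replicate injections per donor x condition.
#' @return data.frame with columns donor_id, condition, true_stoichiometry,
#'   total_peptide, technical_replicates.
#' @export
defaultDonorScenarios <- function(donorIds = paste0("D", 1:6),
                                  baseStoichiometry = seq(0.10, 0.35, length.out = 6),
                                  totalPeptide = seq(60, 160, length.out = 6),
                                  technicalReplicates = 3L) {
  n <- length(donorIds)
  up <- seq_len(n) <= ceiling(n / 2)
  fac <- rbind(CIC = rep(1, n),
               CIM = ifelse(up, 1.15, 0.95),
               MIM = ifelse(up, 1.40, 0.75))
  out <- do.call(rbind, lapply(c("CIC", "CIM", "MIM"), function(cond)
    data.frame(donor_id = donorIds, condition = cond,
               true_stoichiometry = pmin(baseStoichiometry * fac[cond, ], 0.99),
               total_peptide = totalPeptide,
               technical_replicates = as.integer(technicalReplicates),
               stringsAsFactors = FALSE)))
  out <- out[order(out$donor_id, out$condition), ]
  rownames(out) <- NULL
  out
}

#' Simulate donor samples
#'
#' For each donor x condition x technical replicate, generates the four
#' peptide signals: endogenous (light) acetylated peptide at
#' `true_stoichiometry x total_peptide`, endogenous propionylated
#' (unmodified) peptide at `(1 - true_stoichiometry) x total_peptide`, and
#' both heavy SIL standards at the design's donor spike concentration.
#' Noise is independent across peptides and replicates; light and heavy
#' co-elute within an injection.
#'
#' @param scenarios data.frame as from [defaultDonorScenarios()].
#' @param design an [assayDesign()].
#' @param noise a [noiseModel()].
#' @param response signal area units per fmol/uL.
#' @param seed integer seed (mandatory).
#'
#' @return list with `peaks`, `manifest` (donor_id / condition / replicate
#'   filled in, role `"donor"`), and `truth` (donor_id, condition,
#'   true_stoichiometry, total_peptide) for recovery tests.
#' @export
simulateDonorSamples <- function(scenarios = defaultDonorScenarios(),
                                 design = assayDesign(),
                                 noise = noiseModel(),
                                 response = 1000,
                                 seed) {
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  stopifnot(nrow(scenarios) > 0, response > 0,
            all(scenarios$true_stoichiometry > 0),
            all(scenarios$true_stoichiometry < 1),
            all(scenarios$total_peptide > 0))
  set.seed(seed)
  spike <- design$heavySpikeDonor
  inj <- list(); man <- list(); k <- 0L
  for (i in seq_len(nrow(scenarios))) {
    sc <- scenarios[i, ]
    concs <- c("K9[Poy]K14[Ac]"        = sc$true_stoichiometry * sc$total_peptide,
               "K9[Poy]K14[Ac]-heavy"  = spike,
               "K9[Poy]K14[Poy]"       = (1 - sc$true_stoichiometry) * sc$total_peptide,
               "K9[Poy]K14[Poy]-heavy" = spike)
    states <- c("light", "heavy", "light", "heavy")
    for (r in seq_len(sc$technical_replicates)) {
      k <- k + 1L
      id <- sprintf("%s_%s_r%d", sc$donor_id, sc$condition, r)
      rt <- noise$rtMean + stats::rnorm(1L, 0, noise$rtJitterSd)
      rows <- lapply(seq_along(concs), function(j)
        .peakRows(id, "donor", names(concs)[j], states[j],
                  .transitionAreas(response * concs[[j]], noise), rt))
      inj[[k]] <- do.call(rbind, rows)
      man[[k]] <- data.frame(injection_id = id, role = "donor",
                             nominal_conc = NA_real_,
                             donor_id = sc$donor_id,
                             condition = sc$condition,
                             replicate = r, stringsAsFactors = FALSE)
    }
  }
  peaks <- do.call(rbind, inj)
  manifest <- do.call(rbind, man)
  rownames(peaks) <- rownames(manifest) <- NULL
  attr(peaks, "seed") <- seed
  truth <- scenarios[, c("donor_id", "condition", "true_stoichiometry",
                         "total_peptide")]
  rownames(truth) <- NULL
  list(peaks = peaks, manifest = manifest, truth = truth)
}
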