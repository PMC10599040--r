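#' Run the full assay pipeline on simulated data
#'
#' Convenience driver covering the complete workflow: simulate the
#' reversed calibration series and the donor samples, quantify summed
#' transition areas and light:heavy ratios, validate the assay (curve
#' fit, LLOD/LLOQ/ULOQ, accuracy/precision, transition-ratio QC), compute
#' absolute abundances and K14Ac stoichiometry, aggregate per donor and
#' per condition, and compare conditions at both the donor and cohort
#' level.
#'
#' @param scenarios donor scenarios ([defaultDonorScenarios()]).
#' @param design an [assayDesign()].
#' @param noise a [noiseModel()].
#' @param response signal area units per fmol/uL.
#' @param seed integer seed driving both simulations (the calibration
#'   simulation uses `seed`, the donor simulation `seed + 1`).
#'
#' @return list: `calibration` (peaks + manifest), `donors` (peaks,
#'   manifest, truth), `validation` (per-pair [validationReport()]s),
#'   `abundances`, `stoichiometry` (per injection),
#'   `aggregated` (donor and condition tiers), `comparisons` (donor- and
#'   cohort-level Welch tests).
#' @export
runPipeline <- function(scenarios = defaultDonorScenarios(),
                        design = assayDesign(),
                        noise = noiseModel(),
                        response = 1000,
                        seed) {
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  cal <- simulateCalibrationSeries(design, noise, response, seed = seed)
  don <- simulateDonorSamples(scenarios, design, noise, response,
                              seed = seed + 1L)
  validation <- lapply(c("K9[Poy]K14[Ac]", "K9[Poy]K14[Poy]"), function(p)
    validationReport(cal$peaks, cal$manifest, pair = p))
  names(validation) <- c("K9[Poy]K14[Ac]", "K9[Poy]K14[Poy]")
  ratios <- computeRatios(don$peaks)
  abundances <- absoluteAbundance(ratios, design$heavySpikeDonor,
                                  don$manifest)
  stoich <- stoichiometryTable(abundances)
  agg <- aggregateStoichiometry(stoich)
  comparisons <- list(
    donor = compareConditions(stoich, level = "donor"),
    cohort = compareConditions(agg$donor, level = "cohort")
  )
  list(calibration = cal, donors = don, validation = validation,
       abundances = abundances, stoichiometry = stoich,
       aggregated = agg, comparisons = comparisons)
}
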