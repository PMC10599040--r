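# ratios/manifest pair with known back-calculated concentrations under the
# identity line (slope 1, intercept 0): ratio == concentration
mkCal <- function(levels, ratiosByLevel) {
  man <- do.call(rbind, lapply(seq_along(levels), function(i)
    data.frame(injection_id = sprintf("c%d_%d", i, seq_along(ratiosByLevel[[i]])),
               role = "cal", nominal_conc = levels[i],
               donor_id = NA, condition = NA,
               replicate = seq_along(ratiosByLevel[[i]]))))
  rat <- data.frame(injection_id = man$injection_id,
                    sample_role = "cal", peptide_pair = "test",
                    light_to_heavy = 1 / unlist(ratiosByLevel),
                    heavy_to_light = unlist(ratiosByLevel),
                    flagged = FALSE)
  list(ratios = rat, manifest = man)
}

test_that("noiseless reverse calibration is exact at every figure of merit", {
  sim <- simulateCalibrationSeries(noise = noiselessNoise(), seed = 1)
  suppressWarnings(rep <- validationReport(sim$peaks, sim$manifest))
  expect_equal(calSlope(rep$fit), 1, tolerance = 1e-10)
  # intercept = -log10(light internal standard equivalent concentration)
  expect_equal(calIntercept(rep$fit), -log10(100), tolerance = 1e-10)
  expect_equal(rep$r_squared, 1, tolerance = 1e-12)
  expect_equal(rep$accuracy_precision$accuracy_pct, rep(100, 7),
               tolerance = 1e-10)
  expect_equal(rep$accuracy_precision$precision_cv, rep(0, 7),
               tolerance = 1e-10)
  expect_equal(rep$llod, 0)
  expect_equal(rep$lloq, 0.5)
  expect_equal(rep$uloq, 2500)
  expect_equal(rep$linear_range, c(0.5, 2500))
})

test_that("calibration fitting drops bad points and enforces level minimum", {
  cal <- mkCal(c(1, 10, 100), list(c(1, NA), c(10, 11), c(95, 105)))
  expect_warning(fit <- fitReverseCalibration(cal$ratios, cal$manifest),
                 "dropped")
  expect_s4_class(fit, "CalibrationFit")
  two <- mkCal(c(1, 10), list(1, 10))
  expect_error(suppressWarnings(
    fitReverseCalibration(two$ratios, two$manifest)), "fewer than 3")
})

test_that("back-calculation inverts the calibration line", {
  expect_equal(backCalculate(identityFit(), 50), 50)
  expect_true(is.na(backCalculate(identityFit(), -1)))
  # round trip through an arbitrary line: predict then back-calculate
  fit <- identityFit(slope = 0.93, intercept = -1.7)
  conc <- 10^runif(50, -1, 3.5)
  predicted <- 10^(fit@intercept + fit@slope * log10(conc))
  expect_equal(backCalculate(fit, predicted), conc, tolerance = 1e-9)
})

test_that("accuracy and precision match hand arithmetic", {
  cal <- mkCal(c(1, 10, 100), list(c(1, 1), c(10, 10), c(95, 100, 105)))
  ap <- accuracyPrecision(identityFit(), cal$ratios, cal$manifest)
  row <- ap[ap$nominal_conc == 100, ]
  expect_equal(row$accuracy_pct, 100)
  expect_equal(row$precision_cv, 5)   # sample SD of {95,100,105} is 5
  expect_true(all(ap$pass_strict))
})

test_that("LLOD follows the blank mean + 3 SD rule", {
  # {1,1,1,3}: mean 1.5, sample SD 1 -> signal 4.5
  expect_equal(estimateLlod(c(1, 1, 1, 3)), 4.5)
  expect_equal(estimateLlod(c(1, 1, 1, 3), identityFit()), 4.5)
  expect_equal(estimateLlod(c(1, 1, 1, 3), rule = "3sd"), 3)
  # linearity: scaling blank signals scales the LLOD signal
  expect_equal(estimateLlod(10 * c(1, 1, 1, 3)), 45)
  expect_equal(estimateLlod(c(0, 0, 0)), 0)
  expect_error(estimateLlod(c(1, 2)), "at least 3")
})

test_that("LLOQ/ULOQ rule agrees with the reference over all pass patterns", {
  levels <- c(0.5, 1.25, 5, 50, 500, 1250, 2500)
  mkAp <- function(states) {
    # states: 2 strict pass, 1 loose-only pass, 0 fail
    data.frame(nominal_conc = levels, n = 5,
               mean_backcalc = levels,
               accuracy_pct = c(150, 118, 100)[states + 1],
               precision_cv = 5,
               pass_strict = states == 2,
               pass_lloq = states >= 1)
  }
  grid <- expand.grid(rep(list(0:2), 7))
  for (i in seq_len(nrow(grid))) {
    states <- as.integer(grid[i, ])
    got <- suppressWarnings(determineLloqUloq(mkAp(states)))
    ref <- oracleLloqUloq(states == 2, states >= 1)
    if (is.na(ref$uloq)) {
      expect_false(got$pass)
    } else {
      expect_equal(got$uloq, levels[ref$uloq],
                   label = paste(states, collapse = ""))
      expect_equal(got$lloq, levels[ref$lloq],
                   label = paste(states, collapse = ""))
    }
  }
  # named examples: all pass; lowest level imprecise
  all2 <- suppressWarnings(determineLloqUloq(mkAp(rep(2L, 7))))
  expect_equal(all2$lloq, 0.5); expect_equal(all2$uloq, 2500)
  low <- suppressWarnings(determineLloqUloq(mkAp(c(0L, rep(2L, 6)))))
  expect_equal(low$lloq, 1.25)
  # non-contiguous pattern warns and lands above the interior failure
  expect_warning(nc <- determineLloqUloq(mkAp(c(2L, 2L, 0L, rep(2L, 4)))),
                 "non-contiguous")
  expect_equal(nc$lloq, 50)
})

test_that("precision envelope and linearity hold under the assay noise level", {
  sim <- simulateCalibrationSeries(noise = noiseModel(areaCv = 0.05),
                                   seed = 42)
  rep5 <- validationReport(sim$peaks, sim$manifest)
  # ratio of two 5%-CV lognormals has ~7.1% CV; 5-replicate estimates scatter
  expect_true(all(rep5$accuracy_precision$precision_cv < 15))
  expect_lt(median(rep5$accuracy_precision$precision_cv), 9)
  expect_equal(rep5$lloq, 0.5)
  # jackknife stability: dropping one replicate per level moves the fit little
  ratios <- computeRatios(sim$peaks)
  full <- fitReverseCalibration(ratios, sim$manifest, "K9[Poy]K14[Ac]")
  drop1 <- ratios[!grepl("_r1$", ratios$injection_id), ]
  jack <- fitReverseCalibration(drop1, sim$manifest, "K9[Poy]K14[Ac]")
  expect_lt(abs(calSlope(jack) - calSlope(full)), 0.02)
  expect_gt(calRSquared(jack), 0.999)
})

test_that("higher area noise never lowers the expected per-level CV", {
  meanCv <- function(cv) {
    mean(vapply(1:6, function(s) {
      sim <- simulateCalibrationSeries(noise = noiseModel(areaCv = cv),
                                       seed = 1000 + s)
      ratios <- computeRatios(sim$peaks)
      fit <- fitReverseCalibration(ratios, sim$manifest, "K9[Poy]K14[Ac]")
      mean(accuracyPrecision(fit, ratios, sim$manifest)$precision_cv)
    }, 0))
  }
  expect_gt(meanCv(0.08), meanCv(0.02))
})

test_that("figures of merit are deterministic given identical inputs", {
  sim <- simulateCalibrationSeries(seed = 8)
  a <- validationReport(sim$peaks, sim$manifest)
  b <- validationReport(sim$peaks, sim$manifest)
  expect_identical(a$accuracy_precision, b$accuracy_precision)
  expect_identical(a$llod, b$llod)
  expect_identical(calSlope(a$fit), calSlope(b$fit))
})

test_that("transition-ratio QC flags share perturbations, passes clean data", {
  sim <- simulateCalibrationSeries(noise = noiselessNoise(), seed = 4)
  qc <- suppressWarnings(
    transitionRatioQc(sim$peaks, sim$manifest, "K9[Poy]K14[Ac]-heavy",
                      lloq = 0.5))
  # identical fractions everywhere: zero deviation, no flags
  expect_equal(max(qc$table$deviation_pct), 0, tolerance = 1e-9)
  expect_length(qc$flagged, 0)
  # percentage areas sum to 100 per injection
  sums <- as.numeric(tapply(qc$table$pct_area, qc$table$injection_id, sum))
  expect_equal(sums, rep(100, length(sums)), tolerance = 1e-6)
  # doubling one transition's share in one injection trips the 30% rule
  pert <- sim$peaks
  sel <- pert$injection_id == "cal_50_r1" &
    pert$peptide_name == "K9[Poy]K14[Ac]-heavy" &
    pert$transition_label == "y6"
  pert$area[sel] <- pert$area[sel] * 4
  qc2 <- suppressWarnings(
    transitionRatioQc(pert, sim$manifest, "K9[Poy]K14[Ac]-heavy",
                      lloq = 0.5))
  expect_true("cal_50_r1" %in% qc2$flagged)
})

test_that("selectivity surrogate passes clean blanks and catches interference", {
  nn <- noiselessNoise()
  sim <- simulateCalibrationSeries(noise = nn, seed = 6)
  blanks <- sim$peaks[sim$peaks$sample_role == "blank" &
                      sim$peaks$label_state == "heavy" &
                      sim$peaks$peptide_name == "K9[Poy]K14[Ac]-heavy", ]
  res <- selectivityCheck(blanks, llodSignal = 10)
  expect_true(all(res$pass))
  # interference at the analyte retention time fails
  spiked <- blanks
  spiked$area[1] <- 1e4
  expect_false(all(selectivityCheck(spiked, llodSignal = 10)$pass))
  # interference eluting outside the analyte window integrates to ~0
  interf <- simulateChromatogram(5000, noiseModel(areaCv = 0, baselineSd = 0,
                                                  rtJitterSd = 0, rtMean = 18),
                                 seed = 1)
  win <- c(15 - 0.5, 15 + 0.5)
  full <- data.frame(time = seq(14, 19, by = 0.005), intensity = 0)
  full$intensity[match(round(interf$time, 3), round(full$time, 3))] <-
    interf$intensity
  area <- integratePeak(full, window = win, baselinePoints = 1)$area
  expect_lt(area, 10)
})
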