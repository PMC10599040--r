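peps <- studyPeptides()

test_that("neutral monoisotopic masses match hand summation and conventions", {
  # hand-summed oracle values for the derivatized peptide forms
  expect_equal(neutralMass(peps$lightAc), 998.550875, tolerance = 1e-8)
  expect_equal(neutralMass(peps$lightPoy),
               oracleNeutral("KSTGGKAPR", c("1" = ORACLE_POY, "6" = ORACLE_POY)),
               tolerance = 1e-9)
  expect_equal(neutralMass(peps$lightPoy), 1012.566525, tolerance = 1e-8)
  # single residue identity
  expect_equal(neutralMass(modifiedPeptide("G")), 57.02146 + 18.010565,
               tolerance = 1e-6)
  # reporting convention: neutral + one hydrogen atom, to 4 decimals
  expect_equal(mzRound(tableMass(peps$lightAc), 4), 999.5587)
  expect_equal(mzRound(tableMass(peps$heavyPoy), 4), 1023.5826)
  # the printed heavy-Ac and light-Poy masses disagree with their own
  # sequences in the last digit; computed values sit within 1.5e-4 of them
  expect_equal(tableMass(peps$heavyAc), 1009.5669, tolerance = 1.5e-7)
  expect_equal(tableMass(peps$lightPoy), 1013.5744, tolerance = 1.5e-7)
})

test_that("heavy label and acetyl/propionyl mass relationships hold", {
  expect_equal(neutralMass(peps$heavyAc) - neutralMass(peps$lightAc),
               10.008269, tolerance = 1e-5)
  expect_equal(neutralMass(peps$heavyPoy) - neutralMass(peps$lightPoy),
               10.008269, tolerance = 1e-5)
  expect_equal(neutralMass(peps$lightPoy) - neutralMass(peps$lightAc),
               56.026215 - 42.010565, tolerance = 1e-5)
})

test_that("precursor m/z matches the transition list and charge algebra", {
  expect_equal(mzRound(precursorMz(peps$lightAc, 2)), 500.3)
  expect_equal(mzRound(precursorMz(peps$heavyAc, 2)), 505.3)
  expect_equal(mzRound(precursorMz(peps$heavyPoy, 2)), 512.3)
  # m/z(+1) = 2 m/z(+2) - proton, for any peptide
  for (p in peps)
    expect_equal(precursorMz(p, 1), 2 * precursorMz(p, 2) - massConstants()$proton,
                 tolerance = 1e-9)
  expect_error(precursorMz(peps$lightAc, 0), "charge")
})

test_that("fragment m/z matches the transition list and the brute-force oracle", {
  expect_equal(mzRound(fragmentMz(peps$lightAc, "y", 7)), 728.4)
  expect_equal(mzRound(fragmentMz(peps$lightAc, "y", 8)), 815.4)
  expect_equal(mzRound(fragmentMz(peps$heavyAc, "y", 7)), 738.4)
  expect_equal(mzRound(fragmentMz(peps$heavyAc, "y", 8)), 825.4)
  expect_equal(mzRound(fragmentMz(peps$heavyPoy, "y", 7)), 752.4)
  expect_equal(mzRound(fragmentMz(peps$lightPoy, "y", 7)), 742.4)
  # y8 - y7 telescopes to the serine residue mass
  expect_equal(fragmentMz(peps$lightAc, "y", 8) - fragmentMz(peps$lightAc, "y", 7),
               87.03203, tolerance = 1e-6)
  # full cross-check against the independent summation oracle
  modsFor <- list(lightAc = c("1" = ORACLE_POY, "6" = ORACLE_AC),
                  heavyAc = c("1" = ORACLE_POY, "6" = ORACLE_AC),
                  lightPoy = c("1" = ORACLE_POY, "6" = ORACLE_POY),
                  heavyPoy = c("1" = ORACLE_POY, "6" = ORACLE_POY))
  for (nm in names(peps)) {
    hv <- isHeavy(peps[[nm]])
    for (tp in c("y", "b")) for (i in 1:8) for (z in 1:2)
      expect_equal(fragmentMz(peps[[nm]], tp, i, z),
                   oracleFragment("KSTGGKAPR", modsFor[[nm]], hv, tp, i, z),
                   tolerance = 1e-9,
                   label = sprintf("%s %s%d +%d", nm, tp, i, z))
  }
  expect_error(fragmentMz(peps$lightAc, "y", 9), "ion index")
})

test_that("fragment ladder differences equal the modified residue masses", {
  for (p in peps) {
    pmz <- vapply(1:8, function(i) fragmentMz(p, "y", i), 0)
    diffs <- diff(pmz)
    # y_n - y_{n-1} is the modified residue mass at position L - n + 1
    res <- strsplit(peptideSequence(p), "")[[1]]
    expected <- residueMasses()[rev(res)[2:8]]
    mods <- peptideModifications(p)
    for (j in seq_len(nrow(mods))) {
      k <- 9 - mods$position[j] + 1   # y index that first includes the mod
      if (k >= 2 && k <= 8) expected[k - 1] <- expected[k - 1] + mods$delta[j]
    }
    expect_equal(unname(diffs), unname(expected), tolerance = 1e-9)
  }
})

test_that("peptide construction rejects invalid input with informative errors", {
  expect_error(modifiedPeptide("KSTGGXAPR"), "X")
  expect_error(modifiedPeptide("KSTGGKAPR", "2:Ac"), "targets K")
  expect_error(modifiedPeptide("KSTGGKAPR", "12:Poy"), "bounds")
  expect_error(modifiedPeptide("KSTGGKAPK", heavy = TRUE), "arginine")
  expect_error(modifiedPeptide("KSTGGKAPR", "1:Foo"), "Foo")
})

test_that("isobaric overlap filter reproduces the brute-force enumeration", {
  target <- peps$lightAc
  isobar <- modifiedPeptide("KSTGGKAPR", "1:Ac;6:Poy",
                            displayName = "K9[Ac]K14[Poy]")
  cand <- data.frame(ion_type = "y", ion_index = 1:8)
  res <- isobaricOverlapFilter(target, isobar, cand)
  # brute force: enumerate the isobar's y series with the oracle and compare
  isoY <- oracleAllFragments("KSTGGKAPR", c("1" = ORACLE_AC, "6" = ORACLE_POY))
  isoY <- isoY[isoY$ion_type == "y", ]
  tgtY <- vapply(1:8, function(i)
    oracleFragment("KSTGGKAPR", c("1" = ORACLE_POY, "6" = ORACLE_AC),
                   FALSE, "y", i), 0)
  bruteExcluded <- which(vapply(tgtY, function(mz)
    any(abs(isoY$mz - mz) <= 0.25), TRUE))
  expect_equal(sort(res$excluded$ion_index), sort(bruteExcluded))
  expect_equal(res$excluded$ion_index, 1:3)
  expect_equal(res$retained$ion_index, 4:8)
  # the assay's chosen product ions all survive the screen
  expect_true(all(c(6, 7, 8) %in% res$retained$ion_index))
  # excluded y1-y3 are identical ions in both forms (delta 0)
  expect_equal(res$excluded$delta_mz, rep(0, 3), tolerance = 1e-9)
})

test_that("stricter b-series screen flags the y7/b7 near-coincidence", {
  isobar <- modifiedPeptide("KSTGGKAPR", "1:Ac;6:Poy")
  res <- isobaricOverlapFilter(peps$lightAc, isobar,
                               data.frame(ion_type = "y", ion_index = 1:8),
                               isobarIonTypes = c("y", "b"))
  ex7 <- res$excluded[res$excluded$ion_index == 7, ]
  expect_equal(nrow(ex7), 1)
  expect_equal(ex7$isobar_ion_type, "b")
  expect_lt(ex7$delta_mz, 0.05)
})

test_that("isobaric filter degenerate contracts hold", {
  # self-comparison: every candidate matches itself
  res <- isobaricOverlapFilter(peps$lightAc, peps$lightAc,
                               data.frame(ion_type = "y", ion_index = 1:8))
  expect_equal(nrow(res$retained), 0)
  expect_equal(nrow(res$excluded), 8)
  expect_error(
    isobaricOverlapFilter(peps$lightAc, modifiedPeptide("GAR"),
                          data.frame(ion_type = "y", ion_index = 1)),
    "unequal")
})

test_that("transition set builds in assay order and round-trips losslessly", {
  ts <- buildTransitionSet(peps)
  expect_equal(nrow(ts), 12)
  expect_equal(ts$transition_label, paste0("MRM", 1:12))
  expect_equal(ts$peptide_name[c(1, 4, 7, 10)],
               c("K9[Poy]K14[Ac]", "K9[Poy]K14[Ac]-heavy",
                 "K9[Poy]K14[Poy]", "K9[Poy]K14[Poy]-heavy"))
  expect_equal(ts$ion_index[1:3], c(7L, 8L, 6L))
  # printed transition-list values that are arithmetically consistent
  expect_equal(mzRound(ts$q1_mz[1:6]), rep(c(500.3, 505.3), each = 3))
  expect_equal(mzRound(ts$q1_mz[10:12]), rep(512.3, 3))
  expect_equal(mzRound(ts$q3_mz[c(1, 2, 4, 5, 10)]),
               c(728.4, 815.4, 738.4, 825.4, 752.4))
  # heavy - light Q1 difference is half the label delta at charge 2
  expect_equal(ts$q1_mz[4] - ts$q1_mz[1], heavyArgDelta() / 2,
               tolerance = 1e-9)
  # writer/loader round-trip preserves all fields bit-for-bit
  f <- withr::local_tempfile(fileext = ".tsv")
  writeTransitionList(ts, f)
  back <- readTransitionList(f)
  expect_identical(back$q1_mz, ts$q1_mz)
  expect_identical(back$q3_mz, ts$q3_mz)
  expect_identical(back[names(ts)], ts)
  # degenerate contracts
  expect_equal(nrow(buildTransitionSet(list())), 0)
  expect_error(
    buildTransitionSet(list(peps$lightAc, peps$lightAc)), "duplicate")
})

test_that("declared Q3 values are accepted, warned about, or rejected by distance", {
  ts <- buildTransitionSet(peps[1])
  expect_silent(checkDeclaredTransitions(ts))
  off <- ts; off$q3_mz[1] <- off$q3_mz[1] + 0.2
  expect_warning(res <- checkDeclaredTransitions(off), "within tolerance")
  expect_true(all(res$declared))
  expect_equal(res$q3_delta[1], 0.2, tolerance = 1e-9)
  bad <- ts; bad$q3_mz[2] <- bad$q3_mz[2] + 0.3
  expect_error(checkDeclaredTransitions(bad), "deviates")
})
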