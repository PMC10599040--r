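# Monoisotopic residue masses (Da) for the 20 standard amino acids.
.AA_MONO <- c(
  G =  57.02146, A =  71.03711, S =  87.03203, P =  97.05276,
  V =  99.06841, T = 101.04768, C = 103.00919, L = 113.08406,
  I = 113.08406, N = 114.04293, D = 115.02694, Q = 128.05858,
  K = 128.09496, E = 129.04259, M = 131.04049, H = 137.05891,
  F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

.MASS_WATER  <- 18.0105646863
.MASS_PROTON <- 1.00727646688
.MASS_HATOM  <- 1.00782503207
.C13_SHIFT   <- 1.0033548378   # 13C - 12C
.N15_SHIFT   <- 0.9970349      # 15N - 14N

# Chemical/PTM modifications known to the assay: propionyl (derivatization
# of free lysines) and acetyl (the PTM). Both target lysine side chains.
.MODS <- data.frame(
  name   = c("Poy", "Ac"),
  target = c("K", "K"),
  delta  = c(56.026215, 42.010565),
  stringsAsFactors = FALSE
)

#' Monoisotopic residue mass table
#'
#' @return named numeric vector of monoisotopic residue (not free amino
#'   acid) masses in Da for the 20 standard amino acids.
#' @examples
#' residueMasses()[["G"]]  # glycine residue, 57.02146 Da
#' @export
residueMasses <- function() .AA_MONO

#' Fundamental mass constants
#'
#' @return list with `water` (18.010565 Da), `proton` (1.007276 Da) and
#'   `hydrogen` (one hydrogen atom, 1.007825 Da), all monoisotopic.
#' @export
massConstants <- function() {
  list(water = .MASS_WATER, proton = .MASS_PROTON, hydrogen = .MASS_HATOM)
}

#' Modification registry
#'
#' Mass shifts of the modifications handled by the assay: propionyl
#' (`Poy`, +56.026215 Da, introduced chemically on unmodified lysines so
#' that modified and unmodified forms become the same tryptic peptide) and
#' acetyl (`Ac`, +42.010565 Da, the PTM quantified).
#'
#' @return data.frame with columns `name`, `target` (residue) and `delta` (Da).
#' @export
modificationTable <- function() .MODS

#' Heavy-label mass shift
#'
#' Mass added by the \eqn{^{13}C_6^{15}N_4} label on the C-terminal
#' arginine of the SIL standard peptides: 6 x (13C-12C) + 4 x (15N-14N)
#' = 10.008269 Da, i.e. a 5 m/z shift at charge +2.
#'
#' @return numeric scalar, Da.
#' @export
heavyArgDelta <- function() 6 * .C13_SHIFT + 4 * .N15_SHIFT

.parseModSpec <- function(spec) {
  if (is.null(spec) || !nzchar(spec))
    return(data.frame(position = integer(), name = character(),
                      stringsAsFactors = FALSE))
  parts <- strsplit(strsplit(spec, ";", fixed = TRUE)[[1L]], ":", fixed = TRUE)
  bad <- vapply(parts, length, 1L) != 2L
  if (any(bad))
    stop("malformed modification spec: ", spec, call. = FALSE)
  data.frame(
    position = as.integer(vapply(parts, `[`, "", 1L)),
    name     = vapply(parts, `[`, "", 2L),
    stringsAsFactors = FALSE
  )
}

#' Construct a ModifiedPeptide
#'
#' @param sequence one-letter amino-acid string, e.g. `"KSTGGKAPR"`.
#' @param modifications either a spec string `"position:name"` joined by
#'   `";"` (positions 1-based within the peptide, e.g. `"1:Poy;6:Ac"`), or a
#'   data.frame with columns `position` and `name`, or `NULL` for none.
#' @param heavy logical; apply the 13C6 15N4 label to the C-terminal
#'   arginine (fatal if the C-terminal residue is not R).
#' @param displayName optional name; defaults to the annotated sequence
#'   with a `-heavy` suffix when labeled.
#'
#' @return a validated [ModifiedPeptide-class] object.
#' @examples
#' p <- modifiedPeptide("KSTGGKAPR", "1:Poy;6:Ac")
#' neutralMass(p)
#' @export
modifiedPeptide <- function(sequence, modifications = NULL, heavy = FALSE,
                            displayName = NULL) {
  res <- strsplit(sequence, "")[[1L]]
  unknown <- setdiff(res, names(.AA_MONO))
  if (length(unknown))
    stop("unknown residue symbol(s): ", paste(unique(unknown), collapse = ", "),
         call. = FALSE)
  if (is.character(modifications))
    modifications <- .parseModSpec(modifications)
  if (is.null(modifications))
    modifications <- data.frame(position = integer(), name = character(),
                                stringsAsFactors = FALSE)
  idx <- match(modifications$name, .MODS$name)
  if (anyNA(idx))
    stop("unknown modification(s): ",
         paste(unique(modifications$name[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  modifications$delta <- .MODS$delta[idx]
  target <- .MODS$target[idx]
  if (nrow(modifications)) {
    if (any(modifications$position < 1L | modifications$position > length(res)))
      stop("modification position out of sequence bounds", call. = FALSE)
    at <- res[modifications$position]
    bad <- at != target
    if (any(bad))
      stop(sprintf("modification %s targets %s but residue at position %d is %s",
                   modifications$name[bad][1L], target[bad][1L],
                   modifications$position[bad][1L], at[bad][1L]),
           call. = FALSE)
  }
  modifications <- modifications[order(modifications$position),
                                 c("position", "name", "delta"), drop = FALSE]
  rownames(modifications) <- NULL
  obj <- new("ModifiedPeptide", sequence = sequence,
             modifications = modifications, heavy = isTRUE(heavy),
             displayName = "")
  obj@displayName <- if (is.null(displayName)) annotatedSequence(obj)
                     else displayName
  validObject(obj)
  obj
}

#' Annotated sequence string
#'
#' Renders a peptide with bracketed modification names, e.g.
#' `"K[Poy]STGGK[Ac]APR-heavy"`.
#'
#' @param peptide a [ModifiedPeptide-class]
#' @return character scalar.
#' @export
annotatedSequence <- function(peptide) {
  res <- strsplit(peptide@sequence, "")[[1L]]
  m <- peptide@modifications
  if (nrow(m))
    res[m$position] <- sprintf("%s[%s]", res[m$position], m$name)
  paste0(paste(res, collapse = ""), if (peptide@heavy) "-heavy" else "")
}

# Per-position residue masses including modifications and the heavy label.
.positionMasses <- function(peptide) {
  res <- strsplit(peptide@sequence, "")[[1L]]
  pm <- unname(.AA_MONO[res])
  m <- peptide@modifications
  if (nrow(m)) pm[m$position] <- pm[m$position] + m$delta
  if (peptide@heavy) pm[length(pm)] <- pm[length(pm)] + heavyArgDelta()
  pm
}

#' @rdname massOps
#' @export
setGeneric("neutralMass", function(peptide) standardGeneric("neutralMass"))
#' @rdname massOps
#' @export
setGeneric("tableMass", function(peptide) standardGeneric("tableMass"))
#' @rdname massOps
#' @export
setGeneric("precursorMz", function(peptide, charge = 2L)
  standardGeneric("precursorMz"))
#' @rdname massOps
#' @export
setGeneric("fragmentMz", function(peptide, ionType, ionIndex, charge = 1L)
  standardGeneric("fragmentMz"))

#' Peptide mass and m/z arithmetic
#'
#' `neutralMass()` returns the neutral monoisotopic mass: sum of modified
#' residue masses plus water plus the heavy-label shift when present.
#' `tableMass()` adds one hydrogen atom (1.007825 Da) on top of the neutral
#' mass — the reporting convention used by some assay documentation for
#' "calculated monoisotopic molecular mass"; the neutral mass remains the
#' canonical internal representation. `precursorMz()` is
#' (neutral + charge x proton) / charge. `fragmentMz()` gives y- or b-ion
#' m/z: y_n sums the n C-terminal modified residues plus water plus
#' charge x proton; b_n sums the n N-terminal modified residues plus
#' charge x proton; both divided by charge.
#'
#' @param peptide a [ModifiedPeptide-class]
#' @param charge positive integer charge state
#' @param ionType `"y"` or `"b"`
#' @param ionIndex integer in `[1, length(sequence) - 1]`
#' @return mass in Da (`neutralMass`, `tableMass`) or m/z at full internal
#'   precision (`precursorMz`, `fragmentMz`); use [mzRound()] for one-decimal
#'   display values.
#' @examples
#' p <- modifiedPeptide("KSTGGKAPR", "1:Poy;6:Ac")
#' mzRound(precursorMz(p, 2))      # 500.3
#' mzRound(fragmentMz(p, "y", 7))  # 728.4
#' @name massOps
NULL

#' @rdname massOps
#' @export
setMethod("neutralMass", "ModifiedPeptide", function(peptide) {
  sum(.positionMasses(peptide)) + .MASS_WATER
})

#' @rdname massOps
#' @export
setMethod("tableMass", "ModifiedPeptide", function(peptide) {
  neutralMass(peptide) + .MASS_HATOM
})

#' @rdname massOps
#' @export
setMethod("precursorMz", "ModifiedPeptide", function(peptide, charge = 2L) {
  if (length(charge) != 1L || is.na(charge) || charge < 1)
    stop("charge must be a positive integer", call. = FALSE)
  (neutralMass(peptide) + charge * .MASS_PROTON) / charge
})

#' @rdname massOps
#' @export
setMethod("fragmentMz", "ModifiedPeptide",
          function(peptide, ionType, ionIndex, charge = 1L) {
  ionType <- match.arg(ionType, c("y", "b"))
  L <- nchar(peptide@sequence)
  if (length(ionIndex) != 1L || is.na(ionIndex) ||
      ionIndex < 1L || ionIndex >= L)
    stop(sprintf("ion index must lie in [1, %d]", L - 1L), call. = FALSE)
  if (charge < 1) stop("charge must be a positive integer", call. = FALSE)
  pm <- .positionMasses(peptide)
  frag <- if (ionType == "y") sum(pm[(L - ionIndex + 1L):L]) + .MASS_WATER
          else sum(pm[seq_len(ionIndex)])
  (frag + charge * .MASS_PROTON) / charge
})

#' Display rounding for m/z values
#'
#' Rounds half away from zero (the convention of printed transition lists),
#' to one decimal by default. All internal math is done at full precision;
#' this is only for display and comparison against printed values.
#'
#' @param x numeric
#' @param digits decimal places (default 1)
#' @return rounded numeric
#' @export
mzRound <- function(x, digits = 1L) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' The four assay peptides
#'
#' Convenience constructor for the derivatized histone H3 9-17 peptide
#' KSTGGKAPR in its four assay forms: K9-propionyl/K14-acetyl (the PTM
#' form) and K9-propionyl/K14-propionyl (the unmodified form, lysines
#' blocked by derivatization only), each light (endogenous) and heavy
#' (SIL standard). Order matches the assay transition list (MRM1..MRM12).
#'
#' @return named list of four [ModifiedPeptide-class] objects:
#'   `lightAc`, `heavyAc`, `lightPoy`, `heavyPoy`.
#' @export
studyPeptides <- function() {
  seqKAPR <- "KSTGGKAPR"
  list(
    lightAc  = modifiedPeptide(seqKAPR, "1:Poy;6:Ac",
                               displayName = "K9[Poy]K14[Ac]"),
    heavyAc  = modifiedPeptide(seqKAPR, "1:Poy;6:Ac", heavy = TRUE,
                               displayName = "K9[Poy]K14[Ac]-heavy"),
    lightPoy = modifiedPeptide(seqKAPR, "1:Poy;6:Poy",
                               displayName = "K9[Poy]K14[Poy]"),
    heavyPoy = modifiedPeptide(seqKAPR, "1:Poy;6:Poy", heavy = TRUE,
                               displayName = "K9[Poy]K14[Poy]-heavy")
  )
}

#' Screen candidate transitions against an isobaric positional isomer
#'
#' The K9-acetyl/K14-propionyl positional isomer has exactly the same
#' neutral mass (and hence precursor m/z) as the K9-propionyl/K14-acetyl
#' target, so any product ion the two share cannot distinguish them. A
#' candidate ion of the target is excluded when a fragment of the isobar
#' (by default its y-ion series, the series used for quantification) lies
#' within `tolerance` of it; fragments identical in both forms (those
#' spanning neither modified lysine, y1-y3 here) are always caught.
#' Setting `isobarIonTypes = c("y", "b")` additionally screens against the
#' isobar's b-series, a stricter interference criterion that flags
#' near-coincidences such as the isobar's b7 falling 0.011 m/z from the
#' target's y7.
#'
#' @param target,isobar [ModifiedPeptide-class] objects of equal length and
#'   equal neutral mass (within `tolerance`); unequal lengths are fatal.
#' @param candidates data.frame with columns `ion_type`, `ion_index`
#'   describing the target ions under consideration.
#' @param tolerance m/z match tolerance (default 0.25, the instrument
#'   method-match tolerance).
#' @param isobarIonTypes which isobar fragment series to screen against.
#' @param charge product-ion charge (default 1).
#'
#' @return list with data.frames `retained` (ion_type, ion_index, mz) and
#'   `excluded` (additionally the matching isobar ion and its m/z delta).
#' @examples
#' tgt <- modifiedPeptide("KSTGGKAPR", "1:Poy;6:Ac")
#' iso <- modifiedPeptide("KSTGGKAPR", "1:Ac;6:Poy")
#' cand <- data.frame(ion_type = "y", ion_index = 1:8)
#' isobaricOverlapFilter(tgt, iso, cand)$retained$ion_index  # 4:8
#' @export
isobaricOverlapFilter <- function(target, isobar, candidates,
                                  tolerance = 0.25,
                                  isobarIonTypes = "y",
                                  charge = 1L) {
  if (nchar(target@sequence) != nchar(isobar@sequence))
    stop("peptides of unequal sequence length are not positional isomers",
         call. = FALSE)
  if (abs(neutralMass(target) - neutralMass(isobar)) > tolerance)
    stop("peptides are not isobaric within the given tolerance",
         call. = FALSE)
  L <- nchar(isobar@sequence)
  iso <- do.call(rbind, lapply(isobarIonTypes, function(tp)
    data.frame(ion_type = tp, ion_index = seq_len(L - 1L),
               mz = vapply(seq_len(L - 1L), function(i)
                 fragmentMz(isobar, tp, i, charge), 0),
               stringsAsFactors = FALSE)))
  cand <- candidates[, c("ion_type", "ion_index"), drop = FALSE]
  cand$mz <- mapply(function(tp, i) fragmentMz(target, tp, i, charge),
                    cand$ion_type, cand$ion_index)
  hit <- lapply(seq_len(nrow(cand)), function(k) {
    d <- abs(iso$mz - cand$mz[k])
    j <- which.min(d)
    if (d[j] <= tolerance) cbind(cand[k, ], isobar_ion_type = iso$ion_type[j],
                                 isobar_ion_index = iso$ion_index[j],
                                 isobar_mz = iso$mz[j], delta_mz = d[j])
    else NULL
  })
  excluded <- do.call(rbind, hit)
  keep <- vapply(hit, is.null, TRUE)
  retained <- cand[keep, , drop = FALSE]
  rownames(retained) <- NULL
  if (is.null(excluded))
    excluded <- data.frame(ion_type = character(), ion_index = integer(),
                           mz = numeric(), isobar_ion_type = character(),
                           isobar_ion_index = integer(), isobar_mz = numeric(),
                           delta_mz = numeric(), stringsAsFactors = FALSE)
  rownames(excluded) <- NULL
  list(retained = retained, excluded = excluded)
}

.modSpecString <- function(peptide) {
  m <- peptide@modifications
  if (!nrow(m)) return("")
  paste(sprintf("%d:%s", m$position, m$name), collapse = ";")
}

#' Build the MRM transition set
#'
#' Generates one transition per peptide x product ion, in the given order,
#' labeled sequentially (`MRM1`, `MRM2`, ...). For the four assay peptides
#' and product ions y7, y8, y6 this yields the assay's 12 transitions.
#'
#' @param peptides list of [ModifiedPeptide-class] objects, in transition
#'   list order.
#' @param ions data.frame with columns `ion_type`, `ion_index`, in the
#'   order transitions are numbered within each peptide (default y7, y8, y6).
#' @param precursorCharge Q1 charge (default 2).
#' @param productCharge Q3 charge (default 1).
#' @param labelPrefix prefix for transition labels (default `"MRM"`).
#'
#' @return data.frame with columns peptide_name, sequence,
#'   modification_spec, label_state, q1_mz, q1_charge, q3_mz, q3_charge,
#'   ion_type, ion_index, transition_label, declared. m/z values are at
#'   full precision; `declared` is `FALSE` for computed transitions.
#' @examples
#' ts <- buildTransitionSet(studyPeptides())
#' nrow(ts)  # 12
#' @export
buildTransitionSet <- function(peptides,
                               ions = data.frame(ion_type = "y",
                                                 ion_index = c(7L, 8L, 6L)),
                               precursorCharge = 2L, productCharge = 1L,
                               labelPrefix = "MRM") {
  if (!length(peptides))
    return(data.frame(peptide_name = character(), sequence = character(),
                      modification_spec = character(),
                      label_state = character(), q1_mz = numeric(),
                      q1_charge = integer(), q3_mz = numeric(),
                      q3_charge = integer(), ion_type = character(),
                      ion_index = integer(), transition_label = character(),
                      declared = logical(), stringsAsFactors = FALSE))
  rows <- list(); k <- 0L
  seen <- character()
  for (pep in peptides) {
    for (j in seq_len(nrow(ions))) {
      key <- paste(pep@displayName, ions$ion_type[j], ions$ion_index[j])
      if (key %in% seen)
        stop("duplicate (peptide, ion) pair: ", key, call. = FALSE)
      seen <- c(seen, key)
      k <- k + 1L
      rows[[k]] <- data.frame(
        peptide_name      = pep@displayName,
        sequence          = pep@sequence,
        modification_spec = .modSpecString(pep),
        label_state       = if (pep@heavy) "heavy" else "light",
        q1_mz             = precursorMz(pep, precursorCharge),
        q1_charge         = as.integer(precursorCharge),
        q3_mz             = fragmentMz(pep, ions$ion_type[j],
                                       ions$ion_index[j], productCharge),
        q3_charge         = as.integer(productCharge),
        ion_type          = ions$ion_type[j],
        ion_index         = as.integer(ions$ion_index[j]),
        transition_label  = paste0(labelPrefix, k),
        declared          = FALSE,
        stringsAsFactors  = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Check declared (assay-file) Q3 values against computed fragments
#'
#' Printed or instrument-exported transition lists sometimes carry Q3
#' values tuned on the instrument. Values within 0.05 m/z of the computed
#' fragment are accepted silently; between 0.05 and the method match
#' tolerance (0.25 m/z) they are accepted with a warning; beyond the
#' tolerance they are an error.
#'
#' @param transitions data.frame in the [buildTransitionSet()] layout whose
#'   `q3_mz` holds declared values.
#' @param tolerance maximum tolerated disagreement (default 0.25 m/z).
#' @param warnAbove disagreement above which a warning is issued (0.05).
#'
#' @return the input with columns `computed_q3_mz`, `q3_delta` added and
#'   `declared` set to `TRUE`.
#' @export
checkDeclaredTransitions <- function(transitions, tolerance = 0.25,
                                     warnAbove = 0.05) {
  comp <- numeric(nrow(transitions))
  for (i in seq_len(nrow(transitions))) {
    pep <- modifiedPeptide(transitions$sequence[i],
                           transitions$modification_spec[i],
                           heavy = transitions$label_state[i] == "heavy",
                           displayName = transitions$peptide_name[i])
    comp[i] <- fragmentMz(pep, transitions$ion_type[i],
                          transitions$ion_index[i],
                          transitions$q3_charge[i])
  }
  delta <- abs(transitions$q3_mz - comp)
  if (any(delta > tolerance))
    stop(sprintf("declared Q3 for %s deviates %.3f m/z from computed (> %.2f)",
                 transitions$transition_label[which.max(delta)],
                 max(delta), tolerance), call. = FALSE)
  off <- delta > warnAbove
  if (any(off))
    warning(sprintf("declared Q3 within tolerance but off computed by > %.2f m/z: %s",
                    warnAbove,
                    paste(transitions$transition_label[off], collapse = ", ")),
            call. = FALSE)
  transitions$computed_q3_mz <- comp
  transitions$q3_delta <- delta
  transitions$declared <- TRUE
  transitions
}

#' Write / read a transition list
#'
#' Tab-delimited text with the [buildTransitionSet()] columns. Numeric
#' columns are serialized at full double precision so a write/read
#' round-trip preserves every field bit-for-bit.
#'
#' @param transitions transition data.frame
#' @param file path
#' @return `writeTransitionList` returns the path invisibly;
#'   `readTransitionList` returns the data.frame.
#' @export
writeTransitionList <- function(transitions, file) {
  out <- transitions
  for (cl in names(out))
    if (is.double(out[[cl]])) out[[cl]] <- sprintf("%.17g", out[[cl]])
  utils::write.table(out, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' @rdname writeTransitionList
#' @export
readTransitionList <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  num <- c("q1_mz", "q3_mz")
  int <- c("q1_charge", "q3_charge", "ion_index")
  for (cl in intersect(num, names(df))) df[[cl]] <- as.numeric(df[[cl]])
  for (cl in intersect(int, names(df))) df[[cl]] <- as.integer(df[[cl]])
  if ("modification_spec" %in% names(df))
    df$modification_spec[is.na(df$modification_spec)] <- ""
  df
}
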