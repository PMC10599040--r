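#' @import methods
NULL

#' ModifiedPeptide: a derivatized peptide with positioned modifications
#'
#' Represents one assay peptide: an amino-acid sequence, a set of positioned
#' chemical modifications (propionyl from derivatization, acetyl as the PTM
#' of interest), and an optional C-terminal heavy-isotope label
#' (\eqn{^{13}C_6^{15}N_4} arginine, +10.0083 Da). This is the unit whose
#' neutral mass, precursor m/z and fragment-ion m/z are computed.
#'
#' @slot sequence single string of one-letter residue codes.
#' @slot modifications data.frame with columns `position` (1-based within
#'   the peptide), `name` (modification name, e.g. "Poy", "Ac") and
#'   `delta` (monoisotopic mass shift, Da).
#' @slot heavy logical; if `TRUE` the C-terminal residue (which must be R)
#'   carries the 13C6 15N4 label.
#' @slot displayName human-readable name, e.g. `"K9[Poy]K14[Ac]-heavy"`.
#'
#' @seealso [modifiedPeptide()] for the user constructor, [neutralMass()],
#'   [precursorMz()], [fragmentMz()].
#' @exportClass ModifiedPeptide
setClass("ModifiedPeptide",
  representation(
    sequence      = "character",
    modifications = "data.frame",
    heavy         = "logical",
    displayName   = "character"
  )
)

setValidity("ModifiedPeptide", function(object) {
  msg <- character()
  if (length(object@sequence) != 1L || is.na(object@sequence) ||
      nchar(object@sequence) < 1L)
    return("sequence must be a single non-empty string")
  res <- strsplit(object@sequence, "")[[1L]]
  unknown <- setdiff(res, names(residueMasses()))
  if (length(unknown))
    msg <- c(msg, sprintf("unknown residue symbol(s): %s",
                          paste(unique(unknown), collapse = ", ")))
  m <- object@modifications
  if (!all(c("position", "name", "delta") %in% names(m)))
    return("modifications must have columns position, name, delta")
  if (nrow(m)) {
    if (any(m$position < 1L | m$position > length(res)))
      msg <- c(msg, "modification position out of sequence bounds")
    if (anyDuplicated(m$position))
      msg <- c(msg, "at most one modification per residue position")
  }
  if (length(object@heavy) != 1L || is.na(object@heavy))
    msg <- c(msg, "heavy must be TRUE or FALSE")
  else if (object@heavy && res[length(res)] != "R")
    msg <- c(msg, "heavy label requires a C-terminal arginine (R)")
  if (length(msg)) msg else TRUE
})

#' @describeIn ModifiedPeptide compact display
#' @param object a `ModifiedPeptide`
#' @export
setMethod("show", "ModifiedPeptide", function(object) {
  cat("ModifiedPeptide:", object@displayName, "\n")
  cat("  sequence:", annotatedSequence(object), "\n")
  cat(sprintf("  neutral monoisotopic mass: %.6f Da\n", neutralMass(object)))
  invisible(object)
})

#' CalibrationFit: fitted reverse calibration curve
#'
#' Holds the unweighted ordinary-least-squares fit of
#' log10(heavy:light area ratio) on log10(nominal heavy concentration),
#' together with the points used and per-point residuals. Produced by
#' [fitReverseCalibration()]; consumed by [backCalculate()] and the
#' figures-of-merit functions.
#'
#' @slot peptidePair name of the light/heavy peptide pair fitted.
#' @slot slope,intercept coefficients of the log10-log10 line.
#' @slot rSquared squared Pearson correlation on the log-log points.
#' @slot levelsUsed nominal concentrations (fmol/uL) retained in the fit.
#' @slot points data.frame of fitted points (injection_id, nominal_conc,
#'   ratio, log_conc, log_ratio, residual).
#'
#' @exportClass CalibrationFit
setClass("CalibrationFit",
  representation(
    peptidePair = "character",
    slope       = "numeric",
    intercept   = "numeric",
    rSquared    = "numeric",
    levelsUsed  = "numeric",
    points      = "data.frame"
  )
)

setValidity("CalibrationFit", function(object) {
  msg <- character()
  if (!is.finite(object@slope) || !is.finite(object@intercept))
    msg <- c(msg, "slope and intercept must be finite")
  if (object@rSquared < 0 - 1e-12 || object@rSquared > 1 + 1e-12)
    msg <- c(msg, "rSquared must lie in [0, 1]")
  if (length(object@levelsUsed) < 3L)
    msg <- c(msg, "a calibration fit needs at least 3 distinct levels")
  if (length(msg)) msg else TRUE
})

#' @describeIn CalibrationFit compact display
#' @param object a `CalibrationFit`
#' @export
setMethod("show", "CalibrationFit", function(object) {
  cat("CalibrationFit:", object@peptidePair, "\n")
  cat(sprintf("  log10(ratio) = %.5f * log10(conc) + %.5f\n",
              object@slope, object@intercept))
  cat(sprintf("  R^2 = %.6f over %d levels (%g-%g fmol/uL), %d points\n",
              object@rSquared, length(object@levelsUsed),
              min(object@levelsUsed), max(object@levelsUsed),
              nrow(object@points)))
  invisible(object)
})

#' @rdname calibrationAccessors
#' @export
setGeneric("calSlope", function(object) standardGeneric("calSlope"))
#' @rdname calibrationAccessors
#' @export
setGeneric("calIntercept", function(object) standardGeneric("calIntercept"))
#' @rdname calibrationAccessors
#' @export
setGeneric("calRSquared", function(object) standardGeneric("calRSquared"))

#' Accessors for CalibrationFit slots
#'
#' @param object a [CalibrationFit-class] object
#' @return the slope, intercept, or log-log R-squared of the fit.
#' @name calibrationAccessors
NULL

#' @rdname calibrationAccessors
#' @export
setMethod("calSlope", "CalibrationFit", function(object) object@slope)
#' @rdname calibrationAccessors
#' @export
setMethod("calIntercept", "CalibrationFit", function(object) object@intercept)
#' @rdname calibrationAccessors
#' @export
setMethod("calRSquared", "CalibrationFit", function(object) object@rSquared)

#' @rdname peptideAccessors
#' @export
setGeneric("peptideSequence", function(object) standardGeneric("peptideSequence"))
#' @rdname peptideAccessors
#' @export
setGeneric("peptideModifications", function(object) standardGeneric("peptideModifications"))
#' @rdname peptideAccessors
#' @export
setGeneric("isHeavy", function(object) standardGeneric("isHeavy"))
#' @rdname peptideAccessors
#' @export
setGeneric("displayName", function(object) standardGeneric("displayName"))

#' Accessors for ModifiedPeptide slots
#'
#' @param object a [ModifiedPeptide-class] object
#' @return the bare sequence, modification table, heavy flag, or display name.
#' @name peptideAccessors
NULL

#' @rdname peptideAccessors
#' @export
setMethod("peptideSequence", "ModifiedPeptide", function(object) object@sequence)
#' @rdname peptideAccessors
#' @export
setMethod("peptideModifications", "ModifiedPeptide", function(object) object@modifications)
#' @rdname peptideAccessors
#' @export
setMethod("isHeavy", "ModifiedPeptide", function(object) object@heavy)
#' @rdname peptideAccessors
#' @export
setMethod("displayName", "ModifiedPeptide", function(object) object@displayName)
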