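#' Integrate a chromatographic peak
#'
#' Trapezoidal integration of baseline-subtracted intensity over a window.
#' The baseline is the mean of the first and last `baselinePoints` samples
#' of the window; negative net areas are clipped at zero. The apex is the
#' time of maximum intensity within the window.
#'
#' @param trace data.frame with columns `time`, `intensity`
#'   (e.g. from [simulateChromatogram()]).
#' @param window numeric length-2, start and end time (minutes); defaults
#'   to the full trace.
#' @param baselinePoints samples from each window edge used for the
#'   baseline estimate (default 3).
#' @return list with `area` (signal x minutes), `apex` (minutes) and
#'   `baseline` (signal units).
#' @export
integratePeak <- function(trace, window = range(trace$time),
                          baselinePoints = 3L) {
  if (length(window) != 2L || window[1] >= window[2])
    stop("window must be (start, end) with start < end", call. = FALSE)
  sel <- trace$time >= window[1] & trace$time <= window[2]
  if (!any(sel)) stop("empty integration window", call. = FALSE)
  tt <- trace$time[sel]; yy <- trace$intensity[sel]
  n <- length(tt)
  k <- min(baselinePoints, n)
  baseline <- mean(c(yy[seq_len(k)], yy[seq.int(n - k + 1L, n)]))
  y0 <- yy - baseline
  area <- if (n > 1L) sum(diff(tt) * (y0[-n] + y0[-1L]) / 2) else 0
  list(area = max(area, 0), apex = tt[which.max(yy)], baseline = baseline)
}

#' Sum transition areas into a peptide-level area
#'
#' A peptide's quantified signal is the sum of its transition peak areas.
#' Fewer than the expected number of transitions triggers a warning;
#' duplicated transition labels within one injection are fatal.
#'
#' @param peakRows peak-table rows for a single injection x peptide x
#'   label state.
#' @param expectedTransitions number of transitions the assay monitors per
#'   peptide (default 3).
#' @return list (one PeptideArea record): injection_id, peptide_name,
#'   label_state, summed_area, transition_areas (named), rt_apex.
#' @export
sumTransitionAreas <- function(peakRows, expectedTransitions = 3L) {
  if (!nrow(peakRows)) stop("no transition rows supplied", call. = FALSE)
  if (length(unique(peakRows$injection_id)) != 1L ||
      length(unique(peakRows$peptide_name)) != 1L ||
      length(unique(peakRows$label_state)) != 1L)
    stop("rows must belong to one injection, peptide and label state",
         call. = FALSE)
  if (anyDuplicated(peakRows$transition_label))
    stop("duplicate transition label within one injection", call. = FALSE)
  if (nrow(peakRows) < expectedTransitions)
    warning(sprintf("only %d of %d expected transitions present for %s / %s",
                    nrow(peakRows), expectedTransitions,
                    peakRows$injection_id[1L], peakRows$peptide_name[1L]),
            call. = FALSE)
  areas <- stats::setNames(peakRows$area, peakRows$transition_label)
  list(injection_id = peakRows$injection_id[1L],
       peptide_name = peakRows$peptide_name[1L],
       label_state = peakRows$label_state[1L],
       summed_area = sum(areas),
       transition_areas = areas,
       rt_apex = stats::median(peakRows$retention_time))
}

#' Peptide-level areas for a whole peak table
#'
#' Applies [sumTransitionAreas()] to every injection x peptide x label
#' combination of a long peak table.
#'
#' @param peaks long peak table (see [simulateCalibrationSeries()]).
#' @return data.frame: injection_id, sample_role, peptide_name,
#'   label_state, summed_area, rt_apex.
#' @export
peptideAreas <- function(peaks) {
  key <- interaction(peaks$injection_id, peaks$peptide_name,
                     peaks$label_state, drop = TRUE)
  out <- do.call(rbind, lapply(split(peaks, key), function(g) {
    data.frame(injection_id = g$injection_id[1L],
               sample_role = g$sample_role[1L],
               peptide_name = g$peptide_name[1L],
               label_state = g$label_state[1L],
               summed_area = sum(g$area),
               rt_apex = stats::median(g$retention_time),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Light:heavy ratio for one peptide pair in one injection
#'
#' Both directional ratios are returned. A zero heavy area makes the
#' light:heavy ratio undefined; the record is flagged rather than set to
#' infinity, and flagged records are excluded downstream with a warning.
#' A zero light area is a valid observation (analyte below detection).
#'
#' @param light,heavy PeptideArea records (lists from
#'   [sumTransitionAreas()]) for the same injection.
#' @return list (RatioRecord): injection_id, peptide_pair, light_peptide,
#'   heavy_peptide, light_to_heavy, heavy_to_light, flagged.
#' @export
lightHeavyRatio <- function(light, heavy) {
  if (light$injection_id != heavy$injection_id)
    stop("light and heavy areas come from different injections",
         call. = FALSE)
  if (light$label_state != "light" || heavy$label_state != "heavy")
    stop("arguments must be a light and a heavy PeptideArea", call. = FALSE)
  flagged <- heavy$summed_area <= 0
  list(injection_id = light$injection_id,
       peptide_pair = light$peptide_name,
       light_peptide = light$peptide_name,
       heavy_peptide = heavy$peptide_name,
       light_to_heavy = if (flagged) NA_real_
                        else light$summed_area / heavy$summed_area,
       heavy_to_light = if (light$summed_area <= 0) NA_real_
                        else heavy$summed_area / light$summed_area,
       flagged = flagged)
}

#' Light:heavy ratios for a whole peak table
#'
#' Pairs each light peptide with its heavy counterpart (name plus
#' `"-heavy"`) within every injection and computes both directional
#' ratios. Injections whose heavy area is zero are flagged.
#'
#' @param peaks long peak table.
#' @param heavySuffix suffix identifying the heavy partner (default
#'   `"-heavy"`).
#' @return data.frame: injection_id, sample_role, peptide_pair,
#'   light_to_heavy, heavy_to_light, flagged.
#' @export
computeRatios <- function(peaks, heavySuffix = "-heavy") {
  ar <- peptideAreas(peaks)
  lights <- ar[ar$label_state == "light", , drop = FALSE]
  heavies <- ar[ar$label_state == "heavy", , drop = FALSE]
  hkey <- paste(heavies$injection_id,
                sub(paste0(heavySuffix, "$"), "", heavies$peptide_name))
  idx <- match(paste(lights$injection_id, lights$peptide_name), hkey)
  if (anyNA(idx))
    stop("light peptide(s) without a heavy partner: ",
         paste(unique(lights$peptide_name[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  hv <- heavies[idx, , drop = FALSE]
  flagged <- hv$summed_area <= 0
  if (any(flagged))
    warning(sprintf("%d ratio record(s) flagged: zero heavy area",
                    sum(flagged)), call. = FALSE)
  out <- data.frame(injection_id = lights$injection_id,
                    sample_role = lights$sample_role,
                    peptide_pair = lights$peptide_name,
                    light_to_heavy = ifelse(flagged, NA_real_,
                                            lights$summed_area / hv$summed_area),
                    heavy_to_light = ifelse(lights$summed_area > 0,
                                            hv$summed_area / lights$summed_area,
                                            NA_real_),
                    flagged = flagged,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Retention-time coherence check
#'
#' All transitions of an analyte (and its co-eluting heavy partner) must
#' apex together: the check fails when the maximum pairwise apex spread
#' exceeds the tolerance. A single transition passes with a note.
#'
#' @param peakRows peak-table rows for one injection x peptide (optionally
#'   both label states) with `retention_time` per transition.
#' @param tolerance maximum allowed apex spread (minutes, default 0.1).
#' @return list: `pass`, `spread` (minutes), `n`, `note`.
#' @export
rtCoherenceCheck <- function(peakRows, tolerance = 0.1) {
  rt <- peakRows$retention_time
  if (length(rt) < 2L)
    return(list(pass = TRUE, spread = 0, n = length(rt),
                note = "single transition; coherence not assessable"))
  spread <- max(rt) - min(rt)
  list(pass = spread <= tolerance, spread = spread, n = length(rt),
       note = NA_character_)
}
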