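#' Absolute abundance from light:heavy ratios
#'
#' AQUA quantification: the endogenous (light) peptide's absolute
#' concentration is its light:heavy area ratio times the known spiked
#' concentration of the chemically identical heavy standard. Flagged
#' ratio records (zero heavy area) are skipped with a warning.
#'
#' @param ratios ratio table from [computeRatios()] for donor injections.
#' @param heavySpike spiked heavy-standard concentration (fmol/uL, > 0).
#' @param manifest optional run manifest; when given, donor_id, condition
#'   and replicate are joined onto the result.
#' @return data.frame: injection_id, peptide_pair, abundance (fmol/uL),
#'   plus manifest columns when available.
#' @export
absoluteAbundance <- function(ratios, heavySpike, manifest = NULL) {
  if (heavySpike <= 0) stop("heavy spike must be positive", call. = FALSE)
  rr <- ratios
  if (any(rr$flagged)) {
    warning(sprintf("%d flagged ratio record(s) skipped", sum(rr$flagged)),
            call. = FALSE)
    rr <- rr[!rr$flagged, , drop = FALSE]
  }
  out <- data.frame(injection_id = rr$injection_id,
                    peptide_pair = rr$peptide_pair,
                    abundance = rr$light_to_heavy * heavySpike,
                    stringsAsFactors = FALSE)
  if (!is.null(manifest))
    out <- merge(out, manifest[, c("injection_id", "donor_id", "condition",
                                   "replicate")], by = "injection_id")
  rownames(out) <- NULL
  out
}

#' K14Ac stoichiometry
#'
#' Percentage of the site that is modified:
#' 100 x mod / (mod + unmod), from the absolute abundances of the
#' acetylated (modified) and propionylated (unmodified) peptide forms of
#' the same injection. Both abundances zero is undefined and returns `NA`.
#'
#' @param mod,unmod non-negative absolute abundances (fmol/uL); vectorized.
#' @return stoichiometry in percent, in `[0, 100]`.
#' @examples
#' stoichiometryPercent(12.3, 36.9)  # 25
#' @export
stoichiometryPercent <- function(mod, unmod) {
  if (any(mod < 0, na.rm = TRUE) || any(unmod < 0, na.rm = TRUE))
    stop("abundances must be non-negative", call. = FALSE)
  tot <- mod + unmod
  ifelse(tot > 0, 100 * mod / tot, NA_real_)
}

#' Per-injection stoichiometry table
#'
#' Pairs the modified and unmodified peptide abundances of each injection
#' and applies [stoichiometryPercent()]. Injections with both forms zero
#' are excluded with a warning.
#'
#' @param abundances table from [absoluteAbundance()] covering both forms.
#' @param modPeptide,unmodPeptide `peptide_pair` names of the modified
#'   (acetylated) and unmodified (propionylated) forms.
#' @return data.frame: injection_id, donor_id, condition, replicate (when
#'   present), mod_abundance, unmod_abundance, stoichiometry_pct.
#' @export
stoichiometryTable <- function(abundances,
                               modPeptide = "K9[Poy]K14[Ac]",
                               unmodPeptide = "K9[Poy]K14[Poy]") {
  m <- abundances[abundances$peptide_pair == modPeptide, , drop = FALSE]
  u <- abundances[abundances$peptide_pair == unmodPeptide, , drop = FALSE]
  idx <- match(m$injection_id, u$injection_id)
  if (anyNA(idx))
    stop("injection(s) missing the unmodified form", call. = FALSE)
  keep <- c("injection_id",
            intersect(c("donor_id", "condition", "replicate"), names(m)))
  out <- m[, keep, drop = FALSE]
  out$mod_abundance <- m$abundance
  out$unmod_abundance <- u$abundance[idx]
  out$stoichiometry_pct <- stoichiometryPercent(out$mod_abundance,
                                                out$unmod_abundance)
  undef <- is.na(out$stoichiometry_pct)
  if (any(undef)) {
    warning(sprintf("%d injection(s) with undefined stoichiometry excluded",
                    sum(undef)), call. = FALSE)
    out <- out[!undef, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

.summarise <- function(x) {
  mn <- mean(x)
  sdv <- if (length(x) >= 2L) stats::sd(x) else NA_real_
  c(mean = mn, sd = sdv,
    cv = if (is.finite(sdv) && mn != 0) 100 * sdv / mn else NA_real_,
    n = length(x))
}

#' Two-tier stoichiometry aggregation
#'
#' First tier: the technical replicates of each donor x condition are
#' averaged (mean, sample SD, %CV). Second tier: the per-donor means are
#' averaged within each condition across donors. Empty groups are omitted
#' with a warning.
#'
#' @param stoich per-injection table from [stoichiometryTable()].
#' @return list with data.frames `donor` (donor_id, condition, mean_pct,
#'   sd_pct, cv_pct, n) and `condition` (condition, mean_pct, sd_pct,
#'   cv_pct, n_donors).
#' @export
aggregateStoichiometry <- function(stoich) {
  key <- interaction(stoich$donor_id, stoich$condition, drop = TRUE)
  donor <- do.call(rbind, lapply(split(stoich, key), function(g) {
    s <- .summarise(g$stoichiometry_pct)
    data.frame(donor_id = g$donor_id[1L], condition = g$condition[1L],
               mean_pct = s[["mean"]], sd_pct = s[["sd"]],
               cv_pct = s[["cv"]], n = as.integer(s[["n"]]),
               stringsAsFactors = FALSE)
  }))
  donor <- donor[order(donor$donor_id, donor$condition), ]
  rownames(donor) <- NULL
  cond <- do.call(rbind, lapply(split(donor, donor$condition), function(g) {
    s <- .summarise(g$mean_pct)
    data.frame(condition = g$condition[1L], mean_pct = s[["mean"]],
               sd_pct = s[["sd"]], cv_pct = s[["cv"]],
               n_donors = as.integer(s[["n"]]), stringsAsFactors = FALSE)
  }))
  rownames(cond) <- NULL
  list(donor = donor, condition = cond)
}

#' Welch two-sample unequal-variance t-test
#'
#' Wraps `stats::t.test(..., var.equal = FALSE)`: t statistic,
#' Welch-Satterthwaite degrees of freedom, two-sided p-value, and a
#' significance flag at p < 0.05. Groups smaller than two observations
#' are not testable. The degenerate case of zero variance in both groups
#' (where `t.test` cannot run) is handled directly: equal means give
#' t = 0, p = 1; unequal means give a signed infinite t and p = 0.
#'
#' @param groupA,groupB numeric vectors (each length >= 2).
#' @param alpha significance threshold (default 0.05).
#' @return list: t, df, p_value, significant, mean_a, mean_b.
#' @export
welchTTest <- function(groupA, groupB, alpha = 0.05) {
  if (length(groupA) < 2L || length(groupB) < 2L)
    stop("both groups need at least 2 values; comparison not testable",
         call. = FALSE)
  va <- stats::var(groupA); vb <- stats::var(groupB)
  if (va + vb == 0) {
    d <- mean(groupA) - mean(groupB)
    return(list(t = if (d == 0) 0 else sign(d) * Inf,
                df = length(groupA) + length(groupB) - 2,
                p_value = if (d == 0) 1 else 0,
                significant = d != 0,
                mean_a = mean(groupA), mean_b = mean(groupB)))
  }
  tt <- stats::t.test(groupA, groupB, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, significant = tt$p.value < alpha,
       mean_a = mean(groupA), mean_b = mean(groupB))
}

#' Pairwise condition comparisons
#'
#' Welch t-tests for CIC vs CIM, CIC vs MIM and CIM vs MIM. At
#' `level = "donor"` the groups are the technical-replicate
#' stoichiometries of one donor (compare within each donor separately by
#' subsetting `stoich` first). At `level = "cohort"` the groups are the
#' per-donor means of each condition. Pairs with a missing condition are
#' skipped. No multiple-testing correction is applied by default,
#' matching the original analysis; `adjust = "bonferroni"` is available.
#'
#' @param stoich per-injection table ([stoichiometryTable()]) for
#'   `level = "donor"`, or the `$donor` tier of
#'   [aggregateStoichiometry()] for `level = "cohort"`.
#' @param level `"donor"` or `"cohort"`.
#' @param conditions conditions to compare pairwise.
#' @param alpha significance threshold.
#' @param adjust `"none"` (default) or a `stats::p.adjust` method.
#' @return data.frame: (donor_id at donor level,) condition_a,
#'   condition_b, t, df, p_value, significant.
#' @export
compareConditions <- function(stoich, level = c("donor", "cohort"),
                              conditions = c("CIC", "CIM", "MIM"),
                              alpha = 0.05, adjust = "none") {
  level <- match.arg(level)
  pairs <- utils::combn(conditions, 2L, simplify = FALSE)
  testPairs <- function(values, byCond, donor = NA_character_) {
    out <- lapply(pairs, function(p) {
      a <- values[byCond == p[1L]]; b <- values[byCond == p[2L]]
      if (length(a) < 2L || length(b) < 2L) return(NULL)
      w <- welchTTest(a, b, alpha = alpha)
      data.frame(donor_id = donor, condition_a = p[1L], condition_b = p[2L],
                 t = w$t, df = w$df, p_value = w$p_value,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  }
  res <- if (level == "donor") {
    do.call(rbind, lapply(split(stoich, stoich$donor_id), function(g)
      testPairs(g$stoichiometry_pct, g$condition, g$donor_id[1L])))
  } else {
    testPairs(stoich$mean_pct, stoich$condition)
  }
  if (is.null(res)) return(NULL)
  res$p_value <- stats::p.adjust(res$p_value, method = adjust)
  res$significant <- res$p_value < alpha
  if (level == "cohort") res$donor_id <- NULL
  rownames(res) <- NULL
  res
}
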