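# integer rounding, halves away from zero (matches how the headline
# percentages are printed)
roundHalfAway <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Assemble an area report with shrinkage correction and headline ratios
#'
#' Applies the isotropic fixation-shrinkage correction per structure
#' (flagged on or off per entry: ex vivo structures are corrected, literature
#' in vivo comparison values are taken as given), optionally scales
#' gray/white areas by the gray/white-to-pial factor, and computes requested
#' pairwise area ratios from the corrected values. Ratios are also reported
#' as integer percent, rounded half away from zero.
#'
#' @param areas named numeric vector of measured areas (mm^2 or any single
#'   consistent unit), all positive.
#' @param shrinkage a [ShrinkageModel-class].
#' @param gwToPialFactor multiplier estimating a pial area from a
#'   gray/white area (default 1.2).
#' @param applyShrinkage logical, scalar or named per-label vector.
#' @param applyGwFactor logical, scalar or named per-label vector.
#' @param ratios list of character pairs `c(numerator, denominator)`.
#' @return an [AreaReport-class].
#' @export
buildAreaReport <- function(areas, shrinkage = ShrinkageModel(),
                            gwToPialFactor = 1.2, applyShrinkage = TRUE,
                            applyGwFactor = FALSE, ratios = list()) {
  if (is.null(names(areas)) || any(!nzchar(names(areas))))
    stop("areas must be a fully named vector")
  if (any(areas <= 0)) stop("areas must be positive")
  labs <- names(areas)
  expand <- function(flag) {
    if (length(flag) == 1L && is.null(names(flag)))
      return(stats::setNames(rep(flag, length(labs)), labs))
    out <- stats::setNames(rep(FALSE, length(labs)), labs)
    out[names(flag)] <- flag
    out
  }
  doShrink <- expand(applyShrinkage)
  doGw <- expand(applyGwFactor)
  corrected <- areas
  corrected[doGw[labs]] <- corrected[doGw[labs]] * gwToPialFactor
  corrected[doShrink[labs]] <-
    vapply(corrected[doShrink[labs]], correctShrinkage, numeric(1),
           model = shrinkage)
  rat <- numeric(0)
  for (pr in ratios) {
    if (!all(pr %in% labs))
      stop("unknown label in ratio request: ",
           paste(setdiff(pr, labs), collapse = ", "))
    rat[paste0(pr[1], "/", pr[2])] <- corrected[[pr[1]]] / corrected[[pr[2]]]
  }
  new("AreaReport",
      areas = data.frame(label = labs, raw_mm2 = as.numeric(areas),
                         corrected_mm2 = as.numeric(corrected)),
      ratios = rat, percents = roundHalfAway(100 * rat),
      gwToPialFactor = gwToPialFactor)
}
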