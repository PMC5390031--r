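#' Fit a linear HPLC calibration curve
#'
#' Ordinary least squares of peak area on standard concentration
#' (ppm), e.g. from a five-point series at 5/10/20/40/50 ppm. The
#' intercept is retained (the curve is not forced through the origin)
#' and r-squared is reported for QC.
#'
#' @param points data.frame with columns \code{ppm} and \code{area},
#'   or a two-column matrix.
#' @param analyte optional analyte label carried through.
#' @return calibration list: \code{analyte}, \code{slope} (area per
#'   ppm), \code{intercept}, \code{r2}.
#' @examples
#' fit_calibration(data.frame(ppm = c(5, 10, 20, 40, 50),
#'                            area = c(50, 100, 200, 400, 500)))
#' @export
fit_calibration <- function(points, analyte = NA) {
  points <- as.data.frame(points)
  stopifnot(all(c("ppm", "area") %in% names(points)))
  if (nrow(points) < 3) stop("need >= 3 calibration points")
  if (length(unique(points$ppm)) < 2) stop("fit error: degenerate ppm values")
  fit <- lm(area ~ ppm, data = points)
  list(analyte = analyte,
       slope = unname(coef(fit)[2]),
       intercept = unname(coef(fit)[1]),
       r2 = summary(fit)$r.squared)
}

#' Quantify an analyte from its peak area
#'
#' Inverts the calibration (ppm = (area - intercept)/slope) and
#' converts to ug per g dry weight through the extraction arithmetic:
#' ug/g = ppm * extract_volume_ml * dilution / sample_mass_g. Defaults
#' follow a 125 mg flour / 6 ml solvent extraction.
#'
#' @param area observed peak area.
#' @param curve calibration from [fit_calibration()].
#' @param dilution dilution factor (default 1).
#' @param sample_mass_g dry sample mass in grams (default 0.125).
#' @param extract_volume_ml extract volume in ml (default 6).
#' @return concentration in ug/g dry weight; areas below the intercept
#'   are clipped to 0 with a warning.
#' @export
quantify <- function(area, curve, dilution = 1, sample_mass_g = 0.125,
                     extract_volume_ml = 6) {
  if (curve$slope <= 0) stop("calibration slope must be positive")
  ppm <- (area - curve$intercept) / curve$slope
  if (ppm < 0) {
    warning("area below calibration intercept; clipping concentration to 0")
    ppm <- 0
  }
  ppm * extract_volume_ml * dilution / sample_mass_g
}

#' Total isoflavone profile for one genotype/stage
#'
#' Sums the three aglycone concentrations (daidzein, glycitein,
#' genistein) into the total isoflavone content.
#'
#' @param daidzein,glycitein,genistein concentrations in ug/g (>= 0).
#' @param genotype,stage optional labels.
#' @return profile list with the three analytes and \code{total}.
#' @export
profile_totals <- function(daidzein, glycitein, genistein,
                           genotype = NA, stage = NA) {
  vals <- c(daidzein, glycitein, genistein)
  if (any(is.na(vals)) || any(vals < 0)) {
    stop("domain error: analyte concentrations must be >= 0")
  }
  list(genotype = genotype, stage = stage,
       daidzein = daidzein, glycitein = glycitein, genistein = genistein,
       total = daidzein + glycitein + genistein)
}
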