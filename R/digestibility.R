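#' Intake-weighted nutrient:lignin ratio of the diet
#'
#' When a diet mixes forage and a supplement, the nutrient-to-lignin ratio
#' of the whole diet is the mean of the component ratios weighted by their
#' dry-matter intakes:
#' \deqn{r_{diet} = (r_{for} DMI_{for} + r_{sup} DMI_{sup}) / DMI_{tot}.}
#' It is a convex combination, so it always lies between the component
#' ratios, and reduces to the forage ratio for a forage-only diet.
#'
#' @param ratio_forage,ratio_supplement nutrient:lignin ratios
#'   (dimensionless) in forage and supplement.
#' @param dmi_forage,dmi_supplement dry-matter intakes, kg per day.
#' @return the diet ratio (dimensionless).
#' @export
#' @examples
#' diet_ratio(10, 2, 0.9, 0.1)  # 9.2
diet_ratio <- function(ratio_forage, ratio_supplement = 0,
                       dmi_forage, dmi_supplement = 0) {
  if (dmi_forage < 0 || dmi_supplement < 0) stop_rf("intakes must be >= 0")
  total <- dmi_forage + dmi_supplement
  if (total <= 0) stop_rf("total dry-matter intake must be positive")
  if (dmi_supplement > 0 && ratio_supplement <= 0)
    stop_rf("supplement ratio must be positive when supplement is consumed")
  (ratio_forage * dmi_forage + ratio_supplement * dmi_supplement) / total
}

#' Apparent digestibility from an indigestible marker
#'
#' Lignin-marker digestibility: the fraction of a nutrient disappearing
#' across the whole tract is
#' \deqn{1 - (nutrient/lignin)_{feces} / (nutrient/lignin)_{diet}.}
#' Negative values (feces ratio above the diet ratio) are legitimate
#' outcomes of marker methods and are returned as-is with a `negative`
#' attribute set, never clipped, so data problems stay visible.
#'
#' @param feces_ratio nutrient:lignin ratio in feces (>= 0).
#' @param diet_ratio nutrient:lignin ratio in the diet (> 0), e.g. from
#'   [diet_ratio()].
#' @return digestibility in kg per kg, with attribute `negative`.
#' @export
#' @examples
#' apparent_digestibility(4.6, 9.2)  # 0.5
apparent_digestibility <- function(feces_ratio, diet_ratio) {
  if (any(diet_ratio <= 0)) stop_rf("diet ratio must be positive")
  if (any(feces_ratio < 0)) stop_rf("feces ratio must be >= 0")
  d <- 1 - feces_ratio / diet_ratio
  if (any(d < 0))
    warning("negative apparent digestibility: feces ratio exceeds diet ratio",
            call. = FALSE)
  attr(d, "negative") <- d < 0
  d
}
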