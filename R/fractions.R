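#' Feed composition record
#'
#' Proximate composition of a feed on an ash-free dry-matter basis.
#' Detergent-fiber chemistry implies the nesting
#' `lignin <= ADF <= NDF <= 1` (ADF = cellulose + lignin,
#' NDF = ADF + hemicellulose), which is validated here.
#'
#' @param DM dry matter, kg per kg fresh.
#' @param NDF,ADF,lignin,N fractions in kg per kg DM (ash-free).
#' @return object of class `feed_composition`.
#' @export
#' @examples
#' hay <- feed_composition(DM = 0.875, NDF = 0.700, ADF = 0.379,
#'                         lignin = 0.061, N = 0.0756)
feed_composition <- function(DM, NDF, ADF, lignin, N = NA_real_) {
  assert_scalar_number(DM, "DM", lower = 1e-12, upper = 1)
  assert_scalar_number(NDF, "NDF", lower = 0, upper = 1)
  assert_scalar_number(ADF, "ADF", lower = 0, upper = 1)
  assert_scalar_number(lignin, "lignin", lower = 0, upper = 1)
  if (lignin > ADF) stop_rf("lignin exceeds ADF: not a valid composition")
  if (ADF > NDF) stop_rf("ADF exceeds NDF: not a valid composition")
  structure(list(DM = DM, NDF = NDF, ADF = ADF, lignin = lignin, N = N),
            class = "feed_composition")
}

#' Derive cellulose and hemicellulose from detergent fractions
#'
#' Cellulose is the difference between ADF and ash-free lignin;
#' hemicellulose the difference between NDF and ADF.
#'
#' @param comp a [feed_composition()].
#' @return named numeric vector `c(cellulose, hemicellulose)` in
#'   kg per kg DM.
#' @export
#' @examples
#' hay <- feed_composition(DM = 0.875, NDF = 0.700, ADF = 0.379,
#'                         lignin = 0.061)
#' derive_fractions(hay)  # cellulose 0.318, hemicellulose 0.321
derive_fractions <- function(comp) {
  stopifnot(inherits(comp, "feed_composition"))
  c(cellulose = comp$ADF - comp$lignin,
    hemicellulose = comp$NDF - comp$ADF)
}
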