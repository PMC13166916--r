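#' Vegetation carbon stock from growing stock volume
#'
#' IPCC-style stock-change equation: carbon stored in live vegetation is the
#' vegetated area times the growing stock volume, expanded from stem to
#' whole-tree biomass (BEF), converted to mass (basic wood density D),
#' inflated by the belowground fraction (root-to-shoot ratio R) and reduced to
#' carbon (carbon fraction CF):
#'
#' \deqn{VCS = A \times V \times BEF \times D \times (1 + R) \times CF}
#'
#' For planted urban trees (roadside vegetation) the forest-derived product is
#' multiplied by a correction factor of 0.8, reflecting the lower stocking of
#' urban trees relative to natural stands.
#'
#' @param area_ha vegetated area within the grid cell, hectares. Vectorised.
#' @param V growing stock volume, m3/ha. Vectorised.
#' @param BEF biomass expansion factor (dimensionless, >= 1 in practice).
#' @param D basic wood density, tonnes biomass per m3.
#' @param R belowground-to-aboveground biomass ratio (dimensionless).
#' @param CF carbon fraction of biomass, tC per tonne biomass (<= 1).
#' @param urban_correction logical; apply the 0.8 urban-tree correction.
#' @return Vegetation carbon stock in tonnes C.
#' @examples
#' vegetation_c_storage(1, V = 100, BEF = 1.2, D = 0.5, R = 0.25, CF = 0.5)  # 37.5
#' @export
vegetation_c_storage <- function(area_ha, V, BEF, D, R, CF,
                                 urban_correction = FALSE) {
  args <- list(area_ha = area_ha, V = V, BEF = BEF, D = D, R = R, CF = CF)
  for (nm in names(args)) {
    if (any(!is.finite(args[[nm]])) || any(args[[nm]] < 0))
      stop(sprintf("'%s' must be finite and non-negative", nm))
  }
  if (any(CF > 1)) stop("'CF' is a carbon fraction and cannot exceed 1")
  out <- area_ha * V * BEF * D * (1 + R) * CF
  if (urban_correction) out <- out * 0.8
  out
}

#' Tree carbon stock from a DBH inventory
#'
#' Allometric ground truth for single planted trees: summed per-tree carbon
#' from species-specific power-law allometry, \eqn{\sum_j \sum_i a_j \,
#' DBH_{ij}^{b_j}}. The output unit follows the unit the coefficients were
#' fitted in (tC per tree for the tables shipped with this package).
#'
#' @param inventory data frame with columns `species` and `dbh` (diameter at
#'   breast height, cm, > 0); one row per tree.
#' @param coefficients data frame with columns `species`, `a`, `b`. Every
#'   species occurring in `inventory` must be present.
#' @return Total carbon stock of the inventory (scalar).
#' @export
allometric_c_storage <- function(inventory, coefficients) {
  stopifnot(is.data.frame(coefficients),
            all(c("species", "a", "b") %in% names(coefficients)))
  if (is.null(inventory) || nrow(inventory) == 0) return(0)
  stopifnot(all(c("species", "dbh") %in% names(inventory)))
  if (any(inventory$dbh <= 0)) stop("all DBH values must be > 0")
  missing <- setdiff(unique(inventory$species), coefficients$species)
  if (length(missing))
    stop(sprintf("no allometric coefficients for species: %s",
                 paste(missing, collapse = ", ")))
  i <- match(inventory$species, coefficients$species)
  sum(coefficients$a[i] * inventory$dbh^coefficients$b[i])
}

#' Gross primary productivity from the light-use-efficiency model
#'
#' Hourly GPP as the product of light use efficiency, available and absorbed
#' photosynthetically active radiation, a linear temperature/VPD scalar, and a
#' canopy water scalar from the land surface water index:
#'
#' \deqn{GPP = LUE \cdot nPAR \cdot fPAR \cdot (0.382\,T_{air} + 0.0905\,VPD
#'   + 17.72) \cdot \frac{1 + LSWI}{1 + LSWI_{max}}}
#'
#' The three regression coefficients are fixed model constants. The water
#' scalar equals 1 when LSWI is at its growing-season maximum. All arguments
#' are vectorised and recycled.
#'
#' @param LUE light use efficiency, umol CO2 per umol PPFD.
#' @param nPAR normalised PAR, dimensionless in \[0, 1\].
#' @param fPAR fraction of PAR absorbed by the canopy (from EVI), \[0, 1\].
#' @param T_air air temperature, degrees C.
#' @param VPD vapour pressure deficit, kPa.
#' @param LSWI land surface water index, dimensionless.
#' @param LSWI_max per-grid growing-season maximum of LSWI; `1 + LSWI_max`
#'   must be positive.
#' @return GPP in umol CO2 m-2 s-1.
#' @export
gpp_lue <- function(LUE, nPAR, fPAR, T_air, VPD, LSWI, LSWI_max) {
  if (any(nPAR < 0 | nPAR > 1)) stop("'nPAR' must lie in [0, 1]")
  if (any(fPAR < 0 | fPAR > 1)) stop("'fPAR' must lie in [0, 1]")
  if (any(1 + LSWI_max <= 0)) stop("'1 + LSWI_max' must be positive")
  LUE * nPAR * fPAR * (0.382 * T_air + 0.0905 * VPD + 17.72) *
    (1 + LSWI) / (1 + LSWI_max)
}

#' Ecosystem respiration from accumulated GPP and temperature
#'
#' Hourly ecosystem respiration driven by recent productivity (GPP
#' accumulated over the preceding 7 days) and a normalised temperature
#' response:
#'
#' \deqn{R_{eco} = (1 + 0.20\,GPP_{acc}) \cdot
#'   \exp\!\left(1.16\,\frac{T_{air}}{\max(T_{air})}\right)}
#'
#' Both coefficients are fixed model constants. Negative temperatures are
#' allowed (the exponent may be negative).
#'
#' @param GPP_acc GPP accumulated over the trailing 7 days, umol CO2 m-2 s-1
#'   (see [gpp_trailing_acc()]).
#' @param T_air air temperature, degrees C.
#' @param T_air_max period maximum of `T_air` (non-zero), the normaliser.
#' @return Ecosystem respiration in umol CO2 m-2 s-1.
#' @export
reco <- function(GPP_acc, T_air, T_air_max) {
  if (any(T_air_max == 0)) stop("'T_air_max' must be non-zero")
  (1 + 0.20 * GPP_acc) * exp(1.16 * T_air / T_air_max)
}

#' Trailing 7-day GPP accumulation
#'
#' Mean-preserving accumulation of an hourly GPP series over the trailing
#' `window_hours` values (the current hour and the preceding week by
#' default), i.e. a trailing mean so the result stays on the flux scale of
#' umol CO2 m-2 s-1. Leading positions with less than a full week of history
#' use whatever history is available.
#'
#' @param gpp hourly GPP series, umol CO2 m-2 s-1.
#' @param window_hours trailing window length in hours (default 7 days).
#' @return Series of the same length as `gpp`.
#' @export
gpp_trailing_acc <- function(gpp, window_hours = 7 * 24) {
  n <- length(gpp)
  if (n == 0) return(numeric(0))
  w <- min(as.integer(window_hours), n)
  cs <- cumsum(gpp)
  lag <- c(rep(0, w), cs[seq_len(n - w)])
  len <- pmin(seq_len(n), w)
  (cs - lag) / len
}

#' Integrate hourly fluxes to annual net ecosystem productivity
#'
#' NEP is GPP minus ecosystem respiration. Equal-length hourly series are
#' integrated over time and converted from umol CO2 m-2 s-1 to tC ha-1 yr-1
#' using 12 g C per mol CO2 and 10^4 m2 per ha: a flux of 1 umol CO2 m-2 s-1
#' sustained over a 365-day year integrates to 3.78432 tC ha-1 (leap years
#' follow from the actual hour count). Positive NEP is net carbon uptake;
#' negative NEP is net emission.
#'
#' @param gpp,reco hourly flux series of equal length, umol CO2 m-2 s-1.
#' @return Integrated NEP in tC ha-1 over the period covered by the series.
#' @export
annual_nep <- function(gpp, reco) {
  if (length(gpp) != length(reco))
    stop(sprintf("series length mismatch: gpp has %d values, reco has %d",
                 length(gpp), length(reco)))
  # umol m-2 s-1 over 1 h: 3600 s * 1e-6 mol * 12 g/mol = 0.0432 g C m-2,
  # and 1 g C m-2 = 0.01 tC ha-1
  sum((gpp - reco) * 3600 * 1e-6 * 12 * 0.01)
}
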