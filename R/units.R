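#' @keywords internal
R_GAS <- 8.314  # J mol-1 K-1

#' Convert gas-exchange units to the molar convention
#'
#' Harmonizes conductance/resistance and pressure readings from different
#' instruments to a single internal unit system (molar conductance,
#' mol m-2 s-1; pressure, kPa). Velocity-type conductances and resistances
#' are converted to molar units through the ideal-gas molar density of air,
#' `g_mol = g_vel * P / (R * T_K)`.
#'
#' Supported unit tags: `"mol_m2_s"`, `"mmol_m2_s"` (conductance);
#' `"m2_s_mol"` (molar resistance); `"m_s"`, `"cm_s"` (velocity conductance);
#' `"s_m"`, `"s_cm"` (velocity resistance); `"kpa"`, `"hpa"`, `"mbar"`
#' (pressure).
#'
#' @param value numeric vector to convert.
#' @param from,to unit tags (see Details).
#' @param temp air/leaf temperature, degrees C (needed for velocity <-> molar).
#' @param pressure air pressure, kPa (needed for velocity <-> molar).
#' @return numeric vector in `to` units.
#' @export
#' @examples
#' convert_units(250, "mmol_m2_s", "mol_m2_s")
#' convert_units(0.01, "m_s", "mol_m2_s", temp = 25, pressure = 101.325)
convert_units <- function(value, from, to, temp = NULL, pressure = NULL) {
  from <- tolower(from); to <- tolower(to)
  if (identical(from, to)) return(value)

  cond_units <- c("mol_m2_s", "mmol_m2_s", "m2_s_mol", "m_s", "cm_s", "s_m", "s_cm")
  pres_units <- c("kpa", "hpa", "mbar")

  if (from %in% pres_units && to %in% pres_units) {
    to_kpa <- c(kpa = 1, hpa = 0.1, mbar = 0.1)
    return(value * to_kpa[[from]] / to_kpa[[to]])
  }
  if (!(from %in% cond_units && to %in% cond_units)) {
    stop("unsupported unit conversion: ", from, " -> ", to, call. = FALSE)
  }

  mol_density <- function() {
    if (is.null(temp) || is.null(pressure)) {
      stop("velocity <-> molar conversion needs `temp` (C) and `pressure` (kPa)",
           call. = FALSE)
    }
    pressure * 1000 / (R_GAS * (temp + 273.15))  # mol m-3
  }
  # every conductance-type tag -> molar conductance, mol m-2 s-1
  to_mol <- function(v, u) {
    switch(u,
      mol_m2_s  = v,
      mmol_m2_s = v / 1000,
      m2_s_mol  = 1 / v,
      m_s       = v * mol_density(),
      cm_s      = (v / 100) * mol_density(),
      s_m       = mol_density() / v,
      s_cm      = mol_density() / (v * 100)
    )
  }
  from_mol <- function(v, u) {
    switch(u,
      mol_m2_s  = v,
      mmol_m2_s = v * 1000,
      m2_s_mol  = 1 / v,
      m_s       = v / mol_density(),
      cm_s      = 100 * v / mol_density(),
      s_m       = mol_density() / v,
      s_cm      = mol_density() / v / 100
    )
  }
  from_mol(to_mol(value, from), to)
}

#' Scaled vapor pressure deficit
#'
#' The dimensionless evaporative demand used throughout the model:
#' absolute leaf-surface VPD divided by air pressure.
#'
#' @param vpd_kpa vapor pressure deficit at the leaf surface, kPa.
#' @param p_kpa air pressure, kPa.
#' @return dimensionless `D = vpd / p`.
#' @export
#' @examples
#' scaled_vpd(0.3546, 101.325)
scaled_vpd <- function(vpd_kpa, p_kpa) {
  if (any(p_kpa <= 0)) stop("air pressure must be positive", call. = FALSE)
  if (any(vpd_kpa < 0)) stop("VPD must be non-negative", call. = FALSE)
  vpd_kpa / p_kpa
}

#' Saturation vapor pressure (Tetens)
#'
#' Tetens formula in Monteith's form,
#' `e_sat(T) = 0.61078 * exp(17.27 T / (T + 237.3))` kPa.
#'
#' @param temp_c temperature, degrees C.
#' @return saturation vapor pressure, kPa.
#' @export
saturation_vp <- function(temp_c) {
  0.61078 * exp(17.27 * temp_c / (temp_c + 237.3))
}

#' Relative humidity implied by a scaled VPD
#'
#' Inverts `D = VPD / P` to the relative humidity at a given temperature,
#' `RH = 1 - D * P / e_sat(T)`. Useful for translating the dimensionless
#' demand axis of response surfaces back into familiar humidity values
#' (e.g. D = 0.0035 at 30 C and sea level is about 91% RH).
#'
#' @param d scaled vapor pressure deficit, dimensionless.
#' @param temp_c temperature, degrees C (validity checked on [-10, 60]).
#' @param p_kpa air pressure, kPa.
#' @return relative humidity as a fraction in [0, 1]; values that would be
#'   negative (demand exceeding saturation) are clamped to 0 with a warning.
#' @export
#' @examples
#' relative_humidity_from_d(0.0035, temp_c = 30, p_kpa = 101.325)
relative_humidity_from_d <- function(d, temp_c, p_kpa = 101.325) {
  if (any(temp_c < -10 | temp_c > 60)) {
    stop("temp_c outside the supported range [-10, 60] C", call. = FALSE)
  }
  rh <- 1 - d * p_kpa / saturation_vp(temp_c)
  if (any(rh < 0)) {
    warning("computed relative humidity < 0; clamped to 0", call. = FALSE)
    rh <- pmax(rh, 0)
  }
  rh
}
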