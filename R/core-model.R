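# Deterministic ISE response model: Nikolsky-Eisenman forward curve,
# theoretical Nernstian slope, separate-solution-method selectivity, and
# molar <-> ppm unit conversions. All emf are in mV, concentrations in
# mol/L, logs base 10. Activity coefficients are treated as constant (the
# high ionic-strength extractant background) and absorbed into E0, so
# "activity" and "concentration" are used interchangeably downstream.

#' Physical constants used by the Nernstian slope
#'
#' @return Named list with the gas constant `R` (J mol^-1 K^-1) and the
#'   Faraday constant `F` (C mol^-1).
#' @export
physical_constants <- function() {
  list(R = 8.314, F = 96485)
}

#' Analyte specification
#'
#' Describes the primary ion an electrode responds to: its charge (sign
#' included), the molecular mass used for ppm conversion, and the working
#' temperature.
#'
#' @param name Ion label, e.g. `"NH4+"`.
#' @param charge Signed integer charge `z` (non-zero), e.g. `+1` for
#'   ammonium, `-1` for nitrate.
#' @param molecular_mass Molar mass of the ion in g/mol (> 0). The ion's own
#'   mass is used (NH4+ = 18.04, NO3- = 62.00), not a nitrogen-equivalent
#'   mass.
#' @param temperature Absolute temperature in K (> 0), default 298.15.
#' @return An object of class `analyte_spec`.
#' @export
analyte_spec <- function(name, charge, molecular_mass, temperature = 298.15) {
  charge <- as.integer(charge)
  if (is.na(charge) || charge == 0L) {
    stop("invalid analyte: charge must be a non-zero integer", call. = FALSE)
  }
  if (!is.finite(molecular_mass) || molecular_mass <= 0) {
    stop("invalid analyte: molecular_mass must be > 0", call. = FALSE)
  }
  if (!is.finite(temperature) || temperature <= 0) {
    stop("invalid analyte: temperature must be > 0 (kelvin)", call. = FALSE)
  }
  structure(
    list(name = name, charge = charge, molecular_mass = molecular_mass,
         temperature = temperature),
    class = "analyte_spec"
  )
}

#' Ammonium and nitrate analyte presets
#'
#' @param temperature Temperature in K.
#' @return An `analyte_spec`.
#' @export
#' @rdname analyte_presets
analyte_nh4 <- function(temperature = 298.15) {
  analyte_spec("NH4+", +1L, 18.04, temperature)
}

#' @export
#' @rdname analyte_presets
analyte_no3 <- function(temperature = 298.15) {
  analyte_spec("NO3-", -1L, 62.00, temperature)
}

#' Theoretical Nernstian slope
#'
#' The ideal response slope 2.303 R T / (z F), in mV per decade of activity.
#' The sign follows the ion charge: about +59.2 mV/decade for monovalent
#' cations at 25 C and -59.2 for monovalent anions.
#'
#' @param analyte An [analyte_spec()].
#' @param constants Physical constants, see [physical_constants()].
#' @return Slope in mV/decade (signed).
#' @export
theoretical_slope <- function(analyte, constants = physical_constants()) {
  stopifnot(inherits(analyte, "analyte_spec"))
  1000 * log(10) * constants$R * analyte$temperature /
    (analyte$charge * constants$F)
}

#' Summed interference background
#'
#' Collapses a set of interfering ions into the single background term of the
#' Nikolsky-Eisenman equation: sum over J of Kpot_IJ * a_J^(z_I/z_J), in
#' mol/L-equivalents of the primary ion. Only interferents whose charge has
#' the same sign as the primary ion contribute a meaningful term.
#'
#' @param interferents List of interferents; each a list with fields
#'   `activity` (mol/L, >= 0), `charge` (signed non-zero integer) and
#'   `selectivity` (Kpot_IJ, > 0).
#' @param z_i Charge of the primary ion.
#' @return Background level K_bg in mol/L. The empty list gives 0.
#' @export
interference_background <- function(interferents, z_i) {
  z_i <- as.integer(z_i)
  if (z_i == 0L) stop("invalid analyte: charge must be non-zero", call. = FALSE)
  if (length(interferents) == 0L) return(0)
  total <- 0
  for (j in interferents) {
    if (!is.finite(j$activity) || j$activity < 0) {
      stop("interferent activity must be >= 0", call. = FALSE)
    }
    zj <- as.integer(j$charge)
    if (zj == 0L) stop("interferent charge must be non-zero", call. = FALSE)
    if (sign(zj) != sign(z_i)) {
      stop("interferent charge sign must match the primary ion", call. = FALSE)
    }
    if (!is.finite(j$selectivity) || j$selectivity <= 0) {
      stop("selectivity coefficient must be > 0", call. = FALSE)
    }
    total <- total + j$selectivity * j$activity^(z_i / zj)
  }
  total
}

#' Single-electrode response parameters
#'
#' @param E0 Standard potential (mV).
#' @param slope Response slope (mV/decade); sign must match the analyte
#'   charge when one is supplied.
#' @param K_bg Summed interference background (mol/L, >= 0).
#' @param sigma Gaussian emf noise standard deviation (mV, >= 0).
#' @param electrode_id Optional identifier.
#' @return An object of class `electrode_params`.
#' @export
electrode_params <- function(E0, slope, K_bg = 0, sigma = 0,
                             electrode_id = "ISE1") {
  if (!is.finite(E0)) stop("E0 must be finite", call. = FALSE)
  if (!is.finite(slope) || slope == 0) stop("slope must be non-zero", call. = FALSE)
  if (!is.finite(K_bg) || K_bg < 0) stop("K_bg must be >= 0", call. = FALSE)
  if (!is.finite(sigma) || sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  structure(
    list(electrode_id = as.character(electrode_id), E0 = E0, slope = slope,
         K_bg = K_bg, sigma = sigma),
    class = "electrode_params"
  )
}

#' Nikolsky-Eisenman response
#'
#' Noise-free emf of an electrode at a given primary-ion level:
#' `E0 + S * log10(a + K_bg)`. The background term flattens the response as
#' the analyte level falls below K_bg; well above K_bg the curve is the pure
#' Nernstian line.
#'
#' @param params An [electrode_params()].
#' @param a Primary-ion concentration(s), mol/L, >= 0 (vectorised).
#' @return emf in mV.
#' @export
nikolsky_emf <- function(params, a) {
  stopifnot(inherits(params, "electrode_params"))
  if (any(!is.finite(a)) || any(a < 0)) {
    stop("concentration must be finite and >= 0", call. = FALSE)
  }
  arg <- a + params$K_bg
  if (any(arg <= 0)) {
    stop("undefined response: a + K_bg must be > 0", call. = FALSE)
  }
  params$E0 + params$slope * log10(arg)
}

#' Separate-solution-method selectivity coefficient
#'
#' log10 Kpot_IJ from emf readings of the same electrode in two single-ion
#' solutions (primary ion I, interferent J) at equal activity `a`:
#' `(E_J - E_I)/S + (1 - z_I/z_J) * log10(a)`.
#'
#' @param E_i,E_j emf (mV) in the pure I and pure J solutions.
#' @param a Common activity of the two solutions (mol/L, > 0).
#' @param z_i,z_j Signed charges of I and J.
#' @param slope Electrode slope S (mV/decade), non-zero.
#' @return log10 of the selectivity coefficient.
#' @export
ssm_selectivity <- function(E_i, E_j, a, z_i, z_j, slope) {
  if (!is.finite(slope) || slope == 0) {
    stop("degenerate slope: S must be non-zero", call. = FALSE)
  }
  if (!is.finite(a) || a <= 0) stop("activity must be > 0", call. = FALSE)
  z_i <- as.integer(z_i); z_j <- as.integer(z_j)
  if (z_i == 0L || z_j == 0L) stop("charges must be non-zero", call. = FALSE)
  (E_j - E_i) / slope + (1 - z_i / z_j) * log10(a)
}

#' Convert mol/L to ppm (mg/L) and back
#'
#' ppm here means mg of the ion per litre: `c * M * 1000` with M the ion's
#' molar mass in g/mol.
#'
#' @param c Concentration in mol/L (>= 0, vectorised).
#' @param analyte An [analyte_spec()] carrying the molecular mass.
#' @return Concentration in ppm (mg/L).
#' @export
molar_to_ppm <- function(c, analyte) {
  stopifnot(inherits(analyte, "analyte_spec"))
  if (any(!is.finite(c)) || any(c < 0)) {
    stop("concentration must be finite and >= 0", call. = FALSE)
  }
  c * analyte$molecular_mass * 1000
}

#' @param ppm Concentration in ppm (mg/L, >= 0).
#' @export
#' @rdname molar_to_ppm
ppm_to_molar <- function(ppm, analyte) {
  stopifnot(inherits(analyte, "analyte_spec"))
  if (any(!is.finite(ppm)) || any(ppm < 0)) {
    stop("concentration must be finite and >= 0", call. = FALSE)
  }
  ppm / (analyte$molecular_mass * 1000)
}

#' Round a detection limit for display
#'
#' Detection and quantification limits in ppm are conventionally reported at
#' one significant figure.
#'
#' @param x Positive value(s).
#' @param digits Significant digits (default 1).
#' @return Rounded value(s).
#' @export
signif_limit <- function(x, digits = 1) signif(x, digits)
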