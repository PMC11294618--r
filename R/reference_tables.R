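#' Equivalent weights of the major ions
#'
#' Molar mass divided by absolute ionic charge (g/eq), used to convert
#' mg/L to meq/L. IUPAC 2021 atomic masses; SO4 and CO3 use |charge| = 2.
#'
#' @return Named numeric vector of equivalent weights (g/eq) for
#'   Ca, Mg, Na, K, Cl, SO4, HCO3, CO3 and NO3.
#' @export
#' @examples
#' equivalent_weights()[["Ca"]]  # 20.04: 20.04 mg/L Ca2+ is 1 meq/L
equivalent_weights <- function() {
  c(
    Ca   = 40.078 / 2,
    Mg   = 24.305 / 2,
    Na   = 22.990 / 1,
    K    = 39.098 / 1,
    Cl   = 35.450 / 1,
    SO4  = 96.060 / 2,
    HCO3 = 61.016 / 1,
    CO3  = 60.008 / 2,
    NO3  = 62.004 / 1
  )
}

#' Ions counted as cations / anions in the charge balance
#' @name ion_sets
#' @return Character vector of analyte names.
#' @export
cation_names <- function() c("Ca", "Mg", "Na", "K")

#' @rdname ion_sets
#' @export
anion_names <- function() c("Cl", "SO4", "HCO3", "CO3", "NO3")

#' Drinking-water standards and published integrated weights
#'
#' Per-parameter WHO (2011) standard value Sj, ideal (pure-water) value
#' Cjp -- zero for every parameter except pH, whose ideal is 7 -- and the
#' published integrated weight Wj for the 14 parameters entering the
#' integrated-weight water quality index. The published weights sum to 1.
#'
#' @return Data frame with columns `parameter`, `unit`, `Cjp`, `Sj`, `Wj`.
#' @export
#' @examples
#' sum(standards_table()$Wj)  # 1
standards_table <- function() {
  data.frame(
    parameter = c("TDS", "pH", "EC", "Na", "K", "Mg", "Ca", "Mn", "Fe",
                  "Cl", "SO4", "HCO3", "NO3", "TH"),
    unit = c("mg/L", "-", "uS/cm", "mg/L", "mg/L", "mg/L", "mg/L", "mg/L",
             "mg/L", "mg/L", "mg/L", "mg/L", "mg/L", "mg/L"),
    Cjp = c(0, 7, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0),
    Sj  = c(1000, 7.5, 1500, 400, 12, 150, 200, 0.1, 0.3,
            600, 400, 200, 45, 500),
    Wj  = c(0.045074, 0.045624, 0.043698, 0.047656, 0.070666, 0.046403,
            0.047419, 0.250271, 0.100279, 0.050539, 0.047423, 0.054388,
            0.11145, 0.03911),
    stringsAsFactors = FALSE
  )
}

#' Toxicological constants for the potentially toxic elements
#'
#' Packaged defaults for Fe, Mn, Cr and Pb; every value can be overridden
#' by passing a modified copy of this table to the index functions.
#'
#' * `Si`: drinking-water standard (mg/L), WHO 2011 -- also the HPI unit
#'   weight denominator (wi = 1/Si).
#' * `HAL`: highest allowable limit (mg/L) for the heavy-metal index.
#' * `Tr`: Hakanson toxic-response factor (dimensionless).
#' * `c_bg`: background concentration (mg/L). No site-specific background
#'   survey is packaged; the drinking-water limit is used as the default
#'   reference level (synthetic stand-in, overridable).
#' * `RfD_oral`: oral reference dose (mg/kg/day), USEPA IRIS lineage.
#' * `ABS`: gastrointestinal/dermal absorption fraction used to derive
#'   RfD_dermal = RfD_oral * ABS.
#' * `Kp`: skin permeability coefficient (cm/h), USEPA RAGS Part E.
#' * `CSF`: oral cancer slope factor (per mg/kg/day); NA for the
#'   non-carcinogens Fe and Mn.
#'
#' @return Data frame keyed by `metal`.
#' @export
toxicology_table <- function() {
  data.frame(
    metal    = c("Fe", "Mn", "Cr", "Pb"),
    Si       = c(0.3, 0.1, 0.05, 0.01),
    HAL      = c(0.3, 0.1, 0.05, 0.01),
    Tr       = c(1, 1, 2, 5),
    c_bg     = c(0.3, 0.1, 0.05, 0.01),
    RfD_oral = c(0.7, 0.024, 0.003, 0.0014),
    ABS      = c(1, 0.04, 0.025, 1),
    Kp       = c(1e-3, 1e-3, 2e-3, 1e-4),
    CSF      = c(NA, NA, 0.5, 0.0085),
    stringsAsFactors = FALSE
  )
}

#' Receptor exposure profiles
#'
#' Fixed exposure constants for the two receptor groups used throughout
#' the chronic-daily-intake formulas. Averaging time follows the USEPA
#' convention: AT = ED * 365 days for non-carcinogenic effects and
#' 70 * 365 days (lifetime) for carcinogenic effects.
#'
#' @param group `"adult"` or `"child"`.
#' @return Named list: `IR` water intake (L/day), `ED` exposure duration
#'   (years), `EF` exposure frequency (days/year), `ET` exposure time for
#'   dermal contact (h/day), `SA` skin surface area (cm2), `CF` volume
#'   conversion factor (L/cm3), `BW` body weight (kg), `AT_nc` and `AT_ca`
#'   averaging times (days).
#' @export
#' @examples
#' exposure_profile("child")$IR  # 1.8 L/day
exposure_profile <- function(group = c("adult", "child")) {
  group <- match.arg(group)
  p <- switch(group,
    adult = list(IR = 2.2, ED = 70, EF = 350, ET = 0.58, SA = 18000,
                 BW = 70),
    child = list(IR = 1.8, ED = 6, EF = 350, ET = 1, SA = 6600,
                 BW = 15)
  )
  p$CF <- 1e-3
  p$AT_nc <- p$ED * 365
  p$AT_ca <- 70 * 365
  p$group <- group
  p
}

#' Mineral systems for saturation-index calculation
#'
#' Dissolution reactions and log10 equilibrium constants at 25 C
#' (phreeqc.dat lineage compilation) for the four minerals relevant to a
#' carbonate/evaporite aquifer. The carbonate minerals are written in
#' terms of CO3(2-), whose activity is derived from bicarbonate and pH
#' via the second dissociation constant of carbonic acid
#' (log K2 = -10.329 at 25 C).
#'
#' @return Named list of mineral systems; each has `ions` (stoichiometric
#'   coefficients of dissolved products) and `log_K`.
#' @export
mineral_systems <- function() {
  list(
    calcite  = list(ions = c(Ca = 1, CO3 = 1),         log_K = -8.48),
    dolomite = list(ions = c(Ca = 1, Mg = 1, CO3 = 2), log_K = -17.09),
    gypsum   = list(ions = c(Ca = 1, SO4 = 1),         log_K = -4.58),
    halite   = list(ions = c(Na = 1, Cl = 1),          log_K = 1.570)
  )
}

#' Survey-structure targets for the synthetic-sample generator
#'
#' Per-analyte (min, max, mean) targets describing the statistical
#' structure of the 45-well survey the generator emulates: bulk
#' physicochemical parameters and major ions in mg/L (pH unitless, EC in
#' uS/cm, temperature in C, turbidity in NTU) plus the four potentially
#' toxic elements.
#'
#' @return Data frame with columns `analyte`, `min`, `max`, `mean`, `unit`.
#' @export
survey_targets <- function() {
  data.frame(
    analyte = c("Temp", "pH", "Turbidity", "TH", "EC", "TDS", "Ca", "Mg",
                "Na", "K", "Cl", "SO4", "HCO3", "NO3", "Fe", "Mn", "Cr",
                "Pb"),
    min  = c(13.9, 7, 0.074, 830, 2640, 1702, 168, 24.31, 210, 12,
             560, 532, 106, 0.83, 0.001, 0.003, 0.001, 0.001),
    max  = c(38.8, 7.9, 11.5, 1350, 4360, 2790, 341, 157.98, 540, 42,
             1127, 840, 195, 31.54, 3.61, 0.631, 0.031, 0.039),
    mean = c(26.66, 7.45, 1.71, 1097.45, 3646, 2343, 259, 110, 364, 33.30,
             822.25, 697.53, 135.50, 15.82, 0.713, 0.265, 0.012, 0.019),
    unit = c("C", "-", "NTU", "mg/L", "uS/cm", "mg/L", "mg/L", "mg/L",
             "mg/L", "mg/L", "mg/L", "mg/L", "mg/L", "mg/L", "mg/L",
             "mg/L", "mg/L", "mg/L"),
    stringsAsFactors = FALSE
  )
}
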