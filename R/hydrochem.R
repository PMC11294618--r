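#' Chloro-alkaline indices (CAI-I, CAI-II)
#'
#' Indicators of the direction of cation exchange between groundwater and
#' the aquifer matrix, computed from meq/L concentrations:
#'
#' * `CAI_I  = (Cl - (Na + K)) / Cl`
#' * `CAI_II = (Cl - (Na + K)) / (SO4 + HCO3 + CO3 + NO3)`
#'
#' Positive values indicate reverse ion exchange (Ca/Mg in the rock
#' replaced by Na/K from the water); negative values indicate direct
#' exchange. A zero denominator makes that index `NA` (undefined) for the
#' sample; CO3 is taken as 0 when absent.
#'
#' @param ions Data frame of meq/L values ([to_meq()] output).
#' @return Data frame with columns `CAI_I`, `CAI_II` (and `sample_id` when
#'   present).
#' @export
#' @examples
#' cai_indices(data.frame(Cl = 10, Na = 4, K = 0, SO4 = 5,
#'                        HCO3 = 1, NO3 = 0))  # CAI_I = 0.6, CAI_II = 1
cai_indices <- function(ions) {
  co3 <- if ("CO3" %in% names(ions)) ions$CO3 else 0
  k <- if ("K" %in% names(ions)) ions$K else 0
  num <- ions$Cl - (ions$Na + k)
  den2 <- ions$SO4 + ions$HCO3 + co3 + ions$NO3
  cai1 <- ifelse(ions$Cl > 0, num / ions$Cl, NA_real_)
  cai2 <- ifelse(den2 > 0, num / den2, NA_real_)
  out <- data.frame(CAI_I = cai1, CAI_II = cai2)
  if ("sample_id" %in% names(ions)) {
    out <- cbind(sample_id = ions$sample_id, out)
  }
  out
}

#' Milliequivalent percentages for the Piper triangles
#'
#' @param ions Data frame of meq/L values.
#' @return Data frame of percentages: cation triangle (`pct_Ca`, `pct_Mg`,
#'   `pct_NaK`) and anion triangle (`pct_Cl`, `pct_SO4`, `pct_HCO3CO3`);
#'   each triangle sums to 100.
#' @export
piper_percentages <- function(ions) {
  k <- if ("K" %in% names(ions)) ions$K else 0
  co3 <- if ("CO3" %in% names(ions)) ions$CO3 else 0
  cat_tot <- ions$Ca + ions$Mg + ions$Na + k
  an_tot <- ions$Cl + ions$SO4 + ions$HCO3 + co3
  if (any(cat_tot == 0) || any(an_tot == 0)) {
    stop("Piper percentages undefined: zero total cations or anions")
  }
  data.frame(
    pct_Ca = 100 * ions$Ca / cat_tot,
    pct_Mg = 100 * ions$Mg / cat_tot,
    pct_NaK = 100 * (ions$Na + k) / cat_tot,
    pct_Cl = 100 * ions$Cl / an_tot,
    pct_SO4 = 100 * ions$SO4 / an_tot,
    pct_HCO3CO3 = 100 * (ions$HCO3 + co3) / an_tot
  )
}

#' Piper diamond facies classification
#'
#' Assigns each sample to a hydrochemical facies from its milliequivalent
#' percentages. Field-membership thresholds (diamond of the trilinear
#' diagram), applied in order:
#'
#' 1. weak acids (HCO3 + CO3) > 50% of anions -> `"other"`
#'    (bicarbonate-type water, not a facies of this saline system);
#' 2. alkalis (Na + K) > 50% of cations and Cl >= 50% of anions ->
#'    `"Na-Cl"`;
#' 3. alkaline earths (Ca + Mg) >= 50% of cations and SO4 >= 50% of
#'    anions -> `"Ca-Mg-SO4"`;
#' 4. alkaline earths >= 50% and strong acids (Cl + SO4) >= 50% with no
#'    single dominant anion -> `"mixed Ca-Mg-Cl/SO4"`;
#' 5. anything else -> `"other"`.
#'
#' @param ions Data frame of meq/L values.
#' @return Character vector of facies labels.
#' @export
piper_facies <- function(ions) {
  p <- piper_percentages(ions)
  strong <- p$pct_Cl + p$pct_SO4
  lab <- rep("other", nrow(p))
  mixed <- p$pct_NaK <= 50 & strong >= 50
  lab[mixed] <- "mixed Ca-Mg-Cl/SO4"
  lab[p$pct_NaK <= 50 & p$pct_SO4 >= 50] <- "Ca-Mg-SO4"
  lab[p$pct_NaK > 50 & p$pct_Cl >= 50] <- "Na-Cl"
  lab[p$pct_HCO3CO3 > 50] <- "other"
  lab
}

#' Gibbs ratios and mechanism zone
#'
#' Computes the two Gibbs ratios -- `Na/(Na+Ca)` (cations) and
#' `Cl/(Cl+HCO3)` (anions), both on mg/L as in the original
#' weight-based formulation -- against TDS and assigns the
#' controlling mechanism. Zone boundaries (documented approximation of the
#' published boomerang envelopes): evaporation/crystallisation when
#' TDS >= 300 mg/L and ratio >= 0.5; atmospheric precipitation when
#' TDS <= 100 mg/L and ratio >= 0.5; rock dominance otherwise. The zone is
#' assigned per ratio and agrees for typical waters.
#'
#' @param samples A `water_samples` table in mg/L with TDS, Na, Ca, Cl,
#'   HCO3 columns.
#' @return Data frame: `TDS`, `cation_ratio`, `anion_ratio`,
#'   `gibbs_zone_cation`, `gibbs_zone_anion`.
#' @export
gibbs_ratios <- function(samples) {
  dc <- samples$Na + samples$Ca
  da <- samples$Cl + samples$HCO3
  if (any(dc == 0) || any(da == 0)) {
    stop("Gibbs ratios undefined: zero denominator")
  }
  rc <- samples$Na / dc
  ra <- samples$Cl / da
  zone <- function(tds, r) {
    ifelse(r >= 0.5 & tds >= 300, "evaporation",
           ifelse(r >= 0.5 & tds <= 100, "precipitation", "rock-dominance"))
  }
  data.frame(
    TDS = samples$TDS,
    cation_ratio = rc,
    anion_ratio = ra,
    gibbs_zone_cation = zone(samples$TDS, rc),
    gibbs_zone_anion = zone(samples$TDS, ra)
  )
}

#' Sulin classification of groundwater origin
#'
#' Classifies samples by the genetic coefficients `Cl - (Na + K)` and
#' `(Cl - (Na + K)) / Mg` in meq/L:
#'
#' * `Cl - (Na+K) <= 0` (alkali excess; ties break to the meteoric
#'   branch): `(Na + K - Cl)/SO4 > 1` -> `"deep meteoric"` (NaHCO3 type),
#'   otherwise `"shallow meteoric"` (Na2SO4 type);
#' * `Cl - (Na+K) > 0` (chloride excess, marine branch):
#'   `(Cl - (Na+K))/Mg < 1` -> `"recent marine"` (MgCl2 type),
#'   otherwise `"old marine"` (CaCl2 type).
#'
#' @param ions Data frame of meq/L values.
#' @return Character vector of origin labels.
#' @export
sulin_classification <- function(ions) {
  k <- if ("K" %in% names(ions)) ions$K else 0
  excess <- ions$Cl - (ions$Na + k)
  n <- length(excess)
  lab <- character(n)
  for (i in seq_len(n)) {
    if (excess[i] <= 0) {
      r <- if (ions$SO4[i] > 0) -excess[i] / ions$SO4[i] else Inf
      lab[i] <- if (r > 1) "deep meteoric" else "shallow meteoric"
    } else {
      if (ions$Mg[i] == 0) {
        stop("Sulin ratio undefined: Mg = 0 with chloride excess")
      }
      r <- excess[i] / ions$Mg[i]
      lab[i] <- if (r < 1) "recent marine" else "old marine"
    }
  }
  lab
}

#' Ionic strength of a major-ion water (mol/L)
#'
#' `I = 0.5 * sum(c_i * z_i^2)` over the major ions, with molar
#' concentrations derived from meq/L (c = meq / |z| / 1000).
#'
#' @param ions Data frame of meq/L values.
#' @return Numeric vector of ionic strengths.
#' @export
ionic_strength <- function(ions) {
  z <- c(Ca = 2, Mg = 2, Na = 1, K = 1, Cl = 1, SO4 = 2, HCO3 = 1,
         CO3 = 2, NO3 = 1)
  present <- intersect(names(z), names(ions))
  acc <- 0
  for (ion in present) {
    molar <- ions[[ion]] / z[[ion]] / 1000
    acc <- acc + molar * z[[ion]]^2
  }
  0.5 * acc
}

#' Davies-equation activity coefficient
#'
#' `log10(gamma) = -A * z^2 * (sqrt(I)/(1 + sqrt(I)) - 0.3 * I)` with
#' A = 0.5092 at 25 C. Adequate to I ~ 0.5 mol/L, comfortably covering
#' brackish waters (TDS < 3 g/L has I < 0.1).
#'
#' @param I Ionic strength (mol/L).
#' @param z Ionic charge.
#' @return Activity coefficient gamma (dimensionless).
#' @export
davies_gamma <- function(I, z) {
  sq <- sqrt(I)
  10^(-0.5092 * z^2 * (sq / (1 + sq) - 0.3 * I))
}

#' Mineral saturation index SI = log10(IAP / Ksp)
#'
#' Simplified speciation at 25 C: free-ion molarities from the analysed
#' major ions, Davies activity coefficients, and carbonate activity
#' derived from bicarbonate and pH through the second carbonic-acid
#' dissociation (log K2 = -10.329). SI > 0 means the water is
#' supersaturated with the mineral (tends to precipitate it), SI < 0
#' undersaturated (can dissolve more), SI = 0 equilibrium. A zero activity
#' of any recipe ion yields `-Inf` (reported undersaturated). Temperature
#' correction of log K is not applied (documented limitation versus a full
#' speciation code).
#'
#' @param ions Data frame of meq/L values.
#' @param pH Sample pH (vector recycled to rows of `ions`).
#' @param minerals Subset of `names(mineral_systems())`.
#' @return Data frame of SI values, one column per mineral.
#' @export
#' @examples
#' si <- saturation_index(to_meq(worked_fixture()[1, ]), pH = 7.45)
saturation_index <- function(ions, pH,
                             minerals = names(mineral_systems())) {
  sys <- mineral_systems()[minerals]
  z <- c(Ca = 2, Mg = 2, Na = 1, K = 1, Cl = 1, SO4 = 2, HCO3 = 1,
         CO3 = 2, NO3 = 1)
  I <- ionic_strength(ions)
  n <- if (is.data.frame(ions)) nrow(ions) else length(I)
  pH <- rep_len(pH, n)
  activity <- function(ion) {
    meq <- if (ion %in% names(ions)) ions[[ion]] else rep(0, n)
    molar <- meq / z[[ion]] / 1000
    molar * davies_gamma(I, z[[ion]])
  }
  # carbonate from bicarbonate + pH; measured CO3 (rare) is ignored in
  # favour of the equilibrium value so that pH sensitivity is retained
  a_co3 <- activity("HCO3") * 10^(-10.329 + pH)
  out <- data.frame(row.names = seq_len(n))
  for (m in names(sys)) {
    log_iap <- rep(0, n)
    for (ion in names(sys[[m]]$ions)) {
      a <- if (ion == "CO3") a_co3 else activity(ion)
      log_iap <- log_iap + sys[[m]]$ions[[ion]] * log10(a)
    }
    out[[m]] <- log_iap - sys[[m]]$log_K
  }
  out
}

#' Full hydrochemical classification of a sample table
#'
#' Convenience wrapper running [cai_indices()], [piper_facies()],
#' [gibbs_ratios()], [sulin_classification()] and [saturation_index()] on
#' a mg/L sample table.
#'
#' @param samples A `water_samples` table.
#' @return Data frame keyed by `sample_id` with one column per result.
#' @export
classify_hydrochem <- function(samples) {
  ions <- to_meq(samples)
  gib <- gibbs_ratios(samples)
  si <- saturation_index(ions, pH = samples$pH)
  names(si) <- paste0("SI_", names(si))
  cai <- cai_indices(ions)
  cai <- cai[, c("CAI_I", "CAI_II"), drop = FALSE]
  data.frame(
    sample_id = samples$sample_id,
    cbe = charge_balance_error(ions),
    piper_facies = piper_facies(ions),
    gibbs_zone = gib$gibbs_zone_cation,
    cation_ratio = gib$cation_ratio,
    anion_ratio = gib$anion_ratio,
    sulin_origin = sulin_classification(ions),
    cai, si
  )
}
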