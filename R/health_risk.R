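#' Chronic daily intake by ingestion of drinking water
#'
#' `CDI_oral = C * EF * IR * ED / (AT * BW)` in mg/kg/day, where C is the
#' metal concentration (mg/L), EF the exposure frequency (days/year), IR
#' the intake rate (L/day), ED the exposure duration (years), AT the
#' averaging time (days) and BW the body weight (kg). AT is ED * 365 for
#' the non-carcinogenic horizon and 70 * 365 (lifetime) for the
#' carcinogenic horizon.
#'
#' @param C Concentration in mg/L (vectorised).
#' @param profile Receptor profile from [exposure_profile()].
#' @param horizon `"noncarcinogenic"` (default) or `"carcinogenic"`.
#' @return CDI in mg/kg/day.
#' @export
#' @examples
#' cdi_oral(3.61, exposure_profile("adult"))  # 0.1088
cdi_oral <- function(C, profile,
                     horizon = c("noncarcinogenic", "carcinogenic")) {
  horizon <- match.arg(horizon)
  AT <- if (horizon == "carcinogenic") profile$AT_ca else profile$AT_nc
  if (any(profile$BW <= 0) || any(AT <= 0)) {
    stop("BW and AT must be positive")
  }
  C * profile$EF * profile$IR * profile$ED / (AT * profile$BW)
}

#' Chronic daily intake by dermal contact
#'
#' `CDI_dermal = C * ET * EF * Kp * SA * CF * ED / (BW * AT)` in
#' mg/kg/day, with ET the exposure time (h/day), Kp the skin permeability
#' coefficient (cm/h), SA the exposed skin area (cm2) and CF the volume
#' conversion (1e-3 L/cm3).
#'
#' @param C Concentration in mg/L.
#' @param profile Receptor profile.
#' @param Kp Skin permeability coefficient (cm/h).
#' @param horizon Averaging-time horizon as in [cdi_oral()].
#' @return CDI in mg/kg/day.
#' @export
cdi_dermal <- function(C, profile, Kp,
                       horizon = c("noncarcinogenic", "carcinogenic")) {
  horizon <- match.arg(horizon)
  if (is.na(Kp) || Kp <= 0) stop("Kp must be positive")
  AT <- if (horizon == "carcinogenic") profile$AT_ca else profile$AT_nc
  C * profile$ET * profile$EF * Kp * profile$SA * profile$CF *
    profile$ED / (profile$BW * AT)
}

#' Hazard quotient HQ = CDI / RfD
#'
#' For the dermal route the reference dose is adjusted for absorption:
#' `RfD_dermal = RfD_oral * ABS`. HQ > 1 flags potential non-carcinogenic
#' concern.
#'
#' @param CDI Chronic daily intake (mg/kg/day).
#' @param RfD_oral Oral reference dose (mg/kg/day).
#' @param route `"oral"` or `"dermal"`.
#' @param ABS Absorption fraction (required for the dermal route).
#' @return HQ (dimensionless).
#' @export
hazard_quotient <- function(CDI, RfD_oral, route = c("oral", "dermal"),
                            ABS = 1) {
  route <- match.arg(route)
  if (is.na(RfD_oral) || RfD_oral <= 0) stop("RfD must be positive")
  rfd <- if (route == "dermal") RfD_oral * ABS else RfD_oral
  CDI / rfd
}

#' Hazard index: sum of hazard quotients
#'
#' Primary mode (`combine_routes = FALSE`): HQ summed over metals within
#' one route, giving per-route HI -- the form in which multi-metal
#' drinking-water risk is usually reported. With `combine_routes = TRUE`
#' the oral and dermal HI are additionally summed.
#'
#' @param hq Data frame with columns `route` and `HQ` (and anything
#'   else, e.g. `metal`), typically a subset of [health_risk()] output
#'   for one sample and group.
#' @param combine_routes Sum over routes as well.
#' @return Data frame with `route` (or `"combined"`) and `HI`.
#' @export
hazard_index <- function(hq, combine_routes = FALSE) {
  if (!nrow(hq)) stop("need at least one HQ")
  agg <- stats::aggregate(HQ ~ route, data = hq, FUN = sum)
  names(agg)[2] <- "HI"
  if (combine_routes) {
    agg <- data.frame(route = "combined", HI = sum(agg$HI))
  }
  agg
}

#' Carcinogenic risk CR = CDI * CSF
#'
#' Computed with the lifetime averaging time; the conventional
#' acceptability band is 1e-6 to 1e-4.
#'
#' @param CDI Chronic daily intake at the carcinogenic horizon.
#' @param CSF Cancer slope factor (per mg/kg/day).
#' @return CR (dimensionless).
#' @export
cancer_risk <- function(CDI, CSF) {
  if (any(is.na(CSF)) || any(CSF <= 0)) stop("CSF must be positive")
  CDI * CSF
}

#' Deterministic health-risk table for a sample set
#'
#' Runs the full USEPA chain -- CDI (oral and dermal), HQ, per-route HI
#' and CR for the carcinogens -- for every sample, metal, route and
#' receptor group.
#'
#' @param samples A `water_samples` table (mg/L).
#' @param metals Metals to assess.
#' @param groups Receptor groups.
#' @param routes Exposure routes.
#' @param tox Toxicology table.
#' @return List with `hq` (sample x metal x route x group rows: CDI, HQ,
#'   CR where applicable), and `hi` (per sample x route x group).
#' @export
health_risk <- function(samples, metals = c("Fe", "Mn", "Cr", "Pb"),
                        groups = c("adult", "child"),
                        routes = c("oral", "dermal"),
                        tox = toxicology_table()) {
  tox <- tox[match(metals, tox$metal), ]
  if (anyNA(tox$metal)) stop("metal(s) missing from toxicology table")
  rows <- list()
  for (g in groups) {
    prof <- exposure_profile(g)
    for (k in seq_along(metals)) {
      C <- samples[[metals[k]]]
      for (rt in routes) {
        cdi_nc <- if (rt == "oral") cdi_oral(C, prof) else
          cdi_dermal(C, prof, tox$Kp[k])
        hq <- hazard_quotient(cdi_nc, tox$RfD_oral[k], route = rt,
                              ABS = tox$ABS[k])
        cr <- rep(NA_real_, length(C))
        if (!is.na(tox$CSF[k])) {
          cdi_ca <- if (rt == "oral") {
            cdi_oral(C, prof, horizon = "carcinogenic")
          } else {
            cdi_dermal(C, prof, tox$Kp[k], horizon = "carcinogenic")
          }
          cr <- cancer_risk(cdi_ca, tox$CSF[k])
        }
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = samples$sample_id, group = g, metal = metals[k],
          route = rt, CDI = cdi_nc, HQ = hq, CR = cr
        )
      }
    }
  }
  hq_tab <- do.call(rbind, rows)
  hi_tab <- stats::aggregate(HQ ~ sample_id + group + route,
                             data = hq_tab, FUN = sum)
  names(hi_tab)[4] <- "HI"
  list(hq = hq_tab, hi = hi_tab)
}
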