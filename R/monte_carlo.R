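#' Distribution specification for Monte Carlo inputs
#'
#' A light container describing how one input variable is sampled.
#' Families and their parameters:
#'
#' * `point`: `value` -- degenerate mass (any variable may be fixed);
#' * `normal`: `mean`, `sd` -- negative draws are rejected and redrawn
#'   (an error is raised if more than half the draws are rejected,
#'   suggesting explicit truncation bounds);
#' * `truncnorm`: `mean`, `sd`, `lower`, `upper` -- drawn by inverse CDF;
#' * `lognormal`: `meanlog`, `sdlog`;
#' * `uniform`: `min`, `max`;
#' * `empirical`: `values` -- bootstrap resampling of an observed vector.
#'
#' @param family Distribution family (see above).
#' @param ... Family parameters.
#' @return Object of class `dist_spec`.
#' @export
#' @examples
#' draw_spec(dist_spec("uniform", min = 0, max = 1), 5)
dist_spec <- function(family = c("point", "normal", "truncnorm",
                                 "lognormal", "uniform", "empirical"),
                      ...) {
  family <- match.arg(family)
  par <- list(...)
  need <- switch(family,
    point = "value", normal = c("mean", "sd"),
    truncnorm = c("mean", "sd", "lower", "upper"),
    lognormal = c("meanlog", "sdlog"), uniform = c("min", "max"),
    empirical = "values")
  missing <- setdiff(need, names(par))
  if (length(missing)) {
    stop("dist_spec(", family, ") needs parameter(s): ",
         paste(missing, collapse = ", "))
  }
  if (family == "truncnorm" && par$lower >= par$upper) {
    stop("truncation bounds must satisfy lower < upper")
  }
  structure(list(family = family, par = par), class = "dist_spec")
}

#' Draw from a distribution specification
#'
#' @param spec A [dist_spec()].
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
draw_spec <- function(spec, n) {
  stopifnot(inherits(spec, "dist_spec"))
  p <- spec$par
  switch(spec$family,
    point = rep(p$value, n),
    normal = {
      x <- stats::rnorm(n, p$mean, p$sd)
      rejected <- 0L
      while (any(x < 0)) {
        bad <- which(x < 0)
        rejected <- rejected + length(bad)
        if (rejected > n / 2) {
          stop("rejection rate above 50% for normal variable; ",
               "use a truncnorm spec with explicit bounds")
        }
        x[bad] <- stats::rnorm(length(bad), p$mean, p$sd)
      }
      x
    },
    truncnorm = {
      lo <- stats::pnorm(p$lower, p$mean, p$sd)
      hi <- stats::pnorm(p$upper, p$mean, p$sd)
      stats::qnorm(stats::runif(n, lo, hi), p$mean, p$sd)
    },
    lognormal = stats::rlnorm(n, p$meanlog, p$sdlog),
    uniform = stats::runif(n, p$min, p$max),
    empirical = sample(p$values, n, replace = TRUE)
  )
}

#' Default exposure-factor specifications for a receptor group
#'
#' The behavioural factors (IR, ED, ET, SA, BW) are modelled as
#' truncated-normal distributions centred on the deterministic point
#' values with coefficient of variation `cv`, truncated at +/- 3 sd and
#' at zero; EF and CF are kept as point masses. Setting `cv = 0` makes
#' every factor a point mass (the deterministic limit).
#'
#' @param group `"adult"` or `"child"`.
#' @param cv Coefficient of variation of the varying factors
#'   (default 0.2).
#' @return Named list of [dist_spec()] objects for IR, ED, EF, ET, SA,
#'   CF, BW.
#' @export
exposure_factor_specs <- function(group, cv = 0.2) {
  prof <- exposure_profile(group)
  tn <- function(m) {
    if (cv == 0) return(dist_spec("point", value = m))
    s <- cv * m
    dist_spec("truncnorm", mean = m, sd = s,
              lower = max(0, m - 3 * s), upper = m + 3 * s)
  }
  list(
    IR = tn(prof$IR), ED = tn(prof$ED),
    EF = dist_spec("point", value = prof$EF),
    ET = tn(prof$ET), SA = tn(prof$SA),
    CF = dist_spec("point", value = prof$CF),
    BW = tn(prof$BW)
  )
}

#' Fit a concentration distribution from observed samples
#'
#' Default: lognormal by moment matching -- `sdlog^2 = log(1 + s^2/m^2)`,
#' `meanlog = log(m) - sdlog^2 / 2` -- which reproduces the sample mean
#' in expectation. Alternatives: `empirical` (bootstrap of the observed
#' vector) and `point` (at the sample mean). A constant column always
#' yields a point spec; nonpositive values under the lognormal family are
#' raised to a small epsilon with a warning.
#'
#' @param samples A `water_samples` table.
#' @param metal Analyte column to fit.
#' @param family `"lognormal"`, `"empirical"` or `"point"`.
#' @param eps Replacement for nonpositive values (lognormal only).
#' @return A [dist_spec()] with attribute `"metal"`.
#' @export
calibrate_concentration_spec <- function(samples, metal,
                                         family = c("lognormal",
                                                    "empirical", "point"),
                                         eps = 1e-6) {
  family <- match.arg(family)
  v <- samples[[metal]]
  if (length(v) < 3) stop("need at least 3 observations to calibrate")
  spec <- if (stats::sd(v) == 0) {
    dist_spec("point", value = v[1])
  } else if (family == "lognormal") {
    if (any(v <= 0)) {
      warning("nonpositive values raised to ", eps,
              " for lognormal fit of ", metal)
      v[v <= 0] <- eps
    }
    m <- mean(v)
    s2 <- log(1 + stats::var(v) / m^2)
    dist_spec("lognormal", meanlog = log(m) - s2 / 2, sdlog = sqrt(s2))
  } else if (family == "empirical") {
    dist_spec("empirical", values = v)
  } else {
    dist_spec("point", value = mean(v))
  }
  attr(spec, "metal") <- metal
  spec
}

#' Monte Carlo simulation of HQ and CR
#'
#' Propagates distributions over metal concentrations and exposure
#' factors through the chronic-daily-intake, hazard-quotient and
#' cancer-risk formulas. All variables are drawn independently;
#' evaluation is vectorised over iterations through the same functions
#' used by the deterministic pipeline.
#'
#' @param conc_specs Named list of [dist_spec()] per metal (e.g. from
#'   [calibrate_concentration_spec()] per metal).
#' @param tox Toxicology table.
#' @param groups Receptor groups to simulate.
#' @param routes Exposure routes to simulate.
#' @param n_iter Iterations (default 10000).
#' @param seed Mandatory RNG seed, recorded in the result.
#' @param factor_cv Coefficient of variation of the exposure factors
#'   (`0` collapses them to the deterministic point values).
#' @param probs Summary percentiles (default 5th, 50th, 95th;
#'   linear-interpolation type-7 rule).
#' @return Object of class `mc_result`: `draws` (nested list
#'   `[[group]][[metal]][[route]]` with vectors `HQ` and, for
#'   carcinogens, `CR`), `summary` (data frame of mean and percentiles),
#'   `n_iter`, `seed`.
#' @export
simulate_risk <- function(conc_specs, tox = toxicology_table(),
                          groups = c("adult", "child"),
                          routes = c("oral", "dermal"),
                          n_iter = 10000, seed,
                          factor_cv = 0.2,
                          probs = c(0.05, 0.5, 0.95)) {
  if (missing(seed)) stop("seed is required for reproducibility")
  metals <- names(conc_specs)
  missing_m <- setdiff(metals, tox$metal)
  if (length(missing_m)) {
    stop("no toxicology entry for: ", paste(missing_m, collapse = ", "))
  }
  set.seed(seed)
  draws <- list()
  summ <- list()
  for (g in groups) {
    fs <- exposure_factor_specs(g, cv = factor_cv)
    draws[[g]] <- list()
    for (metal in metals) {
      tx <- tox[tox$metal == metal, ]
      C <- draw_spec(conc_specs[[metal]], n_iter)
      prof <- list(
        IR = draw_spec(fs$IR, n_iter), ED = draw_spec(fs$ED, n_iter),
        EF = draw_spec(fs$EF, n_iter), ET = draw_spec(fs$ET, n_iter),
        SA = draw_spec(fs$SA, n_iter), CF = draw_spec(fs$CF, n_iter),
        BW = draw_spec(fs$BW, n_iter)
      )
      prof$AT_nc <- prof$ED * 365
      prof$AT_ca <- 70 * 365
      draws[[g]][[metal]] <- list()
      for (rt in routes) {
        cdi_nc <- if (rt == "oral") cdi_oral(C, prof) else
          cdi_dermal(C, prof, tx$Kp)
        HQ <- hazard_quotient(cdi_nc, tx$RfD_oral, route = rt,
                              ABS = tx$ABS)
        res <- list(HQ = HQ)
        if (!is.na(tx$CSF)) {
          cdi_ca <- if (rt == "oral") {
            cdi_oral(C, prof, horizon = "carcinogenic")
          } else {
            cdi_dermal(C, prof, tx$Kp, horizon = "carcinogenic")
          }
          res$CR <- cancer_risk(cdi_ca, tx$CSF)
        }
        draws[[g]][[metal]][[rt]] <- res
        for (what in names(res)) {
          q <- stats::quantile(res[[what]], probs, type = 7, names = FALSE)
          summ[[length(summ) + 1L]] <- data.frame(
            group = g, metal = metal, route = rt, quantity = what,
            mean = mean(res[[what]]),
            t(stats::setNames(q, paste0("p", probs * 100)))
          )
        }
      }
    }
  }
  structure(
    list(draws = draws, summary = do.call(rbind, summ),
         n_iter = n_iter, seed = seed),
    class = "mc_result"
  )
}

#' Percentile summary of simulated vectors
#'
#' Linear-interpolation (type 7) percentiles of every simulated HQ/CR
#' vector in an `mc_result`, or of a bare numeric vector.
#'
#' @param result An `mc_result` or numeric vector.
#' @param probs Probabilities in (0, 1).
#' @return Data frame (or named vector for numeric input).
#' @export
#' @examples
#' percentile_summary(1:100, probs = 0.95)  # 95.05
percentile_summary <- function(result, probs = c(0.05, 0.5, 0.95)) {
  if (any(probs <= 0 | probs >= 1)) stop("probs must lie in (0, 1)")
  if (is.numeric(result)) {
    if (!length(result)) stop("empty vector")
    return(stats::quantile(result, probs, type = 7))
  }
  stopifnot(inherits(result, "mc_result"))
  rows <- list()
  for (g in names(result$draws)) {
    for (m in names(result$draws[[g]])) {
      for (rt in names(result$draws[[g]][[m]])) {
        for (what in names(result$draws[[g]][[m]][[rt]])) {
          v <- result$draws[[g]][[m]][[rt]][[what]]
          q <- stats::quantile(v, probs, type = 7, names = FALSE)
          rows[[length(rows) + 1L]] <- data.frame(
            group = g, metal = m, route = rt, quantity = what,
            mean = mean(v),
            t(stats::setNames(q, paste0("p", probs * 100)))
          )
        }
      }
    }
  }
  do.call(rbind, rows)
}
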