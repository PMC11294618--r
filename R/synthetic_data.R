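#' Configuration for the synthetic-sample generator
#'
#' The generator emulates the statistical structure of the 45-well
#' survey: per-analyte (min, max, mean) targets, positive inter-analyte
#' correlation blocks (the salinity block TDS-Ca-Cl-SO4-NO3 seen in the
#' first principal component of such data, the trivial TDS-EC link, and
#' a weak anthropogenic Fe-Cr-Pb block), and an approximate charge
#' balance. Correlation magnitudes are invented defaults -- only their
#' signs are constrained by the emulated survey.
#'
#' @param n_samples Number of samples (default 45).
#' @param targets Data frame with `analyte`, `min`, `max`, `mean`
#'   (default [survey_targets()]).
#' @param correlation_blocks List of `list(analytes =, r =)` blocks.
#' @param cbe_tolerance Maximum |CBE| in percent (default 5).
#' @param kappa Beta concentration parameter: larger values concentrate
#'   draws around the target mean (default 4).
#' @param seed RNG seed.
#' @return List of class `generator_config`.
#' @export
generator_config <- function(n_samples = 45, targets = survey_targets(),
                             correlation_blocks = list(
                               list(analytes = c("TDS", "Ca", "Cl",
                                                 "SO4", "NO3"), r = 0.6),
                               list(analytes = c("TDS", "EC"), r = 0.9),
                               list(analytes = c("Fe", "Cr", "Pb"),
                                    r = 0.4)
                             ),
                             cbe_tolerance = 5, kappa = 4, seed = 1) {
  bad <- with(targets, min > mean | mean > max)
  if (any(bad)) {
    stop("infeasible (min, mean, max) for: ",
         paste(targets$analyte[bad], collapse = ", "))
  }
  structure(list(n_samples = n_samples, targets = targets,
                 correlation_blocks = correlation_blocks,
                 cbe_tolerance = cbe_tolerance, kappa = kappa,
                 seed = seed),
            class = "generator_config")
}

# correlation matrix over all analytes from the block structure,
# eigenvalue-clipped to the nearest positive-definite matrix
build_correlation <- function(targets, blocks) {
  ana <- targets$analyte
  R <- diag(length(ana))
  dimnames(R) <- list(ana, ana)
  for (b in blocks) {
    idx <- intersect(b$analytes, ana)
    for (i in idx) for (j in idx) {
      if (i != j) R[i, j] <- max(R[i, j], b$r)
    }
  }
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) < 1e-8) {
    vals <- pmax(ev$values, 1e-8)
    R <- ev$vectors %*% diag(vals) %*% t(ev$vectors)
    d <- sqrt(diag(R))
    R <- R / outer(d, d)
    dimnames(R) <- list(ana, ana)
  }
  R
}

# draw one block of rows from the Gaussian copula + scaled-beta margins
draw_rows <- function(n, cfg, R) {
  t <- cfg$targets
  Z <- matrix(stats::rnorm(n * nrow(t)), n) %*% chol(R)
  U <- stats::pnorm(Z)
  X <- matrix(0, n, nrow(t), dimnames = list(NULL, t$analyte))
  for (j in seq_len(nrow(t))) {
    rng <- t$max[j] - t$min[j]
    if (rng == 0) {
      X[, j] <- t$min[j]
    } else {
      mu <- (t$mean[j] - t$min[j]) / rng
      if (mu <= 0 || mu >= 1) {
        stop("target mean on the boundary for ", t$analyte[j])
      }
      X[, j] <- t$min[j] +
        rng * stats::qbeta(U[, j], cfg$kappa * mu, cfg$kappa * (1 - mu))
    }
  }
  as.data.frame(X)
}

# nudge Na and Cl (the largest, most range-tolerant ions) minimally so
# that |CBE| <= tol; returns NULL when the ranges make it infeasible
repair_balance <- function(row, targets, tol) {
  ew <- equivalent_weights()
  ions <- to_meq(row)
  cbe <- charge_balance_error(ions)
  if (abs(cbe) <= tol) return(row)
  # aim slightly inside the band so rounding cannot push |CBE| above tol
  target <- sign(cbe) * (tol * (1 - 1e-6)) / 100
  c_oth <- ions$Ca + ions$Mg + ions$K
  a_oth <- ions$SO4 + ions$HCO3 + ions$NO3
  tot <- c_oth + a_oth + ions$Na + ions$Cl
  # want (C' - A') = target * total with Na' - Cl' free and total kept
  D <- target * tot - c_oth + a_oth
  d0 <- ions$Na - ions$Cl
  tshift <- (D - d0) / 2
  lim <- function(a) {
    i <- match(a, targets$analyte)
    c(targets$min[i], targets$max[i]) / ew[[a]]
  }
  na_rng <- lim("Na"); cl_rng <- lim("Cl")
  na <- min(max(ions$Na + tshift, na_rng[1]), na_rng[2])
  cl <- na - D
  if (cl < cl_rng[1] || cl > cl_rng[2]) {
    cl <- min(max(cl, cl_rng[1]), cl_rng[2])
    na <- min(max(cl + D, na_rng[1]), na_rng[2])
  }
  row$Na <- na * ew[["Na"]]
  row$Cl <- cl * ew[["Cl"]]
  if (abs(charge_balance_error(to_meq(row))) > tol) return(NULL)
  row
}

#' Generate a synthetic water-sample table
#'
#' Draws correlated analyte values from scaled beta distributions matched
#' to the configured (min, max, mean) targets through a Gaussian copula,
#' then minimally adjusts Na and Cl (within their ranges) so every sample
#' satisfies the charge-balance tolerance. Deterministic for a given
#' seed.
#'
#' @param cfg A [generator_config()].
#' @return A `water_samples` data frame with `sample_id` column `S1..Sn`;
#'   the seed is recorded in attribute `"seed"`.
#' @export
#' @examples
#' s <- generate_samples(generator_config(n_samples = 5, seed = 42))
generate_samples <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(cfg$seed)
  R <- build_correlation(cfg$targets, cfg$correlation_blocks)
  out <- vector("list", cfg$n_samples)
  filled <- 0L
  attempts <- 0L
  while (filled < cfg$n_samples) {
    attempts <- attempts + 1L
    if (attempts > 100L * cfg$n_samples) {
      stop("charge-balance repair failed repeatedly; ",
           "check targets and tolerance")
    }
    row <- draw_rows(1L, cfg, R)
    row <- repair_balance(row, cfg$targets, cfg$cbe_tolerance)
    if (!is.null(row)) {
      filled <- filled + 1L
      out[[filled]] <- row
    }
  }
  tab <- do.call(rbind, out)
  tab <- cbind(sample_id = paste0("S", seq_len(cfg$n_samples)), tab)
  tab <- validate_samples(tab)
  attr(tab, "seed") <- cfg$seed
  tab
}

#' Small fixed hand-checkable sample table
#'
#' Five synthetic reference waters used across examples and tests:
#' `means`, `minima` and `maxima` of the emulated survey targets, a
#' perfectly balanced pure NaCl water (10 meq/L each side), and a water
#' sitting exactly at the drinking-water standards (so its quality index
#' is 100 by construction).
#'
#' @return A `water_samples` data frame with 5 rows.
#' @export
worked_fixture <- function() {
  t <- survey_targets()
  std <- standards_table()
  mk <- function(id, vals) {
    row <- as.list(stats::setNames(vals, t$analyte))
    c(list(sample_id = id), row)
  }
  nacl <- stats::setNames(rep(0, nrow(t)), t$analyte)
  nacl[["Na"]] <- 10 * equivalent_weights()[["Na"]]
  nacl[["Cl"]] <- 10 * equivalent_weights()[["Cl"]]
  nacl[["pH"]] <- 7
  nacl[["Temp"]] <- 25
  nacl[["TDS"]] <- nacl[["Na"]] + nacl[["Cl"]]
  nacl[["EC"]] <- 2 * nacl[["TDS"]]
  stdv <- stats::setNames(rep(0, nrow(t)), t$analyte)
  stdv[std$parameter] <- std$Sj
  stdv[["Cr"]] <- 0.05
  stdv[["Pb"]] <- 0.01
  stdv[["Temp"]] <- 25
  stdv[["Turbidity"]] <- 1
  rows <- list(mk("means", t$mean), mk("minima", t$min),
               mk("maxima", t$max), mk("nacl", nacl),
               mk("standards", stdv))
  tab <- do.call(rbind, lapply(rows, as.data.frame))
  validate_samples(tab)
}
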