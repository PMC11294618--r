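#' Heavy-metal pollution index (HPI)
#'
#' Standard-weighted mean of per-metal sub-indices:
#' `HPI = sum_i(w_i * Q_i) / sum_i(w_i)` with unit weight `w_i = 1/S_i`
#' and sub-index `Q_i = 100 * C_i / S_i` (ideal value 0 for all metals).
#' The default metal set is Fe and Mn (the routinely elevated pair in
#' reducing aquifers); Cr and Pb can be added.
#'
#' Classes (monotone partition resolving the overlapping published
#' scales): excellent \[0, 15), good-to-intermediate \[15, 30),
#' poor \[30, 76), very poor \[76, 100), unsuitable \[100, Inf).
#'
#' @param samples A `water_samples` table (mg/L).
#' @param metals Metals entering the index (default `c("Fe", "Mn")`).
#' @param tox Toxicology table supplying `Si`.
#' @return Data frame: `sample_id`, `hpi`, `class`.
#' @export
#' @examples
#' hpi(data.frame(sample_id = "m", Fe = 0.713, Mn = 0.265))  # 258.2
hpi <- function(samples, metals = c("Fe", "Mn"), tox = toxicology_table()) {
  if (!length(metals)) stop("no metals selected")
  tox <- tox[match(metals, tox$metal), ]
  if (anyNA(tox$metal)) stop("metal(s) missing from toxicology table")
  w <- 1 / tox$Si
  Q <- sapply(seq_along(metals), function(k) {
    100 * samples[[metals[k]]] / tox$Si[k]
  })
  Q <- matrix(Q, nrow = nrow(samples))
  v <- as.numeric(Q %*% w) / sum(w)
  data.frame(sample_id = samples$sample_id, hpi = v, class = hpi_class(v))
}

#' @rdname hpi
#' @param hpi Numeric index values.
#' @export
hpi_class <- function(hpi) {
  cut(hpi, c(-Inf, 15, 30, 76, 100, Inf), right = FALSE,
      labels = c("excellent", "good to intermediate", "poor",
                 "very poor", "unsuitable")) |> as.character()
}

#' Heavy-metal index (HMI / MI)
#'
#' Sum of concentration-to-limit ratios `HMI = sum_i(C_i / HAL_i)` over
#' the selected metals, against their highest allowable limits. Classes:
#' very clean (< 0.3), clean \[0.3, 1), slightly polluted \[1, 2),
#' moderately polluted \[2, 4), highly polluted \[4, 6),
#' seriously polluted (>= 6).
#'
#' @param samples A `water_samples` table (mg/L).
#' @param metals Metals entering the index.
#' @param tox Toxicology table supplying `HAL`.
#' @return Data frame: `sample_id`, `hmi`, `class`.
#' @export
hmi <- function(samples, metals = c("Fe", "Mn", "Cr", "Pb"),
                tox = toxicology_table()) {
  tox <- tox[match(metals, tox$metal), ]
  if (anyNA(tox$HAL)) {
    stop("HAL missing for metal(s): ",
         paste(metals[is.na(tox$HAL)], collapse = ", "))
  }
  v <- rowSums(sapply(seq_along(metals), function(k) {
    samples[[metals[k]]] / tox$HAL[k]
  }) |> matrix(nrow = nrow(samples)))
  data.frame(sample_id = samples$sample_id, hmi = v, class = hmi_class(v))
}

#' @rdname hmi
#' @param hmi Numeric index values.
#' @export
hmi_class <- function(hmi) {
  cut(hmi, c(-Inf, 0.3, 1, 2, 4, 6, Inf), right = FALSE,
      labels = c("very clean", "clean", "slightly polluted",
                 "moderately polluted", "highly polluted",
                 "seriously polluted")) |> as.character()
}

#' Hakanson potential ecological risk index (RI)
#'
#' Per-metal ecological risk factor `Er_i = Tr_i * C_i / c_bg_i`
#' (toxic-response factor times the enrichment over the background
#' level) and their sum `RI = sum_i(Er_i)`. Classes: low (< 30),
#' moderate \[30, 60), significant \[60, 120), very high (>= 120).
#'
#' @param samples A `water_samples` table (mg/L).
#' @param metals Metals entering the index.
#' @param tox Toxicology table supplying `Tr` and `c_bg`.
#' @return Data frame: `sample_id`, one `Er_<metal>` column per metal,
#'   `ri`, `class`.
#' @export
ecological_ri <- function(samples, metals = c("Fe", "Mn", "Cr", "Pb"),
                          tox = toxicology_table()) {
  tox <- tox[match(metals, tox$metal), ]
  if (any(tox$c_bg <= 0)) stop("background value must be positive")
  er <- sapply(seq_along(metals), function(k) {
    tox$Tr[k] * samples[[metals[k]]] / tox$c_bg[k]
  }) |> matrix(nrow = nrow(samples))
  colnames(er) <- paste0("Er_", metals)
  v <- rowSums(er)
  data.frame(sample_id = samples$sample_id, er, ri = v,
             class = ri_class(v))
}

#' @rdname ecological_ri
#' @param ri Numeric index values.
#' @export
ri_class <- function(ri) {
  cut(ri, c(-Inf, 30, 60, 120, Inf), right = FALSE,
      labels = c("low", "moderate", "significant", "very high")) |>
    as.character()
}
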