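#' Read a water-sample table from delimited text
#'
#' Reads a CSV/TSV with one row per sample, a `sample_id` column and one
#' column per analyte in mg/L (pH unitless, EC in uS/cm, temperature in C).
#' Validation: unique sample ids, non-negative concentrations, pH within
#' (0, 14). Columns not in `required` and not recognised analytes are kept
#' but flagged with a message.
#'
#' @param path File path of a delimited text file with a header row.
#' @param sep Field separator (default `","`).
#' @param required Character vector of analyte columns that must be
#'   present (e.g. `required_analytes("iwqi")`).
#' @return Validated data frame of class `water_samples`.
#' @seealso [write_samples()], [validate_samples()]
#' @export
read_samples <- function(path, sep = ",", required = character()) {
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  validate_samples(tab, required = required)
}

#' Write a water-sample table to delimited text
#'
#' @param samples A `water_samples` data frame.
#' @param path Output file path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_samples <- function(samples, path, sep = ",") {
  utils::write.table(samples, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

known_analytes <- function() survey_targets()$analyte

#' Analytes required by a downstream stage
#'
#' @param stage One of `"cbe"`, `"hydrochem"`, `"iwqi"`, `"metals"`.
#' @return Character vector of required analyte columns.
#' @export
required_analytes <- function(stage = c("cbe", "hydrochem", "iwqi",
                                        "metals")) {
  stage <- match.arg(stage)
  switch(stage,
    cbe       = c("Ca", "Mg", "Na", "K", "Cl", "SO4", "HCO3", "NO3"),
    hydrochem = c("pH", "TDS", "Ca", "Mg", "Na", "K", "Cl", "SO4",
                  "HCO3", "NO3"),
    iwqi      = standards_table()$parameter,
    metals    = c("Fe", "Mn", "Cr", "Pb")
  )
}

#' Validate a water-sample table
#'
#' @param samples Data frame with a `sample_id` column and analyte columns.
#' @param required Analyte columns that must be present; a missing one is
#'   an error naming the column.
#' @return The table, classed `water_samples`.
#' @export
validate_samples <- function(samples, required = character()) {
  if (!is.data.frame(samples)) stop("samples must be a data frame")
  if (!"sample_id" %in% names(samples)) {
    stop("missing required column: sample_id")
  }
  if (anyDuplicated(samples$sample_id)) {
    stop("sample_id values must be unique")
  }
  missing <- setdiff(required, names(samples))
  if (length(missing)) {
    stop("missing required analyte column(s): ",
         paste(missing, collapse = ", "))
  }
  ana <- intersect(names(samples), known_analytes())
  for (a in ana) {
    v <- samples[[a]]
    if (!is.numeric(v)) stop("analyte column not numeric: ", a)
    bad <- which(!is.na(v) & v < 0 & a != "Temp")
    if (length(bad)) {
      stop("negative concentration for ", a, " in sample ",
           samples$sample_id[bad[1]])
    }
  }
  if ("pH" %in% names(samples)) {
    ph <- samples$pH
    if (any(!is.na(ph) & (ph <= 0 | ph >= 14))) {
      stop("pH outside (0, 14)")
    }
  }
  extra <- setdiff(names(samples),
                   c("sample_id", "x", "y", known_analytes(), "CO3"))
  if (length(extra)) {
    message("unrecognised column(s) kept but unused: ",
            paste(extra, collapse = ", "))
  }
  class(samples) <- unique(c("water_samples", class(samples)))
  samples
}

#' Convert major-ion concentrations from mg/L to meq/L
#'
#' Each ion is divided by its equivalent weight (molar mass / |charge|).
#' CO3 is treated as 0 when the column is absent (it is reported only
#' sporadically in practice).
#'
#' @param samples A `water_samples` data frame (or any data frame with the
#'   major-ion columns in mg/L).
#' @param ions Ions to convert; defaults to all charge-balance ions.
#' @return Data frame of meq/L values, one row per sample, plus
#'   `sample_id` when present in the input.
#' @export
#' @examples
#' to_meq(data.frame(sample_id = "s1", Ca = 20.04, Na = 22.99))
to_meq <- function(samples, ions = c(cation_names(), anion_names())) {
  ew <- equivalent_weights()
  unknown <- setdiff(ions, names(ew))
  if (length(unknown)) {
    stop("no equivalent weight known for: ", paste(unknown, collapse = ", "))
  }
  n <- nrow(samples)
  out <- data.frame(row.names = seq_len(max(n, 1L)))
  if ("sample_id" %in% names(samples)) out$sample_id <- samples$sample_id
  for (ion in ions) {
    conc <- if (ion %in% names(samples)) samples[[ion]] else rep(0, n)
    out[[ion]] <- conc / ew[[ion]]
  }
  out
}

#' Charge-balance error (CBE, %)
#'
#' Signed percent imbalance between total cations and total anions in
#' meq/L: `CBE = 100 * (sum cations - sum anions) / (sum cations + sum
#' anions)`. Field convention treats |CBE| <= 5% as acceptable analytical
#' quality.
#'
#' @param ions Data frame of meq/L values as returned by [to_meq()], or a
#'   `water_samples` table in mg/L (converted internally).
#' @param in_meq Set `FALSE` to convert from mg/L first.
#' @return Numeric vector of signed CBE percentages, one per sample.
#' @export
#' @examples
#' charge_balance_error(data.frame(Na = 10, Cl = 10))       # 0
#' charge_balance_error(data.frame(Na = 10.5, Cl = 9.5))    # +5
charge_balance_error <- function(ions, in_meq = TRUE) {
  if (!in_meq) ions <- to_meq(ions)
  cat_cols <- intersect(cation_names(), names(ions))
  an_cols <- intersect(anion_names(), names(ions))
  sum_cat <- rowSums(as.matrix(ions[, cat_cols, drop = FALSE]))
  sum_an <- rowSums(as.matrix(ions[, an_cols, drop = FALSE]))
  tot <- sum_cat + sum_an
  if (any(tot == 0)) {
    stop("CBE undefined: all ions zero in at least one sample")
  }
  unname(100 * (sum_cat - sum_an) / tot)
}

#' Flag samples exceeding the charge-balance tolerance
#'
#' @param cbe Vector of CBE percentages.
#' @param tolerance Acceptable |CBE| in percent (default 5).
#' @return Logical vector, `TRUE` where the sample passes.
#' @export
cbe_pass <- function(cbe, tolerance = 5) abs(cbe) <= tolerance

#' Per-analyte min / max / mean summary
#'
#' @param samples A `water_samples` data frame.
#' @param analytes Analyte columns to summarise (default: all recognised
#'   analytes present).
#' @return Data frame with columns `analyte`, `min`, `max`, `mean`.
#' @export
summary_stats <- function(samples,
                          analytes = intersect(names(samples),
                                               known_analytes())) {
  if (nrow(samples) < 1) stop("need at least one sample")
  data.frame(
    analyte = analytes,
    min  = vapply(analytes, function(a) min(samples[[a]]), numeric(1)),
    max  = vapply(analytes, function(a) max(samples[[a]]), numeric(1)),
    mean = vapply(analytes, function(a) mean(samples[[a]]), numeric(1)),
    row.names = NULL
  )
}
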