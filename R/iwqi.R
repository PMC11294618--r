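#' Min-max normalisation of a parameter matrix
#'
#' Maps each column of the m x n sample-by-parameter matrix to \[0, 1\]:
#' `Y_ij = (X_ij - min_j) / (max_j - min_j)`. A constant column carries no
#' discriminating information; it is mapped to 0.5 everywhere (with a
#' warning) so that its entropy is maximal and its entropy weight zero.
#'
#' @param X Numeric matrix or data frame, samples in rows.
#' @return Numeric matrix Y of the same shape, values in \[0, 1\].
#' @export
#' @examples
#' normalize_matrix(cbind(a = c(1, 2, 3)))  # 0, 0.5, 1
normalize_matrix <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("need at least 2 samples to normalise")
  Y <- X
  for (j in seq_len(ncol(X))) {
    rng <- range(X[, j])
    if (diff(rng) == 0) {
      warning("constant column mapped to 0.5: ",
              colnames(X)[j] %||% j)
      Y[, j] <- 0.5
    } else {
      Y[, j] <- (X[, j] - rng[1]) / diff(rng)
    }
  }
  Y
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Entropy (subjective information) weights
#'
#' Shannon-entropy weighting of a normalised parameter matrix. With
#' `P_ij = Y_ij / sum_i(Y_ij)` and the convention `0 * ln 0 = 0`,
#' the per-parameter information entropy is
#' `e_j = -(1/ln m) * sum_i(P_ij * ln P_ij)` (in \[0, 1\]) and the weight
#' `w1_j = (1 - e_j) / sum_j(1 - e_j)`. Parameters whose values differ
#' strongly across samples (low entropy) receive larger weights.
#'
#' A small floor `eps` is added to Y before forming P so that columns
#' containing exact zeros (every column, after min-max normalisation) do
#' not lose their zero samples from the entropy sum.
#'
#' @param Y Normalised matrix from [normalize_matrix()].
#' @param eps Floor added to Y (default 1e-4).
#' @return Named numeric weight vector summing to 1.
#' @export
entropy_weights <- function(Y, eps = 1e-4) {
  Y <- as.matrix(Y) + eps
  m <- nrow(Y)
  P <- sweep(Y, 2, colSums(Y), "/")
  plogp <- P * log(P)
  plogp[P == 0] <- 0
  e <- -colSums(plogp) / log(m)
  if (all(1 - e < 1e-12)) {
    stop("degenerate entropy: all parameters uniform; ",
         "use CRITIC-only weighting")
  }
  w <- (1 - e) / sum(1 - e)
  stats::setNames(w, colnames(Y))
}

#' CRITIC objective weights
#'
#' Criteria Importance Through Inter-criteria Correlation: each
#' parameter's information amount is `S_j = sd_j * sum_k(1 - r_jk)` where
#' `r` is the Pearson correlation matrix of the parameters, and
#' `w2_j = S_j / sum(S_j)`. High-variance parameters that are weakly
#' correlated with the others are weighted highest. As in the original
#' CRITIC formulation the standard deviation is taken on the min-max
#' normalised matrix (`normalize = TRUE`, the default), so that a
#' parameter's weight reflects its contrast across samples rather than
#' its measurement unit; correlations are unaffected by the rescaling.
#' The sd denominator (n vs n-1) cancels in the normalisation and sample
#' sd is used. A zero-variance column gets weight 0 with a warning (its
#' correlations are undefined and taken as 0).
#'
#' @param X Sample-by-parameter matrix, m >= 3 rows.
#' @param normalize Min-max normalise columns before taking sd.
#' @return Named numeric weight vector summing to 1.
#' @export
critic_weights <- function(X, normalize = TRUE) {
  X <- as.matrix(X)
  if (nrow(X) < 3) stop("need at least 3 samples for CRITIC")
  if (normalize) {
    X <- suppressWarnings(normalize_matrix(X))
  }
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    warning("zero-variance column(s) weighted 0: ",
            paste(colnames(X)[sds == 0], collapse = ", "))
  }
  ok <- sds > 0
  r <- matrix(0, ncol(X), ncol(X))
  if (any(ok)) r[ok, ok] <- stats::cor(X[, ok, drop = FALSE])
  diag(r) <- 1
  S <- sds * rowSums(1 - r)
  w <- S / sum(S)
  stats::setNames(w, colnames(X))
}

#' Integrated weights from entropy and CRITIC weights
#'
#' Default (`method = "product"`): `W_j = w1_j * w2_j / sum(w1 * w2)`.
#' The alternative linear combination (`method = "linear"`) is
#' `W_j = p * w1_j + (1 - p) * w2_j` with preference coefficient
#' `p` in \[0, 1\].
#'
#' @param w1,w2 Weight vectors over the same parameters, each summing
#'   to 1.
#' @param method `"product"` (default) or `"linear"`.
#' @param p Preference coefficient for the linear method.
#' @return Named weight vector summing to 1.
#' @export
#' @examples
#' integrated_weights(c(a = .8, b = .2), c(a = .2, b = .8))  # 0.5, 0.5
integrated_weights <- function(w1, w2, method = c("product", "linear"),
                               p = 0.5) {
  method <- match.arg(method)
  if (length(w1) != length(w2)) stop("weight vectors differ in length")
  if (!is.null(names(w1)) && !is.null(names(w2)) &&
      !identical(names(w1), names(w2))) {
    stop("weight vectors cover different parameters")
  }
  if (method == "product") {
    pr <- w1 * w2
    if (sum(pr) == 0) stop("degenerate combination: all products zero")
    pr / sum(pr)
  } else {
    if (p < 0 || p > 1) stop("p must be in [0, 1]")
    p * w1 + (1 - p) * w2
  }
}

#' Preference coefficient of an integrated weight vector
#'
#' Diagnostic companion of the linear combination mode:
#' `p = sum_j((W_j - w1_j)^2 * (W_j - w2_j)^2)`. The derivation of this
#' expression in the method lineage is unclear (it is not the
#' least-squares preference coefficient); it is provided verbatim for
#' comparability and not used by any default.
#'
#' @param W Integrated weight vector.
#' @param w1,w2 Entropy and CRITIC weight vectors.
#' @return Scalar p.
#' @export
preference_coefficient <- function(W, w1, w2) {
  sum((W - w1)^2 * (W - w2)^2)
}

#' Per-parameter quality rating Qj
#'
#' `Q_j = 100 * (C_j - Cjp_j) / (S_j - Cjp_j)` where C_j is the measured
#' concentration, S_j the drinking-water standard and Cjp_j the ideal
#' (pure-water) value -- 0 for every parameter except pH, whose ideal
#' is 7. Q_j = 100 when the sample sits exactly at the standard and may
#' exceed 100 above it.
#'
#' @param sample One-row data frame (or named list/vector) of parameter
#'   concentrations.
#' @param standards Standards table ([standards_table()] by default).
#' @return Named numeric vector of ratings, one per standards row.
#' @export
#' @examples
#' quality_rating(c(Mn = 0.265), standards_table()[8, ])  # 265
quality_rating <- function(sample, standards = standards_table()) {
  if (any(standards$Sj == standards$Cjp)) {
    stop("standards misconfigured: Sj equals Cjp for ",
         paste(standards$parameter[standards$Sj == standards$Cjp],
               collapse = ", "))
  }
  missing <- setdiff(standards$parameter, names(sample))
  if (length(missing)) {
    stop("sample lacks weighted parameter(s): ",
         paste(missing, collapse = ", "))
  }
  cj <- vapply(standards$parameter,
               function(p) as.numeric(sample[[p]]), numeric(1))
  q <- 100 * (cj - standards$Cjp) / (standards$Sj - standards$Cjp)
  stats::setNames(q, standards$parameter)
}

#' Integrated-weight water quality index
#'
#' `IWQI = sum_j(W_j * Q_j)` with weights summing to 1. Quality classes
#' (left-closed intervals, so a score of exactly 100 is "medium"):
#' excellent \[0, 50), good \[50, 100), medium \[100, 150),
#' poor \[150, 200), extremely poor \[200, Inf).
#'
#' @param Q Rating vector from [quality_rating()].
#' @param W Weight vector over the same parameters.
#' @return List with `iwqi` and `class`.
#' @export
iwqi_score <- function(Q, W) {
  if (length(Q) != length(W) ||
      (!is.null(names(Q)) && !is.null(names(W)) &&
       !setequal(names(Q), names(W)))) {
    stop("rating and weight vectors cover different parameters")
  }
  if (!is.null(names(Q)) && !is.null(names(W))) W <- W[names(Q)]
  s <- sum(W * Q)
  list(iwqi = s, class = iwqi_class(s))
}

#' @rdname iwqi_score
#' @param iwqi Numeric vector of index values.
#' @export
iwqi_class <- function(iwqi) {
  cut(iwqi, c(-Inf, 50, 100, 150, 200, Inf), right = FALSE,
      labels = c("excellent", "good", "medium", "poor",
                 "extremely poor")) |> as.character()
}

#' IWQI for a whole sample table
#'
#' Computes entropy, CRITIC and integrated weights from the table itself
#' (`weights = "integrated"`, the default; `"entropy"`, `"critic"`), or
#' uses the published integrated weights shipped with
#' [standards_table()] (`weights = "published"`), then scores every
#' sample.
#'
#' @param samples A `water_samples` table containing every parameter in
#'   `standards`.
#' @param standards Standards table.
#' @param weights Weighting scheme (see above), or a named numeric vector
#'   summing to 1.
#' @return Data frame: `sample_id`, `iwqi`, `class`; the weight vector
#'   used is attached as attribute `"weights"`.
#' @export
iwqi <- function(samples, standards = standards_table(),
                 weights = c("integrated", "entropy", "critic",
                             "published")) {
  pars <- standards$parameter
  X <- as.matrix(samples[, pars])
  if (is.character(weights)) {
    weights <- match.arg(weights)
    W <- switch(weights,
      integrated = integrated_weights(entropy_weights(normalize_matrix(X)),
                                      critic_weights(X)),
      entropy    = entropy_weights(normalize_matrix(X)),
      critic     = critic_weights(X),
      published  = stats::setNames(standards$Wj, pars)
    )
  } else {
    if (abs(sum(weights) - 1) > 1e-6) stop("weights must sum to 1")
    W <- weights[pars]
  }
  scores <- vapply(seq_len(nrow(samples)), function(i) {
    Q <- quality_rating(samples[i, ], standards)
    sum(W[names(Q)] * Q)
  }, numeric(1))
  out <- data.frame(sample_id = samples$sample_id, iwqi = scores,
                    class = iwqi_class(scores))
  attr(out, "weights") <- W
  out
}
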