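# Normalization: within-array intensity-dependent loess of M on A (removes
# dye bias such as the classic "banana" trend) followed by between-array
# quantile normalization of A only.  Spot weights enter the loess fit, so a
# flagged spot (weight 0.1) pulls the curve ten times less than a clean one.

#' Loess-normalize one array's M values
#'
#' Fits a weighted robust local-linear curve of M on A and returns the
#' residual M - c(A).  `iterations` counts robustifying (Tukey bisquare)
#' reweighting passes after the initial fit, matching the lowess convention
#' of the original processing (span = 0.25, iterations = 2).
#'
#' @param M,A,W Numeric vectors for one array (M may contain missing values;
#'   weight-0 spots do not influence the curve but are still normalized).
#' @param span Fraction of spots in each local window.
#' @param iterations Robustifying passes after the initial fit.
#' @return Normalized M vector; missing M stays missing.
#' @export
loess_normalize_array <- function(M, A, W = NULL, span = 0.25,
                                  iterations = 2) {
  stopifnot(length(M) == length(A), span > 0, span <= 1, iterations >= 0)
  if (is.null(W)) W <- rep(1, length(M))
  w <- ifelse(is.finite(M) & is.finite(A), W, 0)
  if (sum(w > 0) < 10)
    stop("normalization error: fewer than 10 usable spots")
  fit <- limma::loessFit(y = M, x = A, weights = w, span = span,
                         iterations = iterations + 1L)
  out <- M - fit$fitted
  out[!is.finite(M)] <- NA_real_
  out
}

#' Quantile-normalize A values across arrays
#'
#' Maps each array's A values onto the mean of the order statistics across
#' arrays ("aquantile"): after normalization the sorted A values of any two
#' arrays agree wherever both are non-missing.  M is not touched.  Ties map
#' to the mean of their tied target values.
#'
#' @param A Numeric matrix, probes x arrays.
#' @param W Ignored (kept for interface symmetry with the loess step).
#' @return The normalized A matrix.
#' @export
aquantile_normalize <- function(A, W = NULL) {
  if (ncol(A) < 2) {
    warning("aquantile: single array, returning input unchanged")
    return(A)
  }
  out <- limma::normalizeQuantiles(A, ties = TRUE)
  dimnames(out) <- dimnames(A)
  out
}

#' Normalize an MA set
#'
#' Applies [loess_normalize_array()] to each array's M values and
#' [aquantile_normalize()] to the A matrix.
#'
#' @param ma An `ma_set`.
#' @param span,iterations Loess parameters, see [loess_normalize_array()].
#' @return A normalized `ma_set`.
#' @export
normalize_ma <- function(ma, span = 0.25, iterations = 2) {
  M <- ma$M
  for (j in seq_len(ncol(M)))
    M[, j] <- loess_normalize_array(ma$M[, j], ma$A[, j], ma$W[, j],
                                    span = span, iterations = iterations)
  A <- if (ncol(ma$A) >= 2) aquantile_normalize(ma$A) else ma$A
  ma_set(M, A, ma$W, probes = ma$probes, arrays = ma$arrays)
}
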