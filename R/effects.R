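# Per-probe log2 expression per sample, solved over the loop design graph,
# and the Epi "stage + dye" model with all pairwise stage contrasts.

#' Estimate per-sample log2 expression over the design graph
#'
#' Per probe, weighted least squares of M on the design matrix whose row for
#' an array carries +1 at its Cy5 sample and -1 at its Cy3 sample (reference
#' column dropped) plus a constant dye column.  Because the loop and bridge
#' hybridizations connect every sample, all effects are jointly estimable
#' relative to the reference.
#'
#' @param ma An `ma_set`; columns must cover the design's arrays.
#' @param g A `design_graph`.
#' @param reference Reference sample id (its effect column is identically 0).
#' @return An object of class `sample_effects`: list with `effects`
#'   (probes x samples, reference column 0), `dye`, `s2`, `nu`, `testable`,
#'   `reference`, `samples`.
#' @export
estimate_sample_effects <- function(ma, g,
                                    reference = g$samples$sample_id[1]) {
  val <- validate_design(g)
  if (!val$full_rank)
    stop("estimability error: design matrix is rank deficient ",
         "(see validate_design)")
  if (!all(g$arrays$array_id %in% ma$arrays))
    stop("ma_set lacks arrays: ",
         paste(setdiff(g$arrays$array_id, ma$arrays), collapse = ", "))
  ord <- match(g$arrays$array_id, ma$arrays)
  X <- sample_effect_design(g, reference)
  fit <- wls_fit(ma$M[, ord, drop = FALSE], ma$W[, ord, drop = FALSE], X)
  ids <- g$samples$sample_id
  effects <- matrix(0, length(ma$probes), length(ids),
                    dimnames = list(ma$probes, ids))
  est <- setdiff(ids, reference)
  effects[, est] <- fit$coef[, est, drop = FALSE]
  effects[!fit$testable, ] <- NA_real_
  effects[, reference] <- ifelse(fit$testable, 0, NA_real_)
  ## unscaled covariance of the effect estimates under the all-usable
  ## weight pattern (reference row/column identically 0); downstream
  ## screens use it to calibrate null distributions over the design graph
  Cinv <- solve(crossprod(X))
  ecov <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  ecov[est, est] <- Cinv[est, est]
  structure(list(effects = effects,
                 dye = fit$coef[, ".dye"],
                 s2 = fit$s2,
                 nu = fit$nu,
                 testable = fit$testable,
                 reference = reference,
                 samples = g$samples,
                 effect_cov = ecov),
            class = "sample_effects")
}

#' @export
print.sample_effects <- function(x, ...) {
  cat(sprintf("sample_effects: %d probes x %d samples (reference %s), %d testable\n",
              nrow(x$effects), ncol(x$effects), x$reference,
              sum(x$testable)))
  invisible(x)
}

#' Epi stage + dye model with all pairwise stage contrasts
#'
#' Restricts to arrays hybridizing two Epi samples, fits per probe a
#' weighted least-squares model with stage-difference columns plus a
#' constant dye column, and tests every pairwise stage comparison with a t
#' statistic on the residual degrees of freedom.  P values are BH-adjusted
#' across probes separately within each of the six contrast families; a
#' contrast is called when its adjusted p value falls below `alpha`
#' (default 0.01\% as in the original analysis).
#'
#' @param ma An `ma_set` covering the Epi arrays.
#' @param g The full or Epi-restricted `design_graph`.
#' @param alpha Adjusted-p calling threshold (default 1e-4).
#' @return A long-format data frame of class `epi_contrasts`: `probe_id`,
#'   `contrast`, `estimate`, `t`, `p`, `q`, `call`, `status`.  Probes with
#'   too few usable arrays are reported with status `"untestable"`, probes
#'   with zero residual variance with status `"degenerate"` (p forced to 0
#'   for a non-zero contrast).
#' @export
fit_epi_pairwise <- function(ma, g, alpha = 1e-4) {
  epi <- subset_design(g, "EPI")
  if (nrow(epi$samples) < 2)
    stop("need at least 2 Epi stages")
  stages_id <- epi$samples$sample_id
  ref <- stages_id[1]
  X <- sample_effect_design(epi, ref)
  p_par <- ncol(X)
  ## contrast matrix for all pairwise stage differences (later - earlier)
  pairs <- utils::combn(stages_id, 2)
  Cmat <- matrix(0, p_par, ncol(pairs),
                 dimnames = list(colnames(X), paste0(
                   sub("^EPI_", "", pairs[2, ]), "-",
                   sub("^EPI_", "", pairs[1, ]))))
  for (j in seq_len(ncol(pairs))) {
    if (pairs[2, j] != ref) Cmat[pairs[2, j], j] <- 1
    if (pairs[1, j] != ref) Cmat[pairs[1, j], j] <- -1
  }
  ord <- match(epi$arrays$array_id, ma$arrays)
  if (anyNA(ord))
    stop("ma_set lacks Epi arrays: ",
         paste(setdiff(epi$arrays$array_id, ma$arrays), collapse = ", "))
  fit <- wls_fit(ma$M[, ord, drop = FALSE], ma$W[, ord, drop = FALSE], X,
                 contrasts = Cmat)

  res <- do.call(rbind, lapply(seq_len(ncol(Cmat)), function(j) {
    est <- fit$cont_est[, j]
    se <- sqrt(fit$s2 * fit$cont_uvar[, j])
    tt <- est / se
    pv <- 2 * stats::pt(-abs(tt), fit$nu)
    status <- ifelse(fit$testable, "ok", "untestable")
    degen <- fit$testable & is.finite(est) & fit$s2 == 0
    status[degen] <- "degenerate"
    tt[degen] <- ifelse(est[degen] == 0, 0, Inf * sign(est[degen]))
    pv[degen] <- ifelse(est[degen] == 0, 1, 0)
    pv[!fit$testable] <- NA_real_
    bh <- bh_fdr(pv, alpha)
    data.frame(probe_id = ma$probes,
               contrast = colnames(Cmat)[j],
               estimate = est, t = tt, p = pv, q = bh$q,
               call = ifelse(is.na(bh$q), FALSE, bh$q < alpha),
               status = status,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  class(res) <- c("epi_contrasts", class(res))
  attr(res, "alpha") <- alpha
  res
}
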