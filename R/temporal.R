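# Temporal Hotelling T2 test over the PE loop: per probe a second-degree
# polynomial in (coded) time is fitted to the log ratios while conserving
# the temporal order and correcting for the dye effect; the linear and
# quadratic coefficients are tested jointly with a 2-df Wald statistic
# referred to an F distribution, followed by BH-FDR across probes.

#' Design matrix for the temporal polynomial test
#'
#' In ratio space the polynomial intercept cancels, so the row for an array
#' hybridizing Cy3 time \eqn{t_i} against Cy5 time \eqn{t_j} is
#' \eqn{[u(t_j) - u(t_i),\; u(t_j)^2 - u(t_i)^2,\; 1]} with `u` the time
#' coding; the constant third column absorbs the dye effect.
#'
#' @param g A `design_graph` whose arrays are all PE-PE (use
#'   [subset_design()] first if needed).
#' @param time_coding `"scaled"` (centered and scaled by the sd of the
#'   design times, the default), `"centered"`, or `"hours"`.  The joint Wald
#'   test is invariant to affine recodings.
#' @return Numeric matrix, arrays x 3, columns `t1`, `t2`, `.dye`.
#' @export
temporal_design_matrix <- function(g, time_coding = c("scaled", "centered",
                                                      "hours")) {
  time_coding <- match.arg(time_coding)
  tt <- g$samples$time_h[match(c(g$arrays$cy3_sample, g$arrays$cy5_sample),
                               g$samples$sample_id)]
  if (anyNA(tt))
    stop("design error: non-PE array present (sample without a time)")
  times <- g$samples$time_h
  sdt <- stats::sd(times)
  if (!is.finite(sdt) || sdt == 0) sdt <- 1  # all samples at one time
  u <- switch(time_coding,
              hours = function(t) t,
              centered = function(t) t - mean(times),
              scaled = function(t) (t - mean(times)) / sdt)
  na <- nrow(g$arrays)
  u3 <- u(tt[seq_len(na)])          # Cy3 times
  u5 <- u(tt[na + seq_len(na)])     # Cy5 times
  X <- cbind(t1 = u5 - u3, t2 = u5^2 - u3^2, .dye = 1)
  rownames(X) <- g$arrays$array_id
  X
}

#' Temporal Hotelling T2 test for differential regulation in time
#'
#' Per probe, a weighted least-squares fit of M on
#' [temporal_design_matrix()] gives \eqn{(\beta_1, \beta_2, d)}; the joint
#' Wald statistic \eqn{T^2 = \beta_s' V_s^{-1} \beta_s} on the two
#' time coefficients, with \eqn{V_s = s^2 (X'WX)^{-1}} restricted to
#' \eqn{(\beta_1, \beta_2)}, is referred as \eqn{F = T^2/2} to
#' \eqn{F(2, \nu)}.  P values are BH-adjusted across all testable probes
#' (single family); a probe is called at `q <= level` (default 15\% FDR).
#'
#' @param ma An `ma_set` covering the PE arrays.
#' @param g The full or PE-restricted `design_graph`.
#' @param level BH-FDR calling level (default 0.15).
#' @param time_coding Passed to [temporal_design_matrix()].
#' @return A data frame of class `temporal_fit`: `probe_id`, `beta1`,
#'   `beta2`, `dye`, `s2`, `nu`, `T2`, `F`, `p`, `q`, `call`, `status`.
#' @export
hotelling_temporal_test <- function(ma, g, level = 0.15,
                                    time_coding = "scaled") {
  pe <- subset_design(g, "PE")
  X <- temporal_design_matrix(pe, time_coding)
  ord <- match(pe$arrays$array_id, ma$arrays)
  if (anyNA(ord))
    stop("ma_set lacks PE arrays: ",
         paste(setdiff(pe$arrays$array_id, ma$arrays), collapse = ", "))
  fit <- wls_fit(ma$M[, ord, drop = FALSE], ma$W[, ord, drop = FALSE], X,
                 cov_idx = 1:2)

  b1 <- fit$coef[, "t1"]
  b2 <- fit$coef[, "t2"]
  ## unscaled covariance of (b1, b2): c11, c12, c22
  c11 <- fit$ucov[, 1]; c12 <- fit$ucov[, 2]; c22 <- fit$ucov[, 3]
  det_c <- c11 * c22 - c12^2
  quad <- (b1^2 * c22 - 2 * b1 * b2 * c12 + b2^2 * c11) / det_c
  T2 <- quad / fit$s2
  status <- ifelse(fit$testable, "ok", "untestable")
  singular <- fit$testable & (!is.finite(det_c) | det_c <= 0)
  status[singular] <- "untestable"
  degen <- fit$testable & !singular & fit$s2 == 0
  T2[degen] <- ifelse(quad[degen] == 0, 0, Inf)
  status[degen] <- "degenerate"
  T2[status == "untestable"] <- NA_real_
  Fstat <- T2 / 2
  p <- stats::pf(Fstat, 2, fit$nu, lower.tail = FALSE)
  p[is.finite(T2) & T2 == 0] <- 1
  p[degen & T2 == Inf] <- 0
  bh <- bh_fdr(p, level)
  res <- data.frame(probe_id = ma$probes,
                    beta1 = b1, beta2 = b2, dye = fit$coef[, ".dye"],
                    s2 = fit$s2, nu = fit$nu, T2 = T2, F = Fstat,
                    p = p, q = bh$q,
                    call = ifelse(is.na(bh$q), FALSE, bh$q <= level),
                    status = status,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(res) <- c("temporal_fit", class(res))
  attr(res, "level") <- level
  res
}

#' Benjamini-Hochberg linear step-up FDR
#'
#' \eqn{q_{(i)} = \min_{j \ge i} m\, p_{(j)} / j}, clipped at 1; missing p
#' values are excluded from the family and return missing q.
#'
#' @param p Numeric vector of p values in \[0, 1\] (NA allowed).
#' @param level FDR level used for the `call` vector (q <= level).
#' @return List with `q` and logical `call`, both aligned to `p`.
#' @export
bh_fdr <- function(p, level = 0.05) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  q <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  m <- length(ok)
  if (m) {
    ord <- ok[order(p[ok])]
    q[ord] <- pmin(1, rev(cummin(rev(m * p[ord] / seq_len(m)))))
  }
  list(q = q, call = !is.na(q) & q <= level)
}
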