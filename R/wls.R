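# Internal per-probe weighted least squares engine.  All probes share the
# design matrix X (arrays x p) but differ in their weight pattern (flags,
# missing spots), so probes are grouped by weight pattern and each group is
# solved with a single matrix product; the common all-usable pattern covers
# the bulk of the probes in one pass.

# M, W: probes x arrays; X: arrays x p.
# cov_idx: coefficient indices whose joint unscaled covariance block is
#   returned per probe (columns of `ucov` in row-major upper-triangle order).
# contrasts: p x q matrix; returns contrast estimates and unscaled variances.
# A probe is testable when it has at least p + 1 usable spots and the
# weighted design has full column rank (residual df nu >= 1).
wls_fit <- function(M, W, X, cov_idx = NULL, contrasts = NULL) {
  np <- nrow(M)
  p <- ncol(X)
  Weff <- W
  Weff[!is.finite(M)] <- 0
  M0 <- M
  M0[!is.finite(M)] <- 0

  coef <- matrix(NA_real_, np, p, dimnames = list(rownames(M), colnames(X)))
  s2 <- rep(NA_real_, np)
  nu <- rep(0L, np)
  testable <- rep(FALSE, np)
  nc <- if (is.null(cov_idx)) 0L else length(cov_idx)
  ucov <- if (nc) matrix(NA_real_, np, nc * (nc + 1L) / 2L) else NULL
  q <- if (is.null(contrasts)) 0L else ncol(contrasts)
  cont_est <- if (q) matrix(NA_real_, np, q,
                            dimnames = list(rownames(M), colnames(contrasts)))
  cont_uvar <- if (q) matrix(NA_real_, np, q)

  key <- do.call(paste, c(as.data.frame(Weff), sep = "\r"))
  for (k in unique(key)) {
    rows <- which(key == k)
    w <- Weff[rows[1], ]
    idx <- which(w > 0)
    n_use <- length(idx)
    if (n_use < p + 1L) next
    Xi <- X[idx, , drop = FALSE]
    wi <- w[idx]
    if (qr(Xi * sqrt(wi))$rank < p) next
    XtWX <- crossprod(Xi, Xi * wi)
    Cinv <- solve(XtWX)
    H <- tcrossprod(Cinv, Xi * wi)        # p x n_use
    Mg <- M0[rows, idx, drop = FALSE]
    Bg <- Mg %*% t(H)                     # n_g x p
    resid <- Mg - tcrossprod(Bg, Xi)
    df_res <- n_use - p
    s2g <- as.vector((resid^2) %*% wi) / df_res
    coef[rows, ] <- Bg
    s2[rows] <- s2g
    nu[rows] <- df_res
    testable[rows] <- TRUE
    if (nc) {
      Cb <- Cinv[cov_idx, cov_idx, drop = FALSE]
      ucov[rows, ] <- matrix(Cb[upper.tri(Cb, diag = TRUE)],
                             length(rows), nc * (nc + 1L) / 2L, byrow = TRUE)
    }
    if (q) {
      cont_est[rows, ] <- Bg %*% contrasts
      uv <- colSums(contrasts * (Cinv %*% contrasts))
      cont_uvar[rows, ] <- matrix(uv, length(rows), q, byrow = TRUE)
    }
  }
  list(coef = coef, s2 = s2, nu = nu, testable = testable, ucov = ucov,
       cont_est = cont_est, cont_uvar = cont_uvar)
}
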