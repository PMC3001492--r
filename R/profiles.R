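# Profile-space analyses: z-scored expression profiles, k-means clustering
# on (squared-Euclidean ~ Pearson) distance, and the divergent-template
# screen that defines the candidate "epicardial lock" genes — genes whose
# temporal behaviour in differentiating PE explants diverges from their
# behaviour during epicardial maturation.

#' Per-sample profile matrix from estimated sample effects
#'
#' Orders the PE samples by time and the Epi samples by stage and returns
#' the probes x (8 + 4) matrix of log2 effects, with a `segments` attribute
#' giving the PE and EPI column index ranges.
#'
#' @param effects A `sample_effects` object.
#' @return Numeric matrix with attribute `segments`.
#' @export
profile_matrix <- function(effects) {
  s <- effects$samples
  pe <- s[s$series == "PE", , drop = FALSE]
  pe <- pe[order(pe$time_h), , drop = FALSE]
  epi <- s[s$series == "EPI", , drop = FALSE]
  epi <- epi[order(epi$stage), , drop = FALSE]
  P <- effects$effects[, c(pe$sample_id, epi$sample_id), drop = FALSE]
  attr(P, "segments") <- list(PE = seq_len(nrow(pe)),
                              EPI = nrow(pe) + seq_len(nrow(epi)))
  P
}

#' Z-score profiles within declared segments
#'
#' Per probe and per segment, subtracts the segment mean and divides by the
#' segment standard deviation (denominator n - 1).  Probes with a
#' zero-variance (flat) or incomplete segment are excluded and reported.
#'
#' @param P Numeric matrix, probes x positions.
#' @param segments List of column index vectors; default one segment
#'   spanning the whole profile.
#' @return List with `z` (z-scored matrix, excluded probes dropped) and
#'   `flat` (character vector of excluded probe ids, status "flat").
#' @export
zscore_profiles <- function(P, segments = list(all = seq_len(ncol(P)))) {
  Z <- P
  bad <- rep(FALSE, nrow(P))
  for (seg in segments) {
    x <- P[, seg, drop = FALSE]
    mu <- rowMeans(x)
    sdv <- sqrt(rowSums((x - mu)^2) / (ncol(x) - 1))
    bad <- bad | !is.finite(sdv) | sdv < 1e-12 | rowSums(!is.finite(x)) > 0
    Z[, seg] <- (x - mu) / sdv
  }
  list(z = Z[!bad, , drop = FALSE],
       flat = rownames(P)[bad])
}

#' K-means clustering of z-scored profiles
#'
#' K-means with the squared-Euclidean objective; on unit-variance rows this
#' is equivalent (up to the constant \eqn{2(n-1)}) to clustering on
#' \eqn{1 - } Pearson correlation.  The best of `restarts` random
#' initializations by total within-cluster sum of squares is kept;
#' deterministic under a fixed seed.
#'
#' @param Z Numeric matrix of z-scored profiles (probes x positions).
#' @param k Number of clusters.
#' @param restarts Random restarts (default 50).
#' @param seed Random seed (default 1).
#' @param max_iter Maximum iterations per start (default 300).
#' @return An object of class `cluster_model`: `k`, `assignments` (named),
#'   `centers` (raw k x positions), `centroids` (re-standardized to zero
#'   mean / unit sd per row), `inertia`, `seed`, `restarts`.
#' @export
kmeans_profiles <- function(Z, k, restarts = 50, seed = 1, max_iter = 300) {
  if (k < 1) stop("parameter error: k must be >= 1")
  if (k > nrow(Z))
    stop("parameter error: k exceeds the number of profiles")
  set.seed(seed)
  km <- suppressWarnings(
    stats::kmeans(Z, centers = k, nstart = restarts, iter.max = max_iter))
  cent <- km$centers
  cmu <- rowMeans(cent)
  csd <- sqrt(rowSums((cent - cmu)^2) / (ncol(cent) - 1))
  csd[csd < 1e-12] <- 1
  structure(list(k = k,
                 assignments = stats::setNames(km$cluster, rownames(Z)),
                 centers = cent,
                 centroids = (cent - cmu) / csd,
                 inertia = km$tot.withinss,
                 seed = seed, restarts = restarts),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("cluster_model: k=%d, %d profiles, inertia %.2f\n",
              x$k, length(x$assignments), x$inertia))
  invisible(x)
}

## raw (pre-z-scoring) segment shapes used by templates and the simulator
pe_shape <- function(kind, times) {
  switch(kind,
         up = stats::plogis((times - 48) / 20),
         down = exp(-times / 40),
         transient_up = exp(-0.5 * ((times - 36) / 18)^2),
         transient_down = -exp(-0.5 * ((times - 60) / 24)^2),
         stop("unknown PE shape: ", kind))
}

epi_shape <- function(kind, n = 4) {
  switch(kind,
         up = seq_len(n),
         down = rev(seq_len(n)),
         stop("unknown Epi shape: ", kind))
}

zseg <- function(x) (x - mean(x)) / stats::sd(x)

#' Default divergent-template library
#'
#' Six 12-point templates (8 PE positions followed by 4 Epi positions), each
#' segment z-scored, pairing PE shapes — a saturating rise, an exponential
#' decline, a transient peak at 36 h and a transient dip at 60 h — with
#' monotone Epi shapes of the opposite or neutral tendency, so that genes
#' behaving the same way in both series match none of them well.  The PE
#' rise/decline and the two transients are deliberately non-mirror-image, so
#' no template is a scalar multiple of another.  The library is a plain
#' matrix and can be replaced by the user.
#'
#' @param times PE design times (default [pe_times()]).
#' @param n_epi Number of Epi positions (default 4).
#' @return Matrix of class `template_library`, templates x 12, with a
#'   `segments` attribute.
#' @export
default_templates <- function(times = pe_times(), n_epi = 4) {
  combos <- list(
    PE_up.Epi_down = c("up", "down"),
    PE_down.Epi_up = c("down", "up"),
    PE_transient_up.Epi_down = c("transient_up", "down"),
    PE_transient_up.Epi_up = c("transient_up", "up"),
    PE_transient_down.Epi_up = c("transient_down", "up"),
    PE_transient_down.Epi_down = c("transient_down", "down")
  )
  tpl <- t(vapply(combos, function(co) {
    c(zseg(pe_shape(co[1], times)), zseg(epi_shape(co[2], n_epi)))
  }, numeric(length(times) + n_epi)))
  colnames(tpl) <- c(sprintf("PE_t%03d", times), paste0("EPI_", seq_len(n_epi)))
  attr(tpl, "segments") <- list(PE = seq_along(times),
                                EPI = length(times) + seq_len(n_epi))
  class(tpl) <- c("template_library", class(tpl))
  tpl
}

## best absolute template correlation for each row of a z-scored profile
## matrix; returns the signed r and the winning template index
best_template_cor <- function(Z, templates) {
  R <- stats::cor(t(Z), t(templates))
  best <- max.col(abs(R), ties.method = "first")
  list(r = R[cbind(seq_len(nrow(R)), best)], best = best)
}

## temporarily use a private RNG stream so screens are deterministic
## without disturbing the caller's random state
with_local_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Screen for divergent PE-vs-Epi expression profiles
#'
#' Per probe, the concatenated segment-z-scored 12-point profile is
#' correlated with every template and the template with the largest absolute
#' Pearson correlation is kept; a probe is called when `q < fdr_level` and
#' `|r| > r_min` (defaults 1\% and 0.6).
#'
#' Two p-value calibrations are available for the best-template |r|.  The
#' default, `"design"`, simulates the null distribution of the statistic
#' from the design-implied covariance of the estimated sample effects
#' (`effects$effect_cov`): effects solved over a loop graph have correlated
#' errors, so smooth null profiles resemble smooth templates far more often
#' than independent noise would, and the classical t transform is badly
#' anticonservative in this setting.  `"t"` applies the textbook transform
#' \eqn{t = r\sqrt{(n-2)/(1-r^2)}} with a Sidak correction for best-of-T
#' template selection; it is appropriate when profile points carry
#' independent errors.
#'
#' @param effects A `sample_effects` object.
#' @param templates A `template_library` (default [default_templates()]).
#' @param fdr_level BH-FDR threshold (default 0.01).
#' @param r_min Minimum absolute correlation (default 0.6).
#' @param p_method `"design"` (Monte-Carlo null over the design covariance,
#'   the default) or `"t"` (t transform with Sidak selection adjustment).
#' @param n_null Null draws for `p_method = "design"` (default 20000).
#' @param null_seed Seed of the private RNG stream used for the null draws.
#' @return A data frame of class `divergence_hits`: `probe_id`,
#'   `best_template`, `r`, `p`, `q`, `call`.  Probes flat in either segment
#'   are excluded (attribute `flat`).
#' @export
divergence_screen <- function(effects, templates = default_templates(),
                              fdr_level = 0.01, r_min = 0.6,
                              p_method = c("design", "t"),
                              n_null = 20000, null_seed = 1) {
  p_method <- match.arg(p_method)
  P <- profile_matrix(effects)
  segs <- attr(P, "segments")
  if (ncol(P) != ncol(templates))
    stop("profile length (", ncol(P), ") does not match template length (",
         ncol(templates), ")")
  zs <- zscore_profiles(P, segs)
  Z <- zs$z
  n <- ncol(Z)
  bt <- best_template_cor(Z, templates)
  r <- bt$r
  best <- bt$best
  if (p_method == "design") {
    if (is.null(effects$effect_cov))
      stop("effects carries no effect_cov; use p_method = \"t\"")
    Sigma <- effects$effect_cov[colnames(P), colnames(P)]
    ev <- eigen(Sigma, symmetric = TRUE)
    pos <- ev$values > max(ev$values) * 1e-12
    L <- ev$vectors[, pos, drop = FALSE] %*%
      diag(sqrt(ev$values[pos]), sum(pos))
    null_max <- with_local_seed(null_seed, {
      E <- matrix(stats::rnorm(n_null * sum(pos)), n_null) %*% t(L)
      colnames(E) <- colnames(P)
      En <- zscore_profiles(E, segs)
      abs(best_template_cor(En$z, templates)$r)
    })
    ## one-sided exceedance p with the +1 guard of a Monte-Carlo test
    ord <- sort(null_max)
    exceed <- length(ord) - findInterval(abs(r) - 1e-12, ord)
    p <- (exceed + 1) / (length(ord) + 1)
  } else {
    r2 <- pmin(r^2, 1 - 1e-15)
    tstat <- r * sqrt((n - 2) / (1 - r2))
    p <- 2 * stats::pt(-abs(tstat), n - 2)
    ## Sidak adjustment for best-of-T template selection
    p <- 1 - (1 - p)^nrow(templates)
  }
  bh <- bh_fdr(p, fdr_level)
  res <- data.frame(probe_id = rownames(Z),
                    best_template = rownames(templates)[best],
                    r = r, p = p, q = bh$q,
                    call = !is.na(bh$q) & bh$q < fdr_level & abs(r) > r_min,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(res) <- c("divergence_hits", class(res))
  attr(res, "flat") <- zs$flat
  attr(res, "fdr_level") <- fdr_level
  attr(res, "r_min") <- r_min
  res
}
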