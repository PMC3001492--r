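# Forward model for a synthetic study with the structure of the real one:
# the 32-array looped/round-robin design, ~20,460 singlet probes,
# intensity-dependent dye bias, per-array dye offsets and scale shifts,
# flagged (corrupted) spots, and planted temporal / archetype / divergent /
# concordant signals with per-probe ground truth.

#' Simulation configuration
#'
#' Defaults state the emulated study: 20,460 probes, spot-level noise of
#' 0.3 log2 units, a smooth sinusoidal dye trend `c(A) = amp * sin(A/2)`
#' that the loess step must remove, per-array dye offsets, a 2\% flag rate,
#' and probe classes 70\% null / 10\% temporal / 10\% cluster archetype /
#' 5\% divergent / 5\% concordant.  Temporal effect sizes are drawn to give
#' roughly 80\% power for the Hotelling test at the default noise level;
#' divergent and concordant profile amplitudes are `profile_snr` times the
#' spot noise.
#'
#' @param n_probes Number of probes (>= 100).
#' @param seed Random seed; the whole study is reproducible under it.
#' @param noise_sd Spot-level noise sd of M, log2 units.
#' @param dye_offset_sd Sd of the per-array constant dye offset.
#' @param dye_trend_amplitude,dye_trend_period Amplitude and period divisor
#'   of the intensity-dependent dye trend `amp * sin(A / period)`.
#' @param flag_rate Fraction of spots flagged (and intensity-corrupted).
#' @param frac_temporal,frac_cluster,frac_divergent,frac_concordant Probe
#'   class fractions; the remainder is null.
#' @param beta1_range,beta2_range Absolute ranges for the linear/quadratic
#'   temporal coefficients (scaled-time units), signs random.
#' @param cluster_amplitude Log2 amplitude of cluster-archetype profiles.
#' @param profile_snr Profile amplitude of divergent/concordant classes as a
#'   multiple of `noise_sd`.
#' @param baseline_mean,baseline_sd Per-probe baseline log2 abundance.
#' @param array_shift_sd Per-array intensity-scale shift sd (log2).
#' @param spot_a_sd Spot-level sd of A around the probe baseline.
#' @param background_level Typical local-background intensity (counts).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_probes = 20460, seed = 1, noise_sd = 0.3,
                       dye_offset_sd = 0.15, dye_trend_amplitude = 0.8,
                       dye_trend_period = 2, flag_rate = 0.02,
                       frac_temporal = 0.10, frac_cluster = 0.10,
                       frac_divergent = 0.05, frac_concordant = 0.05,
                       beta1_range = c(0.20, 0.45),
                       beta2_range = c(0.12, 0.35),
                       cluster_amplitude = 1.2, profile_snr = 3,
                       baseline_mean = 10, baseline_sd = 1.5,
                       array_shift_sd = 0.3, spot_a_sd = 0.25,
                       background_level = 30) {
  fracs <- c(frac_temporal, frac_cluster, frac_divergent, frac_concordant)
  if (any(fracs < 0) || sum(fracs) > 1)
    stop("config error: class fractions must be non-negative and sum to <= 1")
  if (n_probes < 100) stop("config error: n_probes must be >= 100")
  if (noise_sd <= 0) stop("config error: noise_sd must be positive")
  if (flag_rate < 0 || flag_rate >= 1)
    stop("config error: flag_rate must be in [0, 1)")
  structure(as.list(environment())[names(formals(sim_config))],
            class = "sim_config")
}

## scaled-time coding shared with the temporal test
scale_times <- function(times) (times - mean(times)) / stats::sd(times)

#' Simulate a complete synthetic study
#'
#' Builds the 32-array design, draws per-probe truth, and emits one
#' GenePix-style spot record table per array in which the true log ratio is
#' the class-determined expression difference plus per-array dye offset,
#' intensity-dependent dye trend and Gaussian spot noise.  Intensities are
#' kept as floating-point counts so the forward model is exactly invertible
#' by [compute_ma()].  Flagged spots get flag -50 and a corrupted red
#' channel.
#'
#' @param config A `sim_config`.
#' @return A list of class `sim_study` with `design` (a `design_graph`),
#'   `tables` (named list of spot-record data frames), `truth` (list with
#'   `probes` data frame, `effects` matrix, `arrays` data frame) and
#'   `config`.
#' @export
simulate_study <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  g <- study_design()
  times <- pe_times()
  u <- scale_times(times)
  np <- config$n_probes
  probes <- sprintf("P%05d", seq_len(np))

  classes <- c("temporal", "cluster", "divergent", "concordant")
  fr <- c(config$frac_temporal, config$frac_cluster,
          config$frac_divergent, config$frac_concordant)
  n_by <- floor(np * fr)
  cls <- rep("null", np)
  cls[seq_len(sum(n_by))] <- rep(classes, n_by)
  cls <- sample(cls)

  pe_ids <- g$samples$sample_id[g$samples$series == "PE"]
  epi_ids <- g$samples$sample_id[g$samples$series == "EPI"]
  eff <- matrix(0, np, length(pe_ids) + length(epi_ids),
                dimnames = list(probes, c(pe_ids, epi_ids)))
  truth <- data.frame(probe_id = probes, class = cls,
                      beta1 = NA_real_, beta2 = NA_real_,
                      template = NA_character_, archetype = NA_character_,
                      stringsAsFactors = FALSE)

  i_t <- which(cls == "temporal")
  if (length(i_t)) {
    b1 <- stats::runif(length(i_t), config$beta1_range[1],
                       config$beta1_range[2]) * sample(c(-1, 1), length(i_t),
                                                      replace = TRUE)
    b2 <- stats::runif(length(i_t), config$beta2_range[1],
                       config$beta2_range[2]) * sample(c(-1, 1), length(i_t),
                                                      replace = TRUE)
    eff[i_t, pe_ids] <- outer(b1, u) + outer(b2, u^2)
    truth$beta1[i_t] <- b1
    truth$beta2[i_t] <- b2
  }

  i_c <- which(cls == "cluster")
  if (length(i_c)) {
    kinds <- c("up", "down", "transient_up", "transient_down")
    pick <- sample(kinds, length(i_c), replace = TRUE)
    shapes <- t(vapply(kinds, function(k) zseg(pe_shape(k, times)),
                       numeric(length(times))))
    eff[i_c, pe_ids] <- config$cluster_amplitude * shapes[pick, , drop = FALSE]
    truth$archetype[i_c] <- pick
  }

  tpl <- default_templates(times, length(epi_ids))
  i_d <- which(cls == "divergent")
  if (length(i_d)) {
    pick <- sample(rownames(tpl), length(i_d), replace = TRUE)
    scale <- config$profile_snr * config$noise_sd
    eff[i_d, ] <- scale * tpl[pick, , drop = FALSE]
    truth$template[i_d] <- pick
  }

  i_co <- which(cls == "concordant")
  if (length(i_co)) {
    conc <- rbind(
      up_up = c(zseg(pe_shape("up", times)), zseg(epi_shape("up"))),
      down_down = c(zseg(pe_shape("down", times)), zseg(epi_shape("down"))))
    pick <- sample(rownames(conc), length(i_co), replace = TRUE)
    scale <- config$profile_snr * config$noise_sd
    eff[i_co, ] <- scale * conc[pick, , drop = FALSE]
    truth$template[i_co] <- pick
  }

  baseline <- stats::rnorm(np, config$baseline_mean, config$baseline_sd)
  na <- nrow(g$arrays)
  arr_truth <- data.frame(
    array_id = g$arrays$array_id,
    dye_offset = stats::rnorm(na, 0, config$dye_offset_sd),
    array_shift = stats::rnorm(na, 0, config$array_shift_sd),
    stringsAsFactors = FALSE
  )

  tables <- vector("list", na)
  names(tables) <- g$arrays$array_id
  for (a in seq_len(na)) {
    c5 <- g$arrays$cy5_sample[a]
    c3 <- g$arrays$cy3_sample[a]
    A0 <- baseline + arr_truth$array_shift[a] +
      stats::rnorm(np, 0, config$spot_a_sd)
    M <- eff[, c5] - eff[, c3] + arr_truth$dye_offset[a] +
      config$dye_trend_amplitude * sin(A0 / config$dye_trend_period) +
      stats::rnorm(np, 0, config$noise_sd)
    R <- 2^(A0 + M / 2)
    G <- 2^(A0 - M / 2)
    flag <- rep(0L, np)
    nf <- round(config$flag_rate * np)
    if (nf > 0) {
      bad <- sample.int(np, nf)
      flag[bad] <- -50L
      R[bad] <- R[bad] * 2^stats::rnorm(nf, 0, 2)  # aberrant spots
    }
    B <- config$background_level * 2^stats::rnorm(np, 0, 0.2)
    tables[[a]] <- data.frame(
      probe_id = probes, flag = flag,
      f_red_median = R, b_red_median = B,
      f_green_median = G, b_green_median = B,
      stringsAsFactors = FALSE
    )
  }

  structure(list(design = g, tables = tables,
                 truth = list(probes = truth, effects = eff,
                              arrays = arr_truth),
                 config = config),
            class = "sim_study")
}

#' @export
print.sim_study <- function(x, ...) {
  cat(sprintf("sim_study: %d probes x %d arrays (seed %d)\n",
              nrow(x$truth$probes), length(x$tables), x$config$seed))
  print(table(x$truth$probes$class))
  invisible(x)
}

#' Write a simulated study to disk
#'
#' Emits the design tables, one GenePix-style spot table per array, and the
#' probe/array truth tables, all tab-delimited.
#'
#' @param sim A `sim_study`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_sim_study <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_design(sim$design, file.path(dir, "arrays.tsv"),
               file.path(dir, "samples.tsv"))
  for (a in names(sim$tables))
    write_spot_table(sim$tables[[a]], file.path(dir, paste0(a, ".gpr.tsv")))
  utils::write.table(sim$truth$probes, file.path(dir, "truth_probes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  utils::write.table(sim$truth$arrays, file.path(dir, "truth_arrays.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(dir)
}

#' Adjusted Rand index between two partitions
#'
#' @param a,b Cluster label vectors of equal length.
#' @return Numeric scalar in \[-1, 1\]; 1 means identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_i <- sum(comb2(rowSums(tab)))
  sum_j <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_i * sum_j / n2
  max_index <- (sum_i + sum_j) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

#' Evaluate calls against simulation truth
#'
#' @param calls Either a logical vector named by probe id or a data frame
#'   with columns `probe_id` and `call`.
#' @param truth The `truth` element of a `sim_study` (or its `probes` data
#'   frame).
#' @param target_class Truth class(es) counting as planted signal for FDP
#'   and power (default `"temporal"`).
#' @param clustering Optional named cluster assignment vector; ARI is
#'   computed against the truth archetype (or template) labels of the probes
#'   present in it.
#' @param temporal_fit Optional `temporal_fit` data frame; RMSE of
#'   (beta1, beta2) is computed over the planted temporal probes.
#' @return List with `n_calls`, `fdp`, `power`, and optionally `ari` and
#'   `beta_rmse`.
#' @export
evaluate_calls <- function(calls, truth, target_class = "temporal",
                           clustering = NULL, temporal_fit = NULL) {
  probes <- if (is.data.frame(truth)) truth else truth$probes
  if (is.data.frame(calls)) {
    called <- calls$probe_id[calls$call]
    universe <- calls$probe_id
  } else {
    called <- names(calls)[calls]
    universe <- names(calls)
  }
  if (!length(intersect(universe, probes$probe_id)))
    stop("input error: call and truth probe sets are disjoint")
  planted <- probes$probe_id[probes$class %in% target_class]
  fp <- length(setdiff(called, planted))
  out <- list(n_calls = length(called),
              fdp = fp / max(1, length(called)),
              power = if (length(planted))
                length(intersect(called, planted)) / length(planted)
              else NA_real_)
  if (!is.null(clustering)) {
    ids <- names(clustering)
    lab <- probes$archetype[match(ids, probes$probe_id)]
    lab[is.na(lab)] <- probes$template[match(ids, probes$probe_id)][is.na(lab)]
    keep <- !is.na(lab)
    out$ari <- adjusted_rand_index(clustering[keep], lab[keep])
  }
  if (!is.null(temporal_fit)) {
    tp <- probes[probes$class == "temporal", , drop = FALSE]
    m <- match(tp$probe_id, temporal_fit$probe_id)
    d <- cbind(temporal_fit$beta1[m] - tp$beta1,
               temporal_fit$beta2[m] - tp$beta2)
    out$beta_rmse <- sqrt(mean(d^2, na.rm = TRUE))
  }
  out
}
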