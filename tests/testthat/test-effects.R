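test_that("noiseless synthetic data is recovered exactly", {
  cfg <- sim_config(n_probes = 120, seed = 5, noise_sd = 1e-12,
                    dye_offset_sd = 0, dye_trend_amplitude = 0,
                    flag_rate = 0)
  sim <- simulate_study(cfg)
  ma <- ma_from_spot_tables(sim$tables, sim$design)
  eff <- estimate_sample_effects(ma, sim$design, reference = "PE_t000")
  rel <- sim$truth$effects - sim$truth$effects[, "PE_t000"]
  expect_lt(max(abs(eff$effects - rel[, colnames(eff$effects)])), 1e-10)
  expect_lt(max(abs(eff$dye)), 1e-10)
})

test_that("effects on a toy loop match the normal-equations oracle", {
  tl <- tiny_loop(n_probes = 7)
  X <- epilock:::sample_effect_design(tl$g, "PE_t000")
  oracle <- wls_oracle(tl$ma$M, tl$ma$W, X)
  eff <- estimate_sample_effects(tl$ma, tl$g, "PE_t000")
  expect_equal(unname(eff$effects[, c("PE_t024", "PE_t048")]),
               unname(oracle[, 1:2]), tolerance = 1e-10)
  expect_equal(unname(eff$dye), unname(oracle[, 3]), tolerance = 1e-10)

  ## residuals are W-orthogonal to every design column
  fitted <- cbind(eff$effects[, c("PE_t024", "PE_t048")], eff$dye) %*% t(X)
  r <- (tl$ma$M - fitted) * tl$ma$W
  expect_lt(max(abs(r %*% X)), 1e-8)
})

test_that("flipping every dye orientation negates the dye term only", {
  tl <- tiny_loop(n_probes = 6, seed = 9)
  eff <- estimate_sample_effects(tl$ma, tl$g)
  g2 <- tl$g
  tmp <- g2$arrays$cy3_sample
  g2$arrays$cy3_sample <- g2$arrays$cy5_sample
  g2$arrays$cy5_sample <- tmp
  ma2 <- tl$ma
  ma2$M <- -tl$ma$M
  eff2 <- estimate_sample_effects(ma2, g2)
  expect_equal(eff2$effects, eff$effects, tolerance = 1e-10)
  expect_equal(eff2$dye, -eff$dye, tolerance = 1e-10)
})

test_that("effect estimates reach replicate-level accuracy at sigma 0.25", {
  cfg <- sim_config(n_probes = 2000, seed = 17, noise_sd = 0.25,
                    frac_cluster = 0, frac_divergent = 0,
                    frac_concordant = 0)
  sim <- simulate_study(cfg)
  eff <- run_effects(sim, reference = "PE_t000")
  rel <- sim$truth$effects - sim$truth$effects[, "PE_t000"]
  mae <- mean(abs(eff$effects - rel[, colnames(eff$effects)]))
  expect_lt(mae, 3 * 0.25 / sqrt(4))
})

test_that("rank-deficient designs are rejected with a clear error", {
  two <- pe_samples(c(0, 24))
  single <- design_graph(two, data.frame(array_id = "a1",
                                         cy3_sample = "PE_t000",
                                         cy5_sample = "PE_t024",
                                         stringsAsFactors = FALSE))
  M <- matrix(1, 3, 1, dimnames = list(c("P1", "P2", "P3"), "a1"))
  ma <- ma_set(M, M, M * 0 + 1)
  expect_error(estimate_sample_effects(ma, single), "estimability")
})

test_that("Epi pairwise contrasts recover a planted stage difference", {
  cfg <- sim_config(n_probes = 400, seed = 23, noise_sd = 0.2,
                    dye_offset_sd = 0, dye_trend_amplitude = 0, flag_rate = 0,
                    frac_temporal = 0, frac_cluster = 0, frac_divergent = 0,
                    frac_concordant = 0)
  sim <- simulate_study(cfg)
  ## plant a 4 log2-unit HH25 -> HH37 difference into one probe's tables
  target <- "P00007"
  for (a in seq_len(nrow(sim$design$arrays))) {
    c5 <- sim$design$arrays$cy5_sample[a]
    c3 <- sim$design$arrays$cy3_sample[a]
    d <- (c5 == "EPI_HH37") - (c3 == "EPI_HH37")
    if (d != 0) {
      i <- match(target, sim$tables[[a]]$probe_id)
      sim$tables[[a]]$f_red_median[i] <-
        sim$tables[[a]]$f_red_median[i] * 2^(4 * d / 2)
      sim$tables[[a]]$f_green_median[i] <-
        sim$tables[[a]]$f_green_median[i] * 2^(-4 * d / 2)
    }
  }
  ma <- ma_from_spot_tables(sim$tables, sim$design)
  ep <- fit_epi_pairwise(ma, sim$design)
  row <- ep[ep$probe_id == target & ep$contrast == "HH37-HH25", ]
  se <- abs(row$estimate / row$t)
  expect_lt(abs(row$estimate - 4), 3 * se)
  expect_true(row$call)
  expect_true(all(ep$q >= ep$p - 1e-12, na.rm = TRUE))
})

test_that("contrast estimates equal differences of Epi-only sample effects", {
  sim <- small_sim()
  epi <- subset_design(sim$design, "EPI")
  ma <- ma_from_spot_tables(sim$tables[epi$arrays$array_id], epi)
  ep <- fit_epi_pairwise(ma, epi)
  eff <- estimate_sample_effects(ma, epi, reference = "EPI_HH25")
  d <- eff$effects[, "EPI_HH37"] - eff$effects[, "EPI_HH29"]
  row <- ep[ep$contrast == "HH37-HH29", ]
  expect_equal(unname(row$estimate), unname(d), tolerance = 1e-8)
})

test_that("zero residual variance yields a degenerate sentinel, not a drop", {
  g4 <- build_round_robin(epi_samples(c("HH25", "HH29", "HH32")))
  X4 <- epilock:::sample_effect_design(g4, "EPI_HH25")
  M4 <- matrix(as.vector(X4 %*% c(2, 0, 0.1)), 1, dimnames =
                 list("P1", g4$arrays$array_id))
  ma <- ma_set(M4, M4 * 0 + 10, M4 * 0 + 1)
  ep <- fit_epi_pairwise(ma, g4)
  r <- ep[ep$contrast == "HH29-HH25", ]
  expect_equal(r$status, "degenerate")
  expect_equal(r$p, 0)
  expect_true(is.infinite(r$t))
  flat <- ep[ep$contrast == "HH32-HH25", ]  # zero contrast, zero variance
  expect_equal(flat$p, 1)
})

test_that("global-null Epi data rarely produces any call at 0.01%", {
  zero <- vapply(1:10, function(i) {
    cfg <- sim_config(n_probes = 2000, seed = 500 + i, frac_temporal = 0,
                      frac_cluster = 0, frac_divergent = 0,
                      frac_concordant = 0)
    sim <- simulate_study(cfg)
    epi <- subset_design(sim$design, "EPI")
    ma <- ma_from_spot_tables(sim$tables[epi$arrays$array_id], epi)
    sum(fit_epi_pairwise(normalize_ma(ma), epi)$call) == 0
  }, logical(1))
  expect_gte(sum(zero), 9)
})
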