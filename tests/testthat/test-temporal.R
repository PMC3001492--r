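test_that("the temporal design matrix encodes ratio-space polynomials", {
  pe <- subset_design(study_design(), "PE")
  X <- temporal_design_matrix(pe)
  expect_equal(dim(X), c(16L, 3L))
  expect_equal(qr(X)$rank, 3)
  ## dye-swapped mates have negated time entries and the same dye entry
  for (a in seq_len(nrow(pe$arrays))) {
    mate <- which(pe$arrays$cy3_sample == pe$arrays$cy5_sample[a] &
                    pe$arrays$cy5_sample == pe$arrays$cy3_sample[a])
    expect_equal(X[mate, 1:2], -X[a, 1:2], ignore_attr = TRUE)
    expect_equal(X[mate, 3], X[a, 3], ignore_attr = TRUE)
  }
  expect_error(temporal_design_matrix(study_design()), "non-PE")

  ## all samples at one time: time columns vanish and probes are untestable
  same <- design_graph(
    data.frame(sample_id = c("PE_a", "PE_b"), series = "PE",
               time_h = c(24, 24), stage = NA_character_,
               stringsAsFactors = FALSE),
    data.frame(array_id = c("x_a", "x_b", "y_a", "y_b"),
               cy3_sample = c("PE_a", "PE_b", "PE_a", "PE_b"),
               cy5_sample = c("PE_b", "PE_a", "PE_b", "PE_a"),
               stringsAsFactors = FALSE))
  Xs <- temporal_design_matrix(same, "hours")
  expect_true(all(Xs[, 1:2] == 0))
  M <- matrix(rnorm(8), 2, 4, dimnames = list(c("P1", "P2"), same$arrays$array_id))
  ma <- ma_set(M, M * 0 + 10, M * 0 + 1)
  tf <- hotelling_temporal_test(ma, same)
  expect_true(all(tf$status == "untestable"))
})

test_that("a flat probe gives F = 0, p = 1 and no call", {
  pe <- subset_design(study_design(), "PE")
  M <- matrix(0, 1, 16, dimnames = list("P1", pe$arrays$array_id))
  ma <- ma_set(M, M + 10, M + 1)
  tf <- hotelling_temporal_test(ma, pe)
  expect_equal(tf$F, 0)
  expect_equal(tf$p, 1)
  expect_false(tf$call)
})

test_that("the Wald F matches a weighted lm oracle", {
  pe <- subset_design(study_design(), "PE")
  X <- temporal_design_matrix(pe)
  set.seed(31)
  n <- 12
  M <- matrix(rnorm(n * 16, sd = 0.4), n, 16,
              dimnames = list(sprintf("P%02d", 1:n), pe$arrays$array_id))
  W <- matrix(sample(c(1, 1, 1, 0.1), n * 16, replace = TRUE), n, 16,
              dimnames = dimnames(M))
  ma <- ma_set(M, M * 0 + 10, W)
  tf <- hotelling_temporal_test(ma, pe)
  for (i in seq_len(n)) {
    fit <- stats::lm(M[i, ] ~ 0 + X, weights = W[i, ])
    b <- stats::coef(fit)[1:2]
    V <- stats::vcov(fit)[1:2, 1:2]
    Fo <- drop(t(b) %*% solve(V, b)) / 2
    expect_equal(tf$F[i], Fo, tolerance = 1e-8)
    expect_equal(tf$p[i], stats::pf(Fo, 2, fit$df.residual,
                                    lower.tail = FALSE), tolerance = 1e-8)
  }
})

test_that("F and p are invariant to time recoding and dye swaps", {
  sim <- small_sim()
  pe <- subset_design(sim$design, "PE")
  ma <- ma_from_spot_tables(sim$tables[pe$arrays$array_id], pe)
  t1 <- hotelling_temporal_test(ma, pe, time_coding = "scaled")
  for (coding in c("hours", "centered")) {
    t2 <- hotelling_temporal_test(ma, pe, time_coding = coding)
    expect_lt(max(abs(t1$F - t2$F)), 1e-8)
    expect_lt(max(abs(t1$p - t2$p)), 1e-8)
  }
  g2 <- pe
  tmp <- g2$arrays$cy3_sample
  g2$arrays$cy3_sample <- g2$arrays$cy5_sample
  g2$arrays$cy5_sample <- tmp
  ma2 <- ma
  ma2$M <- -ma$M
  t3 <- hotelling_temporal_test(ma2, g2)
  expect_equal(t3$F, t1$F, tolerance = 1e-10)
  expect_identical(t3$call, t1$call)
})

test_that("bh_fdr implements the linear step-up rule", {
  r <- bh_fdr(c(0.01, 0.02, 0.03, 0.04), 0.05)
  expect_true(all(r$call))
  expect_equal(r$q, c(0.04, 0.04, 0.04, 0.04))
  r2 <- bh_fdr(c(0.5, 0.9), 0.4)
  expect_false(any(r2$call))
  ## independent cross-check against stats::p.adjust on random families
  set.seed(4)
  for (i in 1:5) {
    p <- runif(200)^(1 + i / 2)
    expect_equal(bh_fdr(p)$q, stats::p.adjust(p, "BH"), tolerance = 1e-12)
  }
  pna <- c(0.01, NA, 0.2)
  rna <- bh_fdr(pna, 0.05)
  expect_true(is.na(rna$q[2]))
  expect_equal(rna$q[c(1, 3)], stats::p.adjust(pna[c(1, 3)], "BH"))
})

test_that("BH keeps the false-call fraction at bay under uniform p values", {
  set.seed(6)
  fdp <- vapply(1:200, function(i) {
    calls <- bh_fdr(runif(1000), 0.15)$call
    sum(calls) > 0  # every call is false under the global null
  }, logical(1))
  mc_se <- stats::sd(fdp) / sqrt(length(fdp))
  expect_lte(mean(fdp), 0.15 + 2 * mc_se)
})

test_that("planted temporal signals are detected with decent power", {
  ## non-binding regression guard at the calibrated default effect sizes
  pw <- vapply(1:2, function(i) {
    cfg <- sim_config(n_probes = 2500, seed = 600 + i, frac_cluster = 0,
                      frac_divergent = 0, frac_concordant = 0)
    sim <- simulate_study(cfg)
    tf <- run_pe_temporal(sim)
    evaluate_calls(data.frame(probe_id = tf$probe_id, call = tf$call),
                   sim$truth, "temporal")$power
  }, numeric(1))
  expect_gte(mean(pw), 0.6)
})
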