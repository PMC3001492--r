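# Shared fixtures built in code.  Expensive simulations are cached per
# session so several tests can reuse the same stated-world draw.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

## a small default-world simulation shared across module tests
small_sim <- function() {
  cached("small_sim", simulate_study(sim_config(n_probes = 800, seed = 3)))
}

## toy spot-record data frame in the internal column layout
toy_records <- function() {
  data.frame(
    probe_id = c("P1", "P2", "P3"),
    flag = c(0L, -75L, 0L),
    f_red_median = c(256, 400, 1000),
    b_red_median = c(10, 10, 10),
    f_green_median = c(256, 100, 500),
    b_green_median = c(12, 12, 12),
    stringsAsFactors = FALSE
  )
}

## write a GenePix-style file for `records` and return its path
write_toy_gpr <- function(records, path = tempfile(fileext = ".gpr.tsv")) {
  write_spot_table(records, path)
  path
}

## tiny 3-sample dye-swapped loop with a hand-filled ma_set
tiny_loop <- function(n_probes = 5, seed = 42) {
  g <- build_pe_loop(pe_samples(c(0, 24, 48)))
  set.seed(seed)
  M <- matrix(rnorm(n_probes * 6), n_probes, 6,
              dimnames = list(sprintf("P%d", seq_len(n_probes)),
                              g$arrays$array_id))
  W <- matrix(sample(c(1, 1, 1, 0.1), n_probes * 6, replace = TRUE),
              n_probes, 6, dimnames = dimnames(M))
  A <- matrix(10, n_probes, 6, dimnames = dimnames(M))
  list(g = g, ma = ma_set(M, A, W))
}

## direct normal-equations WLS oracle: solve((X' W X)) X' W y per probe
wls_oracle <- function(M, W, X) {
  t(vapply(seq_len(nrow(M)), function(i) {
    w <- W[i, ]
    solve(crossprod(X, X * w), crossprod(X, w * M[i, ]))[, 1]
  }, numeric(ncol(X))))
}

## run MA -> normalize -> temporal test on the PE arm of a simulated study
run_pe_temporal <- function(sim, level = 0.15, normalize = TRUE) {
  pe <- subset_design(sim$design, "PE")
  ma <- ma_from_spot_tables(sim$tables[pe$arrays$array_id], pe)
  if (normalize) ma <- normalize_ma(ma)
  hotelling_temporal_test(ma, pe, level = level)
}

## run the full chain up to sample effects
run_effects <- function(sim, normalize = TRUE, reference = NULL) {
  ma <- ma_from_spot_tables(sim$tables, sim$design)
  if (normalize) ma <- normalize_ma(ma)
  if (is.null(reference)) reference <- sim$design$samples$sample_id[1]
  estimate_sample_effects(ma, sim$design, reference)
}
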