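test_that("the full study design reproduces the published layout", {
  g <- study_design()
  expect_equal(nrow(g$arrays), 32)
  ## technical replicates per sample live within each series block; the
  ## bridge arrays additionally touch PE_t048, HH25 and HH29
  count_in <- function(block, s) sum(block$arrays$cy3_sample == s |
                                       block$arrays$cy5_sample == s)
  pe <- subset_design(g, "PE"); epi <- subset_design(g, "EPI")
  expect_true(all(vapply(pe$samples$sample_id, count_in, 0L,
                         block = pe) == 4))
  expect_true(all(vapply(epi$samples$sample_id, count_in, 0L,
                         block = epi) == 6))
  expect_equal(nrow(pe$arrays) + nrow(epi$arrays), 28)  # plus 4 bridges
  v <- validate_design(g)
  expect_true(v$connected)
  expect_true(v$dye_balanced)
  expect_true(v$swap_paired)
  expect_true(v$full_rank)
  expect_equal(v$rank, nrow(g$samples))
})

test_that("loop and round-robin sizes follow the dye-swap rules for n = 2..8", {
  fake <- function(n) data.frame(sample_id = sprintf("PE_t%03d", seq_len(n)),
                                 series = "PE", time_h = as.numeric(seq_len(n)),
                                 stage = NA_character_,
                                 stringsAsFactors = FALSE)
  for (n in 2:8) {
    loop <- build_pe_loop(fake(n))
    expect_equal(nrow(loop$arrays), 2 * n)
    deg <- vapply(loop$samples$sample_id, function(s)
      sum(loop$arrays$cy3_sample == s | loop$arrays$cy5_sample == s), 0L)
    expect_true(all(deg == 4))
    rr <- build_round_robin(fake(n))
    expect_equal(nrow(rr$arrays), n * (n - 1))
    deg <- vapply(rr$samples$sample_id, function(s)
      sum(rr$arrays$cy3_sample == s | rr$arrays$cy5_sample == s), 0L)
    expect_true(all(deg == 2 * (n - 1)))
    expect_true(validate_design(loop)$swap_paired)
    expect_true(validate_design(rr)$swap_paired)
  }
  expect_error(build_pe_loop(fake(1)), "design error")
  expect_error(build_round_robin(fake(1)), "design error")
})

test_that("a 3-sample loop has undirected incidence rank 2", {
  g <- build_pe_loop(pe_samples(c(0, 24, 48)))
  expect_equal(nrow(g$arrays), 6)
  inc <- matrix(0, nrow(g$arrays), 3,
                dimnames = list(NULL, g$samples$sample_id))
  for (a in seq_len(nrow(g$arrays))) {
    inc[a, g$arrays$cy5_sample[a]] <- 1
    inc[a, g$arrays$cy3_sample[a]] <- -1
  }
  expect_equal(qr(inc)$rank, 2)
})

test_that("bridges connect the two series and are validated", {
  pe <- build_pe_loop(pe_samples())
  epi <- build_round_robin(epi_samples())
  full <- connect_series(pe, epi, list(c("EPI_HH25", "PE_t048"),
                                       c("EPI_HH29", "PE_t048")))
  expect_equal(nrow(full$arrays), 32)
  expect_true(validate_design(full)$connected)

  none <- connect_series(pe, epi, list())
  expect_false(validate_design(none)$connected)
  expect_false(validate_design(none)$full_rank)

  one <- connect_series(pe, epi, list(c("EPI_HH25", "PE_t048")))
  expect_equal(nrow(one$arrays), 30)
  expect_true(validate_design(one)$connected)

  expect_error(connect_series(pe, epi, list(c("EPI_HH99", "PE_t048"))),
               "unknown bridge sample")
})

test_that("validation flags rank deficiency and dye imbalance", {
  two <- pe_samples(c(0, 24))
  single <- design_graph(two, data.frame(array_id = "a1",
                                         cy3_sample = "PE_t000",
                                         cy5_sample = "PE_t024",
                                         stringsAsFactors = FALSE))
  v <- validate_design(single)
  expect_false(v$full_rank)  # 1 array cannot separate dye from the contrast

  ## a swap partner replaced by a same-orientation repeat: the two samples
  ## of that pair each end up with a dye imbalance of 2
  g <- build_pe_loop(pe_samples(c(0, 24, 48)))
  arr <- g$arrays
  b <- which(arr$array_id == "PE_t000_t024_b")
  arr$cy3_sample[b] <- "PE_t000"; arr$cy5_sample[b] <- "PE_t024"
  arr$array_id[b] <- "PE_t000_t024_c"
  v <- validate_design(design_graph(g$samples, arr))
  expect_false(v$swap_paired)
  expect_equal(sort(unname(v$dye_balance[c("PE_t000", "PE_t024")])), c(2L, 2L))
  expect_true(all(v$dye_balance[setdiff(names(v$dye_balance),
                                        c("PE_t000", "PE_t024"))] == 0))
})

test_that("design tables round-trip byte-stably", {
  g <- study_design()
  d <- withr::local_tempdir()
  p1 <- file.path(d, "arrays.tsv"); p2 <- file.path(d, "samples.tsv")
  write_design(g, p1, p2)
  g2 <- read_design(p1, p2)
  expect_equal(g2$arrays, g$arrays)
  expect_equal(g2$samples, g$samples)
  p3 <- file.path(d, "arrays2.tsv"); p4 <- file.path(d, "samples2.tsv")
  write_design(g2, p3, p4)
  expect_identical(readLines(p3), readLines(p1))
  expect_identical(readLines(p4), readLines(p2))
})
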