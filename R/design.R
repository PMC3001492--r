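# Hybridization design: samples as nodes, two-color arrays as dye-directed
# edges.  The study couples an 8-point proepicardial (PE) explant time course
# (loop design with dye swaps) to a 4-stage epicardial (Epi) series
# (dye-swapped round robin), connected by bridge hybridizations, so that all
# samples are jointly estimable without a common reference.

#' Default PE explant culture times
#'
#' Hours in culture for the eight proepicardial samples.  The pre-explant
#' HH16 sample is assigned 0 h.
#' @return Numeric vector of length 8.
#' @export
pe_times <- function() c(0, 14, 24, 36, 48, 60, 72, 120)

#' Default epicardial Hamburger-Hamilton stages
#' @return Character vector of length 4.
#' @export
epi_stages <- function() c("HH25", "HH29", "HH32", "HH37")

#' Sample tables for the PE time course and the Epi stage series
#'
#' @param times Hours in culture (PE); 0 denotes the pre-explant HH16 sample.
#' @return A data frame with columns `sample_id`, `series`, `time_h`, `stage`.
#' @export
pe_samples <- function(times = pe_times()) {
  stopifnot(!anyDuplicated(times), !is.unsorted(times))
  data.frame(
    sample_id = sprintf("PE_t%03d", times),
    series = "PE",
    time_h = as.numeric(times),
    stage = ifelse(times == 0, "HH16", NA_character_),
    stringsAsFactors = FALSE
  )
}

#' @rdname pe_samples
#' @param stages Hamburger-Hamilton stage labels (Epi).
#' @export
epi_samples <- function(stages = epi_stages()) {
  stopifnot(!anyDuplicated(stages))
  data.frame(
    sample_id = paste0("EPI_", stages),
    series = "EPI",
    time_h = NA_real_,
    stage = stages,
    stringsAsFactors = FALSE
  )
}

## deterministic array id for the hybridization cy3 -> cy5; shared series
## prefix is collapsed ("PE_t014_t024"), mixed-series pairs keep full ids.
pair_id <- function(cy3, cy5) {
  p3 <- sub("_.*$", "", cy3)
  p5 <- sub("_.*$", "", cy5)
  if (identical(p3, p5) && grepl("_", cy3) && grepl("_", cy5)) {
    paste0(p3, "_", sub("^[^_]*_", "", cy3), "_", sub("^[^_]*_", "", cy5))
  } else {
    paste0(cy3, "_", cy5)
  }
}

## a dye-swapped array pair for one unordered sample pair
swap_pair <- function(s1, s2) {
  data.frame(
    array_id = paste0(pair_id(s1, s2), c("_a", "_b")),
    cy3_sample = c(s1, s2),
    cy5_sample = c(s2, s1),
    stringsAsFactors = FALSE
  )
}

#' Construct a design graph
#'
#' @param samples Sample table (`sample_id`, `series`, `time_h`, `stage`).
#' @param arrays Array table (`array_id`, `cy3_sample`, `cy5_sample`).
#' @return An object of class `design_graph`.
#' @export
design_graph <- function(samples, arrays) {
  stopifnot(is.data.frame(samples), is.data.frame(arrays))
  if (anyDuplicated(samples$sample_id))
    stop("design error: duplicated sample ids")
  if (anyDuplicated(arrays$array_id))
    stop("design error: duplicated array ids")
  if (any(arrays$cy3_sample == arrays$cy5_sample))
    stop("design error: self-hybridization (cy3_sample == cy5_sample)")
  unknown <- setdiff(c(arrays$cy3_sample, arrays$cy5_sample),
                     samples$sample_id)
  if (length(unknown))
    stop("design error: arrays reference unknown samples: ",
         paste(unknown, collapse = ", "))
  structure(list(samples = samples, arrays = arrays),
            class = "design_graph")
}

#' @export
print.design_graph <- function(x, ...) {
  cat(sprintf("design_graph: %d samples (%s), %d arrays\n",
              nrow(x$samples),
              paste(sprintf("%s=%d", names(table(x$samples$series)),
                            table(x$samples$series)), collapse = ", "),
              nrow(x$arrays)))
  invisible(x)
}

#' Dye-swapped loop design over an ordered sample series
#'
#' Successive samples (cyclically, last back to first) are co-hybridized in
#' both dye orientations: n samples give 2n arrays and every sample appears
#' on exactly 4 arrays.
#'
#' @param samples Ordered sample table.
#' @return A `design_graph`.
#' @export
build_pe_loop <- function(samples) {
  if (nrow(samples) < 2) stop("design error: a loop needs at least 2 samples")
  ids <- samples$sample_id
  n <- length(ids)
  arrays <- do.call(rbind, lapply(seq_len(n), function(i) {
    swap_pair(ids[i], ids[i %% n + 1])
  }))
  design_graph(samples, arrays)
}

#' Dye-swapped round-robin design
#'
#' Every unordered pair of samples is hybridized in both dye orientations:
#' n samples give n(n-1) arrays, each sample on 2(n-1) arrays.
#'
#' @param samples Sample table.
#' @return A `design_graph`.
#' @export
build_round_robin <- function(samples) {
  if (nrow(samples) < 2)
    stop("design error: a round robin needs at least 2 samples")
  ids <- samples$sample_id
  pairs <- utils::combn(ids, 2)
  arrays <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    swap_pair(pairs[1, j], pairs[2, j])
  }))
  design_graph(samples, arrays)
}

#' Connect two design graphs with dye-swapped bridge hybridizations
#'
#' @param g1,g2 `design_graph` objects with disjoint samples.
#' @param bridges List of length-2 character vectors naming sample pairs,
#'   each realized as a dye-swapped array pair.
#' @return The merged `design_graph`.
#' @export
connect_series <- function(g1, g2, bridges) {
  samples <- rbind(g1$samples, g2$samples)
  known <- samples$sample_id
  bridge_arrays <- lapply(bridges, function(b) {
    stopifnot(length(b) == 2)
    if (!all(b %in% known))
      stop("design error: unknown bridge sample: ",
           paste(setdiff(b, known), collapse = ", "))
    swap_pair(b[1], b[2])
  })
  design_graph(samples,
               do.call(rbind, c(list(g1$arrays, g2$arrays), bridge_arrays)))
}

#' The full 32-array study design
#'
#' Eight PE time points in a dye-swapped loop (16 arrays), four Epi stages in
#' a dye-swapped round robin (12 arrays), and dye-swapped bridges of both
#' HH25 and HH29 to the PE explant at 48 h (4 arrays).
#'
#' @param times,stages Passed to [pe_samples()] and [epi_samples()].
#' @return A `design_graph` with 32 arrays.
#' @export
study_design <- function(times = pe_times(), stages = epi_stages()) {
  pe <- build_pe_loop(pe_samples(times))
  epi <- build_round_robin(epi_samples(stages))
  connect_series(pe, epi,
                 list(c("EPI_HH25", "PE_t048"), c("EPI_HH29", "PE_t048")))
}

#' Restrict a design graph to arrays within one series
#'
#' @param g A `design_graph`.
#' @param series `"PE"` or `"EPI"`; arrays whose two samples both belong to
#'   the series are kept, bridge arrays are dropped.
#' @return A `design_graph`.
#' @export
subset_design <- function(g, series) {
  keep_s <- g$samples[g$samples$series == series, , drop = FALSE]
  in_series <- g$arrays$cy3_sample %in% keep_s$sample_id &
    g$arrays$cy5_sample %in% keep_s$sample_id
  design_graph(keep_s, g$arrays[in_series, , drop = FALSE])
}

## design matrix for per-probe sample-effect estimation: +1 at the Cy5
## sample, -1 at the Cy3 sample, reference column dropped, plus a constant
## dye column.
sample_effect_design <- function(g, reference) {
  ids <- g$samples$sample_id
  stopifnot(reference %in% ids)
  keep <- setdiff(ids, reference)
  X <- matrix(0, nrow(g$arrays), length(keep) + 1,
              dimnames = list(g$arrays$array_id, c(keep, ".dye")))
  for (a in seq_len(nrow(g$arrays))) {
    c5 <- g$arrays$cy5_sample[a]
    c3 <- g$arrays$cy3_sample[a]
    if (c5 %in% keep) X[a, c5] <- X[a, c5] + 1
    if (c3 %in% keep) X[a, c3] <- X[a, c3] - 1
  }
  X[, ".dye"] <- 1
  X
}

#' Validate a design graph
#'
#' Checks connectivity of the underlying undirected graph, per-sample dye
#' balance (|#Cy5 - #Cy3|), dye-swap pairing, and estimability: the rank of
#' the sample-effect design matrix (incidence columns minus a reference plus
#' a dye column) must equal #samples - 1 + 1.  Failures are reported, not
#' thrown: the bridge arrays of the real design cannot be dye-balanced
#' against every partner, so imbalance is a warning-level finding.
#'
#' @param g A `design_graph`.
#' @return A `design_validation` list with elements `connected`,
#'   `dye_balance` (named integer), `dye_balanced`, `swap_paired`, `rank`,
#'   `full_rank`, `ok`.
#' @export
validate_design <- function(g) {
  ids <- g$samples$sample_id
  n <- length(ids)
  ## connectivity by traversal over the undirected sample graph
  adj <- lapply(stats::setNames(ids, ids), function(i) character(0))
  for (a in seq_len(nrow(g$arrays))) {
    s3 <- g$arrays$cy3_sample[a]; s5 <- g$arrays$cy5_sample[a]
    adj[[s3]] <- c(adj[[s3]], s5)
    adj[[s5]] <- c(adj[[s5]], s3)
  }
  seen <- character(0)
  if (n > 0) {
    frontier <- ids[1]
    while (length(frontier)) {
      seen <- union(seen, frontier)
      frontier <- setdiff(unique(unlist(adj[frontier])), seen)
    }
  }
  connected <- length(seen) == n
  dye_balance <- vapply(ids, function(s) {
    abs(sum(g$arrays$cy5_sample == s) - sum(g$arrays$cy3_sample == s))
  }, integer(1))
  ## dye-swap pairing: each orientation occurs as often as its reverse
  key <- factor(paste(g$arrays$cy3_sample, g$arrays$cy5_sample, sep = "\r"))
  rev_key <- factor(paste(g$arrays$cy5_sample, g$arrays$cy3_sample, sep = "\r"),
                    levels = levels(key))
  swap_paired <- !anyNA(rev_key) && all(table(key) == table(rev_key))
  rk <- if (nrow(g$arrays)) qr(sample_effect_design(g, ids[1]))$rank else 0L
  full_rank <- rk == n  # (n - 1) sample effects + 1 dye column
  structure(list(connected = connected,
                 dye_balance = dye_balance,
                 dye_balanced = all(dye_balance == 0),
                 swap_paired = swap_paired,
                 rank = rk,
                 full_rank = full_rank,
                 ok = connected && full_rank),
            class = "design_validation")
}

#' @export
print.design_validation <- function(x, ...) {
  cat(sprintf("design validation: connected=%s, dye-balanced=%s, swap-paired=%s, rank=%d (full rank: %s)\n",
              x$connected, x$dye_balanced, x$swap_paired, x$rank, x$full_rank))
  invisible(x)
}

#' Read or write a design as tab-delimited tables
#'
#' The array table has columns `array_id`, `cy3_sample`, `cy5_sample`; the
#' sample table `sample_id`, `series`, `time_h`, `stage`.  Writing then
#' reading reproduces the design byte-for-byte.
#'
#' @param g A `design_graph`.
#' @param arrays_path,samples_path File paths for the two tables.
#' @return `write_design` returns the paths invisibly; `read_design` a
#'   `design_graph`.
#' @export
write_design <- function(g, arrays_path, samples_path) {
  utils::write.table(g$arrays, arrays_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  utils::write.table(g$samples, samples_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(c(arrays_path, samples_path))
}

#' @rdname write_design
#' @export
read_design <- function(arrays_path, samples_path) {
  arrays <- utils::read.delim(arrays_path, stringsAsFactors = FALSE)
  samples <- utils::read.delim(samples_path, stringsAsFactors = FALSE)
  samples$time_h <- as.numeric(samples$time_h)
  samples$stage <- as.character(samples$stage)
  design_graph(samples, arrays)
}
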