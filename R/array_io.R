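# GenePix-style spot-table ingestion and per-array M/A computation.  Arrays
# carry one record per probe ("printed in singlets"); flagged spots are kept
# but downweighted to 0.1, matching the original processing.

#' Column dialect for GenePix-style spot tables
#'
#' @param id,flags,f_red,b_red,f_green,b_green Header names of the probe id,
#'   flag, and foreground/background median columns (red = Cy5 = 635 nm,
#'   green = Cy3 = 532 nm).
#' @param comment Comment-line prefix skipped on read.
#' @param control_pattern Regular expression; matching probe ids are treated
#'   as control spots and removed.
#' @return A named list used by [read_spot_table()] and [write_spot_table()].
#' @export
genepix_dialect <- function(id = "ID", flags = "Flags",
                            f_red = "F635 Median", b_red = "B635 Median",
                            f_green = "F532 Median", b_green = "B532 Median",
                            comment = "#",
                            control_pattern = "^(CTRL|CONTROL|BLANK|EMPTY)") {
  list(id = id, flags = flags, f_red = f_red, b_red = b_red,
       f_green = f_green, b_green = b_green, comment = comment,
       control_pattern = control_pattern)
}

#' Read a per-array spot table
#'
#' Reads a tab-delimited GenePix-style results table, drops control spots
#' (ids matching the dialect's `control_pattern`), and returns one record per
#' probe.
#'
#' @param path File path.
#' @param dialect Column dialect, see [genepix_dialect()].
#' @return A data frame with columns `probe_id`, `flag`, `f_red_median`,
#'   `b_red_median`, `f_green_median`, `b_green_median`.
#' @export
read_spot_table <- function(path, dialect = genepix_dialect()) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           comment.char = dialect$comment,
                           stringsAsFactors = FALSE)
  req <- c(dialect$id, dialect$flags, dialect$f_red, dialect$b_red,
           dialect$f_green, dialect$b_green)
  missing_cols <- setdiff(req, names(tab))
  if (length(missing_cols))
    stop(sprintf("format error in '%s': missing column(s) %s", path,
                 paste(sQuote(missing_cols), collapse = ", ")))
  rec <- data.frame(
    probe_id = as.character(tab[[dialect$id]]),
    flag = as.integer(tab[[dialect$flags]]),
    f_red_median = as.numeric(tab[[dialect$f_red]]),
    b_red_median = as.numeric(tab[[dialect$b_red]]),
    f_green_median = as.numeric(tab[[dialect$f_green]]),
    b_green_median = as.numeric(tab[[dialect$b_green]]),
    stringsAsFactors = FALSE
  )
  if (nzchar(dialect$control_pattern))
    rec <- rec[!grepl(dialect$control_pattern, rec$probe_id), , drop = FALSE]
  if (anyDuplicated(rec$probe_id))
    stop(sprintf("format error in '%s': duplicated probe id(s), e.g. %s",
                 path, rec$probe_id[duplicated(rec$probe_id)][1]))
  rownames(rec) <- NULL
  rec
}

#' @rdname read_spot_table
#' @param records A spot-record data frame as returned by [read_spot_table()].
#' @export
write_spot_table <- function(records, path, dialect = genepix_dialect()) {
  out <- records
  names(out) <- c(dialect$id, dialect$flags, dialect$f_red, dialect$b_red,
                  dialect$f_green, dialect$b_green)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-spot M/A values and weights for one array
#'
#' M = log2(R/G) and A = (log2 R + log2 G)/2, with R and G the red (Cy5) and
#' green (Cy3) signals under the background policy.  Flagged spots
#' (flag < 0) receive weight 0.1; spots with a non-positive signal after
#' background subtraction receive weight 0 with M and A missing.
#'
#' @param records Spot records for one array ([read_spot_table()]).
#' @param background_policy `"none"` (foreground medians as-is, the default)
#'   or `"subtract"` (foreground minus local background).
#' @return A data frame `probe_id`, `M`, `A`, `weight`.
#' @export
compute_ma <- function(records, background_policy = c("none", "subtract")) {
  background_policy <- match.arg(background_policy)
  R <- records$f_red_median
  G <- records$f_green_median
  if (background_policy == "subtract") {
    R <- R - records$b_red_median
    G <- G - records$b_green_median
  }
  w <- ifelse(records$flag < 0, 0.1, 1.0)
  bad <- !(is.finite(R) & is.finite(G) & R > 0 & G > 0)
  w[bad] <- 0
  lR <- ifelse(bad, NA_real_, log2(pmax(R, .Machine$double.xmin)))
  lG <- ifelse(bad, NA_real_, log2(pmax(G, .Machine$double.xmin)))
  data.frame(probe_id = records$probe_id,
             M = lR - lG,
             A = (lR + lG) / 2,
             weight = w,
             stringsAsFactors = FALSE)
}

#' Construct an MA set
#'
#' Container for per-probe, per-array log ratios (M), average log intensity
#' (A) and spot weights (W), all probes x arrays.
#'
#' @param M,A,W Numeric matrices of identical dimension.
#' @param probes,arrays Row and column identifiers.
#' @return An object of class `ma_set`.
#' @export
ma_set <- function(M, A, W, probes = rownames(M), arrays = colnames(M)) {
  stopifnot(all(dim(M) == dim(A)), all(dim(M) == dim(W)),
            length(probes) == nrow(M), length(arrays) == ncol(M))
  if (any(W < 0 | W > 1, na.rm = TRUE))
    stop("weights must lie in [0, 1]")
  dimnames(M) <- dimnames(A) <- dimnames(W) <- list(probes, arrays)
  structure(list(M = M, A = A, W = W, probes = probes, arrays = arrays),
            class = "ma_set")
}

#' @export
print.ma_set <- function(x, ...) {
  cat(sprintf("ma_set: %d probes x %d arrays (mean weight %.3f)\n",
              length(x$probes), length(x$arrays), mean(x$W)))
  invisible(x)
}

#' Assemble an MA set from per-array spot tables
#'
#' @param tables Named list of spot-record data frames, one per array; names
#'   must match `design$arrays$array_id`.
#' @param design A `design_graph`; its array order defines the column order.
#' @param background_policy Passed to [compute_ma()].
#' @param probes Optional probe universe; defaults to the union of probe ids
#'   in input order of the first table.  Probes absent from an array get
#'   weight 0 for that array.
#' @return An `ma_set`.
#' @export
ma_from_spot_tables <- function(tables, design,
                                background_policy = c("none", "subtract"),
                                probes = NULL) {
  background_policy <- match.arg(background_policy)
  array_ids <- design$arrays$array_id
  missing_arr <- setdiff(array_ids, names(tables))
  if (length(missing_arr))
    stop("no spot table for array(s): ", paste(missing_arr, collapse = ", "))
  if (is.null(probes))
    probes <- unique(unlist(lapply(tables[array_ids],
                                   function(t) t$probe_id), use.names = FALSE))
  np <- length(probes)
  M <- A <- matrix(NA_real_, np, length(array_ids))
  W <- matrix(0, np, length(array_ids))
  for (j in seq_along(array_ids)) {
    ma <- compute_ma(tables[[array_ids[j]]], background_policy)
    idx <- match(ma$probe_id, probes)
    keep <- !is.na(idx)
    M[idx[keep], j] <- ma$M[keep]
    A[idx[keep], j] <- ma$A[keep]
    W[idx[keep], j] <- ma$weight[keep]
  }
  ma_set(M, A, W, probes = probes, arrays = array_ids)
}

#' Serialize an MA set as three TSV matrices
#'
#' Writes/reads `M.tsv`, `A.tsv`, `W.tsv` with probe rows and array columns.
#'
#' @param ma An `ma_set`.
#' @param dir Directory for the three files.
#' @return `write_ma_set` the directory invisibly; `read_ma_set` an `ma_set`.
#' @export
write_ma_set <- function(ma, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (part in c("M", "A", "W")) {
    df <- data.frame(probe_id = ma$probes, ma[[part]],
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, file.path(dir, paste0(part, ".tsv")), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_ma_set
#' @export
read_ma_set <- function(dir) {
  parts <- lapply(c(M = "M", A = "A", W = "W"), function(part) {
    df <- utils::read.delim(file.path(dir, paste0(part, ".tsv")),
                            check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df$probe_id
    m
  })
  ma_set(parts$M, parts$A, parts$W)
}
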