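# End-to-end orchestration: ingestion -> M/A -> normalization -> sample
# effects -> temporal test -> clustering -> Epi contrasts -> divergence
# screen, with every intermediate written as TSV and a JSON manifest that
# makes a run self-describing and reproducible.

#' Pipeline configuration
#'
#' Collects every tunable of the full analysis with the study's defaults:
#' loess span 0.25 with 2 robustifying iterations, temporal BH-FDR 15\%, Epi
#' adjusted-p threshold 0.01\%, divergence BH-FDR 1\% with |r| > 0.6, 7 PE
#' clusters and 6 divergence clusters.
#'
#' @param background_policy `"none"` or `"subtract"` ([compute_ma()]).
#' @param span,iterations Loess parameters ([loess_normalize_array()]).
#' @param temporal_level Temporal test BH-FDR level.
#' @param epi_alpha Epi pairwise adjusted-p threshold.
#' @param divergence_fdr,r_min Divergence-screen thresholds.
#' @param k_pe,k_divergence Cluster counts for the temporal and divergent
#'   gene sets.
#' @param kmeans_restarts,seed K-means restarts and master seed.
#' @param reference Reference sample id (default: first design sample).
#' @param templates Optional `template_library`; default
#'   [default_templates()].
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(background_policy = "none", span = 0.25,
                            iterations = 2, temporal_level = 0.15,
                            epi_alpha = 1e-4, divergence_fdr = 0.01,
                            r_min = 0.6, k_pe = 7, k_divergence = 6,
                            kmeans_restarts = 50, seed = 1,
                            reference = NULL, templates = NULL) {
  stopifnot(temporal_level > 0, temporal_level < 1,
            epi_alpha > 0, epi_alpha < 1,
            divergence_fdr > 0, divergence_fdr < 1,
            k_pe >= 1, k_divergence >= 1)
  structure(as.list(environment())[names(formals(pipeline_config))],
            class = "pipeline_config")
}

stage_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline aborted at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  path
}

#' Run the full analysis pipeline
#'
#' Executes ingestion, M/A computation, normalization, sample-effect
#' estimation, the temporal Hotelling test, profile clustering of the
#' temporally called probes, the Epi pairwise contrasts and the
#' divergent-template screen, writing every intermediate and final table
#' under `out_dir` together with a JSON manifest (package version, config,
#' per-stage row counts, file checksums).  Rerunning on identical inputs and
#' config reproduces identical files.
#'
#' @param design A `design_graph`, or a length-2 character vector of paths
#'   (arrays table, samples table) for [read_design()].
#' @param tables Named list of spot-record data frames (one per array), or a
#'   directory containing `<array_id>.gpr.tsv` files.
#' @param out_dir Output directory (created if needed).
#' @param config A `pipeline_config`.
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(design, tables, out_dir,
                         config = pipeline_config()) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (is.character(design))
    design <- run_stage("design", read_design(design[1], design[2]))
  counts <- list()

  tables <- run_stage("ingestion", {
    if (is.character(tables)) {
      paths <- file.path(tables, paste0(design$arrays$array_id, ".gpr.tsv"))
      names(paths) <- design$arrays$array_id
      lapply(paths, read_spot_table)
    } else tables
  })
  stage_log("ingestion", "%d spot tables", length(tables))

  ma <- run_stage("ma", ma_from_spot_tables(tables, design,
                                            config$background_policy))
  counts$probes <- length(ma$probes)
  counts$arrays <- length(ma$arrays)
  stage_log("ma", "%d probes x %d arrays", counts$probes, counts$arrays)

  ma_norm <- run_stage("normalize",
                       normalize_ma(ma, span = config$span,
                                    iterations = config$iterations))
  write_ma_set(ma_norm, file.path(out_dir, "ma_normalized"))

  reference <- if (is.null(config$reference)) design$samples$sample_id[1]
               else config$reference
  eff <- run_stage("effects",
                   estimate_sample_effects(ma_norm, design, reference))
  counts$effects_testable <- sum(eff$testable)
  stage_log("effects", "%d/%d probes testable", counts$effects_testable,
            counts$probes)
  write_tsv(data.frame(probe_id = rownames(eff$effects), eff$effects,
                       dye = eff$dye, s2 = eff$s2, nu = eff$nu,
                       testable = eff$testable, check.names = FALSE),
            file.path(out_dir, "sample_effects.tsv"))

  tfit <- run_stage("temporal",
                    hotelling_temporal_test(ma_norm, design,
                                            level = config$temporal_level))
  counts$temporal_called <- sum(tfit$call)
  stage_log("temporal", "%d probes called at FDR %.2f",
            counts$temporal_called, config$temporal_level)
  write_tsv(tfit, file.path(out_dir, "temporal_fit.tsv"))

  cl_pe <- run_stage("cluster", {
    called <- tfit$probe_id[tfit$call]
    if (length(called) >= config$k_pe) {
      P <- profile_matrix(eff)
      segs <- attr(P, "segments")
      zs <- zscore_profiles(P[called, segs$PE, drop = FALSE])
      kmeans_profiles(zs$z, config$k_pe, restarts = config$kmeans_restarts,
                      seed = config$seed)
    } else NULL
  })
  if (!is.null(cl_pe)) {
    counts$pe_clustered <- length(cl_pe$assignments)
    write_tsv(data.frame(probe_id = names(cl_pe$assignments),
                         cluster = unname(cl_pe$assignments)),
              file.path(out_dir, "pe_clusters.tsv"))
    stage_log("cluster", "%d probes in %d PE clusters", counts$pe_clustered,
              cl_pe$k)
  } else {
    counts$pe_clustered <- 0L
    stage_log("cluster", "skipped: fewer called probes than k")
  }

  epi <- run_stage("epi", fit_epi_pairwise(ma_norm, design,
                                           alpha = config$epi_alpha))
  counts$epi_called <- sum(epi$call)
  stage_log("epi", "%d contrast calls at adjusted p < %g", counts$epi_called,
            config$epi_alpha)
  write_tsv(epi, file.path(out_dir, "epi_contrasts.tsv"))

  templates <- if (is.null(config$templates)) default_templates()
               else config$templates
  div <- run_stage("divergence",
                   divergence_screen(eff, templates,
                                     fdr_level = config$divergence_fdr,
                                     r_min = config$r_min))
  counts$divergence_tested <- nrow(div)
  counts$divergence_called <- sum(div$call)
  counts$divergence_flat <- length(attr(div, "flat"))
  stage_log("divergence", "%d called of %d tested (%d flat excluded)",
            counts$divergence_called, counts$divergence_tested,
            counts$divergence_flat)
  write_tsv(div, file.path(out_dir, "divergence_hits.tsv"))

  cl_div <- run_stage("cluster", {
    hit <- div$probe_id[div$call]
    if (length(hit) >= config$k_divergence) {
      P <- profile_matrix(eff)
      zs <- zscore_profiles(P[hit, , drop = FALSE], attr(P, "segments"))
      kmeans_profiles(zs$z, config$k_divergence,
                      restarts = config$kmeans_restarts, seed = config$seed)
    } else NULL
  })
  if (!is.null(cl_div)) {
    write_tsv(data.frame(probe_id = names(cl_div$assignments),
                         cluster = unname(cl_div$assignments)),
              file.path(out_dir, "divergence_clusters.tsv"))
  }

  outputs <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  outputs <- setdiff(outputs, file.path(out_dir, "manifest.json"))
  manifest <- list(
    package = "epilock",
    version = as.character(utils::packageVersion("epilock")),
    config = config[setdiff(names(config), "templates")],
    counts = counts,
    files = stats::setNames(as.list(unname(tools::md5sum(outputs))),
                            basename(outputs))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  stage_log("done", "manifest written to %s",
            file.path(out_dir, "manifest.json"))
  invisible(manifest)
}
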