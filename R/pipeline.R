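#' Default end-to-end pipeline configuration
#'
#' Returns the configuration list understood by [run_pipeline()], with every
#' stage's tunable parameters at its documented default. Any element can be
#' overridden before the run; the same structure can be stored as a YAML
#' file and loaded with [read_config()].
#'
#' @param seed Master seed for simulation.
#' @return Named list.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    design = list(transcript_times = c(0, 10, 25, 55, 115),
                  protein_times = c(10, 25, 55, 115, 235),
                  pulse_minutes = 5, control_label = "DD", n_replicates = 3),
    classes = list(concordant = 200, transcript_only = 200,
                   protein_only = 100, null = 2000),
    noise = list(),             # overrides of noise_model() defaults
    params = list(),            # overrides of sim_params() defaults
    input = NULL,               # list(transcript=, protein=) TSV paths to skip simulation
    protein_layer = TRUE,
    genome_size = NULL,         # default: number of transcript features
    thresholds = list(p_threshold = 0.01, fc_threshold = 2, pseudocount = 1,
                      timing_boundary = 25, min_runs = 2, knn_k = 10,
                      fdr = 0.05, moderation_weight = 0.75),
    cluster = list(k_init = 30, tightness_quantile = 0.5, merge_r = 0.8,
                   min_size = 5),
    output_dir = NULL)
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys override [default_config()]. Note the
#'   `null` gene class must be written quoted (`'null':`) since a bare `null`
#'   is YAML's null literal.
#' @return Configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  for (k in names(user)) {
    if (is.list(cfg[[k]]) && is.list(user[[k]])) {
      for (k2 in names(user[[k]])) cfg[[k]][[k2]] <- user[[k]][[k2]]
    } else cfg[[k]] <- user[[k]]
  }
  cfg
}

.stage_msg <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full analysis pipeline
#'
#' Executes simulation (or loads input matrices), transcript
#' differential-expression calling, the proteome processing chain,
#' transcript-protein integration, tight profile clustering and the summary
#' report, logging one line per stage with the thresholds used. When
#' `config$output_dir` is set, all stage tables are written as TSV/JSON
#' together with a JSON manifest carrying the configuration, its hash, the
#' package version and the md5 checksum of every output file; a rerun with
#' the same configuration reproduces identical checksums.
#'
#' @param config Configuration list from [default_config()]/[read_config()]
#'   (or a path to a YAML file).
#' @return List of class `pipeline_run` with elements `sim`, `transcript`
#'   (`profiles`, `calls`, `pca`), `proteome`, `integration` (`pairs`,
#'   `partition`, `grid`, `lag`, `paired`), `clusters`, `summary`,
#'   `manifest`.
#' @export
run_pipeline <- function(config = default_config()) {
  if (is.character(config)) config <- read_config(config)
  th <- config$thresholds
  design <- do.call(pulse_design, c(config$design, list(seed = config$seed)))
  noise <- do.call(noise_model, config$noise)
  params <- do.call(sim_params, config$params)

  if (is.null(config$input)) {
    .stage_msg("simulate", "classes: %s; seed %d",
               paste(names(config$classes), unlist(config$classes),
                     sep = "=", collapse = ", "), config$seed)
    sim <- simulate_light_pulse(unlist(config$classes), design, noise,
                                params, seed = config$seed)
    tmat <- sim$transcript
    pmat <- if (isTRUE(config$protein_layer)) sim$protein else NULL
  } else {
    .stage_msg("load", "reading matrices from configured input paths")
    sim <- NULL
    tmat <- read_abundance_tsv(config$input$transcript)
    pmat <- if (isTRUE(config$protein_layer) && !is.null(config$input$protein))
      read_abundance_tsv(config$input$protein) else NULL
  }

  .stage_msg("de-transcripts", "P < %g and %g-fold in >= 1 time point; pseudocount %g",
             th$p_threshold, th$fc_threshold, th$pseudocount)
  tnorm <- normalize_library(tmat)
  tprof <- fold_changes(tnorm, design, pseudocount = th$pseudocount)
  tcalls <- call_regulated_transcripts(tprof, p_threshold = th$p_threshold,
                                       fc_threshold = th$fc_threshold,
                                       timing_boundary = th$timing_boundary)
  .stage_msg("de-transcripts", "%d of %d transcripts regulated",
             sum(tcalls$regulated), nrow(tcalls))
  pca <- tryCatch(pca_summary(tprof), error = function(e) NULL)

  prot <- NULL; integ <- NULL
  if (!is.null(pmat)) {
    .stage_msg("proteome", ">= %d runs, kNN k = %d, FDR < %g, %g-fold",
               th$min_runs, th$knn_k, th$fdr, th$fc_threshold)
    prot <- proteome_pipeline(pmat, design, min_runs = th$min_runs,
                              knn_k = th$knn_k, fdr = th$fdr,
                              fc_threshold = th$fc_threshold,
                              moderation_weight = th$moderation_weight)
    .stage_msg("proteome", "%d proteins analysed, %d regulated",
               nrow(prot$imputed), sum(prot$calls$regulated))
    genome <- if (is.null(config$genome_size)) nrow(tmat) else config$genome_size
    pairs <- match_pairs(tcalls, prot$calls)
    partition <- partition_categories(tcalls, prot$calls, n_genome = genome)
    grid <- NULL; lag <- NULL; paired <- NULL
    if (length(pairs$pairs) >= 3) {
      grid <- lag_correlation(pairs, tprof, prot$profiles)
      lag <- estimate_peak_lag(grid)
      paired <- paired_profile_export(pairs, tprof, prot$profiles)
      .stage_msg("integrate", "%d pairs; peak lag %g min (%s -> %s)",
                 length(pairs$pairs), lag$lag_minutes,
                 lag$transcript_condition, lag$protein_condition)
    } else {
      .stage_msg("integrate", "only %d pairs; lag grid skipped",
                 length(pairs$pairs))
    }
    integ <- list(pairs = pairs, partition = partition, grid = grid,
                  lag = lag, paired = paired)
  } else {
    .stage_msg("proteome", "protein layer absent; proteome and integration skipped")
  }

  clusters <- NULL
  reg_ids <- tcalls$feature_id[tcalls$regulated]
  if (length(reg_ids) >= max(2, config$cluster$min_size)) {
    z <- zscore_profiles(structure(list(
      log2fc = tprof$log2fc[reg_ids, , drop = FALSE],
      design = design, layer = "transcript"), class = "fc_profiles"))
    k_init <- min(config$cluster$k_init, nrow(z$z))
    if (nrow(z$z) >= 2 && k_init >= 2) {
      clusters <- extract_tight_clusters(
        z, k_init = k_init,
        tightness_quantile = config$cluster$tightness_quantile,
        merge_r = config$cluster$merge_r,
        min_size = config$cluster$min_size, seed = config$seed)
      cs <- cluster_summary(clusters, length(reg_ids))
      .stage_msg("cluster", "%d clusters, %d of %d genes (%.1f%%)",
                 cs$n_clusters, cs$n_clustered, length(reg_ids),
                 cs$fraction_clustered)
    }
  }

  summary <- if (!is.null(integ)) summarize_calls(tcalls, prot$calls, integ$partition)

  out <- list(sim = sim,
              transcript = list(profiles = tprof, calls = tcalls, pca = pca),
              proteome = prot, integration = integ, clusters = clusters,
              summary = summary, config = config)
  out$manifest <- .write_outputs(out, config)
  class(out) <- "pipeline_run"
  out
}

# write stage tables + manifest when an output directory is configured
.write_outputs <- function(run, config) {
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                               null = "null")
  tmp <- tempfile(); writeLines(cfg_json, tmp)
  manifest <- list(package_version = as.character(utils::packageVersion("photolag")),
                   seed = config$seed,
                   config_hash = unname(tools::md5sum(tmp)))
  unlink(tmp)
  dir <- config$output_dir
  if (is.null(dir)) return(manifest)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(run$sim)) write_light_sim(run$sim, file.path(dir, "simulated"))
  write_profiles_tsv(run$transcript$profiles, file.path(dir, "transcript_profiles.tsv"))
  write_calls_tsv(run$transcript$calls, file.path(dir, "transcript_calls.tsv"))
  if (!is.null(run$proteome)) {
    write_profiles_tsv(run$proteome$profiles, file.path(dir, "protein_profiles.tsv"))
    write_calls_tsv(run$proteome$calls, file.path(dir, "protein_calls.tsv"))
    utils::write.table(run$proteome$presence$presence,
                       file.path(dir, "protein_presence.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(run$proteome$presence$overlap,
                         file.path(dir, "protein_overlap.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(run$integration)) {
    jsonlite::write_json(unclass(run$integration$partition),
                         file.path(dir, "category_partition.json"),
                         auto_unbox = TRUE, digits = NA)
    if (!is.null(run$integration$grid)) {
      g <- run$integration$grid
      gd <- data.frame(transcript_condition = rownames(g$r),
                       round(g$r, 6), check.names = FALSE)
      utils::write.table(gd, file.path(dir, "lag_grid_r.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      utils::write.table(run$integration$paired,
                         file.path(dir, "paired_profiles.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  if (!is.null(run$clusters)) {
    mem <- do.call(rbind, lapply(run$clusters$clusters, function(cl)
      data.frame(feature_id = cl$members, cluster = cl$id, shape = cl$shape,
                 stringsAsFactors = FALSE)))
    mem <- rbind(mem, data.frame(feature_id = run$clusters$unassigned,
                                 cluster = "unassigned", shape = NA,
                                 stringsAsFactors = FALSE))
    utils::write.table(mem, file.path(dir, "cluster_membership.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(run$summary))
    jsonlite::write_json(unclass(run$summary)[names(run$summary) != "partition"],
                         file.path(dir, "summary.json"), auto_unbox = TRUE,
                         digits = NA)
  files <- list.files(dir, recursive = TRUE, full.names = TRUE)
  manifest$outputs <- lapply(stats::setNames(files, basename(files)),
                             function(f) unname(tools::md5sum(f)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("pipeline_run\n")
  cat(sprintf("  transcripts regulated: %d of %d\n",
              sum(x$transcript$calls$regulated), nrow(x$transcript$calls)))
  if (!is.null(x$proteome))
    cat(sprintf("  proteins regulated: %d of %d\n",
                sum(x$proteome$calls$regulated), nrow(x$proteome$imputed)))
  if (!is.null(x$integration) && !is.null(x$integration$lag))
    cat(sprintf("  pairs: %d; peak lag %g min\n",
                length(x$integration$pairs$pairs),
                x$integration$lag$lag_minutes))
  invisible(x)
}
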