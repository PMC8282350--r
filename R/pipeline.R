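#' Configuration for a simulate-then-analyze pipeline run
#'
#' @param out_dir output directory (created if missing).
#' @param seed integer master seed; every stage derives its own sub-seed
#'   from it, so a rerun with the same seed reproduces every table
#'   byte-for-byte.
#' @param stages character vector among `"structure"`, `"nmj"`, `"mtf"`,
#'   `"ephys"`, `"rnaseq"`.
#' @param params named list of per-stage parameter overrides (each element a
#'   list passed to that stage's generator spec).
#' @param plots also write PNG figures (requires ggplot2; tables are the
#'   contract, plots a convenience).
#' @return object of class `study_config`.
#' @export
study_config <- function(out_dir, seed = 1,
                         stages = c("structure", "nmj", "mtf", "ephys",
                                    "rnaseq"),
                         params = list(), plots = FALSE) {
  stopifnot(is.character(out_dir), length(out_dir) == 1,
            all(stages %in% c("structure", "nmj", "mtf", "ephys", "rnaseq")))
  structure(list(out_dir = out_dir, seed = as.integer(seed), stages = stages,
                 params = params, plots = isTRUE(plots)),
            class = "study_config")
}

## Stage sub-seeds: fixed offsets from the master seed (kept < 2^31).
stage_seed <- function(seed, stage) {
  (seed + 1000L * match(stage, c("structure", "nmj", "mtf", "ephys",
                                 "rnaseq"))) %% .Machine$integer.max
}

#' Run the simulate-then-analyze pipeline
#'
#' Executes the selected stages: each stage generates a synthetic dataset
#' under the study conditions (overridable via `config$params`), analyzes it
#' with the corresponding package functions, and writes its result tables
#' (CSV/JSON) under `out_dir/tables/`. A manifest with MD5 hashes of every
#' table, the effective configuration, and a structured run log (package and
#' R versions, seed, per-stage status) are written alongside. Reruns with
#' the same configuration are byte-identical.
#'
#' @param config a [study_config()].
#' @return invisibly, a list with per-stage results and statuses.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "study_config"))
  tab_dir <- file.path(config$out_dir, "tables")
  dir.create(tab_dir, recursive = TRUE, showWarnings = FALSE)
  if (length(config$stages) == 0)
    warning("no stages selected; writing an empty bundle")

  results <- list()
  status <- list()
  for (stage in config$stages) {
    res <- tryCatch(
      run_stage(stage, stage_seed(config$seed, stage),
                config$params[[stage]] %||% list(), tab_dir, config$plots),
      error = function(e) e)
    if (inherits(res, "error")) {
      status[[stage]] <- paste("failed:", conditionMessage(res))
    } else {
      status[[stage]] <- "ok"
      results[[stage]] <- res
    }
  }

  jsonlite::write_json(list(out_dir = config$out_dir, seed = config$seed,
                            stages = config$stages, params = config$params),
                       file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  files <- sort(list.files(tab_dir, full.names = TRUE))
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)))
  write.csv(manifest, file.path(config$out_dir, "manifest.csv"),
            row.names = FALSE)
  jsonlite::write_json(list(package = "ntmetrics",
                            package_version =
                              as.character(utils::packageVersion("ntmetrics")),
                            r_version = R.version.string,
                            seed = config$seed, status = status),
                       file.path(config$out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(results = results, status = status))
}

run_stage <- function(stage, seed, par, tab_dir, plots) {
  switch(stage,
    structure = {
      spec <- do.call(structure_image_spec, modifyList(
        list(field_size_um = c(400, 400), pixel_size_um = 0.2), par))
      g <- make_structure_image(spec, seed = seed)
      m <- tissue_structure_metrics(g$fov, seed = seed + 1L)
      df <- data.frame(nuclei_per_mm2 = m$nuclei_per_mm2,
                       myogenic_index = as.numeric(m$myogenic_index),
                       myotube_width_um = as.numeric(m$myotube_width_um),
                       sarcomere_index = m$sarcomere_index,
                       sarcomere_length_um = m$sarcomere_length_um)
      write.csv(df, file.path(tab_dir, "structure_metrics.csv"),
                row.names = FALSE)
      list(metrics = m, truth = g$truth)
    },
    nmj = {
      args <- modifyList(list(coloc_fraction = 0.6, seed = seed), par)
      g <- do.call(make_nmj_image, args)
      m <- nmj_metrics(g$fov)
      df <- data.frame(synapsin_area_pct = m$synapsin_area_pct,
                       btx_area_pct = m$btx_area_pct,
                       n_clusters = length(m$btx_cluster_areas_um2),
                       mean_cluster_um2 = mean(m$btx_cluster_areas_um2),
                       coloc_pct = as.numeric(m$coloc_pct))
      write.csv(df, file.path(tab_dir, "nmj_metrics.csv"), row.names = FALSE)
      list(metrics = m, truth = g$truth)
    },
    mtf = {
      geom <- do.call(mtf_geometry, modifyList(
        list(gel_thickness_um = 250), par$geometry %||% list()))
      spec <- do.call(mtf_video_spec, modifyList(
        list(n_films = 2, pixel_size_mm = 0.04), par$video %||% list()))
      g <- make_mtf_video(spec, geom, seed = seed)
      res <- analyze_mtf(g)
      sm <- do.call(rbind, lapply(seq_along(res$summaries), function(i) {
        s <- res$summaries[[i]]
        data.frame(film = i, basal_kpa = s$basal_kpa,
                   twitch_kpa = s$twitch_kpa, tetanus_kpa = s$tetanus_kpa,
                   tetanus_to_twitch = s$tetanus_to_twitch,
                   in_physiological_range = s$in_physiological_range)
      }))
      write.csv(sm, file.path(tab_dir, "mtf_summary.csv"), row.names = FALSE)
      write.csv(res$stress, file.path(tab_dir, "mtf_stress.csv"),
                row.names = FALSE)
      list(summaries = res$summaries, truth = g$truth)
    },
    ephys = {
      spec <- do.call(ephys_trace_spec, modifyList(
        list(duration_s = 60), par))
      g <- make_ephys_trace(spec, seed = seed)
      pre <- preprocess_trace(g$trace)
      ev <- detect_mepsps(pre)
      s <- summarize_ephys(ev, pre)
      write.csv(as.data.frame(ev), file.path(tab_dir, "mepsp_events.csv"),
                row.names = FALSE)
      df <- data.frame(mepsp_freq_hz = s$mepsp_freq_hz,
                       mean_amplitude_mv = s$mean_amplitude_mv,
                       mean_tau_rise_ms = s$mean_tau_rise_ms,
                       mean_tau_decay_ms = s$mean_tau_decay_ms,
                       rmp_mv = s$rmp_mv, n_events = s$n_events)
      write.csv(df, file.path(tab_dir, "ephys_summary.csv"), row.names = FALSE)
      list(summary = s, truth = g$truth)
    },
    rnaseq = {
      spec <- do.call(count_matrix_spec, modifyList(
        list(n_genes = 1500), par))
      g <- make_count_matrix(spec, seed = seed)
      nm <- fpkm_uq(g$cm)
      deg <- differential_expression(nm)
      pca <- pca_with_loadings(nm, n_components = 3)
      ord <- suppressWarnings(cluster_heatmap_order(nm))
      write.csv(as.data.frame(deg), file.path(tab_dir, "deg_table.csv"),
                row.names = FALSE)
      jsonlite::write_json(
        list(variance_pct = pca$variance_pct,
             scores = as.data.frame(pca$scores),
             top_genes_pc1 = top_loading_genes(pca, 1)),
        file.path(tab_dir, "pca.json"), digits = NA)
      jsonlite::write_json(list(gene_order = ord$gene_order,
                                sample_order = ord$sample_order),
                           file.path(tab_dir, "heatmap_order.json"),
                           digits = NA)
      if (plots) write_rnaseq_plots(deg, pca, tab_dir)
      list(deg = deg, pca = pca, order = ord, truth = g$truth)
    },
    stop("unknown stage: ", stage))
}

## Volcano and PCA scatter conveniences (tables remain the contract).
write_rnaseq_plots <- function(deg, pca, tab_dir) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    warning("ggplot2 not available; skipping plots")
    return(invisible(NULL))
  }
  gg <- ggplot2::ggplot(as.data.frame(deg),
                        ggplot2::aes(x = log2_fc, y = neg_log10_p,
                                     color = is_deg)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p", color = "DEG") +
    ggplot2::theme_minimal()
  ggplot2::ggsave(file.path(tab_dir, "volcano.png"), gg,
                  width = 5, height = 4, dpi = 120)
  sc <- as.data.frame(pca$scores)
  sc$sample <- rownames(sc)
  gg2 <- ggplot2::ggplot(sc, ggplot2::aes(x = PC1, y = PC2,
                                          label = sample)) +
    ggplot2::geom_point() + ggplot2::geom_text(vjust = -0.6, size = 3) +
    ggplot2::theme_minimal()
  ggplot2::ggsave(file.path(tab_dir, "pca_scores.png"), gg2,
                  width = 5, height = 4, dpi = 120)
  invisible(NULL)
}
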