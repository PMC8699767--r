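#' Per-condition summaries (mean and SD) of a results table
#'
#' Groups a long-format [results_table()] and reports the replicate count,
#' mean and sample standard deviation (n - 1 denominator) per group, in
#' deterministic lexicographic group order. Groups with a single replicate
#' report SD 0 and are flagged.
#'
#' @param table A [results_table()].
#' @param group_keys Grouping columns, default `c("condition", "metric")`.
#' @param metric Optional metric name to restrict to; an unknown metric is
#'   an error.
#' @return A tibble with columns `group_keys`, `n`, `mean`, `sd`,
#'   `sd_undefined` (TRUE when n = 1) and the list-column `values`.
#' @export
summarize_results <- function(table, group_keys = c("condition", "metric"),
                              metric = NULL) {
  validate_results_table(table)
  tbl <- table
  if (!is.null(metric)) {
    if (!metric %in% tbl$metric) stop(sprintf("unknown metric '%s'", metric))
    tbl <- tbl[tbl$metric == metric, ]
  }
  if (nrow(tbl) == 0L) stop("results table is empty for the requested metric")
  out <- tbl |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_keys))) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$value),
      sd = if (dplyr::n() > 1L) stats::sd(.data$value) else 0,
      sd_undefined = dplyr::n() == 1L,
      values = list(.data$value),
      units = .data$units[1L],
      .groups = "drop") |>
    dplyr::arrange(dplyr::across(dplyr::all_of(group_keys)))
  out
}

resolve_synthetic <- function(synth, pixel_size_um) {
  args <- synth
  type <- args$type %||% "nuclei"
  args$type <- NULL
  args$pixel_size_um <- args$pixel_size_um %||% pixel_size_um
  if (!is.null(args$image_shape)) args$image_shape <- as.integer(unlist(args$image_shape))
  spec <- do.call(synth_spec, args)
  switch(type,
    nuclei = { g <- generate_nuclei_image(spec)
               list(channels = list(dapi = g$dapi, marker = g$marker), truth = g$truth) },
    cell_body = { g <- generate_cell_body_image(spec)
                  list(channels = list(stain = g$stain), truth = g$truth) },
    coculture = { g <- generate_coculture_image(spec)
                  list(channels = g$channels, truth = g$truth) },
    stop(sprintf("unknown synthetic image type '%s'", type)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

need_channel <- function(channels, name, stage, image_id) {
  if (is.null(channels[[name]])) {
    stop(sprintf("stage '%s' needs channel '%s' for image '%s' but the config does not provide it",
                 stage, name, image_id))
  }
  channels[[name]]
}

#' Run the full quantification pipeline from a config
#'
#' Executes the requested stages (nuclei detection, marker classification,
#' elongation index, receptor-cluster quantification, myotube morphometry)
#' for every image of every condition listed in a JSON config (or an
#' equivalent list), collects all metrics into a [results_table()], writes
#' per-stage CSVs under `out_dir` and logs every parameter with its
#' provenance (user-supplied or Otsu default). Re-running with an
#' identical config (including synthetic seeds) reproduces all outputs
#' byte-exactly.
#'
#' Config keys: `pixel_size_um`, `out_dir`, `stages` (subset of
#' `"nuclei"`, `"markers"`, `"elongation"`, `"clusters"`, `"myotubes"`),
#' `params` (per-stage parameter lists) and `conditions`, a list of
#' `{name, images}` where each image has an `id` and either `synthetic`
#' (a [synth_spec()] argument list plus `type` of `"nuclei"`,
#' `"cell_body"` or `"coculture"`) or `channels` (named file paths).
#'
#' @param config Path to a JSON config file, or the equivalent list.
#' @param out_dir Output directory; overrides the config's `out_dir`.
#' @return The aggregated [results_table()], invisibly (also written to
#'   `out_dir/results.csv`).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- if (is.character(config)) {
    jsonlite::read_json(config, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                        simplifyMatrix = FALSE)
  } else config
  out_dir <- out_dir %||% cfg$out_dir
  if (is.null(out_dir)) stop("config must name an `out_dir` (or pass one explicitly)")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ps_um <- cfg$pixel_size_um %||% 0.5
  stages <- unlist(cfg$stages) %||% character()
  prm <- cfg$params %||% list()
  tbl <- results_table()
  log_lines <- c("nmjquant pipeline log",
                 sprintf("pixel_size_um = %g (user)", ps_um),
                 sprintf("stages = %s", paste(stages, collapse = ", ")))
  conditions <- cfg$conditions %||% list()
  n_images <- sum(vapply(conditions, function(cd) length(cd$images %||% list()), integer(1)))
  if (n_images == 0L) {
    warning("config lists no images; writing an empty results table")
  }
  for (cd in conditions) {
    cond <- cd$name %||% "condition"
    for (im in (cd$images %||% list())) {
      id <- im$id %||% "image"
      if (!is.null(im$synthetic)) {
        resolved <- resolve_synthetic(im$synthetic, ps_um)
        channels <- resolved$channels
        truth <- resolved$truth
        log_lines <- c(log_lines, sprintf("[%s/%s] synthetic image (type %s, seed %s)",
                                          cond, id, im$synthetic$type %||% "nuclei",
                                          im$synthetic$seed %||% "default"))
      } else {
        channels <- lapply(im$channels, function(p) read_image(p, ps_um))
        truth <- NULL
        log_lines <- c(log_lines, sprintf("[%s/%s] channels: %s", cond, id,
                                          paste(names(channels), collapse = ", ")))
      }
      centers <- NULL
      cls <- NULL
      if ("nuclei" %in% stages) {
        p <- prm$nuclei %||% list()
        dapi <- need_channel(channels, "dapi", "nuclei", id)
        thr <- p$detect_threshold %||% (0.2 * max(dapi$pixels))
        centers <- detect_nuclei(dapi, p$min_sigma_px %||% 3, p$max_sigma_px %||% 6,
                                 detect_threshold = thr)
        log_lines <- c(log_lines, sprintf("[%s/%s] nuclei: detect_threshold = %g (%s), %d detected",
                                          cond, id, thr,
                                          if (is.null(p$detect_threshold)) "default 0.2*max" else "user",
                                          n_points(centers)))
        tbl <- add_result(tbl, cond, id, "n_nuclei", n_points(centers), "count")
      }
      if ("markers" %in% stages) {
        p <- prm$markers %||% list()
        marker_img <- need_channel(channels, "marker", "markers", id)
        if (is.null(p$threshold)) stop("markers stage requires params$markers$threshold (user-defined)")
        rule <- p$rule %||% "point_max"
        if (rule == "point_max") {
          if (is.null(centers)) stop("markers stage (point_max) needs the nuclei stage first")
          cls <- classify_point_max(marker_img, centers, p$threshold,
                                    smooth_sigma_px = p$smooth_sigma_px %||% 0.5,
                                    window_px = p$window_px %||% 3L)
        } else {
          dapi <- need_channel(channels, "dapi", "markers", id)
          if (is.null(centers)) stop("markers stage (nuclear_mean) needs the nuclei stage first")
          segm <- segment_nuclei(dapi, centers, p$nuc_smooth_sigma_px %||% 2,
                                 p$fg_threshold)
          cls <- classify_nuclear_mean(marker_img, segm, p$threshold)
        }
        log_lines <- c(log_lines, sprintf("[%s/%s] markers: rule %s, threshold %g (user), %d/%d positive",
                                          cond, id, rule, p$threshold,
                                          cls$n_positive, cls$n_total))
        tbl <- add_result(tbl, cond, id, "fraction_positive",
                          cls$fraction_positive, "index")
      }
      if ("elongation" %in% stages) {
        p <- prm$elongation %||% list()
        stain <- channels$stain %||% channels$marker
        if (is.null(stain)) stop("stage 'elongation' needs channel 'stain' (or 'marker')")
        if (is.null(p$seg_threshold)) stop("elongation stage requires params$elongation$seg_threshold (user-defined)")
        n_pos <- p$n_positive %||%
          (if (!is.null(cls)) cls$n_positive else truth$n_cells)
        if (is.null(n_pos)) stop("elongation stage needs `n_positive` (from markers, config, or ground truth)")
        ep <- elongation_params(smooth_sigma_px = p$smooth_sigma_px %||% 8,
                                seg_threshold = p$seg_threshold,
                                n_erosions = p$n_erosions %||% 8L,
                                min_area_px2 = p$min_area_px2 %||% 960,
                                min_eccentricity = p$min_eccentricity %||% 0.75,
                                min_major_axis_px = p$min_major_axis_px %||% 120)
        er <- elongation_index(stain, n_pos, ep)
        log_lines <- c(log_lines, sprintf("[%s/%s] elongation: threshold %g (user), index %.4f (%d objects / %g cells)",
                                          cond, id, p$seg_threshold, er$index,
                                          n_objects(er$residual_objects), n_pos))
        tbl <- add_result(tbl, cond, id, "elongation_index", er$index, "index")
      }
      if ("clusters" %in% stages) {
        p <- prm$clusters %||% list()
        btx <- need_channel(channels, "btx", "clusters", id)
        myo <- need_channel(channels, "myotube", "clusters", id)
        if (is.null(p$btx_threshold)) stop("clusters stage requires params$clusters$btx_threshold (user-defined)")
        cl_mask <- segment_clusters(btx, p$btx_threshold, p$min_area_px2 %||% 4)
        ct <- cluster_table(cl_mask, ps_um)
        seg <- segment_myotubes_for_normalization(
          myo, unlist(p$percentiles %||% c(1, 99)), p$myotube_threshold %||% 0.5)
        if (seg$total_area_mm2 > 0) ct <- normalize_cluster_count(ct, seg$total_area_mm2)
        log_lines <- c(log_lines, sprintf("[%s/%s] clusters: btx_threshold %g (user), %d clusters on %.4f mm2",
                                          cond, id, p$btx_threshold,
                                          ct$summary$n_clusters, seg$total_area_mm2))
        tbl <- add_result(tbl, cond, id, "n_clusters", ct$summary$n_clusters, "count")
        if (ct$summary$n_clusters > 0) {
          tbl <- add_result(tbl, cond, id, "mean_cluster_area", ct$summary$mean_area_um2, "um2")
          tbl <- add_result(tbl, cond, id, "mean_cluster_intensity", ct$summary$mean_intensity_au, "au")
        }
        if (!is.na(ct$summary$clusters_per_mm2)) {
          tbl <- add_result(tbl, cond, id, "clusters_per_mm2", ct$summary$clusters_per_mm2, "count_per_mm2")
        }
        if (!is.null(channels$rapsyn) && !is.null(p$secondary_rule)) {
          sc <- score_secondary_channel(cl_mask, channels$rapsyn,
                                        rule = p$secondary_rule,
                                        threshold = p$secondary_threshold,
                                        secondary_threshold = p$secondary_binarize_threshold)
          tbl <- add_result(tbl, cond, id, "fraction_rapsyn_positive",
                            sc$fraction_positive, "index")
        }
      }
      if ("myotubes" %in% stages) {
        p <- prm$myotubes %||% list()
        myo <- need_channel(channels, "myotube", "myotubes", id)
        seg <- segment_myotubes_for_normalization(
          myo, unlist(p$percentiles %||% c(1, 99)), p$threshold %||% 0.5)
        rec <- measure_myotubes(seg$mask, ps_um)
        cov <- coverage_by_class(rec)
        log_lines <- c(log_lines, sprintf("[%s/%s] myotubes: %d objects, coverage large %.3f%% / small %.3f%%",
                                          cond, id, nrow(rec),
                                          cov$coverage_percent[1], cov$coverage_percent[2]))
        tbl <- add_result(tbl, cond, id, "coverage_large", cov$coverage_percent[1], "percent")
        tbl <- add_result(tbl, cond, id, "coverage_small", cov$coverage_percent[2], "percent")
      }
    }
  }
  write_table(tbl, file.path(out_dir, "results.csv"))
  writeLines(log_lines, file.path(out_dir, "pipeline.log"))
  invisible(tbl)
}
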