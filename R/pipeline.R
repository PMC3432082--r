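#' Pipeline configuration
#'
#' The resolved parameter set of a pipeline run. Defaults encode the
#' analysis conditions the package is calibrated for: 0.07 um/px and
#' 0.3 um z-steps, maximum-intensity projection of 10 sections, Otsu
#' gradient segmentation with the 0.5-1.1 um^2 bouton size window, CDA
#' with maximum displacement radius 20 px at 90% retention, and a 10-sample
#' post-event dF/F0 window. The object serializes to YAML and reloads to
#' an identical object ([write_config()] / [read_config()]); every
#' [run_pipeline()] call writes its resolved config next to its outputs.
#'
#' @param seed Integer seed governing every stochastic step.
#' @param calibration List `pixel_size_um`, `z_step_um`.
#' @param projection List `z_start`, `n_slices`, `method`.
#' @param segmentation List of [segment_boutons()] options.
#' @param cda List `max_radius`, `min_retained_fraction`, `weighted`.
#' @param dynamics List `post_samples`, optional `baseline_window`,
#'   `t_event`, `t_measure`.
#' @param stats List `design` (`"one-way"` or `"two-way"`), `posthoc`
#'   (`"dunnett"`, `"bonferroni"` or `"none"`), `control`, `alpha`,
#'   `n_mc`.
#' @param simulate List of generator settings for the `simulate` command
#'   (`n_boutons`, `coloc_fraction`, ...).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            calibration = list(pixel_size_um = 0.07,
                                               z_step_um = 0.3),
                            projection = list(z_start = 1L, n_slices = 10L,
                                              method = "max"),
                            segmentation = list(smooth_sigma = 1,
                                                threshold_method = "otsu",
                                                close_size = 3L,
                                                connectivity = 8L,
                                                min_um2 = 0.5,
                                                max_um2 = 1.1),
                            cda = list(max_radius = 20,
                                       min_retained_fraction = 0.9,
                                       weighted = TRUE),
                            dynamics = list(post_samples = 10L),
                            stats = list(design = "one-way",
                                         posthoc = "dunnett",
                                         control = NULL,
                                         alpha = 0.05, n_mc = 200000L),
                            simulate = list()) {
  structure(list(seed = as.integer(seed), calibration = calibration,
                 projection = projection, segmentation = segmentation,
                 cda = cda, dynamics = dynamics, stats = stats,
                 simulate = simulate),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path YAML path.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path, precision = 15L)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(pipeline_config, x)
}

cal_from_config <- function(config) {
  calibration(config$calibration$pixel_size_um,
              config$calibration$z_step_um)
}

write_table_csv <- function(df, path) {
  write.csv(df, path, row.names = FALSE)
  path
}

#' Run one pipeline command
#'
#' Dispatches one of the five analysis tracks over files on disk, writing
#' every output plus the resolved configuration and a manifest (inputs,
#' config hash, package version, output checksums — no timestamps, so
#' reruns with the same seed and config are byte-identical).
#'
#' Commands: `"simulate"` generates a two-channel colocalization scene, a
#' bouton field and fluorescence traces with ground truth; `"boutons"`
#' segments and counts boutons in a stack; `"coloc"` runs the CDA on two
#' channel stacks plus a confinement mask; `"dynamics"` quantifies dF/F0
#' (and, when configured, unloading) from a time-series CSV; `"stats"`
#' runs the configured ANOVA and post-test on a tidy CSV
#' (`value, group[, group2]`).
#'
#' @param config A [pipeline_config()].
#' @param command One of `"simulate"`, `"boutons"`, `"coloc"`,
#'   `"dynamics"`, `"stats"`.
#' @param out_dir Output directory (created if missing).
#' @param inputs Named list of input paths: `stack` (boutons); `ch1`,
#'   `ch2`, `confinement` (coloc); `timeseries`, optional `control`
#'   (dynamics); `data` (stats).
#' @return Invisibly, a list with `status` (0 on success), `outputs`
#'   (paths) and `manifest` (path).
#' @export
run_pipeline <- function(config, command = c("simulate", "boutons", "coloc",
                                             "dynamics", "stats"),
                         out_dir, inputs = list()) {
  stopifnot(inherits(config, "pipeline_config"))
  command <- match.arg(command)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_path <- file.path(out_dir, "config.yaml")
  write_config(config, cfg_path)
  cal <- cal_from_config(config)
  need <- function(nm) {
    p <- inputs[[nm]]
    if (is.null(p) || !file.exists(p)) {
      stop(sprintf("[%s] missing or unreadable input '%s'%s", command, nm,
                   if (is.null(p)) "" else sprintf(" (%s)", p)),
           call. = FALSE)
    }
    p
  }
  outputs <- character(0)
  add <- function(p) outputs <<- c(outputs, p)

  if (command == "simulate") {
    sim <- config$simulate
    cs <- coloc_scene_spec(
      shape = sim$coloc_shape %||% c(1L, 256L, 256L),
      coloc_fraction = sim$coloc_fraction %||% 0.5,
      cal = cal, seed = config$seed)
    scene <- generate_coloc_scene(cs)
    add(write_stack(scene$ch1, file.path(out_dir, "ch1.tif")))
    add(write_stack(scene$ch2, file.path(out_dir, "ch2.tif")))
    add(write_mask(scene$confinement, file.path(out_dir, "confinement.tif")))
    add(write_json_result(scene$truth, file.path(out_dir, "coloc_truth.json")))
    bs <- bouton_field_spec(
      shape = sim$bouton_shape %||% c(config$projection$n_slices, 512L, 512L),
      n_boutons = sim$n_boutons %||% 50L,
      cal = cal, seed = config$seed + 1L)
    field <- generate_bouton_field(bs)
    add(write_stack(field$stack, file.path(out_dir, "boutons.tif")))
    add(write_json_result(field$truth, file.path(out_dir, "bouton_truth.json")))
    tspec <- timeseries_spec(
      step_amplitude = sim$step_amplitude %||% 0.68,
      bleach_rate_per_s = sim$bleach_rate_per_s %||% 0.002,
      noise_sd = sim$ts_noise_sd %||% 0.05,
      seed = config$seed + 2L)
    tsim <- generate_timeseries(tspec)
    add(write_timeseries_csv(tsim$traces, file.path(out_dir, "timeseries.csv")))
    add(write_json_result(tsim$truth[names(tsim$truth) != "clean"],
                          file.path(out_dir, "timeseries_truth.json")))
  } else if (command == "boutons") {
    st <- read_stack(need("stack"), cal = cal)
    seg <- do.call(segment_boutons, c(
      list(x = st, z_start = config$projection$z_start,
           n_slices = config$projection$n_slices,
           method = config$projection$method),
      config$segmentation))
    add(write_table_csv(as.data.frame(seg$table),
                        file.path(out_dir, "bouton_table.csv")))
    h <- area_histogram(seg$table)
    add(write_table_csv(
      data.frame(bin_lo = h$edges[-length(h$edges)],
                 bin_hi = h$edges[-1], count = h$counts),
      file.path(out_dir, "area_histogram.csv")))
    add(write_label_map(seg$labels, file.path(out_dir, "labels.tif")))
    add(write_json_result(c(seg$settings, list(count = seg$count)),
                          file.path(out_dir, "segmentation_settings.json")))
  } else if (command == "coloc") {
    ch1 <- read_stack(need("ch1"), cal = cal)
    ch2 <- read_stack(need("ch2"), cal = cal)
    conf <- read_mask(need("confinement"))
    inp <- segment_coloc_channels(ch1, ch2, conf,
                                  method = config$projection$method)
    res <- cda_effective_colocalization(
      inp, max_radius = config$cda$max_radius,
      min_retained_fraction = config$cda$min_retained_fraction,
      weighted = config$cda$weighted)
    add(write_json_result(res, file.path(out_dir, "coloc_result.json")))
    add(write_table_csv(
      data.frame(m1_d0 = res$m1_d0, m1_random = res$m1_random,
                 m1_effective = res$m1_effective,
                 percent_effective = res$percent_effective,
                 n_displacements = res$n_displacements,
                 p_null = res$p_null),
      file.path(out_dir, "coloc_summary.csv")))
  } else if (command == "dynamics") {
    traces <- read_timeseries_csv(need("timeseries"))
    if (!is.null(inputs$control)) {
      ctrl <- read_timeseries_csv(inputs$control)[[1]]
      bw <- config$dynamics$baseline_window
      if (!is.null(bw)) ctrl <- normalize_trace(ctrl, unlist(bw))
      traces <- lapply(traces, bleach_correct, control = ctrl)
    }
    ev <- config$dynamics$t_event
    bw <- config$dynamics$baseline_window
    rows <- lapply(traces, function(tr) {
      if (!is.null(bw)) tr <- normalize_trace(tr, unlist(bw))
      if (!is.null(ev)) tr$meta$event_time_s <- ev
      df <- delta_f(tr, post_samples = config$dynamics$post_samples %||% 10L)
      out <- data.frame(roi_id = df$roi_id, f_pre = df$f_pre,
                        f_post = df$f_post, delta = df$delta)
      if (!is.null(config$dynamics$t_measure)) {
        out$unloading_decay <- unloading_decay(
          tr, t_event = ev %||% tr$meta$event_time_s,
          t_measure = config$dynamics$t_measure)
      }
      out
    })
    add(write_table_csv(do.call(rbind, rows),
                        file.path(out_dir, "dynamics.csv")))
  } else if (command == "stats") {
    df <- read.csv(need("data"))
    stopifnot(all(c("value", "group") %in% names(df)))
    if (identical(config$stats$design, "two-way")) {
      stopifnot("group2" %in% names(df))
      an <- two_way_anova(df$value, df$group, df$group2)
      add(write_table_csv(an$table, file.path(out_dir, "anova.csv")))
    } else {
      an <- one_way_anova(df$value, df$group)
      add(write_table_csv(
        data.frame(F = an$F, df_between = an$df_between,
                   df_within = an$df_within, p = an$p),
        file.path(out_dir, "anova.csv")))
    }
    add(write_table_csv(group_summary(df$value, df$group),
                        file.path(out_dir, "group_summary.csv")))
    ph <- config$stats$posthoc %||% "none"
    if (identical(ph, "dunnett")) {
      ctrl <- config$stats$control %||% levels(factor(df$group))[1]
      add(write_table_csv(
        dunnett_posthoc(df$value, df$group, control = ctrl,
                        alpha = config$stats$alpha %||% 0.05,
                        n_mc = config$stats$n_mc %||% 200000L,
                        seed = config$seed),
        file.path(out_dir, "posthoc.csv")))
    } else if (identical(ph, "bonferroni")) {
      add(write_table_csv(
        bonferroni_pairwise(df$value, df$group,
                            alpha = config$stats$alpha %||% 0.05),
        file.path(out_dir, "posthoc.csv")))
    }
  }

  manifest_path <- file.path(out_dir, "manifest.json")
  manifest <- list(
    command = command,
    package_version = as.character(utils::packageVersion("cdaq")),
    inputs = inputs,
    config_md5 = unname(tools::md5sum(cfg_path)),
    outputs = lapply(setNames(outputs, basename(outputs)),
                     function(p) unname(tools::md5sum(p))))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA)
  invisible(list(status = 0L, outputs = outputs, manifest = manifest_path,
                 config = cfg_path))
}
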