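#' Run the full analysis pipeline from a configuration
#'
#' Executes the requested stages in order -- `simulate` (synthetic
#' population + renders), `cells` (lengths, minicells, constrictions),
#' `clusters` (profile extraction, cluster calls, localization fractions),
#' `demograph`, `timelapse` (division tracking and fission statistics) and
#' `atpase` (trace simulation/reading, control subtraction, rates) -- and
#' writes versioned outputs plus a machine-readable `summary.json` into the
#' output directory. Identical configuration and seed give an identical
#' summary. Stages whose configuration block is absent are skipped; omitted
#' stages leave the others unchanged.
#'
#' @param config A configuration list or path to a YAML file. Top-level
#'   fields: `out_dir`, `seed`, and per-stage blocks `simulate`
#'   (`preset` or [population_params()] fields, `n`, render settings),
#'   `cells` (`minicell_cutoff`, `constriction_depth`), `clusters`
#'   (`k_sigma`, `min_width_segments`), `demograph` (`bin_size`),
#'   `timelapse` (`fission_probability`, `n_divisions`, `frame_interval`),
#'   `atpase` (`preset` or [kinetic_truth()] fields, `window`).
#' @return Invisibly, the summary list.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop_input("config must be a list or a YAML path")
  out_dir <- config$out_dir %||% stop_input("config$out_dir is required")
  seed <- as.integer(config$seed %||% 1L)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  summary <- list(version = as.character(utils::packageVersion("pomogram")),
                  seed = seed,
                  config_hash = digest::digest(config, algo = "sha1"))
  truths <- NULL; renders <- NULL; profiles <- NULL

  sim <- config$simulate
  if (!is.null(sim)) {
    params <- if (!is.null(sim$preset)) population_preset(sim$preset)
              else do.call(population_params,
                           sim[intersect(names(sim), names(formals(population_params)))])
    n <- as.integer(sim$n %||% 100L)
    truths <- sample_cell_population(params, n, seed = seed)
    write.csv(truths, file.path(out_dir, "truth.csv"), row.names = FALSE)
    renders <- render_population(truths, seed = seed,
                                 pixel_size = sim$pixel_size %||% 0.1,
                                 noise_sd = sim$noise_sd %||% 0.1)
    write_mesh_csv(lapply(renders, `[[`, "mesh"),
                   file.path(out_dir, "meshes.csv"), seed = seed)
    summary$simulate <- list(preset = params$label, n = n)
  } else if (!is.null(config$mesh_csv)) {
    renders <- NULL
    meshes <- read_mesh_csv(config$mesh_csv)
  }

  if (!is.null(config$cells)) {
    meshes <- if (!is.null(renders)) lapply(renders, `[[`, "mesh")
              else read_mesh_csv(config$mesh_csv %||%
                                   stop_input("cells stage needs simulate or mesh_csv"))
    cc <- config$cells
    lens <- vapply(meshes, cell_length, numeric(1))
    cons <- do.call(rbind, lapply(meshes, function(m)
      detect_constriction(width_profile(m), relative_positions(m),
                          min_depth = cc$constriction_depth %||% 0.10,
                          cell_id = m$cell_id)))
    mini <- classify_minicell(lens, cutoff = cc$minicell_cutoff %||% 2.0)
    percell <- data.frame(cell_id = vapply(meshes, `[[`, "", "cell_id"),
                          length_um = lens, minicell = mini,
                          constriction = cons$present,
                          constriction_position = cons$relative_position)
    write.csv(percell, file.path(out_dir, "cells.csv"), row.names = FALSE)
    ls <- summarize_lengths(lens)
    summary$cells <- list(n = ls$n, mean_length_um = ls$mean,
                          sd_length_um = ls$sd, median_um = ls$median,
                          minicell_fraction = mean(mini),
                          constriction_frequency = mean(cons$present))
  }

  if (!is.null(config$clusters) && !is.null(renders)) {
    kc <- config$clusters
    profiles <- lapply(renders, function(r) extract_profile(r$image, r$mesh))
    calls <- lapply(profiles, detect_clusters,
                    k_sigma = kc$k_sigma %||% 2,
                    min_width_segments = kc$min_width_segments %||% 2)
    all_calls <- do.call(rbind, calls)
    if (nrow(all_calls) > 0)
      all_calls$localization <- classify_localization(
        all_calls$relative_position,
        nucleoid_span = kc$nucleoid_span %||% 0.8)
    write.csv(all_calls, file.path(out_dir, "cluster_calls.csv"),
              row.names = FALSE)
    frac <- cluster_fraction(calls)
    loc_frac <- if (nrow(all_calls) > 0)
      as.list(prop.table(table(all_calls$localization))) else list()
    summary$clusters <- list(cluster_fraction = frac,
                             localization_fractions = loc_frac)
  }

  if (!is.null(config$demograph) && !is.null(profiles)) {
    lens <- vapply(renders, function(r) cell_length(r$mesh), numeric(1))
    dg <- build_demograph(profiles, lens,
                          bin_size = config$demograph$bin_size %||% 0.1)
    write.csv(dg$matrix, file.path(out_dir, "demograph.csv"),
              row.names = FALSE)
    grDevices::png(file.path(out_dir, "demograph.png"), width = 600,
                   height = 400)
    plot(dg)
    grDevices::dev.off()
    summary$demograph <- list(n_cells = dg$n_cells, cap_value = dg$cap_value)
  }

  if (!is.null(config$timelapse)) {
    tc <- config$timelapse
    params <- if (!is.null(tc$preset)) population_preset(tc$preset)
              else population_preset("WT")
    sim_tl <- simulate_timelapse(params,
                                 fission_probability = tc$fission_probability %||% 0.8,
                                 n_divisions = tc$n_divisions %||% 50,
                                 frame_interval = tc$frame_interval %||% 20,
                                 seed = seed)
    lin <- link_generations(sim_tl)
    fs <- fission_summary(lin)
    write.csv(lin$events, file.path(out_dir, "division_events.csv"),
              row.names = FALSE)
    summary$timelapse <- list(n_events = fs$n_events,
                              n_excluded = fs$n_excluded,
                              fission_fraction = fs$fission_fraction)
  }

  if (!is.null(config$atpase)) {
    ac <- config$atpase
    traces <- if (!is.null(ac$trace_csv)) {
      read_trace_csv(ac$trace_csv)
    } else {
      truth <- if (!is.null(ac$preset)) kinetic_preset(ac$preset)
               else do.call(kinetic_truth,
                            ac[intersect(names(ac), names(formals(kinetic_truth)))])
      tr <- simulate_atpase_trace(truth, seed = seed)
      write_trace_csv(tr, file.path(out_dir, "traces.csv"), seed = seed)
      tr
    }
    samples <- Filter(function(x) !x$is_control, traces)
    controls <- Filter(function(x) x$is_control, traces)
    window <- as.numeric(ac$window %||% c(300, Inf))
    rates <- lapply(samples, function(s) {
      corr <- if (length(controls)) subtract_control(s, controls[[1]]) else s
      specific_activity(adp_rate(corr, window = window))
    })
    rate_tab <- do.call(rbind, lapply(rates, function(r)
      data.frame(adp_rate_uM_hr = r$adp_rate,
                 specific_activity = r$specific_activity,
                 r_squared = r$r_squared, enzyme_conc = r$enzyme_conc)))
    write.csv(rate_tab, file.path(out_dir, "rates.csv"), row.names = FALSE)
    summary$atpase <- list(specific_activities = rate_tab$specific_activity)
  }

  json <- jsonlite::toJSON(summary, auto_unbox = TRUE, digits = 10,
                           pretty = TRUE)
  writeLines(json, file.path(out_dir, "summary.json"))
  invisible(summary)
}
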