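#' Default pipeline configuration
#'
#' All stage defaults equal the standard measurement values where one
#' exists: 107 nm pixels, 19 ms frames, 19/25 nm precisions, jump-fit lag
#' defaults (1-5 for 1D, 10-50 for 2D), STaSI parameters (2% false-positive
#' limit, 70-photon separation, 50-frame dwell, 6-frame lag) and the
#' 107 nm co-localization radius.
#'
#' @param seed Integer seed for the synthetic stages.
#' @return A nested list with class `"pipeline_config"`.
#' @export
default_pipeline_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    acquisition = list(
      pixel_size = 0.107, frame_interval = 0.019, frame_count = 30,
      field_size = 64, psf_sigma = 0.128,
      loc_precision = c(0.019, 0.025),
      photons_per_fluorophore = 500, background_photons = 10
    ),
    trajectories = list(
      n = 300, populations = list(D = c(2.5, 1.0), fraction = c(0.5, 0.5)),
      immobile_fraction = 0.2, d_threshold = 0.05, n_components = 2,
      coloc_radius = 0.107
    ),
    stepcount = list(
      n_traces = 60, mix = c(0.6, 0.25, 0.1, 0.05), frame_count = 800,
      fp_limit = 0.02, min_separation = 70, min_dwell = 50, max_lag = 6
    ),
    piccs = list(
      density = 2, alpha_true = 0.092, displacement_sigma = 0.0225,
      area = 400, r_max = 0.5
    ),
    kinetics = list(
      ka = 1.5e5, kd = 4.1e-4, conc = 1e-7, t_assoc = 220, t_diss = 220,
      noise_sigma = 0.002
    )
  ), class = "pipeline_config")
}

#' Read / write a pipeline configuration (YAML)
#'
#' Configurations round-trip exactly (`load -> save -> load` identical).
#' Unknown keys at any level are rejected to catch typos.
#'
#' @param path YAML file.
#' @param config A `"pipeline_config"` list.
#' @return A `"pipeline_config"` (read); `path` invisibly (write).
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  ref <- unclass(default_pipeline_config())
  check_keys <- function(x, template, where) {
    bad <- setdiff(names(x), names(template))
    if (length(bad))
      abort(sprintf("unknown config key(s) %s in %s",
                    paste(bad, collapse = ", "), where))
  }
  check_keys(cfg, ref, "top level")
  for (blk in intersect(names(cfg), names(ref))) {
    if (is.list(ref[[blk]]) && is.list(cfg[[blk]]))
      check_keys(cfg[[blk]], ref[[blk]], blk)
  }
  merged <- utils::modifyList(ref, cfg)
  structure(merged, class = "pipeline_config")
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full synthetic analysis pipeline
#'
#' Executes every stage on synthetic data generated from the
#' configuration: planar trajectory simulation, mobile/immobile
#' classification, jump-distance mixture fitting, photobleaching trace
#' simulation and step counting, point-pattern simulation and PICCS, and
#' binding-curve simulation and kinetic fitting. Produces a
#' machine-readable report; with `out_dir` set, intermediate tables and
#' the JSON report are written there.
#'
#' @param config A `"pipeline_config"` (see [default_pipeline_config()],
#'   [read_pipeline_config()]).
#' @param out_dir Output directory, or NULL for no files.
#' @param quiet Suppress progress messages (default FALSE).
#' @return The report as a nested list (invisibly classed
#'   `"pipeline_report"`), with blocks `mobility`, `diffusion`,
#'   `stepcount`, `piccs`, `kinetics` and a `meta` block (seed, package
#'   version).
#' @export
run_pipeline <- function(config = default_pipeline_config(), out_dir = NULL,
                         quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  stopifnot(inherits(config, "pipeline_config") || is.list(config))
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  seed <- config$seed %||% 1L
  acq <- config$acquisition

  make_cfg <- function(seed_offset, frame_count = acq$frame_count) {
    acq_config(
      pixel_size = acq$pixel_size, frame_interval = acq$frame_interval,
      frame_count = frame_count, field_size = acq$field_size,
      psf_sigma = acq$psf_sigma, loc_precision = acq$loc_precision,
      photons_per_fluorophore = acq$photons_per_fluorophore,
      background_photons = acq$background_photons,
      rng_seed = (seed * 1000L + seed_offset) %% .Machine$integer.max
    )
  }

  # --- trajectories: simulate, classify, fit diffusion mixture ----------
  say("stage trajectories: simulating and classifying")
  tj <- config$trajectories
  pops <- as_tibble(tj$populations)
  locs <- sim_planar_trajectories(pops, n = tj$n,
                                  immobile_fraction = tj$immobile_fraction,
                                  cfg = make_cfg(1L))
  cls <- classify_mobility(locs, d_threshold = tj$d_threshold,
                           cfg = make_cfg(1L))
  frac <- prop_table(table(factor(cls$mobility,
                                  c("mobile", "immobile", "unclassified"))))
  mobile_ids <- cls$traj_id[cls$mobility == "mobile"]
  jumps <- jump_magnitudes(locs[locs$traj_id %in% mobile_ids, ], lag = 1, d = 2)
  jf <- fit_jump_distribution(jumps, d = 2, n_components = tj$n_components,
                              dt = acq$frame_interval,
                              eps = acq$loc_precision[1])

  # --- step counting ----------------------------------------------------
  say("stage stepcount: simulating bleach traces and counting")
  sc <- config$stepcount
  n_fluor <- sample(seq_along(sc$mix), sc$n_traces, replace = TRUE,
                    prob = sc$mix)
  traces <- sim_bleach_traces(n_fluor, make_cfg(2L, sc$frame_count))
  counts <- purrr::map_int(unique(traces$trace_id), function(id) {
    fit <- stasi_segment(traces$photons[traces$trace_id == id],
                         fp_limit = sc$fp_limit,
                         min_separation = sc$min_separation)
    count_bleach_steps(fit, min_dwell = sc$min_dwell,
                       max_lag = sc$max_lag)$n_steps
  })
  step_hist <- as.list(table(counts))

  # --- PICCS ------------------------------------------------------------
  say("stage piccs: pattern pair and correlation fit")
  pc <- config$piccs
  pp <- sim_point_pattern_pair(pc$density, pc$alpha_true,
                               pc$displacement_sigma, pc$area,
                               cfg = make_cfg(3L))
  side <- sqrt(pc$area)
  cv <- piccs_correlation(pp, radii = seq(0.005, pc$r_max, by = 0.005),
                          bounds = c(0, side, 0, side))
  pfit <- fit_piccs(cv)

  # --- kinetics ---------------------------------------------------------
  say("stage kinetics: binding curve fit")
  kn <- config$kinetics
  bc <- sim_binding_curve(kn$ka, kn$kd, kn$conc, kn$t_assoc, kn$t_diss,
                          kn$noise_sigma, cfg = make_cfg(4L))
  kfit <- fit_binding_phases(bc)

  report <- list(
    meta = list(seed = seed,
                package = as.character(utils::packageVersion("poretrack"))),
    mobility = list(fraction_mobile = unname(frac["mobile"]),
                    fraction_immobile = unname(frac["immobile"]),
                    fraction_unclassified = unname(frac["unclassified"]),
                    n_trajectories = nrow(cls)),
    diffusion = list(D_components = jf$components$D_um2_s,
                     weights = jf$components$weight,
                     n_jumps = jf$n),
    stepcount = list(histogram = step_hist, n_traces = sc$n_traces),
    piccs = list(alpha = pfit$alpha, sigma_c_nm = 1000 * pfit$sigma_c_um,
                 rho_um2 = pfit$rho),
    kinetics = list(ka = kfit$ka, kd = kfit$kd, k_obs = kfit$k_obs,
                    KD = kfit$KD)
  )
  validate_report(report)

  if (!is.null(out_dir)) {
    write_localizations(locs, file.path(out_dir, "trajectories.csv"))
    write_traces(traces, file.path(out_dir, "bleach_traces.csv"))
    utils::write.csv(as.data.frame(pp), file.path(out_dir, "patterns.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(bc), file.path(out_dir, "binding_curve.csv"),
                     row.names = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    say("report written to %s", file.path(out_dir, "report.json"))
  }
  invisible(structure(report, class = "pipeline_report"))
}

# check the report against the checked-in schema (required key paths)
validate_report <- function(report) {
  schema_path <- system.file("schema", "report_schema.json",
                             package = "poretrack")
  if (schema_path == "") return(invisible(TRUE))
  schema <- jsonlite::read_json(schema_path)
  for (blk in names(schema$required)) {
    if (!blk %in% names(report))
      abort(sprintf("report lacks required block '%s'", blk))
    need <- unlist(schema$required[[blk]])
    miss <- setdiff(need, names(report[[blk]]))
    if (length(miss))
      abort(sprintf("report block '%s' lacks field(s) %s", blk,
                    paste(miss, collapse = ", ")))
  }
  invisible(TRUE)
}
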