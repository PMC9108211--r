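#' Assemble a full scenario configuration
#'
#' Bundles geometry, kinetics, channel/pump parameters, stimulation,
#' solver options and the probe set into one configuration object, the
#' single input of [run_scenario()].
#'
#' @param geometry an [geometry_spec()].
#' @param h grid spacing (um).
#' @param kinetics [kinetic_params()].
#' @param channel [channel_params()].
#' @param pumps [pump_params()].
#' @param train [ap_train()] or `NULL` for an unstimulated run.
#' @param solver [solver_config()].
#' @param probes list with numeric vectors `R`, `H` (um) and optional
#'   `n_phi_max`; probes are the cross product of `R` and `H`.
#' @param t_end simulated duration (s).
#' @param V_rest resting potential (mV) used for gating initialization and
#'   leak calibration.
#' @param constants [physical_constants()].
#' @param rho_vgcc_override channel density (um^-2) overriding the value
#'   derived as `n_channels / area(C)`; `NULL` (default) derives it.
#' @param snapshot_times times (s) at which full field snapshots are
#'   kept in the result (exportable with [write_vtk_image()]), or `NULL`.
#' @param label free-text scenario label.
#' @return list of class `az_config`.
#' @export
scenario_config <- function(geometry, h = 0.01,
                            kinetics = kinetic_params(),
                            channel = channel_params(),
                            pumps = pump_params(),
                            train = ap_train(),
                            solver = solver_config(),
                            probes = list(R = c(0.02, 0.03, 0.04, 0.05),
                                          H = c(0.01, 0.02, 0.03, 0.04),
                                          n_phi_max = 64L),
                            t_end = if (!is.null(train)) 2 / train$frequency else 0.05,
                            V_rest = -70,
                            constants = physical_constants(),
                            rho_vgcc_override = NULL,
                            snapshot_times = NULL,
                            label = "scenario") {
  stopifnot(inherits(geometry, "az_geometry"), t_end > 0)
  structure(list(geometry = geometry, h = h, kinetics = kinetics,
                 channel = channel, pumps = pumps, train = train,
                 solver = solver, probes = probes, t_end = t_end,
                 V_rest = V_rest, constants = constants,
                 rho_vgcc_override = rho_vgcc_override,
                 snapshot_times = snapshot_times, label = label),
            class = "az_config")
}

#' Canonical scenario presets
#'
#' The three anatomical scenarios: `"tbar_clustered"` (T-bar present,
#' channels clustered in the 70 nm annular zone), `"no_tbar_clustered"`
#' (same channel zone, obstacle absent) and `"no_tbar_dispersed"`
#' (no T-bar, the same 6 channels spread over the 140 nm disk). All three
#' share kinetics, stimulation and solver settings; only the geometry and
#' the channel zone differ.
#'
#' The channel density is derived as `n_channels / area(C)` on the actual
#' grid, so every scenario carries exactly `n_channels` channels at any
#' resolution. `use_literature_density = TRUE` instead applies the rounded
#' literature densities 2297.1 um^-2 (clustered) / 395.8 um^-2
#' (dispersed).
#'
#' @param name preset name.
#' @param box_mode `"reduced"` (0.6 x 0.6 x 0.3 um desk-scale box, the
#'   default), `"full"` (the full-size 1.2 x 1.2 x 0.6 um box), or `"mini"`
#'   (0.24 x 0.24 x 0.12 um, for cheap parameter sweeps). The far-field
#'   walls sit well outside the sub-50-nm microdomain in every mode;
#'   scenario ratios are insensitive to the choice (the far-field
#'   invariance is itself under test).
#' @param h grid spacing (um).
#' @param frequency stimulation frequency (Hz).
#' @param t_end simulated duration (s); default two stimulation periods.
#' @param n_channels channel count (default 6).
#' @param use_literature_density use the rounded literature channel
#'   densities instead of the derived ones.
#' @param ... further arguments passed to [scenario_config()]
#'   (`kinetics`, `pumps`, `solver`, `probes`, ...).
#' @return an `az_config`.
#' @export
make_preset <- function(name = c("tbar_clustered", "no_tbar_clustered",
                                 "no_tbar_dispersed"),
                        box_mode = c("reduced", "full", "mini"),
                        h = 0.01, frequency = 40,
                        t_end = 2 / frequency,
                        n_channels = 6L,
                        use_literature_density = FALSE, ...) {
  name <- match.arg(name)
  box_mode <- match.arg(box_mode)
  box <- switch(box_mode, full = c(1.2, 1.2, 0.6),
                reduced = c(0.6, 0.6, 0.3), mini = c(0.24, 0.24, 0.12))
  geo <- switch(name,
    tbar_clustered = geometry_spec(box_dims = box, has_tbar = TRUE,
                                   channels_clustered = TRUE,
                                   n_channels = n_channels),
    no_tbar_clustered = geometry_spec(box_dims = box, has_tbar = FALSE,
                                      channels_clustered = TRUE,
                                      n_channels = n_channels),
    no_tbar_dispersed = geometry_spec(box_dims = box, has_tbar = FALSE,
                                      channels_clustered = FALSE,
                                      n_channels = n_channels))
  rho <- NULL
  if (use_literature_density) {
    rho <- if (name == "no_tbar_dispersed") 395.8 else 2297.1
    rho <- rho * n_channels / 6
  }
  scenario_config(geometry = geo, h = h,
                  train = ap_train(frequency = frequency,
                                   duration = t_end),
                  t_end = t_end,
                  rho_vgcc_override = rho,
                  label = name, ...)
}

#' Run and compare the three scenarios
#'
#' Runs the requested presets at each stimulation frequency and reports
#' the scenario ratios (percent excess and folds) at every probe and
#' every completed action-potential period.
#'
#' @param scenarios preset names (must include `tbar_clustered` and
#'   `no_tbar_clustered`).
#' @param frequencies stimulation frequencies (Hz).
#' @param ... passed to [make_preset()] (`box_mode`, `h`, `t_end`, ...).
#' @return list with `results` (nested by frequency then scenario) and
#'   `ratios` (long data.frame).
#' @export
run_comparison <- function(scenarios = c("tbar_clustered",
                                         "no_tbar_clustered",
                                         "no_tbar_dispersed"),
                           frequencies = 40, ...) {
  all_res <- list()
  rows <- list()
  for (f in frequencies) {
    res <- lapply(scenarios, function(s)
      run_scenario(make_preset(s, frequency = f, ...)))
    names(res) <- scenarios
    all_res[[as.character(f)]] <- res
    tb <- res[["tbar_clustered"]]
    cl <- res[["no_tbar_clustered"]]
    dp <- res[["no_tbar_dispersed"]]
    periods <- unique(tb$peaks$period)
    for (p in periods) {
      for (r in seq_len(nrow(tb$probe_meta))) {
        cmp <- scenario_ratios(tb, cl, dp,
                               R = tb$probe_meta$R[r],
                               H = tb$probe_meta$H[r], peak_index = p)
        cmp$frequency <- f
        rows[[length(rows) + 1L]] <- cmp
      }
    }
  }
  list(results = all_res, ratios = do.call(rbind, rows))
}

#' Channel-number sensitivity sweep
#'
#' Re-runs the scenario comparison for several channel counts and reports
#' per-count peak tables, cross-scenario ratios and the proportionality
#' diagnostic (peak rise above baseline versus channel count).
#'
#' @param counts channel counts (>= 1).
#' @param R,H probe used for the diagnostic (um).
#' @param scenarios preset names.
#' @param ... passed to [make_preset()].
#' @return list with `ratios` (per count), `proportionality` (data.frame
#'   of count, scenario, peak rise), and `results`.
#' @export
sweep_vgcc <- function(counts = c(1L, 6L, 20L), R = 0.03, H = 0.01,
                       scenarios = c("tbar_clustered", "no_tbar_clustered",
                                     "no_tbar_dispersed"), ...) {
  stopifnot(all(counts >= 1))
  out_r <- list()
  prop <- list()
  results <- list()
  for (n in counts) {
    res <- lapply(scenarios, function(s)
      run_scenario(make_preset(s, n_channels = n, ...)))
    names(res) <- scenarios
    results[[as.character(n)]] <- res
    cmp <- scenario_ratios(res[["tbar_clustered"]],
                           res[["no_tbar_clustered"]],
                           res[["no_tbar_dispersed"]],
                           R = R, H = H, peak_index = 1L)
    cmp$n_channels <- n
    out_r[[length(out_r) + 1L]] <- cmp
    ca0 <- res[[1]]$config$kinetics$Ca_V0
    for (s in scenarios) {
      pk <- scenario_peak(res[[s]], R, H, 1L)
      prop[[length(prop) + 1L]] <-
        data.frame(n_channels = n, scenario = s, peak = pk,
                   rise = pk - ca0)
    }
  }
  list(ratios = do.call(rbind, out_r),
       proportionality = do.call(rbind, prop),
       results = results)
}

scenario_peak <- function(res, R, H, period) {
  sel <- res$peaks$R == R & res$peaks$H == H & res$peaks$period == period
  res$peaks$value[which(sel)]
}

#' Buffer and pump on/off comparison
#'
#' Runs each scenario once with the standard buffering rates and maximal
#' pump densities and once with buffering, pumps and leak switched off,
#' and reports paired peak tables.
#'
#' @param scenarios preset names.
#' @param R,H probe (um).
#' @param ... passed to [make_preset()].
#' @return data.frame with peaks for both cases per scenario.
#' @export
sweep_buffer_pumps <- function(scenarios = c("tbar_clustered",
                                             "no_tbar_clustered",
                                             "no_tbar_dispersed"),
                               R = 0.03, H = 0.01, ...) {
  rows <- list()
  for (s in scenarios) {
    on <- run_scenario(make_preset(s, ...))
    off <- run_scenario(make_preset(
      s, kinetics = kinetic_params(k_on = 0, k_off = 0),
      pumps = pump_params(rho_pmca = 0, rho_ncx = 0), ...))
    rows[[s]] <- data.frame(
      scenario = s,
      peak_on = scenario_peak(on, R, H, 1L),
      peak_off = scenario_peak(off, R, H, 1L))
  }
  out <- do.call(rbind, rows)
  out$increase_pct <- 100 * (out$peak_off - out$peak_on) / out$peak_on
  out
}

#' Grid-convergence study
#'
#' Runs the same physical configuration on nested refinement levels
#' (spacing halved per level) and reports the successive relative
#' differences of all probe values at the final time. The default
#' configuration is a short single-pulse run.
#'
#' @param config base `az_config`; its `h` is the coarsest level.
#' @param levels number of nested levels (>= 2).
#' @param scale_dt scale the time steps with `(h/h_base)^2` so the
#'   diffusion number `D*dt/h^2` (and hence the splitting error of the
#'   dimension-split solver) is held constant across levels; the
#'   remaining level-to-level differences then measure the spatial
#'   discretization. With `FALSE` the base configuration's steps are
#'   used at every level.
#' @return list with `h_levels`, `values` (per level), and the
#'   [grid_convergence()] report.
#' @export
convergence_study <- function(config, levels = 3L, scale_dt = TRUE) {
  stopifnot(levels >= 2)
  hs <- config$h / 2^(seq_len(levels) - 1)
  vals <- lapply(hs, function(hh) {
    cf <- config
    cf$h <- hh
    if (scale_dt) {
      s <- (hh / config$h)^2
      cf$solver$dt_spike <- config$solver$dt_spike * s
      cf$solver$dt_rest <- config$solver$dt_rest * s
    }
    res <- run_scenario(cf)
    value_at_time(res, cf$t_end)
  })
  list(h_levels = hs, values = vals,
       report = grid_convergence(vals, hs))
}

## ---- configuration I/O ------------------------------------------------

## fields kept integer on restore; everything else numeric becomes double
.az_int_fields <- c("n_channels", "a", "b", "n_phi_max", "max_halvings",
                    "record_every", "z")

az_serialize <- function(x) {
  if (is.list(x)) {
    out <- lapply(x, az_serialize)
    cls <- class(x)
    if (length(cls) && cls[1] != "list" && cls[1] != "data.frame")
      out[[".az_class"]] <- cls
    out
  } else x
}

az_restore <- function(x, name = "") {
  if (is.list(x)) {
    cls <- x[[".az_class"]]
    x[[".az_class"]] <- NULL
    out <- lapply(seq_along(x), function(i)
      az_restore(x[[i]], names(x)[i] %||% ""))
    names(out) <- names(x)
    if (!is.null(cls)) {
      class(out) <- unlist(cls)
      out <- az_rehydrate(out)
    }
    out
  } else if (is.numeric(x)) {
    if (name %in% .az_int_fields) as.integer(x) else as.numeric(x)
  } else x
}

## Rebuild serialized objects through their constructors so derived
## quantities (K_D, B_V0, waveform normalization, ...) are recomputed at
## full precision rather than read back from rounded text.
az_rehydrate <- function(x) {
  cls <- class(x)[1]
  take <- function(drop) x[setdiff(names(x), drop)]
  switch(cls,
    az_kinetics = do.call(kinetic_params, take(c("K_D", "B_V0"))),
    az_train = {
      a <- take(c("norm", "w_end"))
      if (!is.null(a$waveform)) a$waveform <- as.data.frame(a$waveform)
      do.call(ap_train, a)
    },
    az_geometry = do.call(geometry_spec, take(character())),
    az_gate = do.call(gate_params, take(character())),
    az_channel = channel_params(p_x = x$p_x, a = x$a, b = x$b,
                                m = x$gates$m, h = x$gates$h),
    az_pumps = do.call(pump_params, take(character())),
    az_solver = do.call(solver_config, take(character())),
    x)
}

#' Write / read a scenario configuration
#'
#' Serializes an `az_config` to JSON (`.json`) or YAML (`.yml`/`.yaml`).
#' The round trip is lossless: `read_config(write_config(cfg, f))`
#' reconstructs an identical configuration.
#'
#' @param config an `az_config`.
#' @param path output file; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "az_config"))
  ser <- az_serialize(config)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  } else if (ext %in% c("yml", "yaml")) {
    writeLines(yaml::as.yaml(ser, precision = 15), path)
  } else stop("config format must be .json, .yml or .yaml")
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                        simplifyMatrix = FALSE)
  } else if (ext %in% c("yml", "yaml")) {
    yaml::read_yaml(path)
  } else stop("config format must be .json, .yml or .yaml")
  cfg <- az_restore(raw)
  ## members serialized as JSON null come back absent; reinstate them
  for (nm in c("train", "rho_vgcc_override", "snapshot_times")) {
    if (is.null(cfg[[nm]])) {
      cfg[nm] <- list(NULL)
    }
  }
  cfg <- cfg[intersect(c("geometry", "h", "kinetics", "channel", "pumps",
                         "train", "solver", "probes", "t_end", "V_rest",
                         "constants", "rho_vgcc_override",
                         "snapshot_times", "label"),
                       names(cfg))]
  class(cfg) <- "az_config"
  attr(cfg, "source_text") <- paste(readLines(path), collapse = "\n")
  cfg
}

## ---- result output ----------------------------------------------------

#' Write a scenario result to disk
#'
#' Writes the probe traces and peak table as CSV, the mass-balance log as
#' CSV, run metadata as JSON, and an echo of the configuration (the exact
#' source text when the configuration was read from a file).
#'
#' @param res an `az_result`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_result <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tr <- data.frame(time = res$times, res$probes, U = res$U_avg,
                   check.names = FALSE)
  utils::write.csv(tr, file.path(dir, "probes.csv"), row.names = FALSE)
  if (!is.null(res$peaks))
    utils::write.csv(res$peaks, file.path(dir, "peaks.csv"),
                     row.names = FALSE)
  utils::write.csv(data.frame(time = res$times, res$mass),
                   file.path(dir, "mass.csv"), row.names = FALSE)
  for (sn in res$snapshots) {
    write_vtk_image(sn$Ca, res$grid,
                    file.path(dir, sprintf("snap_Ca_t%.6f.vtk", sn$t)), "Ca")
    write_vtk_image(sn$B, res$grid,
                    file.path(dir, sprintf("snap_B_t%.6f.vtk", sn$t)), "B")
  }
  src <- attr(res$config, "source_text")
  if (!is.null(src)) {
    writeLines(src, file.path(dir, "config.json"))
  } else {
    write_config(res$config, file.path(dir, "config.json"))
  }
  jsonlite::write_json(
    list(package = "azsim",
         version = as.character(utils::packageVersion("azsim")),
         label = res$config$label,
         rho_vgcc = res$rho_vgcc,
         leak_flux = res$leak_flux),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Export a field snapshot as legacy-ASCII VTK image data
#'
#' Writes a cell-centered scalar field as a `STRUCTURED_POINTS` legacy
#' VTK file (plain text) for inspection in ParaView; obstacle cells are
#' written as `nan`.
#'
#' @param arr numeric array on the grid (e.g. `state$Ca`).
#' @param grid the `az_grid`.
#' @param path output `.vtk` file.
#' @param name scalar name in the file.
#' @return `path`, invisibly.
#' @export
write_vtk_image <- function(arr, grid, path, name = "Ca") {
  sh <- grid$shape
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "azsim field snapshot", "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", sh[1], sh[2], sh[3]),
               sprintf("ORIGIN %g %g %g", grid$h / 2, grid$h / 2,
                       grid$h / 2),
               sprintf("SPACING %g %g %g", grid$h, grid$h, grid$h),
               sprintf("POINT_DATA %d", prod(sh)),
               sprintf("SCALARS %s float 1", name),
               "LOOKUP_TABLE default"), con)
  v <- as.numeric(arr)
  v[is.na(v)] <- NaN
  writeLines(paste(format(v, trim = TRUE, digits = 7)), con)
  invisible(path)
}
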