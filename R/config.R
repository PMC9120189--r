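default_run_config <- function() {
  list(
    seed = 1L,
    output_dir = "menpsim_out",
    stages = c("spectro"),
    strict = FALSE,
    spectro = list(particle = "spion", amplitude = 80000, frequency = 25250,
                   bias = 0, t_end = 0.004, dt = 1e-6, K = 9L),
    particle = list(preset = "menp", r_core_nm = 12, H = c(0, 0, 4000),
                    E = c(0, 0, 50), kappa = 1, temperature = 300),
    me_coupling = list(core_radius_nm = 12, convention = "signed_projection",
                       f_min_E = 35.62 / 539.82, f_min_B = 0.13 / 10.14,
                       concentration_scale = 1),
    neuron = list(template = "ball_and_stick", n_dend = 2L,
                  grid_dims = c(200, 200, 200), grid_spacing = 20,
                  grid_origin = c(-100, -100, -100), t_end_ms = 20,
                  dt_ms = 1, sigma_ext = 0.3, h_hat = c(1, 0, 0)),
    network = list(scale = 0.1, duration_ms = 140, dt_ms = 0.1,
                   grid_dims = c(200, 700, 200), grid_spacing = 50,
                   frame_ms = 1, sigma_ext = 0.3, h_hat = c(1, 0, 0)),
    perfuse = list(n_particles = 40000L, D_um2_s = 15, v_um_ms = 650,
                   dt_ms = 0.01, window_ms = 1.0, init_sd_um = 50,
                   boundary = "exclude")
  )
}

#' Load a declarative run configuration
#'
#' Reads a YAML run configuration, fills unspecified keys from the
#' defaults, and (in strict mode) rejects unknown keys with a
#' path-to-key diagnostic. An empty file yields the full default
#' configuration. Configurations round-trip losslessly through
#' [save_config].
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @param strict Reject unknown keys.
#' @return A `run_config` list.
#' @export
load_config <- function(path = NULL, strict = FALSE) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    if (length(user) > 0) {
      cfg <- merge_config(cfg, user, strict = strict, where = "")
    }
  }
  structure(cfg, class = "run_config")
}

merge_config <- function(base, user, strict, where) {
  for (k in names(user)) {
    key <- paste0(where, k)
    if (!k %in% names(base)) {
      if (strict) stop("unknown configuration key: '", key, "'")
      base[[k]] <- user[[k]]
    } else if (is.list(base[[k]]) && is.list(user[[k]]) &&
               !is.null(names(base[[k]]))) {
      base[[k]] <- merge_config(base[[k]], user[[k]], strict,
                                paste0(key, "."))
    } else {
      base[[k]] <- user[[k]]
    }
  }
  base
}

#' Save a run configuration
#'
#' @param cfg A `run_config`.
#' @param path Output YAML file.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path, precision = 12L)
  invisible(path)
}

#' Derive a per-stage seed from the global seed
#'
#' Stages draw their seeds as `global_seed + 1000 * stage_index` (kept
#' below 2^31), so any stage can be rerun in isolation with the same
#' stream. Stage indices: spectro 1, particle 2, neuron 3, network 4,
#' perfuse 5.
#'
#' @param seed Global integer seed.
#' @param stage Stage name.
#' @return Integer stage seed.
#' @export
stage_seed <- function(seed, stage) {
  idx <- match(stage, c("spectro", "particle", "neuron", "network",
                        "perfuse"))
  if (is.na(idx)) stop("unknown stage: ", stage)
  as.integer((as.numeric(seed) + 1000 * idx) %% 2^31)
}

#' Generate deterministic test/demo fixtures
#'
#' Writes small plain-text fixture files of the requested kind:
#' `"morphology"` (SWC), `"raster"` (two-column spikes with injected
#' synchronous volleys), `"mh_curve"` (two-column odd-symmetric curve) or
#' `"field"` (site table of a small lattice potential). Byte-identical
#' for identical seeds.
#'
#' @param kind Fixture kind.
#' @param dir Output directory (created if needed).
#' @param seed RNG seed.
#' @param params Optional kind-specific parameter list. For `"raster"`:
#'   `n_cells`, `duration_ms`, `volley_times_ms`, `background_hz`.
#' @return Invisibly, the written file path.
#' @export
make_fixtures <- function(kind = c("morphology", "raster", "field",
                                   "mh_curve"),
                          dir = ".", seed = 1L, params = list()) {
  kind <- match.arg(kind)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(dir, paste0("fixture_", kind, ".txt"))
  set.seed(seed)
  if (kind == "morphology") {
    path <- file.path(dir, "fixture_morphology.swc")
    m <- synth_morphology("branched", depth = params$depth %||% 3L,
                          seed = seed)
    write_swc(m, path)
  } else if (kind == "raster") {
    n_cells <- params$n_cells %||% 100L
    dur <- params$duration_ms %||% 140
    volleys <- params$volley_times_ms %||% c(27, 59, 91, 119)
    bg <- params$background_hz %||% 2
    n_bg <- stats::rpois(1, bg * n_cells * dur / 1000)
    sp <- data.frame(cell = sample.int(n_cells, n_bg, replace = TRUE),
                     t_ms = stats::runif(n_bg, 0, dur))
    for (tv in volleys) {
      cells <- sample.int(n_cells, round(0.6 * n_cells))
      sp <- rbind(sp, data.frame(cell = cells,
                                 t_ms = tv + stats::rnorm(length(cells),
                                                          0, 0.5)))
    }
    sp <- sp[order(sp$t_ms), ]
    con <- file(path, "w")
    writeLines("# cell_id t_ms", con)
    writeLines(sprintf("%d %.4f", sp$cell, sp$t_ms), con)
    close(con)
  } else if (kind == "mh_curve") {
    spec <- particle_preset("spion")
    write_mh_curve(mh_curve(spec, H_max = 2e5, n_points = 101), path)
  } else {
    g <- field_grid(c(20, 20, 20), 5)
    phi <- matrix(g$coords[, 1] * 0.1, ncol = 1)   # linear ramp, mV
    con <- file(path, "w")
    writeLines("# x_um y_um z_um phi_mV", con)
    utils::write.table(cbind(g$coords, phi), con, row.names = FALSE,
                       col.names = FALSE)
    close(con)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the simulation pipeline
#'
#' Executes the selected stages in dependency order (spectro, particle,
#' neuron, network, perfuse), writing stage outputs into the configured
#' output directory, and returns a run manifest recording the
#' configuration snapshot, per-stage seeds, timestamps and output-file
#' checksums. Reruns with an identical configuration produce identical
#' checksums.
#'
#' @param cfg A `run_config` from [load_config].
#' @return A `run_manifest` list (also written as JSON to the output
#'   directory).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("menpsim")),
                   started = format(Sys.time(), tz = "UTC"),
                   config = unclass(cfg), stages = list(), outputs = list())
  outputs <- character(0)
  field <- NULL
  raster <- NULL
  for (stage in cfg$stages) {
    sseed <- stage_seed(cfg$seed, stage)
    manifest$stages[[stage]] <- list(seed = sseed)
    if (stage == "spectro") {
      sc <- cfg$spectro
      spec <- particle_preset(sc$particle)
      d <- drive_field(sc$amplitude, sc$frequency, bias = sc$bias,
                       t_end = sc$t_end, dt = sc$dt)
      ts <- magnetization_timeseries(spec, generate_drive(d))
      hs <- harmonic_spectrum(ts, f0 = sc$frequency, K = sc$K)
      f <- file.path(cfg$output_dir, "spectrum.txt")
      write_spectrum(hs, f)
      outputs <- c(outputs, f)
    } else if (stage == "particle") {
      pc <- cfg$particle
      spec <- particle_preset(pc$preset, temperature = pc$temperature,
                              r_core_nm = pc$r_core_nm)
      st <- solve_lumped_me(spec, H_applied = pc$H, E_applied = pc$E,
                            kappa = pc$kappa)
      f <- file.path(cfg$output_dir, "lumped_state.yaml")
      yaml::write_yaml(list(M = st$M, M_particle = st$M_particle,
                            H_eff = st$H_eff, converged = st$converged,
                            iterations = st$iterations), f)
      outputs <- c(outputs, f)
    } else if (stage == "neuron") {
      nc <- cfg$neuron
      morph <- synth_morphology(nc$template, n_dend = nc$n_dend,
                                seed = sseed)
      t_ms <- seq(0, nc$t_end_ms, by = nc$dt_ms)
      cur <- ap_current_source(morph, t_ms)
      grid <- field_grid(nc$grid_dims, nc$grid_spacing,
                         origin = nc$grid_origin, t_ms = t_ms)
      grid$phi <- extracellular_potential(morph, cur, grid$coords,
                                          sigma_ext = nc$sigma_ext)
      grid$sigma_ext <- nc$sigma_ext
      grid <- efield_from_potential(grid)
      field <- voxel_magnetization(grid, h_hat = nc$h_hat,
                                   r_core_nm = cfg$me_coupling$core_radius_nm,
                                   convention = cfg$me_coupling$convention,
                                   scale = cfg$me_coupling$concentration_scale)
      f <- file.path(cfg$output_dir, "neuron_field.rds")
      saveRDS(field, f)
      outputs <- c(outputs, f)
    } else if (stage == "network") {
      nc <- cfg$network
      net <- build_network(default_layers(scale = nc$scale), seed = sseed)
      raster <- simulate_network(net, duration_ms = nc$duration_ms,
                                 dt_ms = nc$dt_ms, seed = sseed + 1L)
      f1 <- file.path(cfg$output_dir, "raster.txt")
      write_raster(raster, f1)
      t_frames <- seq(0, nc$duration_ms, by = nc$frame_ms)
      src <- network_source_currents(raster, t_frames)
      grid <- field_grid(nc$grid_dims, nc$grid_spacing)
      grid <- network_potential(src, grid, sigma_ext = nc$sigma_ext)
      grid <- efield_from_potential(grid)
      field <- voxel_magnetization(grid, h_hat = nc$h_hat,
                                   r_core_nm = cfg$me_coupling$core_radius_nm,
                                   convention = cfg$me_coupling$convention,
                                   scale = cfg$me_coupling$concentration_scale)
      sig <- voxel_signal(field)
      f2 <- file.path(cfg$output_dir, "voxel_signal.txt")
      utils::write.table(
        data.frame(t_ms = sig$t_ms, mean_uAm = sig$mean_uAm,
                   sd_uAm = sig$sd_uAm),
        f2, row.names = FALSE)
      f3 <- file.path(cfg$output_dir, "network_field.rds")
      saveRDS(field, f3)
      outputs <- c(outputs, f1, f2, f3)
    } else if (stage == "perfuse") {
      if (is.null(field)) {
        f_field <- file.path(cfg$output_dir, "network_field.rds")
        if (!file.exists(f_field)) {
          stop("perfuse stage requires a magnetization field; ",
               "run the 'network' (or 'neuron') stage first")
        }
        field <- readRDS(f_field)
      }
      pc <- cfg$perfuse
      centers <- if (!is.null(raster)) detect_bursts(raster) else numeric(0)
      if (length(centers) == 0L) {
        centers <- stats::median(field$t)
      }
      pcfg <- perfusion_config(n_particles = pc$n_particles,
                               D_um2_s = pc$D_um2_s, v_um_ms = pc$v_um_ms,
                               dt_ms = pc$dt_ms, window_ms = pc$window_ms,
                               centers_ms = centers,
                               init_sd_um = pc$init_sd_um,
                               boundary = pc$boundary, seed = sseed)
      traces <- lapply(centers, function(cm)
        sample_signal(field, pcfg, center_ms = cm))
      f <- file.path(cfg$output_dir, "perfused_signal.txt")
      con <- file(f, "w")
      writeLines("# center_ms t_ms mean_uAm sd_uAm n", con)
      for (i in seq_along(traces)) {
        tr <- traces[[i]]
        writeLines(sprintf("%g %g %g %g %d", centers[i], tr$t_ms,
                           tr$mean_uAm, tr$sd_uAm, tr$n), con)
      }
      close(con)
      outputs <- c(outputs, f)
    } else {
      stop("unknown stage: ", stage)
    }
  }
  sums <- tools::md5sum(outputs)
  manifest$outputs <- as.list(sums)
  manifest$finished <- format(Sys.time(), tz = "UTC")
  mf <- file.path(cfg$output_dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  structure(manifest, class = "run_manifest")
}
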