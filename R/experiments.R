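#' Configuration of an in-silico EMG/MMG experiment
#'
#' Bundles geometry, discretisation, stimulus and sensor layout for one
#' simulation run. Defaults reproduce the reference protocol: a 4 x 1.5 x 2
#' cm muscle, a recruited fibre line at depth `depth` stimulated once at its
#' neuromuscular junction, a single recording channel at `x_l = 2.5` cm,
#' `x_t = 0.6` cm on the recording surface, and a channel line across the
#' fibres at `x_l = 2.5` cm (pitch = grid spacing, at least 0.05 cm).
#'
#' @param depth activation depth, cm.
#' @param d_fat fat-layer thickness, cm.
#' @param spacing grid spacing, cm (0.05 for production runs, 0.1 for quick
#'   desk-scale runs).
#' @param duration simulated time, ms. 30 ms lets the action potential
#'   traverse the full fibre length at the model's conduction velocity.
#' @param dt PDE time step, ms; 0.1 ms matches the 10 kHz output sampling.
#' @param dt_ode membrane reaction substep, ms.
#' @param L,W,H muscle dimensions, cm.
#' @param air_padding air-box width for the magnetic stage, cm.
#' @param stim a [stimulus_protocol()], or `NULL` for an unstimulated run.
#' @param channel `(x_l, x_t)` of the single analysis channel, cm.
#' @param line_x fibre-axis coordinate of the cross-fibre channel line, cm.
#' @param line_pitch channel pitch along the line, cm; defaults to the grid
#'   spacing (not finer than 0.05 cm).
#' @param line_B magnetic components to record along the channel line
#'   (subset of `"B_l"`, `"B_t"`, `"B_n"`); the line always records EMG.
#'   Magnetic line recordings cost one adjoint solve per sensor and
#'   component axis, so they are opt-in.
#' @param params a [tissue_parameters()] list.
#' @param membrane an [hh_parameters()] list.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(depth = 0.3, d_fat = 0, spacing = 0.1,
                              duration = 30, dt = 0.1, dt_ode = 0.01,
                              L = 4, W = 1.5, H = 2, air_padding = 4,
                              stim = stimulus_protocol(),
                              channel = c(2.5, 0.6), line_x = 2.5,
                              line_pitch = NULL, line_B = character(0),
                              params = tissue_parameters(),
                              membrane = hh_parameters()) {
  if (is.null(line_pitch)) line_pitch <- max(0.05, spacing)
  stopifnot(duration > 0, dt > 0, dt_ode > 0)
  structure(as.list(environment()), class = "experiment_config")
}

#' Run one forward EMG/MMG experiment
#'
#' Executes the full pipeline for one configuration: grid and motor-unit
#' construction, coupled electric time stepping, domain-wise current
#' densities, and magnetic sensor evaluation through reciprocity weights.
#' The run is deterministic: identical configurations give identical
#' outputs.
#'
#' @param config an [experiment_config()].
#' @param cache optional environment; reuses magnetic adjoint solves across
#'   runs that share a geometry (e.g. a depth sweep).
#' @param record_contributions if `TRUE`, record the per-domain magnetic
#'   contributions at the single analysis channel.
#' @param snapshot_times times (ms) at which to store the full field state
#'   (potentials, transmembrane potentials, current densities).
#' @param progress print per-stage timing.
#' @return An `mm_run` object: `channels` (list of channel recordings, the
#'   first being the single analysis channel), `contributions` (per
#'   component, time x domain matrices in pT), `line` (channel-line
#'   indices into `channels`), `snapshots`, and the model objects.
#' @export
run_experiment <- function(config, cache = NULL, record_contributions = TRUE,
                           snapshot_times = numeric(0), progress = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  say <- function(...) if (progress) message(sprintf(...))
  t0 <- Sys.time()
  grid <- build_grid(config$L, config$W, config$H, config$d_fat,
                     config$spacing, config$air_padding)
  mus <- build_motor_unit_map(grid, config$depth)
  cond <- build_conductivities(grid, params = config$params)
  op <- assemble_elliptic_operator(grid, cond, mus)
  say("assembly: %.1f s", as.numeric(Sys.time() - t0, units = "secs"))

  # sensor layout on the recording surface
  line_y <- seq(0, config$W, by = config$line_pitch)
  pos_single <- matrix(config$channel, nrow = 1)
  pos_line <- cbind(config$line_x, line_y)
  node_of <- function(p) grid_index(grid,
                                    snap_index(p[1], grid$spacing, grid$nx),
                                    snap_index(p[2], grid$spacing, grid$ny),
                                    grid$surface_iz)
  node_single <- node_of(config$channel)
  nodes_line <- apply(pos_line, 1, node_of)

  t0 <- Sys.time()
  w_single <- magnetic_sensor_weights(grid, pos_single,
                                      c("B_l", "B_t", "B_n"), cache)
  w_line <- if (length(config$line_B))
    magnetic_sensor_weights(grid, pos_line, config$line_B, cache)
  say("sensor adjoints: %.1f s", as.numeric(Sys.time() - t0, units = "secs"))

  nsteps <- as.integer(round(config$duration / config$dt))
  time <- (0:nsteps) * config$dt
  nl <- length(line_y)
  emg_single <- numeric(nsteps + 1)
  emg_line <- matrix(0, nsteps + 1, nl)
  B_single <- matrix(0, nsteps + 1, 3,
                     dimnames = list(NULL, c("B_l", "B_t", "B_n")))
  contrib <- if (record_contributions)
    lapply(1:3, function(i) matrix(0, nsteps + 1, length(DOMAIN_SOURCES),
                                   dimnames = list(NULL, DOMAIN_SOURCES)))
  B_line <- if (length(config$line_B))
    array(0, c(nsteps + 1, nl, length(config$line_B)),
          dimnames = list(NULL, NULL, config$line_B))
  snapshots <- list()
  snap_steps <- if (length(snapshot_times))
    as.integer(round(snapshot_times / config$dt)) else integer(0)
  mu0 <- config$params$mu_0

  state <- em_initial_state(op, config$membrane)
  t0 <- Sys.time()
  for (s in seq_len(nsteps)) {
    state <- em_step(op, state, config$dt, config$dt_ode, config$stim,
                     config$membrane)
    r <- s + 1L
    emg_single[r] <- state$phi[node_single]
    emg_line[r, ] <- state$phi[nodes_line]
    J <- current_densities(op, state$phi, state$V)
    jt <- lapply(DOMAIN_SOURCES, function(d)
      tissue_currents(grid, mus, J, d))
    names(jt) <- DOMAIN_SOURCES
    jt_tot <- jt[[1]] + jt[[2]] + jt[[3]] + jt[[4]]
    B_single[r, ] <- sensor_B(w_single, jt_tot, mu0)
    if (record_contributions)
      for (d in seq_along(DOMAIN_SOURCES)) {
        bd <- sensor_B(w_single, jt[[d]], mu0)
        for (ci in 1:3) contrib[[ci]][r, d] <- bd[1, ci]
      }
    if (!is.null(B_line)) {
      bl <- sensor_B(w_line, jt_tot, mu0)
      B_line[r, , ] <- bl
    }
    if (s %in% snap_steps)
      snapshots[[as.character(time[r])]] <-
        list(t = time[r], phi = state$phi, V = state$V, J = J)
  }
  say("time stepping: %.1f s", as.numeric(Sys.time() - t0, units = "secs"))

  mk_chan <- function(posn, phi_series, Bmat) {
    series <- cbind(phi = phi_series,
                    B_l = NA_real_, B_t = NA_real_, B_n = NA_real_)
    if (!is.null(Bmat)) series[, colnames(Bmat)] <- Bmat
    structure(list(position = posn, time = time, series = series,
                   sampling_rate = 1000 / config$dt),
              class = "channel_recording")
  }
  channels <- vector("list", 1 + nl)
  channels[[1]] <- mk_chan(config$channel, emg_single, B_single)
  for (i in seq_len(nl))
    channels[[1 + i]] <- mk_chan(c(config$line_x, line_y[i]), emg_line[, i],
                                 if (!is.null(B_line))
                                   matrix(B_line[, i, ],
                                          ncol = length(config$line_B),
                                          dimnames = list(NULL,
                                                          config$line_B)))
  if (record_contributions) {
    names(contrib) <- c("B_l", "B_t", "B_n")
    for (ci in 1:3)
      contrib[[ci]] <- cbind(contrib[[ci]], total = B_single[, ci])
  }
  structure(list(config = config, time = time, channels = channels,
                 line = 1 + seq_len(nl), contributions = contrib,
                 snapshots = snapshots, grid = grid, mus = mus),
            class = "mm_run")
}

#' @export
print.mm_run <- function(x, ...) {
  cat(sprintf("<mm_run> depth %g cm, d_fat %g cm, h = %g cm, %g ms, %d channels\n",
              x$config$depth, x$config$d_fat, x$config$spacing,
              x$config$duration, length(x$channels)))
  invisible(x)
}

# logical index of the analysis window: stimulus onset to the end of the run
analysis_window <- function(run) {
  onset <- if (is.null(run$config$stim)) 0 else run$config$stim$onset
  run$time >= onset - 1e-9
}

#' Signal metrics of the single analysis channel
#'
#' RMS and mean frequency over the analysis window (stimulus onset to the
#' end of the simulation).
#'
#' @param run an `mm_run`.
#' @return A data.frame with one row per measurement-vector component
#'   (`EMG`, `B_l`, `B_t`, `B_n`): RMS (mV for EMG, pT for MMG) and mean
#'   frequency (Hz).
#' @export
run_metrics <- function(run) {
  ch <- run$channels[[1]]
  fs <- ch$sampling_rate
  win <- analysis_window(run)
  comp <- c("phi", "B_l", "B_t", "B_n")
  out <- data.frame(component = c("EMG", "B_l", "B_t", "B_n"),
                    rms = NA_real_, mnf = NA_real_)
  for (i in seq_along(comp)) {
    xs <- ch$series[win, comp[i]]
    out$rms[i] <- rms(xs)
    out$mnf[i] <- mean_frequency(psd(xs, fs))
  }
  out
}

#' Run an activation-depth sweep
#'
#' One run per depth, sharing grid geometry and magnetic adjoint solves.
#'
#' @param depths activation depths, cm.
#' @param ... further arguments to [experiment_config()].
#' @param cache environment for adjoint reuse (created if `NULL`).
#' @param progress print timing.
#' @return A named list of `mm_run` objects (names = depths).
#' @export
depth_sweep <- function(depths = c(0.3, 0.5, 0.7, 0.9, 1.1), ...,
                        cache = NULL, progress = FALSE) {
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  runs <- lapply(depths, function(d)
    run_experiment(experiment_config(depth = d, ...), cache = cache,
                   progress = progress))
  names(runs) <- as.character(depths)
  runs
}

#' Run the fat-thickness sweep at constant source-sensor distance
#'
#' When the fat layer thickens, correspondingly more superficial fibres are
#' stimulated so the geometric distance between source and sensor stays
#' fixed: `(d_fat, depth)` pairs (0, 0.9), (0.2, 0.7), (0.4, 0.5) by
#' default.
#'
#' @param pairs a list of `c(d_fat, depth)` pairs.
#' @param ... further arguments to [experiment_config()].
#' @param cache environment for adjoint reuse.
#' @param progress print timing.
#' @return A named list of `mm_run` objects (names = fat thicknesses).
#' @export
fat_sweep <- function(pairs = list(c(0, 0.9), c(0.2, 0.7), c(0.4, 0.5)),
                      ..., cache = NULL, progress = FALSE) {
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  runs <- lapply(pairs, function(p)
    run_experiment(experiment_config(d_fat = p[1], depth = p[2], ...),
                   cache = cache, progress = progress))
  names(runs) <- vapply(pairs, function(p) as.character(p[1]), "")
  runs
}

#' Normalised depth-sweep metrics table
#'
#' RMS and mean frequency of every measurement-vector component at the
#' single channel, for each run, divided by the values of the reference run
#' (by default the smallest depth).
#'
#' @param runs a list of `mm_run` objects as from [depth_sweep()].
#' @param reference index or name of the reference run.
#' @return A data.frame with one row per run: depth and normalised
#'   `EMG_RMS`, `EMG_MNF`, `B_l_RMS`, ... columns.
#' @export
normalised_metrics <- function(runs, reference = 1) {
  ms <- lapply(runs, run_metrics)
  ref <- ms[[reference]]
  rows <- lapply(seq_along(runs), function(i) {
    m <- ms[[i]]
    vals <- c(rbind(m$rms / ref$rms, m$mnf / ref$mnf))
    names(vals) <- c(rbind(paste0(m$component, "_RMS"),
                           paste0(m$component, "_MNF")))
    c(depth = runs[[i]]$config$depth, d_fat = runs[[i]]$config$d_fat, vals)
  })
  as.data.frame(do.call(rbind, rows))
}

#' Per-domain contribution report
#'
#' For each magnetic component at the single channel: RMS of each domain
#' contribution divided by the RMS of the total (measurable) field, plus a
#' closure check that the contributions sum to the total field.
#'
#' @param run an `mm_run` recorded with `record_contributions = TRUE`.
#' @return A data.frame with columns `component`, `domain`,
#'   `normalised_rms`; attribute `closure_error` holds the maximal relative
#'   deviation of the summed contributions from the total.
#' @export
contribution_report <- function(run) {
  if (is.null(run$contributions))
    stop("run was not recorded with contributions")
  rows <- list()
  closure <- 0
  win <- analysis_window(run)
  for (comp in names(run$contributions)) {
    m <- run$contributions[[comp]][win, , drop = FALSE]
    tot <- m[, "total"]
    s <- rowSums(m[, DOMAIN_SOURCES, drop = FALSE])
    closure <- max(closure, max(abs(s - tot)) / max(abs(tot), 1e-300))
    for (d in DOMAIN_SOURCES)
      rows[[length(rows) + 1]] <- data.frame(
        component = comp, domain = d,
        normalised_rms = rms(m[, d]) / rms(tot))
  }
  out <- do.call(rbind, rows)
  attr(out, "closure_error") <- closure
  out
}

#' RMS profile along the cross-fibre channel line
#'
#' @param run an `mm_run`.
#' @param component `"phi"` (EMG) or a magnetic component recorded along
#'   the line (`line_B` in the configuration).
#' @return A data.frame with `position` (cm, cross-fibre coordinate) and
#'   `rms`.
#' @export
line_profile <- function(run, component = "phi") {
  chans <- run$channels[run$line]
  win <- analysis_window(run)
  vals <- vapply(chans, function(ch) {
    xs <- ch$series[win, component]
    if (anyNA(xs)) stop(sprintf("component %s was not recorded on the line",
                                component))
    rms(xs)
  }, 0)
  data.frame(position = vapply(chans, function(ch) ch$position[2], 0),
             rms = vals)
}
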