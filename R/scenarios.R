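#' Scenario configuration
#'
#' Declarative description of one end-to-end forward run: geometry, fiber
#' mode, pacemaker location, sensor model, ionic configuration, durations and
#' the master RNG seed. The six published configuration-matrix rows (a-f) are
#' expressible purely through these fields.
#'
#' @param uterus_shape `"sphere"` or `"pear"`
#' @param abdomen_shape `"sphere"` or `"cap"`
#' @param fiber_mode `"fixed_angle"` or `"random"`
#' @param fiber_angle fixed fiber angle (rad) for `fixed_angle` mode
#' @param n_regions,min_sep region count and minimum seed separation (m) for
#'   `random` mode
#' @param pacemaker_location `"fundus"`, `"lateral"`, `"back"`, or a numeric
#'   3-vector (m). Fundus is the +y pole, lateral the +x equator point, back
#'   the published posterior site (0, 0.13, -0.075) m
#' @param sensor_mode `"normal_component"` or `"gradiometer"`
#' @param ionic `"uniform"` or `"two_region"` (region-specific parameters
#'   keyed to the pacemaker center)
#' @param duration simulated time (s)
#' @param dt diffusion time step (s)
#' @param mmg_rate sensor sampling rate (Hz) for the output record
#' @param snapshot_times times (s) at which field maps are stored
#' @param subdiv icosphere subdivision depth
#' @param seed master RNG seed (drives region sampling and fiber angles)
#' @param pacemaker optional [pacemaker_spec()] overriding the defaults
#' @return object of class `scenario_config`.
#' @export
scenario_config <- function(uterus_shape = c("sphere", "pear"),
                            abdomen_shape = c("sphere", "cap"),
                            fiber_mode = c("fixed_angle", "random"),
                            fiber_angle = pi / 4,
                            n_regions = 25, min_sep = 0.04,
                            pacemaker_location = "fundus",
                            sensor_mode = c("normal_component",
                                            "gradiometer"),
                            ionic = c("uniform", "two_region"),
                            duration = 60, dt = 2e-3, mmg_rate = 5,
                            snapshot_times = c(10, 36, 55),
                            subdiv = 4, seed = 1, pacemaker = NULL) {
  structure(list(uterus_shape = match.arg(uterus_shape),
                 abdomen_shape = match.arg(abdomen_shape),
                 fiber_mode = match.arg(fiber_mode),
                 fiber_angle = fiber_angle,
                 n_regions = n_regions, min_sep = min_sep,
                 pacemaker_location = pacemaker_location,
                 sensor_mode = match.arg(sensor_mode),
                 ionic = match.arg(ionic),
                 duration = duration, dt = dt, mmg_rate = mmg_rate,
                 snapshot_times = snapshot_times,
                 subdiv = subdiv, seed = seed, pacemaker = pacemaker),
            class = "scenario_config")
}

# Resolve a named pacemaker location on the mid-wall sphere of radius r.
pacemaker_center <- function(location, r) {
  if (is.numeric(location) && length(location) == 3)
    return(as.numeric(location))
  switch(location,
         fundus = c(0, r, 0),
         lateral = c(r, 0, 0),
         back = c(0, 0.13, -0.075),
         stop("unknown pacemaker location: ", location))
}

#' Run a forward scenario end to end
#'
#' Composes geometry, fiber field, monodomain propagation, magnetic forward
#' computation and sensor sampling from a [scenario_config()]. Returns all
#' intermediate artifacts plus a provenance manifest (config, seeds, package
#' version) sufficient for exact re-execution.
#'
#' @param config a [scenario_config()]
#' @param out_dir optional directory; when given, the manifest (JSON), sensor
#'   array (CSV) and MMG record (CSV) are written there
#' @return object of class `scenario_result`: list with `mesh`, `fibers`,
#'   `solution`, `array`, `mmg` (list with `time`, `B` time x channel, T),
#'   `maps` (channel readings at each snapshot), `manifest`.
#' @export
run_scenario <- function(config, out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("scenario stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  spec <- geometry_spec(subdiv = config$subdiv)
  mesh <- stage("geometry", switch(config$uterus_shape,
    sphere = make_spherical_uterus(spec),
    pear = make_pear_uterus(spec)))
  abdomen <- stage("geometry", make_abdomen_surface(
    spec, shape = if (config$abdomen_shape == "cap") "concave_cap"
                  else "sphere"))
  fibers <- stage("fibers", {
    if (config$fiber_mode == "fixed_angle") {
      fiber_field(mesh, config$fiber_angle)
    } else {
      part <- partition_regions(mesh, config$n_regions, config$min_sep,
                                rng_seed = config$seed)
      ang <- sample_fiber_angles(part, rng_seed = config$seed + 1)
      fiber_field(mesh, ang, part)
    }
  })
  r_mid <- spec$uterus_radius - spec$wall_thickness / 2
  center <- pacemaker_center(config$pacemaker_location, r_mid)
  pm <- if (is.null(config$pacemaker))
    pacemaker_spec(center = center) else config$pacemaker
  ionic <- if (config$ionic == "uniform") fhn_params() else
    region_ionic(center = pm$center)
  mmg_times <- seq(0, config$duration, by = 1 / config$mmg_rate)
  snap <- sort(unique(c(config$snapshot_times, mmg_times)))
  sol <- stage("propagation", simulate_propagation(
    mesh, fibers, ionic = ionic, pacemaker = pm,
    duration = config$duration, dt = config$dt, snapshot_times = snap))
  array <- stage("sensors", sara_array(abdomen))
  readings <- stage("forward_field", {
    vapply(seq_along(sol$times), function(k) {
      src <- source_current_density(sol$vm[, k], mesh, fibers)
      gradiometer_readings(src, array, mode = config$sensor_mode)
    }, numeric(array$count))
  })
  readings <- t(readings) # time x channel
  map_idx <- vapply(config$snapshot_times,
                    function(t) which.min(abs(sol$times - t)), integer(1))
  mmg_idx <- vapply(mmg_times,
                    function(t) which.min(abs(sol$times - t)), integer(1))
  manifest <- list(config = unclass(config),
                   seed = config$seed,
                   package = "uteromag",
                   version = as.character(utils::packageVersion("uteromag")),
                   n_vertices = nrow(mesh$vertices),
                   n_faces = nrow(mesh$faces),
                   sensor_count = array$count)
  res <- structure(list(mesh = mesh, abdomen = abdomen, fibers = fibers,
                        solution = sol, array = array,
                        mmg = list(time = sol$times[mmg_idx],
                                   B = readings[mmg_idx, , drop = FALSE]),
                        maps = readings[map_idx, , drop = FALSE],
                        manifest = manifest),
                   class = "scenario_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    save_sensor_array(array, file.path(out_dir, "sensors.csv"))
    mm <- data.frame(time_s = res$mmg$time, res$mmg$B)
    names(mm) <- c("time_s", paste0("ch", seq_len(array$count)))
    utils::write.csv(mm, file.path(out_dir, "mmg.csv"), row.names = FALSE)
  }
  res
}

#' SARA-style preprocessing filter specification
#'
#' Defaults mirror the published acquisition pipeline: downsample to 32 Hz,
#' zero-phase 0.1-1 Hz band-pass, zero-phase 0.25-0.35 Hz band-stop (the
#' maternal-breathing notch). Filters are 4th-order Butterworth designs
#' applied forward-backward.
#'
#' @param rate downsample target rate (Hz)
#' @param band band-pass edges (Hz)
#' @param notch band-stop edges (Hz)
#' @return object of class `filter_spec`.
#' @export
filter_spec <- function(rate = 32, band = c(0.1, 1),
                        notch = c(0.25, 0.35)) {
  stopifnot(band[1] > 0, band[1] < band[2], band[2] < rate / 2,
            notch[1] < notch[2])
  structure(list(rate = rate, band = band, notch = notch),
            class = "filter_spec")
}

#' Preprocess an MMG record
#'
#' Downsamples to the target rate (anti-aliased; skipped when the input rate
#' is already at or below the target), then applies the zero-phase band-pass
#' and band-stop filters channel by channel.
#'
#' @param record list with `time` (s, uniform grid) and `B`
#'   (time x channel matrix)
#' @param spec a [filter_spec()]
#' @return filtered record in the same format.
#' @export
preprocess_mmg <- function(record, spec = filter_spec()) {
  t <- record$time
  B <- as.matrix(record$B)
  fs <- 1 / stats::median(diff(t))
  if (fs < 2 * spec$band[2])
    stop("input rate ", signif(fs, 4), " Hz below twice the band edge")
  if (length(t) < 24)
    stop("record shorter than filter warm-up")
  if (fs > spec$rate) {
    # anti-alias then resample onto the target grid
    lp <- signal::butter(4, (0.8 * spec$rate / 2) / (fs / 2), type = "low")
    B <- apply(B, 2, function(x) signal::filtfilt(lp, x))
    t2 <- seq(min(t), max(t), by = 1 / spec$rate)
    B <- apply(B, 2, function(x) stats::approx(t, x, xout = t2)$y)
    t <- t2
    fs <- spec$rate
  }
  bp <- signal::butter(2, spec$band / (fs / 2), type = "pass")
  bs <- signal::butter(2, spec$notch / (fs / 2), type = "stop")
  B <- apply(B, 2, function(x)
    signal::filtfilt(bs, signal::filtfilt(bp, x)))
  list(time = t, B = B)
}

#' Small deterministic fixture bundle for fast tests
#'
#' Emits a coarse sphere mesh (OFF), a 5-region fiber field (CSV), a
#' 2-second cell trace (CSV) and a 4-sensor toy array (CSV) into `dir`.
#'
#' @param seed integer seed
#' @param dir output directory (default: a fresh temporary directory)
#' @return named list of file paths, with attribute `"hashes"` holding
#'   content checksums.
#' @export
generate_fixtures <- function(seed = 1, dir = tempfile("fixtures")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  spec <- geometry_spec(subdiv = 2)
  mesh <- make_spherical_uterus(spec)
  mesh_path <- file.path(dir, "sphere.off")
  save_surface_mesh(mesh, mesh_path)
  part <- partition_regions(mesh, n_regions = 5, min_sep = 0.04,
                            rng_seed = seed)
  ang <- sample_fiber_angles(part, rng_seed = seed)
  ff <- fiber_field(mesh, ang, part)
  fib_path <- file.path(dir, "fibers.csv")
  utils::write.csv(data.frame(element = seq_along(ff$alpha),
                              region = part$region, alpha = ff$alpha,
                              a3x = ff$a3[, 1], a3y = ff$a3[, 2],
                              a3z = ff$a3[, 3]),
                   fib_path, row.names = FALSE)
  tr <- simulate_cell(fhn_params(), stimulus("constant", 0.15),
                      duration = 2)
  tr_path <- file.path(dir, "trace.csv")
  utils::write.csv(data.frame(time_s = tr$time, vm_V = tr$vm, w_V = tr$w),
                   tr_path, row.names = FALSE)
  abd <- make_abdomen_surface(geometry_spec(subdiv = 2))
  arr <- sara_array(abd, count = 4, n_rings = 1)
  arr_path <- file.path(dir, "sensors.csv")
  save_sensor_array(arr, arr_path)
  paths <- list(mesh = mesh_path, fibers = fib_path, trace = tr_path,
                sensors = arr_path)
  hashes <- vapply(paths, function(p)
    paste(as.character(tools::md5sum(p)), collapse = ""), "")
  attr(paths, "hashes") <- hashes
  paths
}
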