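# Packaged studies, configuration files, fixtures and field output: the glue
# that ties profiles, kinematics, solver and analysis into the two
# simulation campaigns shipped with the package (the hovering-plate
# validation case and the four-section forward-flight sweep).

#' Resolution presets
#'
#' `"coarse"` is the desk-scale test surface (256x128 forward-flight grid or
#' 256x256 validation tank, 4 cycles, statistics over the last cycles);
#' `"full"` is the faithful mode (512x256, 15 cycles, statistics over
#' tau in \[3, 15)).
#'
#' @param preset `"coarse"` or `"full"`.
#' @param mode `"forward"` or `"validation"`.
#' @return list with `grid`, `n_cycles`, `record_window`.
#' @export
resolution_preset <- function(preset = c("coarse", "full"),
                              mode = c("forward", "validation")) {
  preset <- match.arg(preset)
  mode <- match.arg(mode)
  if (preset == "coarse") {
    if (mode == "forward") {
      list(grid = c(256L, 128L), n_cycles = 4, record_window = c(2, 4))
    } else {
      list(grid = c(256L, 256L), n_cycles = 4, record_window = c(3, 4))
    }
  } else {
    if (mode == "forward") {
      list(grid = c(512L, 256L), n_cycles = 15, record_window = c(3, 15))
    } else {
      list(grid = c(512L, 512L), n_cycles = 15, record_window = c(3, 15))
    }
  }
}

#' The four packaged wing cross-sections
#'
#' Corrugated bee-like stand-in, its smoothed approximation, the 0.125c
#' ellipse and the 0.0125c flat plate, all with a 4 mm chord.
#'
#' @param chord chord in mm.
#' @param which subset of section names.
#' @return named list of [wing_profile()]s.
#' @export
standard_sections <- function(chord = 4,
                              which = c("corrugated", "smoothed", "ellipse",
                                        "plate")) {
  which <- match.arg(which, several.ok = TRUE)
  all <- list()
  if ("corrugated" %in% which || "smoothed" %in% which) {
    corr <- make_corrugated(chord, corrugation_spec())
    if ("corrugated" %in% which) all$corrugated <- corr
    if ("smoothed" %in% which) all$smoothed <- smooth_profile(corr, 0.2)
  }
  if ("ellipse" %in% which) all$ellipse <- make_ellipse(chord, 0.125)
  if ("plate" %in% which) all$plate <- make_flat_plate(chord, 0.0125)
  all[intersect(which, names(all))]
}

#' Hovering flat-plate validation case
#'
#' The closed-tank hovering case: a flat plate (chord 23.85 mm) in quiescent
#' mineral oil, driven by f = 0.25 Hz, r = 162.5 mm, theta1a = 23.5 deg,
#' theta3a = 45 deg normal-hovering kinematics; all tank walls no-slip.
#' Coefficients use the resistive drag convention and are normalized by the
#' maximum translational speed. The plate thickness (which the case
#' definition leaves open) is 0.1c so the section spans several cells at
#' the coarse resolution; the
#' tank is 10c x 10c, leaving over two chords of wall clearance around the
#' 5.6c stroke.
#'
#' @param preset resolution preset name.
#' @param thickness_ratio plate thickness as a fraction of chord.
#' @export
validation_case <- function(preset = "coarse", thickness_ratio = 0.1) {
  pr <- resolution_preset(preset, "validation")
  plate <- make_flat_plate(23.85, thickness_ratio)
  flight_case(profile = plate, kin = validation_kinematics(),
              fluid = oil_properties(), V_inf = 0,
              domain_c = c(10, 10), grid = pr$grid,
              n_cycles = pr$n_cycles, record_window = pr$record_window,
              boundary_mode = "closed-tank-validation",
              coef_velocity = "kinematic")
}

#' Forward-flight case for one section and flight speed
#'
#' Bee kinematics (150 Hz, 110/24 deg, r0 = 6.61 mm, theta2A from the speed
#' table) in air on the 22c x 11c domain with inflow on the right boundary.
#'
#' @param profile a [wing_profile()] (chord 4 mm in the packaged sweep).
#' @param V_inf flight speed in m/s (1 to 5).
#' @param preset resolution preset name.
#' @export
forward_case <- function(profile, V_inf, preset = "coarse") {
  pr <- resolution_preset(preset, "forward")
  flight_case(profile = profile, kin = bee_kinematics(V_inf = V_inf),
              fluid = air_properties(), V_inf = V_inf,
              domain_c = c(22, 11), grid = pr$grid,
              n_cycles = pr$n_cycles, record_window = pr$record_window,
              boundary_mode = "open-forward-flight",
              coef_velocity = "kinematic")
}

#' Run the cross-section comparison sweep
#'
#' Runs each section at each flight speed and assembles the comparison
#' report against the corrugated reference.
#'
#' @param sections named list of profiles (default [standard_sections()]).
#' @param speeds flight speeds in m/s.
#' @param preset resolution preset name.
#' @param reference_section name of the reference section.
#' @param verbose print per-cycle progress.
#' @return list with `runs` (named list of `flap_run`) and `report`.
#' @export
section_sweep <- function(sections = standard_sections(), speeds = 1:5,
                          preset = "coarse", reference_section = "corrugated",
                          verbose = FALSE) {
  runs <- list()
  for (V in speeds) {
    for (nm in names(sections)) {
      key <- sprintf("%s_V%g", nm, V)
      runs[[key]] <- run_case(forward_case(sections[[nm]], V, preset),
                              verbose = verbose)
    }
  }
  w <- resolution_preset(preset, "forward")$record_window
  reports <- lapply(speeds, function(V) {
    sel <- runs[sprintf("%s_V%g", names(sections), V)]
    names(sel) <- names(sections)
    r <- build_report(sel, reference_section, w)
    r$V_inf <- V
    r
  })
  list(runs = runs, report = dplyr::bind_rows(reports))
}

#' Domain-width dependency sweep
#'
#' Reruns a case at several domain widths (in chords) and reports the mean
#' coefficient deltas between consecutive widths; the deltas should shrink
#' as the domain grows.
#'
#' @param case a [flight_case()].
#' @param widths_c at least two domain widths in chords.
#' @return tibble with one row per width and delta columns.
#' @export
domain_sweep <- function(case, widths_c) {
  if (length(widths_c) < 2) abort("need at least two domain widths")
  rows <- lapply(widths_c, function(w) {
    nx <- as.integer(round(case$nx * w / case$domain_c[1]))
    c2 <- flight_case(profile = case$profile, kin = case$kin,
                      fluid = case$fluid, V_inf = case$V_inf,
                      domain_c = c(w, case$domain_c[2]),
                      grid = c(nx, case$ny),
                      CFL_max = case$CFL_max, eta = case$eta,
                      n_cycles = case$n_cycles,
                      record_window = case$record_window,
                      boundary_mode = case$boundary_mode,
                      coef_velocity = case$coef_velocity,
                      lid_u = case$lid_u)
    r <- run_case(c2)
    m <- time_average(r$forces, c("CL", "CD"), case$record_window)
    tibble(width_c = w, mean_CL = m$CL, mean_CD = m$CD)
  })
  out <- dplyr::bind_rows(rows)
  out$delta_CL <- c(NA, abs(diff(out$mean_CL)))
  out$delta_CD <- c(NA, abs(diff(out$mean_CD)))
  out
}

# ---- fixtures --------------------------------------------------------------

#' Generate the synthetic fixture files used by tests and examples
#'
#' `kind = "profiles"` writes the four standard section files; `"motion-trace"`
#' writes a sampled bee motion CSV; `"taylor-green"` and `"couette"` write
#' small CSV initial-condition fields for the analytic solver checks.
#' Regeneration is deterministic.
#'
#' @param kind one of `"profiles"`, `"taylor-green"`, `"couette"`,
#'   `"motion-trace"`.
#' @param dir output directory (created if missing).
#' @return paths of the written files.
#' @export
make_fixtures <- function(kind = c("profiles", "taylor-green", "couette",
                                   "motion-trace"),
                          dir) {
  kind <- match.arg(kind)
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(sprintf("cannot create fixture directory '%s'", dir))
  }
  if (file.access(dir, 2) != 0) abort(sprintf("directory '%s' is not writable", dir))
  paths <- character(0)
  if (kind == "profiles") {
    secs <- standard_sections()
    for (nm in names(secs)) {
      p <- file.path(dir, paste0(nm, ".txt"))
      save_profile(secs[[nm]], p)
      paths <- c(paths, p)
    }
  } else if (kind == "taylor-green") {
    tg <- taylor_green_state(64, 64, nu = 0.01)
    p <- file.path(dir, "taylor_green_uv.csv")
    d <- expand.grid(i = seq_len(nrow(tg$u)), j = seq_len(ncol(tg$u)))
    d$u <- as.vector(tg$u)
    write.csv(d, p, row.names = FALSE, quote = FALSE)
    paths <- p
  } else if (kind == "couette") {
    p <- file.path(dir, "couette_profile.csv")
    y <- seq(0, 1, length.out = 65)
    write.csv(data.frame(y = y, u = y), p, row.names = FALSE, quote = FALSE)
    paths <- p
  } else {
    p <- file.path(dir, "bee_motion_3ms.csv")
    write_motion_trace(bee_kinematics(V_inf = 3), p)
    paths <- p
  }
  paths
}

#' Taylor-Green vortex state on a periodic unit-square-times-2pi domain
#'
#' Divergence-free analytic initial condition
#' `u = sin(x) cos(y)`, `v = -cos(x) sin(y)` on `[0, 2pi)^2`, the standard
#' analytic decay benchmark: kinetic energy decays as `exp(-4 nu t)`.
#'
#' @param nx,ny grid cells.
#' @param nu kinematic viscosity (m^2/s, domain units).
#' @param t evaluation time.
#' @return a `flow_state` with periodic grid metadata.
#' @export
taylor_green_state <- function(nx, ny, nu, t = 0) {
  L <- 2 * pi
  dx <- L / nx; dy <- L / ny
  dec <- exp(-2 * nu * t)
  xu <- (0:nx) * dx
  yu <- ((1:ny) - 0.5) * dy
  u <- outer(xu, yu, function(x, y) sin(x) * cos(y)) * dec
  xv <- ((1:nx) - 0.5) * dx
  yv <- (0:ny) * dy
  v <- outer(xv, yv, function(x, y) -cos(x) * sin(y)) * dec
  structure(list(u = u, v = v, p = matrix(0, nx, ny),
                 chi = matrix(0, nx, ny), t = t,
                 grid = list(nx = nx, ny = ny, dx = dx, dy = dy,
                             Lx = L, Ly = L, bc = 0L)),
            class = "flow_state")
}

# ---- configuration files ---------------------------------------------------

config_schema <- list(
  case = c("V_inf", "domain_c", "grid", "CFL_max", "eta", "n_cycles",
           "record_window", "boundary_mode", "coef_velocity", "anchor",
           "lid_u", "preset"),
  fluid = c("rho", "mu", "nu", "standard"),
  profile = c("type", "chord", "thickness_ratio", "file", "n_veins",
              "vein_amplitudes", "vein_radius", "membrane_thickness",
              "notch_position", "notch_depth", "jitter", "seed",
              "smooth_window"),
  kinematics = c("mode", "f", "theta1A", "theta2A", "theta3A", "phi1",
                 "phi2", "r0", "V_inf_lookup"))

#' Read a flight-case configuration file
#'
#' YAML with `fluid`, `profile`, `kinematics` and `case` sections; unknown
#' keys are a schema error naming the offending key. See the packaged
#' examples under `inst/extdata`.
#'
#' @param path YAML file.
#' @return a [flight_case()].
#' @export
read_case_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (sec in names(cfg)) {
    if (!sec %in% names(config_schema)) {
      abort(sprintf("config schema error: unknown section '%s'", sec))
    }
    bad <- setdiff(names(cfg[[sec]]), config_schema[[sec]])
    if (length(bad)) {
      abort(sprintf("config schema error: unknown key '%s' in section '%s'",
                    bad[1], sec))
    }
  }
  fl <- cfg$fluid
  fluid <- if (!is.null(fl$standard)) {
    switch(fl$standard, air = air_properties(), oil = oil_properties(),
           abort(sprintf("unknown standard fluid '%s'", fl$standard)))
  } else {
    fluid_properties(rho = fl$rho, mu = fl$mu, nu = fl$nu)
  }
  pf <- cfg$profile
  profile <- switch(pf$type %||% "plate",
    plate = make_flat_plate(pf$chord, pf$thickness_ratio %||% 0.0125),
    ellipse = make_ellipse(pf$chord, pf$thickness_ratio %||% 0.125),
    corrugated = make_corrugated(pf$chord, do.call(corrugation_spec,
      pf[intersect(names(pf), c("n_veins", "vein_amplitudes", "vein_radius",
                                "membrane_thickness", "notch_position",
                                "notch_depth", "jitter", "seed"))])),
    smoothed = smooth_profile(
      make_corrugated(pf$chord, corrugation_spec()), pf$smooth_window %||% 0.2),
    file = load_profile(pf$file),
    abort(sprintf("unknown profile type '%s'", pf$type)))
  kn <- cfg$kinematics
  kin <- if (identical(kn$mode, "hover-validation")) {
    validation_kinematics()
  } else if (!is.null(kn$V_inf_lookup)) {
    bee_kinematics(V_inf = kn$V_inf_lookup)
  } else {
    kinematics_spec(f = kn$f, theta1A = kn$theta1A, theta2A = kn$theta2A,
                    theta3A = kn$theta3A, phi1 = kn$phi1 %||% 0,
                    phi2 = kn$phi2 %||% 0, r0 = kn$r0,
                    mode = kn$mode %||% "forward-flight")
  }
  cs <- cfg$case %||% list()
  args <- list(profile = profile, kin = kin, fluid = fluid)
  for (k in setdiff(names(cs), "preset")) args[[k]] <- cs[[k]]
  if (!is.null(cs$preset)) {
    md <- if (identical(cs$boundary_mode, "closed-tank-validation"))
      "validation" else "forward"
    pr <- resolution_preset(cs$preset, md)
    for (k in names(pr)) if (is.null(args[[k]])) args[[k]] <- pr[[k]]
  }
  if (!is.null(args$domain_c)) args$domain_c <- as.numeric(args$domain_c)
  if (!is.null(args$grid)) args$grid <- as.integer(args$grid)
  if (!is.null(args$record_window)) args$record_window <- as.numeric(args$record_window)
  do.call(flight_case, args)
}

#' Run a configured case and write its artifacts
#'
#' Runs the case, writes the force CSV (`forces.csv`), a one-row summary
#' (`summary.csv`) and optional VTK legacy snapshots, plus a
#' reproducibility header (`run_info.txt`) with the config hash.
#'
#' @param case a [flight_case()] or path to a YAML config.
#' @param out_dir output directory.
#' @param snapshot_taus tau values for VTK field snapshots.
#' @param verbose per-cycle progress lines.
#' @return the `flap_run`, invisibly.
#' @export
run_study_case <- function(case, out_dir, snapshot_taus = numeric(0),
                           verbose = FALSE) {
  cfg_txt <- NULL
  if (is.character(case)) {
    cfg_txt <- paste(readLines(case), collapse = "\n")
    case <- read_case_config(case)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  run <- run_case(case, snapshot_taus = snapshot_taus, verbose = verbose)
  write.csv(run$forces, file.path(out_dir, "forces.csv"),
            row.names = FALSE, quote = FALSE)
  g <- glance(run)
  write.csv(g, file.path(out_dir, "summary.csv"), row.names = FALSE,
            quote = FALSE)
  for (nm in setdiff(names(run$snapshots), "initial")) {
    write_vtk(run$snapshots[[nm]],
              file.path(out_dir, paste0(gsub("[^0-9a-zA-Z_.]", "_", nm), ".vtk")))
  }
  hash <- if (!is.null(cfg_txt)) sum(utf8ToInt(cfg_txt) * seq_along(utf8ToInt(cfg_txt))) %% 1e9 else NA
  writeLines(c(sprintf("flapwing %s", as.character(utils::packageVersion("flapwing"))),
               sprintf("config_hash %s", format(hash)),
               sprintf("steps %d", run$steps),
               sprintf("eta %.6g", run$eta),
               sprintf("v_kin_max %.6g", run$v_kin)),
             file.path(out_dir, "run_info.txt"))
  invisible(run)
}

# ---- VTK legacy output -----------------------------------------------------

#' Write a flow state as a legacy ASCII VTK structured-points file
#'
#' Cell-centred u, v (interpolated from faces), pressure, solid fraction and
#' node-interpolated vorticity.
#'
#' @param state a `flow_state`.
#' @param path output `.vtk` file.
#' @export
write_vtk <- function(state, path) {
  g <- state$grid
  nx <- g$nx; ny <- g$ny
  uc <- (state$u[1:nx, , drop = FALSE] + state$u[2:(nx + 1), , drop = FALSE]) / 2
  vc <- (state$v[, 1:ny, drop = FALSE] + state$v[, 2:(ny + 1), drop = FALSE]) / 2
  w <- vorticity(state)
  wc <- (w[1:nx, 1:ny] + w[2:(nx + 1), 1:ny] +
         w[1:nx, 2:(ny + 1)] + w[2:(nx + 1), 2:(ny + 1)]) / 4
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               sprintf("flapwing flow state t=%.9g", state$t),
               "ASCII", "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d 1", nx, ny),
               sprintf("ORIGIN %.9g %.9g 0", g$dx / 2, g$dy / 2),
               sprintf("SPACING %.9g %.9g 1", g$dx, g$dy),
               sprintf("POINT_DATA %d", nx * ny)), con)
  wfield <- function(name, m) {
    writeLines(c(sprintf("SCALARS %s double 1", name), "LOOKUP_TABLE default"), con)
    writeLines(sprintf("%.9g", as.vector(m)), con)
  }
  wfield("u", uc); wfield("v", vc); wfield("p", state$p)
  wfield("vorticity", wc)
  chi <- state$chi
  if (!is.null(state$chiu)) {
    chi <- (state$chiu[1:nx, ] + state$chiu[2:(nx + 1), ]) / 2
  }
  wfield("solid_fraction", chi)
  invisible(path)
}

#' Write a flow state as a plain-text CSV field table
#'
#' Long-format alternative to the VTK writer: one row per cell with
#' cell-centre coordinates, velocity components, pressure, solid fraction
#' and vorticity.
#'
#' @param state a `flow_state`.
#' @param path output `.csv` file.
#' @export
write_state_csv <- function(state, path) {
  g <- state$grid
  nx <- g$nx; ny <- g$ny
  uc <- (state$u[1:nx, , drop = FALSE] + state$u[2:(nx + 1), , drop = FALSE]) / 2
  vc <- (state$v[, 1:ny, drop = FALSE] + state$v[, 2:(ny + 1), drop = FALSE]) / 2
  w <- vorticity(state)
  wc <- (w[1:nx, 1:ny] + w[2:(nx + 1), 1:ny] +
         w[1:nx, 2:(ny + 1)] + w[2:(nx + 1), 2:(ny + 1)]) / 4
  chi <- state$chi
  if (!is.null(state$chiu)) {
    chi <- (state$chiu[1:nx, ] + state$chiu[2:(nx + 1), ]) / 2
  }
  d <- data.frame(x = rep((seq_len(nx) - 0.5) * g$dx, ny),
                  y = rep((seq_len(ny) - 0.5) * g$dy, each = nx),
                  u = as.vector(uc), v = as.vector(vc),
                  p = as.vector(state$p), solid_fraction = as.vector(chi),
                  vorticity = as.vector(wc))
  write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
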