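# Fixed-Cartesian-grid fractional-step solver for the 2D unsteady
# incompressible Navier-Stokes equations with the moving wing imposed by
# Brinkman volume penalization. Staggered (MAC) arrangement; explicit
# 2nd-order upwind-biased advection and explicit diffusion; implicit
# pointwise penalization; pressure projection via a sparse Cholesky
# factorization computed once per run (the grid never moves).

#' Fluid properties
#'
#' @param rho density in kg/m^3.
#' @param mu dynamic viscosity in Pa s (give either `mu` or `nu`).
#' @param nu kinematic viscosity in m^2/s.
#' @export
fluid_properties <- function(rho, mu = NULL, nu = NULL) {
  if (rho <= 0) abort("density must be positive")
  if (is.null(mu) && is.null(nu)) abort("give mu or nu")
  if (is.null(mu)) mu <- nu * rho
  if (mu <= 0) abort("viscosity must be positive")
  structure(list(rho = rho, mu = mu, nu = mu / rho), class = "fluid_properties")
}

#' Standard sea-level air
#' @export
air_properties <- function() fluid_properties(rho = 1.204, mu = 1.82e-5)

#' Mineral oil of the hovering validation experiment
#' @export
oil_properties <- function() fluid_properties(rho = 880, nu = 1.15e-4)

bc_code <- function(boundary_mode) {
  switch(boundary_mode,
         "periodic" = 0L,
         "closed-tank-validation" = 1L,
         "open-forward-flight" = 2L,
         "channel" = 3L,
         abort(sprintf("unknown boundary_mode '%s'", boundary_mode)))
}

#' Configure one flapping-wing flow simulation
#'
#' Collects the fluid, freestream, domain/grid, penalization and CFL
#' settings, cycle count, wing profile and kinematics into a single
#' validated configuration. The freestream enters through the right boundary
#' moving in -x; domain sizes are in chords. Grid cells must be square to
#' within 1% and the full wing excursion must fit inside the domain.
#'
#' @param profile a [wing_profile()].
#' @param kin a [kinematics_spec()].
#' @param fluid a [fluid_properties()].
#' @param V_inf freestream speed in m/s.
#' @param domain_c domain width and height in chords (default 22 x 11).
#' @param grid number of cells `c(nx, ny)`.
#' @param CFL_max maximum advective CFL number (<= 1).
#' @param eta penalization time scale in s; `NULL` sets it at run time to
#'   the initial CFL-limited time step.
#' @param n_cycles flap cycles to simulate from rest.
#' @param record_window tau interval `c(lo, hi)` for statistics; default the
#'   last full cycle.
#' @param boundary_mode `"open-forward-flight"`, `"closed-tank-validation"`
#'   or `"periodic"` (the last used by the verification tests).
#' @param coef_velocity normalization speed for coefficients:
#'   `"kinematic"` uses the wing's maximum translational speed, `"freestream"`
#'   uses `V_inf` (static grid-study convention).
#' @param anchor mean wing position as a fraction of the domain.
#' @param lid_u tangential velocity of the top wall (closed mode only).
#' @return an object of class `flight_case`.
#' @export
flight_case <- function(profile, kin, fluid = air_properties(), V_inf = 0,
                        domain_c = c(22, 11), grid = c(512, 256),
                        CFL_max = 1, eta = NULL, n_cycles = 4,
                        record_window = NULL,
                        boundary_mode = c("open-forward-flight",
                                          "closed-tank-validation",
                                          "periodic", "channel"),
                        coef_velocity = c("kinematic", "freestream"),
                        anchor = c(0.5, 0.5), lid_u = 0) {
  boundary_mode <- match.arg(boundary_mode)
  coef_velocity <- match.arg(coef_velocity)
  stopifnot(inherits(profile, "wing_profile"), inherits(kin, "kinematics_spec"),
            inherits(fluid, "fluid_properties"))
  if (CFL_max <= 0 || CFL_max > 1) abort("CFL_max must be in (0, 1]")
  if (!is.null(eta) && eta <= 0) abort("eta must be positive")
  if (n_cycles < 0) abort("n_cycles must be >= 0")
  c_m <- profile$chord / 1000
  Lx <- domain_c[1] * c_m; Ly <- domain_c[2] * c_m
  nx <- as.integer(grid[1]); ny <- as.integer(grid[2])
  dx <- Lx / nx; dy <- Ly / ny
  if (abs(dx - dy) > 0.01 * max(dx, dy)) {
    abort(sprintf("grid cells must be square within 1%% (dx=%.4g, dy=%.4g m)", dx, dy))
  }
  if (is.null(record_window)) record_window <- c(max(0, n_cycles - 1), n_cycles)
  case <- structure(list(profile = profile, kin = kin, fluid = fluid,
                         V_inf = V_inf, domain_c = domain_c,
                         nx = nx, ny = ny, dx = dx, dy = dy,
                         Lx = Lx, Ly = Ly, c_m = c_m,
                         CFL_max = CFL_max, eta = eta, n_cycles = n_cycles,
                         record_window = record_window,
                         boundary_mode = boundary_mode,
                         coef_velocity = coef_velocity,
                         anchor = anchor, lid_u = lid_u),
                    class = "flight_case")
  check_excursion(case)
  case
}

# the wing's full excursion (translation + rotated bounding radius) must
# stay at least 2 cells inside the domain
check_excursion <- function(case) {
  kin <- case$kin
  t_hi <- if (kin$mode == "tow") case$n_cycles / kin$f else 1 / kin$f
  tt <- seq(0, max(t_hi, 0), length.out = 512)
  tr <- translation(tt, kin)
  bb <- do.call(rbind, case$profile$loops)
  rotates <- kin$mode != "tow" && kin$theta3A > 0
  # bounding radius when the section pitches; axis-aligned bbox otherwise
  rx <- if (rotates) max(sqrt(bb[, 1]^2 + bb[, 2]^2)) else max(abs(bb[, 1]))
  ry <- if (rotates) rx else max(abs(bb[, 2]))
  rx <- rx / 1000; ry <- ry / 1000
  cx <- case$anchor[1] * case$Lx + tr$x / 1000
  cy <- case$anchor[2] * case$Ly + tr$y / 1000
  m <- 2 * max(case$dx, case$dy)
  if (min(cx) - rx < m || max(cx) + rx > case$Lx - m ||
      min(cy) - ry < m || max(cy) + ry > case$Ly - m) {
    abort("wing excursion leaves the computational domain; enlarge domain_c or reduce the stroke")
  }
  invisible(case)
}

#' @export
print.flight_case <- function(x, ...) {
  cat(sprintf("<flight_case> %s | %s | grid %dx%d on %gx%g chords | V_inf=%g m/s | %g cycles\n",
              x$profile$name, x$boundary_mode, x$nx, x$ny,
              x$domain_c[1], x$domain_c[2], x$V_inf, x$n_cycles))
  invisible(x)
}

#' Wing-free fluid box for analytic solver verification
#'
#' A square-celled domain with no immersed body, used by the Taylor-Green,
#' Couette and convergence checks. Same stepping machinery as a full case.
#'
#' @param nx,ny grid cells.
#' @param Lx,Ly domain size in m.
#' @param fluid a [fluid_properties()].
#' @param boundary_mode `"periodic"`, `"closed-tank-validation"`,
#'   `"open-forward-flight"` or `"channel"` (periodic in x, walls in y).
#' @param V_inf freestream speed (forward mode).
#' @param lid_u top-wall tangential velocity (closed mode).
#' @param CFL_max advective CFL limit.
#' @export
fluid_box_case <- function(nx, ny, Lx, Ly = Lx * ny / nx,
                           fluid = fluid_properties(rho = 1, nu = 0.01),
                           boundary_mode = "periodic", V_inf = 0,
                           lid_u = 0, CFL_max = 0.5) {
  dx <- Lx / nx; dy <- Ly / ny
  if (abs(dx - dy) > 0.01 * max(dx, dy)) abort("cells must be square within 1%")
  structure(list(profile = NULL, kin = NULL, fluid = fluid, V_inf = V_inf,
                 domain_c = c(NA, NA), nx = as.integer(nx), ny = as.integer(ny),
                 dx = dx, dy = dy, Lx = Lx, Ly = Ly, c_m = NA,
                 CFL_max = CFL_max, eta = NULL, n_cycles = 0,
                 record_window = c(0, 0), boundary_mode = boundary_mode,
                 coef_velocity = "freestream", anchor = c(0.5, 0.5),
                 lid_u = lid_u),
            class = "flight_case")
}

#' Initial flow state of a case
#'
#' Impulsive start: uniform freestream (forward flight) or quiescent fluid.
#'
#' @param case a [flight_case()].
#' @export
initial_state <- function(case) {
  u0 <- if (case$boundary_mode == "open-forward-flight") -case$V_inf else 0
  state <- list(u = matrix(u0, case$nx + 1, case$ny),
                v = matrix(0, case$nx, case$ny + 1),
                p = matrix(0, case$nx, case$ny),
                chi = matrix(0, case$nx, case$ny),
                t = 0,
                grid = list(nx = case$nx, ny = case$ny, dx = case$dx,
                            dy = case$dy, Lx = case$Lx, Ly = case$Ly,
                            bc = bc_code(case$boundary_mode)))
  class(state) <- "flow_state"
  state
}

# ---- pressure Poisson operator --------------------------------------------

# Assemble the negated discrete Laplacian consistent with correct_velocity()
# and return its Cholesky factor. Pure-Neumann/periodic operators are pinned
# at one cell; the RHS is demeaned before solving.
make_poisson <- function(nx, ny, dx, dy, bc) {
  N <- nx * ny
  i <- rep(seq_len(nx), ny)
  j <- rep(seq_len(ny), each = nx)
  id <- function(i, j) (j - 1L) * nx + i
  me <- id(i, j)
  rows <- list(); diag <- numeric(N)
  cx <- 1 / dx^2; cy <- 1 / dy^2
  add <- function(r, c, w) rows[[length(rows) + 1L]] <<- cbind(r, c, w)
  px <- bc %in% c(0L, 3L); py <- bc == 0L
  # east/west/north/south couplings
  for (s in list(list(di = 1L, dj = 0L, w = cx), list(di = -1L, dj = 0L, w = cx),
                 list(di = 0L, dj = 1L, w = cy), list(di = 0L, dj = -1L, w = cy))) {
    i2 <- i + s$di; j2 <- j + s$dj
    wrap_x <- px && s$di != 0L
    wrap_y <- py && s$dj != 0L
    if (wrap_x) i2 <- ((i2 - 1L) %% nx) + 1L
    if (wrap_y) j2 <- ((j2 - 1L) %% ny) + 1L
    ok <- i2 >= 1L & i2 <= nx & j2 >= 1L & j2 <= ny
    add(me[ok], id(i2[ok], j2[ok]), rep(-s$w, sum(ok)))
    diag[me[ok]] <- diag[me[ok]] + s$w
    if (bc == 2L && s$di == -1L) {
      # left outflow: p = 0 at the boundary face
      edge <- me[!ok & i == 1L]
      diag[edge] <- diag[edge] + 2 * cx
    }
  }
  add(me, me, diag)
  M <- do.call(rbind, rows)
  A <- Matrix::sparseMatrix(i = M[, 1], j = M[, 2], x = M[, 3], dims = c(N, N))
  pure_neumann <- bc != 2L
  if (pure_neumann) A[1, 1] <- A[1, 1] + 2 * (cx + cy)
  list(ch = Matrix::Cholesky(A, LDL = FALSE, perm = TRUE),
       pure_neumann = pure_neumann, nx = nx, ny = ny)
}

solve_poisson <- function(ps, div) {
  rhs <- -as.vector(div)
  if (ps$pure_neumann) rhs <- rhs - mean(rhs)
  phi <- as.numeric(Matrix::solve(ps$ch, rhs))
  matrix(phi, ps$nx, ps$ny)
}

# ---- time step control -----------------------------------------------------

#' CFL-limited time step
#'
#' `dt = CFL_max * dX / V_ref` with `V_ref = max(|Vx| + V_inf, |Vy|,
#' max field speed)` where `(Vx, Vy)` is the wing's translational velocity,
#' additionally capped by the explicit diffusive limit `dX^2 / (4 nu)` and by
#' the penalization time scale `eta`. A vanishing `V_ref` falls back to the
#' diffusive cap.
#'
#' @param state a `flow_state`.
#' @param case a [flight_case()].
#' @param body_vel list or one-row data frame with `vx`, `vy` (m/s).
#' @export
compute_dt <- function(state, case, body_vel) {
  dX <- min(case$dx, case$dy)
  vfield <- max_courant_speed(state$u, state$v)  # max |u_c| + |v_c| per cell
  vref <- max(abs(body_vel$vx) + abs(case$V_inf), abs(body_vel$vy), vfield)
  dt_diff <- dX^2 / (4 * case$fluid$nu)
  eta <- case$eta %||% Inf
  if (vref <= 0) return(min(dt_diff, eta))
  min(stable_dt(vref, dX, dt_diff, case$CFL_max), dt_diff, eta)
}

# Combined explicit advection-diffusion step bound. The one-sided
# second-order gradient has spectral radius 4/dX under forward Euler, so
# its own stability limit is an advective Courant number of 1/2; the
# factor 0.45 keeps a margin below it. Always below each individual cap.
stable_dt <- function(vref, dX, dt_diff, CFL_max) {
  0.45 * CFL_max / (vref / dX + 1 / dt_diff)
}

# ---- stepping --------------------------------------------------------------

# run context: everything reusable across steps
build_context <- function(case) {
  bc <- bc_code(case$boundary_mode)
  no_wing <- is.null(case$profile)
  loops_m <- if (no_wing) NULL else lapply(case$profile$loops, function(m) m / 1000)
  ps <- make_poisson(case$nx, case$ny, case$dx, case$dy, bc)
  vk <- if (no_wing) 0 else v_kin_max(case$kin)
  vmag <- switch(case$coef_velocity,
                 kinematic = vk,
                 freestream = case$V_inf)
  if (!no_wing && vmag <= 0 && case$kin$mode != "tow") {
    abort("coefficient reference velocity is zero; choose the other coef_velocity")
  }
  # static/towed diagnostics without a freestream: unit reference speed
  if (is.null(vmag) || vmag <= 0) vmag <- 1
  eta <- case$eta
  if (is.null(eta)) {
    # aim for dt/eta near 1 in the developed flow: field speeds typically
    # exceed the kinematic reference by a factor ~2.5 once vortices form
    dX <- min(case$dx, case$dy)
    vref0 <- max(vk + abs(case$V_inf), 1e-12)
    dt_diff <- dX^2 / (4 * case$fluid$nu)
    eta <- min(stable_dt(2.5 * vref0, dX, dt_diff, case$CFL_max), dt_diff)
  }
  list(bc = bc, loops_m = loops_m, ps = ps, v_kin = vk, V_mag = vmag,
       eta = eta, A_ref = case$c_m, no_wing = no_wing,
       anchor_m = c(case$anchor[1] * case$Lx, case$anchor[2] * case$Ly))
}

# scalar motion sample as a plain list (hot path; no tibble overhead)
motion_scalar <- function(t, spec) {
  tr <- translation(t, spec)
  v <- body_velocity(t, spec)
  list(t = t, tau = spec$f * t, x = tr$x[1], y = tr$y[1],
       theta3 = pitch_angle(t, spec),
       vx = v$vx[1], vy = v$vy[1], omega3 = placement_omega(t, spec))
}

# solid fraction fields at u-faces, v-faces and cell centres for the wing
# placed at time t
wing_masks <- function(case, ctx, t, centers = FALSE) {
  tr <- translation(t, case$kin)
  ang <- placement_angle(t, case$kin)
  a <- ang * pi / 180
  R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  cx <- ctx$anchor_m[1] + tr$x[1] / 1000
  cy <- ctx$anchor_m[2] + tr$y[1] / 1000
  loops <- lapply(ctx$loops_m, function(m) {
    out <- m %*% t(R)
    out[, 1] <- out[, 1] + cx
    out[, 2] <- out[, 2] + cy
    out
  })
  eps <- (case$mask_eps %||% 0.5) * max(case$dx, case$dy)
  chiu <- polygon_chi(loops, 0, case$dx, case$nx + 1,
                      case$dy / 2, case$dy, case$ny, eps)
  chiv <- polygon_chi(loops, case$dx / 2, case$dx, case$nx,
                      0, case$dy, case$ny + 1, eps)
  chic <- if (centers) {
    polygon_chi(loops, case$dx / 2, case$dx, case$nx,
                case$dy / 2, case$dy, case$ny, eps)
  } else NULL
  list(chiu = chiu, chiv = chiv, chic = chic, xc = cx, yc = cy)
}

#' Advance the flow one time step
#'
#' Fractional step: explicit upwind-biased advection and diffusion, implicit
#' Brinkman penalization toward the wing's rigid-body motion, then a
#' projection onto divergence-free fields via the pressure Poisson solve.
#'
#' @param state a `flow_state`.
#' @param case a [flight_case()].
#' @param ctx internal run context from a previous call (rebuilt if `NULL`).
#' @param dt time step in s; computed by [compute_dt()] if `NULL`.
#' @return the advanced `flow_state`; attributes `force` (N/m, on the body)
#'   and `motion` record the step's penalization force and wing motion.
#' @export
step_flow <- function(state, case, ctx = NULL, dt = NULL) {
  if (is.null(ctx)) ctx <- attr(state, "ctx")
  if (is.null(ctx)) ctx <- build_context(case)
  tn <- state$t
  mot <- if (ctx$no_wing) list(vx = 0, vy = 0) else motion_scalar(tn, case$kin)
  if (is.null(dt)) {
    case_eta <- case; case_eta$eta <- ctx$eta
    dt <- compute_dt(state, case_eta, mot)
  }
  t1 <- tn + dt
  pred <- predict_velocity(state$u, state$v, case$dx, case$dy,
                           case$fluid$nu, dt, ctx$bc, case$V_inf, case$lid_u)
  if (ctx$no_wing) {
    mot1 <- NULL
    pen <- list(u = pred$u, v = pred$v, fx = 0, fy = 0)
    masks <- NULL
  } else {
    mot1 <- motion_scalar(t1, case$kin)
    omega_pl <- mot1$omega3
    masks <- wing_masks(case, ctx, t1, centers = FALSE)
    pen <- penalize_rigid(pred$u, pred$v, masks$chiu, masks$chiv,
                          mot1$vx, mot1$vy, omega_pl,
                          masks$xc, masks$yc, case$dx, case$dy, dt, ctx$eta)
  }
  div <- divergence_mac(pen$u, pen$v, case$dx, case$dy)
  phi <- solve_poisson(ctx$ps, div)
  cor <- correct_velocity(pen$u, pen$v, phi, case$dx, case$dy, ctx$bc)
  if (!all(is.finite(cor$u)) || !all(is.finite(cor$v))) {
    abort(sprintf("solver diverged (non-finite velocity) at t = %.6g s (tau = %.4g)",
                  t1, t1 * case$kin$f))
  }
  f_scale <- case$fluid$rho * case$dx * case$dy / dt
  force <- c(Fx = pen$fx * f_scale, Fy = pen$fy * f_scale)
  out <- state
  out$u <- cor$u; out$v <- cor$v
  out$p <- phi * case$fluid$rho / dt
  out$t <- t1
  if (!ctx$no_wing) {
    out$chiu <- masks$chiu; out$chiv <- masks$chiv
    out$body <- list(vx = mot1$vx, vy = mot1$vy, omega = omega_pl,
                     xc = masks$xc, yc = masks$yc, eta = ctx$eta)
  }
  attr(out, "force") <- force
  attr(out, "motion") <- mot1
  attr(out, "dt") <- dt
  attr(out, "ctx") <- ctx
  out
}

# pitch placement rate in rad/s (equals omega3; the validation mode's 90 deg
# offset is constant)
placement_omega <- function(t, spec) {
  if (spec$mode == "tow") return(0)
  deg2rad(spec$theta3A) * 2 * pi * spec$f * cos(2 * pi * spec$f * t)
}

#' Run a full flapping simulation
#'
#' Simulates `case$n_cycles` flap periods from rest, recording the
#' penalization force on the wing and the lift/drag coefficients each step,
#' with optional field snapshots at requested stroke phases.
#'
#' @param case a [flight_case()].
#' @param snapshot_taus absolute tau values at which to store field
#'   snapshots (the initial state is always kept).
#' @param verbose print one progress line per cycle.
#' @return an object of class `flap_run`: list with `forces` (tibble with
#'   `t`, `tau`, `Fx`, `Fy`, `CL`, `CD`), `snapshots`, `case`, `v_kin`,
#'   `V_mag`, `eta`, `steps`.
#' @export
run_case <- function(case, snapshot_taus = numeric(0), verbose = FALSE) {
  stopifnot(inherits(case, "flight_case"))
  ctx <- build_context(case)
  state <- initial_state(case)
  t_end <- case$n_cycles / case$kin$f
  snapshots <- list(initial = state)
  pend_taus <- sort(snapshot_taus)
  cap <- 4096L
  rec <- list(t = numeric(cap), tau = numeric(cap), Fx = numeric(cap),
              Fy = numeric(cap), CL = numeric(cap), CD = numeric(cap))
  nrec <- 0L
  cyc_done <- 0L
  q <- 0.5 * case$fluid$rho * ctx$V_mag^2 * ctx$A_ref
  t_wall0 <- proc.time()[["elapsed"]]
  while (state$t < t_end - 1e-12) {
    state <- step_flow(state, case, ctx)
    f <- attr(state, "force"); mot <- attr(state, "motion")
    co <- force_coefficients(f[["Fx"]], f[["Fy"]], case$fluid$rho, ctx$V_mag,
                             ctx$A_ref,
                             convention = if (case$boundary_mode == "closed-tank-validation")
                               "resistive" else "forward",
                             translation_dir = c(mot$vx, mot$vy))
    nrec <- nrec + 1L
    if (nrec > cap) {
      cap <- cap * 2L
      rec <- lapply(rec, function(v) { length(v) <- cap; v })
    }
    tau <- state$t * case$kin$f
    rec$t[nrec] <- state$t; rec$tau[nrec] <- tau
    rec$Fx[nrec] <- f[["Fx"]]; rec$Fy[nrec] <- f[["Fy"]]
    rec$CL[nrec] <- co$CL; rec$CD[nrec] <- co$CD
    while (length(pend_taus) && tau >= pend_taus[1] - 1e-12) {
      snapshots[[sprintf("tau_%.4g", pend_taus[1])]] <- state
      pend_taus <- pend_taus[-1]
    }
    if (tau >= cyc_done + 1) {
      cyc_done <- cyc_done + 1L
      if (verbose) {
        dX <- min(case$dx, case$dy)
        message(sprintf(
          "cycle=%d steps=%d dt=%.3e max_cfl=%.3f div_res=%.3e",
          cyc_done, nrec, attr(state, "dt"),
          max(abs(state$u), abs(state$v)) * attr(state, "dt") / dX,
          max(abs(divergence_mac(state$u, state$v, case$dx, case$dy)))))
      }
    }
  }
  forces <- tibble(t = rec$t[seq_len(nrec)], tau = rec$tau[seq_len(nrec)],
                   Fx = rec$Fx[seq_len(nrec)], Fy = rec$Fy[seq_len(nrec)],
                   CL = rec$CL[seq_len(nrec)], CD = rec$CD[seq_len(nrec)])
  structure(list(forces = forces, snapshots = snapshots, case = case,
                 v_kin = ctx$v_kin, V_mag = ctx$V_mag, eta = ctx$eta,
                 q = q, steps = nrec,
                 wall_s = proc.time()[["elapsed"]] - t_wall0),
            class = "flap_run")
}

#' @export
print.flap_run <- function(x, ...) {
  cat(sprintf("<flap_run> %s: %d steps over %g cycles (%.1f s wall)\n",
              x$case$profile$name, x$steps, x$case$n_cycles, x$wall_s))
  if (nrow(x$forces) > 0) {
    w <- x$case$record_window
    m <- time_average(x$forces, cols = c("CL", "CD"), window = w)
    cat(sprintf("  mean CL=%.4g, mean CD=%.4g over tau in [%g, %g)\n",
                m$CL, m$CD, w[1], w[2]))
  }
  invisible(x)
}

#' Vorticity field of a flow state
#'
#' `dv/dx - du/dy` by central differences at grid nodes; positive values are
#' counter-clockwise rotation.
#'
#' @param state a `flow_state`.
#' @return `(nx+1) x (ny+1)` matrix in 1/s.
#' @export
vorticity <- function(state) {
  vorticity_nodes(state$u, state$v, state$grid$dx, state$grid$dy)
}

#' Discrete divergence field of a flow state
#' @param state a `flow_state`.
#' @export
divergence <- function(state) {
  divergence_mac(state$u, state$v, state$grid$dx, state$grid$dy)
}
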