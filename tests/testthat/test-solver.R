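# analytic verification of the flow solver

test_that("compute_dt honours every cap and never exceeds the CFL bound", {
  case <- fluid_box_case(64, 64, 64e-4,
                         fluid = fluid_properties(rho = 1, nu = 1e-6),
                         boundary_mode = "closed-tank-validation",
                         CFL_max = 1)
  dX <- case$dx
  st <- initial_state(case)
  # quiescent fluid: falls back to the diffusive/eta caps
  expect_equal(compute_dt(st, case, list(vx = 0, vy = 0)),
               dX^2 / (4 * case$fluid$nu))
  case$eta <- 1e-7
  expect_equal(compute_dt(st, case, list(vx = 0, vy = 0)), 1e-7)
  # random states: dt * V_ref / dX never exceeds CFL_max, nor any cap
  case$eta <- NULL
  set.seed(17)
  for (k in 1:100) {
    st$u[] <- rnorm(length(st$u))
    st$v[] <- rnorm(length(st$v))
    bv <- list(vx = rnorm(1), vy = rnorm(1))
    dt <- compute_dt(st, case, bv)
    vref <- max(abs(bv$vx), abs(bv$vy), max(abs(st$u)), max(abs(st$v)))
    expect_lte(dt * vref / dX, case$CFL_max + 1e-12)
    expect_lte(dt, dX^2 / (4 * case$fluid$nu))
  }
})

test_that("uniform freestream with no solid is preserved exactly", {
  case <- fluid_box_case(48, 24, 0.48, fluid = fluid_properties(rho = 1, nu = 1e-5),
                         boundary_mode = "open-forward-flight", V_inf = 2)
  st <- initial_state(case)
  for (k in 1:5) st <- step_flow(st, case, dt = 1e-4)
  expect_lt(max(abs(st$u + 2)), 1e-12)
  expect_lt(max(abs(st$v)), 1e-12)
})

test_that("Taylor-Green kinetic energy decays at the analytic rate", {
  nu <- 0.01
  n <- 128
  case <- fluid_box_case(n, n, 2 * pi, fluid = fluid_properties(rho = 1, nu = nu),
                         boundary_mode = "periodic")
  st <- taylor_green_state(n, n, nu)
  ke0 <- sum(st$u[-1, ]^2) / 2 + sum(st$v[, -1]^2) / 2
  t_end <- 2
  while (st$t < t_end - 1e-9) st <- step_flow(st, case, dt = min(0.01, t_end - st$t))
  ke <- sum(st$u[-1, ]^2) / 2 + sum(st$v[, -1]^2) / 2
  expect_equal(ke / ke0, exp(-4 * nu * t_end), tolerance = 0.01)
  # divergence-free after stepping
  expect_lt(max(abs(divergence(st))), 1e-8 * max(abs(st$u)) / case$dx)
})

test_that("vorticity operator is exact for rigid rotation and uniform flow", {
  n <- 32
  case <- fluid_box_case(n, n, 1, boundary_mode = "closed-tank-validation")
  st <- initial_state(case)
  om <- 3.2; xc <- 0.5; yc <- 0.5
  yu <- (seq_len(n) - 0.5) * case$dy
  st$u <- outer(rep(1, n + 1), -om * (yu - yc)) + 0 * st$u
  xv <- (seq_len(n) - 0.5) * case$dx
  st$v <- outer(om * (xv - xc), rep(1, n + 1))
  w <- vorticity(st)
  expect_equal(max(abs(w - 2 * om)), 0, tolerance = 1e-10)
  st$u[] <- 4; st$v[] <- -1
  expect_lt(max(abs(vorticity(st))), 1e-12)
})

test_that("vorticity of Taylor-Green matches the analytic field at 2nd order", {
  nu <- 0.01
  werr <- function(n) {
    st <- taylor_green_state(n, n, nu)
    w <- vorticity(st)
    xs <- (0:n) * st$grid$dx
    wex <- outer(xs, xs, function(x, y) 2 * sin(x) * sin(y))
    sqrt(mean((w[2:n, 2:n] - wex[2:n, 2:n])^2))
  }
  e1 <- werr(32); e2 <- werr(64)
  expect_gt(log2(e1 / e2), 1.9)
})

test_that("a penalized wall drives a steady Couette profile", {
  # streamwise-periodic channel, moving lid, a thick penalized plate near the
  # bottom: the fluid above the plate settles to the linear Couette profile
  U <- 0.05
  plate <- make_flat_plate(10, 0.28)
  case <- flight_case(profile = plate, kin = tow_kinematics(0),
                      fluid = fluid_properties(rho = 1000, nu = 2e-4),
                      domain_c = c(1.2, 1.2), grid = c(32L, 32L),
                      n_cycles = 0, boundary_mode = "channel",
                      coef_velocity = "freestream", V_inf = 0,
                      anchor = c(0.5, 0.2), lid_u = U)
  H <- case$Ly
  st <- initial_state(case)
  t_visc <- H^2 / case$fluid$nu
  while (st$t < 1.2 * t_visc) st <- step_flow(st, case)
  # u(y) at mid-width above the plate's upper face, clear of the smeared band
  ytop <- 0.2 * H + 0.28 * 0.010 / 2
  ys <- (seq_len(case$ny) - 0.5) * case$dy
  sel <- ys > ytop + 2 * case$dy & ys < H - case$dy
  uprof <- st$u[case$nx / 2, sel]
  ylin <- (ys[sel] - ytop) / (H - ytop) * U
  expect_lt(max(abs(uprof - ylin)) / U, 0.02)
})

test_that("runs are deterministic and empty for zero cycles", {
  plate <- make_flat_plate(4, 0.1)
  kin <- kinematics_spec(f = 50, theta1A = 20, theta2A = 0, theta3A = 20,
                         r0 = 10)
  case <- flight_case(profile = plate, kin = kin,
                      fluid = fluid_properties(rho = 1.2, nu = 1.5e-5),
                      V_inf = 1, domain_c = c(12, 6), grid = c(72L, 36L),
                      n_cycles = 0, boundary_mode = "open-forward-flight")
  r0 <- run_case(case)
  expect_equal(nrow(r0$forces), 0)
  expect_named(r0$snapshots, "initial")
  case$n_cycles <- 1
  case$record_window <- c(0, 1)
  ra <- run_case(case)
  rb <- run_case(case)
  expect_identical(ra$forces, rb$forces)
})

test_that("configs whose stroke leaves the domain are refused", {
  plate <- make_flat_plate(4, 0.1)
  kin <- kinematics_spec(f = 150, theta1A = 110, theta2A = 0, theta3A = 24,
                         r0 = 6.61)
  expect_error(
    flight_case(profile = plate, kin = kin,
                fluid = fluid_properties(rho = 1.2, nu = 1.5e-5),
                domain_c = c(6, 6), grid = c(64L, 64L),
                boundary_mode = "open-forward-flight"),
    "excursion")
})

test_that("static plate in freestream matches the towed plate (Galilean)", {
  nu <- 5e-4; V <- 1
  plate <- make_flat_plate(10, 0.2)
  t_end <- 0.012
  # static plate, freestream V
  c1 <- flight_case(profile = plate, kin = tow_kinematics(0),
                    fluid = fluid_properties(rho = 1, nu = nu),
                    V_inf = V, domain_c = c(10, 6), grid = c(120L, 72L),
                    n_cycles = 0, boundary_mode = "open-forward-flight",
                    coef_velocity = "freestream", anchor = c(0.5, 0.5))
  s1 <- initial_state(c1); f1 <- c()
  while (s1$t < t_end) { s1 <- step_flow(s1, c1); f1 <- c(f1, attr(s1, "force")[["Fx"]]) }
  # towed plate in still fluid, closed tank of the same size and grid
  kin <- tow_kinematics(V)
  c2 <- flight_case(profile = plate, kin = kin,
                    fluid = fluid_properties(rho = 1, nu = nu),
                    V_inf = 0, domain_c = c(10, 6), grid = c(120L, 72L),
                    n_cycles = t_end, boundary_mode = "closed-tank-validation",
                    coef_velocity = "kinematic", anchor = c(0.28, 0.5))
  s2 <- initial_state(c2); f2 <- c(); tt2 <- c()
  while (s2$t < t_end) { s2 <- step_flow(s2, c2); f2 <- c(f2, attr(s2, "force")[["Fx"]]); tt2 <- c(tt2, s2$t) }
  # compare late-time drag magnitude (opposite sign conventions cancel in
  # the comparison: both are the x-force on the body; tow drag is -x)
  tt1 <- cumsum(rep(NA, 0))
  d1 <- abs(mean(tail(f1, ceiling(length(f1) * 0.2))))
  d2 <- abs(mean(tail(f2, ceiling(length(f2) * 0.2))))
  expect_lt(abs(d1 - d2) / d1, 0.03)
})
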