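test_that("fixtures are generated deterministically and round-trip", {
  d1 <- withr::local_tempdir()
  p1 <- make_fixtures("profiles", d1)
  expect_length(p1, 4)
  for (f in p1) {
    p <- load_profile(f)
    expect_equal(p$chord, 4, tolerance = 1e-9)
  }
  d2 <- withr::local_tempdir()
  p2 <- make_fixtures("profiles", d2)
  for (k in seq_along(p1)) {
    expect_identical(readLines(p1[k]), readLines(p2[k]))
  }
  tg <- make_fixtures("taylor-green", d1)
  expect_true(file.exists(tg))
  mt <- make_fixtures("motion-trace", d1)
  expect_gt(nrow(read.csv(mt)), 100)
})

test_that("the Taylor-Green initial field is discretely divergence-free", {
  st <- taylor_green_state(64, 64, nu = 0.01)
  expect_lt(max(abs(divergence(st))), 1e-12)
})

test_that("case configs round-trip through YAML with schema validation", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "fluid:",
    "  standard: oil",
    "profile:",
    "  type: plate",
    "  chord: 23.85",
    "  thickness_ratio: 0.1",
    "kinematics:",
    "  mode: hover-validation",
    "case:",
    "  boundary_mode: closed-tank-validation",
    "  coef_velocity: kinematic",
    "  domain_c: [10, 10]",
    "  grid: [64, 64]",
    "  n_cycles: 1"), f)
  case <- read_case_config(f)
  expect_s3_class(case, "flight_case")
  expect_equal(case$fluid$rho, 880)
  expect_equal(case$kin$f, 0.25)
  expect_equal(case$nx, 64L)
  # unknown keys are schema errors naming the key
  f2 <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(readLines(f), "  frobnicate: 1"), f2)
  expect_error(read_case_config(f2), "frobnicate")
})

test_that("run_study_case writes forces, summary and VTK artifacts", {
  plate <- make_flat_plate(20, 0.1)
  kin <- kinematics_spec(f = 2, theta1A = 10, theta2A = 0, theta3A = 20,
                         r0 = 100, mode = "hover-validation")
  case <- flight_case(profile = plate, kin = kin,
                      fluid = fluid_properties(rho = 100, nu = 1e-4),
                      domain_c = c(6, 6), grid = c(48L, 48L),
                      n_cycles = 0.25, record_window = c(0, 0.25),
                      boundary_mode = "closed-tank-validation",
                      coef_velocity = "kinematic")
  out <- withr::local_tempdir()
  suppressWarnings(run <- run_study_case(case, out, snapshot_taus = 0.2))
  expect_true(file.exists(file.path(out, "forces.csv")))
  expect_true(file.exists(file.path(out, "summary.csv")))
  vtk <- list.files(out, pattern = "\\.vtk$")
  expect_length(vtk, 1)
  head <- readLines(file.path(out, vtk), n = 4)
  expect_identical(head[1], "# vtk DataFile Version 3.0")
  expect_identical(head[4], "DATASET STRUCTURED_POINTS")
  # plain-text field table alternative
  csvf <- file.path(out, "fields.csv")
  write_state_csv(run$snapshots[[2]], csvf)
  flds <- read.csv(csvf)
  expect_identical(names(flds),
                   c("x", "y", "u", "v", "p", "solid_fraction", "vorticity"))
  expect_equal(nrow(flds), 48 * 48)
  # rerun is byte-identical (pure function of the config)
  out2 <- withr::local_tempdir()
  suppressWarnings(run_study_case(case, out2, snapshot_taus = 0.2))
  expect_identical(readLines(file.path(out, "forces.csv")),
                   readLines(file.path(out2, "forces.csv")))
})

test_that("domain sweep needs two widths and reports one row per width", {
  plate <- make_flat_plate(10, 0.2)
  case <- flight_case(profile = plate, kin = tow_kinematics(0),
                      fluid = fluid_properties(rho = 1, nu = 5e-4),
                      V_inf = 1, domain_c = c(8, 4), grid = c(64L, 32L),
                      n_cycles = 0.01, record_window = c(0, 0.01),
                      boundary_mode = "open-forward-flight",
                      coef_velocity = "freestream")
  expect_error(domain_sweep(case, 22), "two domain widths")
  sw <- suppressWarnings(domain_sweep(case, c(6, 8, 12)))
  expect_equal(nrow(sw), 3)
  expect_true(is.na(sw$delta_CD[1]))
})

test_that("tidiers and plots expose the run results", {
  plate <- make_flat_plate(20, 0.1)
  kin <- kinematics_spec(f = 2, theta1A = 10, theta2A = 0, theta3A = 20,
                         r0 = 100, mode = "hover-validation")
  case <- flight_case(profile = plate, kin = kin,
                      fluid = fluid_properties(rho = 100, nu = 1e-4),
                      domain_c = c(6, 6), grid = c(32L, 32L),
                      n_cycles = 1, record_window = c(0, 1),
                      boundary_mode = "closed-tank-validation",
                      coef_velocity = "kinematic")
  run <- run_case(case)
  td <- tidy(run)
  expect_true(all(c("t", "tau", "Fx", "Fy", "CL", "CD") %in% names(td)))
  g <- glance(run)
  expect_equal(nrow(g), 1)
  expect_true(is.finite(g$mean_CL))
  p <- autoplot(run)
  expect_s3_class(p, "ggplot")
  p2 <- plot_vorticity(run$snapshots$initial)
  expect_s3_class(p2, "ggplot")
  p3 <- autoplot(case$profile)
  expect_s3_class(p3, "ggplot")
})
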