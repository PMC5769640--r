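test_that("flat plate matches its closed-form area and chord", {
  p <- make_flat_plate(4, 0.0125)
  expect_s3_class(p, "wing_profile")
  expect_equal(p$chord, 4)
  m <- do.call(rbind, p$loops)
  expect_equal(diff(range(m[, 1])), 4, tolerance = 1e-9)
  expect_equal(diff(range(m[, 2])), 0.05, tolerance = 1e-6)
  expect_equal(profile_area(p), plate_area_exact(4, 0.0125), tolerance = 1e-3)
})

test_that("degenerate plate parameters are rejected", {
  expect_error(make_flat_plate(4, 0), "thickness_ratio")
  expect_error(make_flat_plate(-1, 0.0125), "chord")
  expect_error(make_flat_plate(4, 1.2), "thickness_ratio")
})

test_that("ellipse area converges to pi*a*b with vertex count", {
  for (n in c(128, 512)) {
    p <- make_ellipse(4, 0.125, n = n)
    expect_equal(profile_area(p), pi * 2 * 0.25,
                 tolerance = if (n == 128) 1e-3 else 1e-4)
  }
  # unit thickness ratio gives a circle of diameter c
  circ <- make_ellipse(2, 1)
  m <- do.call(rbind, circ$loops)
  expect_equal(max(abs(sqrt(m[, 1]^2 + m[, 2]^2) - 1)), 0, tolerance = 1e-12)
})

test_that("zero-corrugation limit is congruent with the flat plate", {
  spec <- corrugation_spec(vein_amplitudes = rep(0, 8),
                           vein_radius = 0.0125 / 2,
                           membrane_thickness = 0.0125,
                           notch_depth = 0)
  co <- make_corrugated(4, spec, n = 320)
  pl <- make_flat_plate(4, 0.0125, n = 320)
  a <- do.call(rbind, co$loops)
  b <- do.call(rbind, pl$loops)
  expect_equal(nrow(a), nrow(b))
  expect_lt(max(abs(a - b)), 1e-9)
})

test_that("corrugated section has one thickness maximum per vein", {
  co <- make_corrugated(4, corrugation_spec(notch_depth = 0), n = 2048)
  sc <- thickness_scan(co, nbin = 160)
  sc <- sc[!is.na(sc$thickness), ]
  # interior local maxima of the thickness profile
  y <- sc$thickness
  pk <- which(y[2:(length(y) - 1)] > y[1:(length(y) - 2)] &
              y[2:(length(y) - 1)] > y[3:length(y)]) + 1
  # prominence filter: vein bumps rise well above the membrane
  pk <- pk[y[pk] > 0.6 * max(y)]
  expect_equal(length(pk), 8)
})

test_that("corrugated generator is deterministic and jitter is seeded", {
  s <- corrugation_spec(jitter = 0.005, seed = 42L)
  a <- make_corrugated(4, s)
  b <- make_corrugated(4, s)
  expect_identical(a$loops, b$loops)
  s2 <- corrugation_spec(jitter = 0.005, seed = 43L)
  expect_false(isTRUE(all.equal(a$loops, make_corrugated(4, s2)$loops)))
})

test_that("self-intersecting corrugation is rejected with a node hint", {
  # large vein disks on a tightly folded camber: the normal offset folds over
  spec <- corrugation_spec(vein_amplitudes = c(0.1, -0.1, 0.1, -0.1,
                                               0.1, -0.1, 0.1, -0.1),
                           membrane_thickness = 0.002,
                           vein_radius = 0.06)
  expect_error(make_corrugated(4, spec), "vein node")
})

test_that("amplitudes beyond the thin-profile bound are rejected", {
  expect_error(corrugation_spec(vein_amplitudes = rep(0.2, 8)), "0.1")
})

test_that("smoothing reduces corrugation and preserves the chord", {
  co <- make_corrugated(4)
  sm <- smooth_profile(co, 0.2)
  expect_equal(sm$chord, 4, tolerance = 1e-9)
  m <- do.call(rbind, sm$loops)
  expect_equal(diff(range(m[, 1])), 4, tolerance = 0.04)  # chord within 1%
  # camber deviation strictly reduced
  dev <- function(p) {
    sc <- thickness_scan(p, 100)
    m <- do.call(rbind, p$loops)
    br <- seq(min(m[, 1]), max(m[, 1]), length.out = 101)
    mids <- tapply(m[, 2], cut(m[, 1], br, include.lowest = TRUE),
                   function(y) mean(range(y)))
    max(abs(mids), na.rm = TRUE)
  }
  expect_lt(dev(sm), dev(co))
})

test_that("smoothing a flat plate changes almost nothing", {
  # corners round slightly; bulk shape and area survive
  pl <- make_flat_plate(4, 0.05)
  sm <- smooth_profile(pl, 0.1)
  expect_equal(profile_area(sm), profile_area(pl), tolerance = 0.05)
  expect_equal(sm$chord, pl$chord, tolerance = 1e-12)
})

test_that("smoothing is idempotent and rejects windows at or above the chord", {
  co <- make_corrugated(4)
  s1 <- smooth_profile(co, 0.2)
  s2 <- smooth_profile(s1, 0.2)
  d <- max(abs(do.call(rbind, s1$loops) - do.call(rbind, s2$loops)))
  expect_lt(d, 1e-6 * co$chord)
  expect_error(smooth_profile(co, 1.25), "window")
})

test_that("rasterization conserves area and halves its error with the cell", {
  el <- make_ellipse(4, 0.125)
  # the rasterizer's target is the polygon (shoelace) area
  exact <- profile_area(el)
  g <- function(cell) list(cell = cell, xlim = c(-3, 3), ylim = c(-2, 2))
  a1 <- sum(rasterize(el, grid = g(0.08))) * 0.08^2
  a2 <- sum(rasterize(el, grid = g(0.04))) * 0.04^2
  expect_equal(a1, pi * 2 * 0.25, tolerance = 0.01)   # ideal-ellipse check
  e1 <- abs(a1 - exact); e2 <- abs(a2 - exact)
  expect_lt(e2, e1 / 1.8)
})

test_that("rasterization is symmetric under 180-degree rotation of an ellipse", {
  el <- make_ellipse(4, 0.125)
  g <- list(cell = 0.05, xlim = c(-3, 3), ylim = c(-2, 2))
  f0 <- rasterize(el, list(x = 0, y = 0, angle = 0), g)
  f180 <- rasterize(el, list(x = 0, y = 0, angle = 180), g)
  expect_equal(f0, f180, tolerance = 1e-9)
})

test_that("placement outside the grid is a placement error", {
  el <- make_ellipse(4, 0.125)
  g <- list(cell = 0.05, xlim = c(-3, 3), ylim = c(-2, 2))
  expect_error(rasterize(el, list(x = 4, y = 0, angle = 0), g), "outside")
})

test_that("profile files round-trip and report parse errors with line numbers", {
  p <- make_ellipse(4, 0.125)
  f <- withr::local_tempfile(fileext = ".txt")
  save_profile(p, f)
  q <- load_profile(f)
  expect_equal(q$loops[[1]], p$loops[[1]], tolerance = 1e-8,
               ignore_attr = TRUE)
  # two-point loop
  f2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("0 0", "1 0"), f2)
  expect_error(load_profile(f2), "fewer than 3")
  # figure-eight loop
  f3 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("0 0", "1 1", "1 0", "0 1"), f3)
  expect_error(load_profile(f3), "self-intersect")
  # junk line
  f4 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("0 0", "not numbers", "1 0"), f4)
  expect_error(load_profile(f4), "line 2")
})

test_that("every generator output satisfies the profile invariants", {
  secs <- standard_sections()
  for (nm in names(secs)) {
    p <- secs[[nm]]
    m <- do.call(rbind, p$loops)
    expect_equal(diff(range(m[, 1])), p$chord, tolerance = 1e-9 * p$chord)
    for (lp in p$loops) {
      expect_gt(abs(flapwing:::shoelace_area(lp)), 0)
      expect_identical(flapwing:::polygon_self_intersection(lp)[1], 0L)
    }
  }
})
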