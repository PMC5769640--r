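# Wing cross-section geometry: generators for the four sections compared in
# the package (corrugated bee-like, smoothed, ellipse, flat plate), plus
# validation, smoothing, rasterization onto a solver grid and plain-text IO.
# All profile coordinates are millimetres; the pitch/placement reference
# point is the mid-chord on the camber line, at the origin, with the leading
# edge toward +x.

#' Construct and validate a wing cross-section profile
#'
#' A `wing_profile` is one or more closed polygonal loops (coordinates in mm)
#' with a chord length equal to the total x-extent. Loops are stored open
#' (closure is implied; the first vertex must not repeat at the end).
#' Validation enforces simple (non-self-intersecting) loops, nonzero enclosed
#' area per loop, and chord consistency to 1e-9 relative.
#'
#' @param vertices a two-column matrix (single loop) or list of such matrices.
#' @param chord chord length in mm; defaults to the x-extent of the vertices.
#' @param name label used in reports and plots.
#' @return an object of class `wing_profile` with elements `loops`, `chord`,
#'   `name`.
#' @export
wing_profile <- function(vertices, chord = NULL, name = "profile") {
  if (is.matrix(vertices)) vertices <- list(vertices)
  loops <- lapply(vertices, function(m) {
    m <- as.matrix(m)
    if (ncol(m) != 2) abort("each loop must be a two-column (x, y) matrix")
    storage.mode(m) <- "double"
    if (nrow(m) >= 2 && all(abs(m[1, ] - m[nrow(m), ]) < 1e-12)) {
      m <- m[-nrow(m), , drop = FALSE]   # drop explicit closure
    }
    m
  })
  for (k in seq_along(loops)) {
    m <- loops[[k]]
    if (nrow(m) < 3) {
      abort(sprintf("loop %d has fewer than 3 distinct vertices", k))
    }
    if (abs(shoelace_area(m)) <= 1e-12) {
      abort(sprintf("loop %d has zero enclosed area", k))
    }
    hit <- polygon_self_intersection(m)
    if (hit[1] != 0) {
      abort(sprintf("loop %d self-intersects (segments %d and %d)",
                    k, hit[1], hit[2]))
    }
  }
  xs <- unlist(lapply(loops, function(m) m[, 1]))
  extent <- max(xs) - min(xs)
  if (is.null(chord)) chord <- extent
  if (abs(extent - chord) > 1e-9 * chord) {
    abort(sprintf("x-extent (%.9g mm) does not match chord (%.9g mm)",
                  extent, chord))
  }
  structure(list(loops = loops, chord = chord, name = name),
            class = "wing_profile")
}

#' @export
print.wing_profile <- function(x, ...) {
  cat(sprintf("<wing_profile> %s: chord %.4g mm, %d loop(s), %d vertices, area %.4g mm^2\n",
              x$name, x$chord, length(x$loops),
              sum(vapply(x$loops, nrow, 1L)), profile_area(x)))
  invisible(x)
}

# signed shoelace area of an open-stored loop (mm^2)
shoelace_area <- function(m) {
  x <- m[, 1]; y <- m[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  sum(x * y2 - x2 * y) / 2
}

#' Total enclosed area of a profile in mm^2
#' @param p a `wing_profile`.
#' @export
profile_area <- function(p) sum(vapply(p$loops, function(m) abs(shoelace_area(m)), 1))

# Shared builder: closed section from camber and half-thickness functions of
# chordwise position s in [0, chord] (mm). The membrane surfaces are offset
# from the camber line along its local normal (the physically meaningful
# thickness direction); semicircular end caps close the section, with radii
# equal to the local half-thickness. Callers must keep the camber slope ~0
# near the ends so the caps meet the surfaces cleanly. Output is a single
# counter-clockwise loop centred so that mid-chord is at x = 0. Returns the
# raw loop when validate = FALSE (used to diagnose self-intersection).
section_from_surfaces <- function(chord, camber, halfth, n = 320,
                                  name = "section", camber_slope = NULL,
                                  validate = TRUE) {
  rl <- halfth(0); rr <- halfth(chord)
  if (rl <= 0 || rr <= 0) abort("half-thickness must be positive at the ends")
  xl <- rl; xr <- chord - rr
  if (xr <= xl) abort("thickness too large for the chord")
  ns <- max(8L, ceiling(n * 0.4))
  ncap <- 2L * max(4L, ceiling(n * 0.05)) + 1L   # odd: cap apex hit exactly
  xs <- seq(xl, xr, length.out = ns)
  zp <- if (is.null(camber_slope)) rep(0, ns) else camber_slope(xs)
  den <- sqrt(1 + zp^2)
  nxv <- -zp / den; nyv <- 1 / den                # unit normal to the camber
  h <- halfth(xs); z <- camber(xs)
  lower <- cbind(xs - h * nxv, z - h * nyv)
  a1 <- seq(-pi / 2, pi / 2, length.out = ncap)[-c(1, ncap)]
  capr <- cbind(xr + rr * cos(a1), camber(xr) + rr * sin(a1))
  upper <- cbind(rev(xs + h * nxv), rev(z + h * nyv))
  a2 <- seq(pi / 2, 3 * pi / 2, length.out = ncap)[-c(1, ncap)]
  capl <- cbind(xl + rl * cos(a2), camber(xl) + rl * sin(a2))
  m <- rbind(lower, capr, upper, capl)
  m[, 1] <- m[, 1] - chord / 2
  if (!validate) return(m)
  wing_profile(m, chord = chord, name = name)
}

#' Flat-plate cross-section
#'
#' Rectangle of length `chord` and uniform thickness
#' `thickness_ratio * chord`, closed by semicircular end caps (the caps are
#' included in the chord length). This is the most common section in the
#' flapping-flight literature; thickness ratios of 0 to 0.03 are typical.
#'
#' @param chord chord length in mm.
#' @param thickness_ratio thickness as a fraction of chord, in (0, 1).
#' @param n approximate number of boundary points (>= 256 by default).
#' @export
make_flat_plate <- function(chord, thickness_ratio, n = 320) {
  if (!is.numeric(chord) || chord <= 0) abort("chord must be positive")
  if (!is.numeric(thickness_ratio) || thickness_ratio <= 0 || thickness_ratio >= 1)
    abort("thickness_ratio must be in (0, 1)")
  t2 <- thickness_ratio * chord / 2
  section_from_surfaces(chord, function(s) rep(0, length(s)),
                        function(s) rep(t2, length(s)), n = n,
                        name = sprintf("plate_%g", thickness_ratio))
}

#' Elliptical cross-section
#'
#' Ellipse with major axis `chord` and minor axis `thickness_ratio * chord`.
#'
#' @inheritParams make_flat_plate
#' @export
make_ellipse <- function(chord, thickness_ratio, n = 256) {
  if (!is.numeric(chord) || chord <= 0) abort("chord must be positive")
  if (!is.numeric(thickness_ratio) || thickness_ratio <= 0 || thickness_ratio > 1)
    abort("thickness_ratio must be in (0, 1]")
  n <- max(n, 128L)
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  m <- cbind(chord / 2 * cos(th), chord / 2 * thickness_ratio * sin(th))
  wing_profile(m, chord = chord, name = sprintf("ellipse_%g", thickness_ratio))
}

#' Corrugation parameters for the synthetic bee-like section
#'
#' Parametric stand-in for a corrugated insect wing cross-section: a thin
#' membrane whose camber line passes through `n_veins` corrugation nodes,
#' with a circular thickening (vein) at each node and an indentation at the
#' fore/hind wing interface. Defaults give eight veins with camber offsets
#' alternating +/-0.02 chord, a 0.0125c membrane and the interface notch at
#' 0.55c.
#'
#' @param n_veins number of vein nodes along the chord.
#' @param vein_amplitudes signed camber offsets at the nodes, as fractions of
#'   chord; each must lie within [-0.1, 0.1] so the section stays thin.
#' @param vein_radius vein thickening radius as a fraction of chord.
#' @param membrane_thickness membrane thickness as a fraction of chord.
#' @param notch_position chordwise location of the fore/hind interface
#'   indentation, as a fraction of chord in (0, 1).
#' @param notch_depth fraction of the local thickness removed at the notch.
#' @param jitter half-width of uniform random perturbation added to the
#'   amplitudes (fraction of chord); 0 disables randomness.
#' @param seed integer seed used when `jitter > 0`.
#' @export
corrugation_spec <- function(n_veins = 8,
                             vein_amplitudes = rep(c(0.02, -0.02), length.out = n_veins),
                             vein_radius = 0.025,
                             membrane_thickness = 0.0125,
                             notch_position = 0.55,
                             notch_depth = 0.5,
                             jitter = 0,
                             seed = 1L) {
  if (n_veins < 1) abort("n_veins must be at least 1")
  if (length(vein_amplitudes) != n_veins)
    abort("vein_amplitudes must have length n_veins")
  if (any(abs(vein_amplitudes) > 0.1))
    abort("vein amplitudes are bounded by 0.1 chord; profiles stay thin")
  if (membrane_thickness <= 0) abort("membrane_thickness must be positive")
  if (notch_position <= 0 || notch_position >= 1)
    abort("notch_position must be inside (0, 1)")
  if (vein_radius < membrane_thickness / 2)
    abort("vein_radius must be at least half the membrane thickness")
  if (notch_depth < 0 || notch_depth >= 1)
    abort("notch_depth must be in [0, 1)")
  structure(list(n_veins = as.integer(n_veins),
                 vein_amplitudes = as.numeric(vein_amplitudes),
                 vein_radius = vein_radius,
                 membrane_thickness = membrane_thickness,
                 notch_position = notch_position,
                 notch_depth = notch_depth,
                 jitter = jitter, seed = as.integer(seed)),
            class = "corrugation_spec")
}

# smooth compact bump, 1 at s = 0, 0 for |s| >= 1
cos_bump <- function(s) ifelse(abs(s) < 1, cos(pi * s / 2)^2, 0)

#' Synthetic corrugated (bee-like) cross-section
#'
#' Builds a thin closed section whose camber line interpolates the vein-node
#' offsets of `spec` (natural cubic spline pinned to zero at both ends), with
#' a circular thickening at each node and an indentation at the fore/hind
#' interface. Thickness is measured vertically between the upper and lower
#' surfaces, which keeps the polygon simple whenever the thickness stays
#' positive; a violation raises an error naming the nearest vein node.
#' Deterministic for a fixed `seed`.
#'
#' @param chord chord length in mm.
#' @param spec a [corrugation_spec()].
#' @param n approximate number of boundary points.
#' @export
make_corrugated <- function(chord, spec = corrugation_spec(), n = 512) {
  stopifnot(inherits(spec, "corrugation_spec"))
  if (!is.numeric(chord) || chord <= 0) abort("chord must be positive")
  amps <- spec$vein_amplitudes
  if (spec$jitter > 0) {
    amps <- amps + with_fixed_seed(spec$seed,
      stats::runif(spec$n_veins, -spec$jitter, spec$jitter))
  }
  xk <- chord * seq_len(spec$n_veins) / (spec$n_veins + 1)
  tm2 <- spec$membrane_thickness * chord / 2
  # pin the camber (and its slope) to zero at both ends so the semicircular
  # caps meet the surfaces cleanly
  x_anchor <- c(0, tm2, xk, chord - tm2, chord)
  z_anchor <- c(0, 0, amps * chord, 0, 0)
  cam <- splinefun(x_anchor, z_anchor, method = "natural")
  rv <- spec$vein_radius * chord
  halfth <- function(s) {
    h <- rep(tm2, length(s))
    for (x0 in xk) h <- h + (rv - tm2) * cos_bump((s - x0) / rv)
    h
  }
  xn <- spec$notch_position * chord
  wn <- 0.03 * chord
  notch <- function(s) spec$notch_depth * cos_bump((s - xn) / wn)
  # the notch removes a fraction of the local thickness from the upper side
  camber_eff <- function(s) cam(s) - halfth(s) * notch(s)
  halfth_eff <- function(s) halfth(s) * (1 - notch(s))
  slope_eff <- function(s) cam(s, deriv = 1)
  loop <- section_from_surfaces(chord, camber_eff, halfth_eff, n = n,
                                camber_slope = slope_eff, validate = FALSE)
  hit <- polygon_self_intersection(loop)
  if (hit[1] != 0) {
    bad_x <- loop[hit[1], 1] + chord / 2
    node <- which.min(abs(xk - bad_x))
    abort(sprintf("corrugation amplitudes produce a self-intersecting boundary near vein node %d (x = %.3g mm)",
                  node, bad_x))
  }
  wing_profile(loop, chord = chord, name = "corrugated")
}

# run code with a fixed RNG seed, restoring the caller's RNG state
with_fixed_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Low-pass smooth a profile boundary
#'
#' Splits each loop into upper and lower surfaces at its extreme-x points,
#' resamples both on a common uniform chordwise grid, and removes surface
#' wavelengths shorter than `2 * window * chord` by cosine-transform
#' truncation. The operation is a projection, hence idempotent; the chord is
#' preserved exactly (x coordinates are untouched) and corrugation amplitude
#' is never increased. This derives the "approximate" smoothed section from
#' the corrugated one.
#'
#' @param p a `wing_profile`.
#' @param window smoothing scale as a fraction of chord, in (0, 1);
#'   boundary features narrower than about `window * chord` are removed.
#' @param n_resample number of chordwise samples per surface.
#' @export
smooth_profile <- function(p, window, n_resample = 256) {
  stopifnot(inherits(p, "wing_profile"))
  if (!is.numeric(window) || window <= 0 || window >= 1)
    abort("window must be a fraction of chord in (0, 1)")
  kmax <- max(1L, floor(1 / window))
  loops <- lapply(p$loops, function(m) {
    i_min <- which.min(m[, 1]); i_max <- which.max(m[, 1])
    idx <- seq_len(nrow(m))
    # walk the loop from the min-x vertex to the max-x vertex and back
    path <- c(idx[i_min:length(idx)], idx[seq_len(i_min - 1)], i_min)
    cut <- which(path == i_max)[1]
    chain1 <- m[path[1:cut], , drop = FALSE]
    chain2 <- m[path[cut:length(path)], , drop = FALSE]
    xs <- seq(m[i_min, 1], m[i_max, 1], length.out = n_resample)
    y1 <- approx(chain1[, 1], chain1[, 2], xout = xs, ties = mean)$y
    y2 <- approx(chain2[, 1], chain2[, 2], xout = xs, ties = mean)$y
    # camber in a cosine basis, half-thickness in a sine basis (zero at the
    # ends, so the two surfaces always meet in one vertex per end). Both
    # truncations are projections, making the smoother exactly idempotent.
    n <- n_resample
    zc <- (y1 + y2) / 2
    h <- (y1 - y2) / 2
    h[1] <- 0; h[n] <- 0
    zc <- dct_truncate(zc, kmax)
    h <- dst_truncate(h, kmax)
    rbind(cbind(xs, zc + h), cbind(rev(xs[-c(1, n)]),
                                   rev((zc - h)[-c(1, n)])))
  })
  wing_profile(loops, chord = p$chord, name = paste0(p$name, "_smoothed"))
}

# keep sine modes 1..kmax of a signal vanishing at both ends (DST via odd
# extension); the truncated series still vanishes at the ends exactly
dst_truncate <- function(h, kmax) {
  n <- length(h)
  m <- n - 1
  z <- c(h[1:m], -h[seq(n, 2)])          # odd extension, length 2m
  Z <- fft(z)
  keep <- rep(FALSE, 2 * m)
  ks <- seq_len(min(kmax, m - 1))
  keep[1 + ks] <- TRUE
  keep[2 * m + 1 - ks] <- TRUE
  Z[!keep] <- 0
  out <- Re(fft(Z, inverse = TRUE))[1:n] / (2 * m)
  out[1] <- 0; out[n] <- 0
  out
}

# keep cosine modes 0..kmax of a non-periodic signal (DCT via even extension)
dct_truncate <- function(y, kmax) {
  n <- length(y)
  ext <- c(y, rev(y))
  Y <- fft(ext)
  keep <- rep(FALSE, 2 * n)
  ks <- 0:min(kmax, n - 1)
  keep[1 + ks] <- TRUE
  keep[2 * n + 1 - ks[-1]] <- TRUE
  Y[!keep] <- 0
  Re(fft(Y, inverse = TRUE))[seq_len(n)] / (2 * n)
}

# closed-loop arc length
loop_length <- function(m) {
  d <- diff(rbind(m, m[1, , drop = FALSE]))
  sum(sqrt(rowSums(d^2)))
}

# resample a closed loop to n points uniform in arc length
resample_loop <- function(m, n) {
  mc <- rbind(m, m[1, , drop = FALSE])
  seg <- sqrt(rowSums(diff(mc)^2))
  s <- c(0, cumsum(seg))
  L <- s[length(s)]
  st <- seq(0, L, length.out = n + 1)[-(n + 1)]
  cbind(approx(s, mc[, 1], xout = st)$y, approx(s, mc[, 2], xout = st)$y)
}

# keep Fourier modes 0..kmax of a periodic signal
fourier_truncate <- function(x, kmax) {
  n <- length(x)
  X <- fft(x)
  keep <- rep(FALSE, n)
  keep[1] <- TRUE
  if (kmax >= 1) {
    ks <- seq_len(min(kmax, floor((n - 1) / 2)))
    keep[1 + ks] <- TRUE
    keep[n + 1 - ks] <- TRUE
  }
  X[!keep] <- 0
  Re(fft(X, inverse = TRUE)) / n
}

#' Rigid-body transform of a profile (rotation about mid-chord, then shift)
#'
#' @param p a `wing_profile`.
#' @param x,y translation in mm.
#' @param angle rotation in degrees, counter-clockwise.
#' @return list of transformed loop matrices (mm); not a validated profile.
#' @export
transform_profile <- function(p, x = 0, y = 0, angle = 0) {
  a <- angle * pi / 180
  R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  lapply(p$loops, function(m) {
    out <- m %*% t(R)
    out[, 1] <- out[, 1] + x
    out[, 2] <- out[, 2] + y
    out
  })
}

#' Rasterize a profile onto a Cartesian grid as a solid-fraction field
#'
#' Places the profile (rotation about mid-chord, then translation) and
#' evaluates a solid fraction in each cell from the signed distance to the
#' boundary, ramping linearly from 1 to 0 across a band of one cell centred
#' on the boundary (smoothed signed-distance convention). The grid-summed
#' solid fraction converges to the polygon area as the cell size shrinks.
#'
#' @param p a `wing_profile`.
#' @param placement list with `x`, `y` (mm) and `angle` (degrees).
#' @param grid list with `cell` (mm), `xlim`, `ylim` (mm, length-2 each).
#' @param eps smoothing half-width in mm; default half a cell.
#' @return matrix of solid fractions, rows indexing x, columns indexing y.
#' @export
rasterize <- function(p, placement = list(x = 0, y = 0, angle = 0),
                      grid, eps = NULL) {
  stopifnot(inherits(p, "wing_profile"))
  loops <- transform_profile(p, placement$x %||% 0, placement$y %||% 0,
                             placement$angle %||% 0)
  cell <- grid$cell
  if (is.null(cell) || cell <= 0) abort("grid$cell must be a positive cell size")
  if (is.null(eps)) eps <- cell / 2
  bb <- do.call(rbind, loops)
  if (min(bb[, 1]) < grid$xlim[1] || max(bb[, 1]) > grid$xlim[2] ||
      min(bb[, 2]) < grid$ylim[1] || max(bb[, 2]) > grid$ylim[2]) {
    abort("profile placement lies outside the grid extents")
  }
  nx <- round(diff(grid$xlim) / cell)
  ny <- round(diff(grid$ylim) / cell)
  polygon_chi(loops, grid$xlim[1] + cell / 2, cell, nx,
              grid$ylim[1] + cell / 2, cell, ny, eps)
}

#' Write a profile to a plain-text file
#'
#' Whitespace-delimited x y pairs in mm, loops separated by blank lines,
#' `#` comments, 9 significant digits.
#'
#' @param p a `wing_profile`.
#' @param path output file.
#' @export
save_profile <- function(p, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# wing profile: %s", p$name), con)
  writeLines(sprintf("# chord_mm %.9g", p$chord), con)
  for (k in seq_along(p$loops)) {
    if (k > 1) writeLines("", con)
    m <- p$loops[[k]]
    writeLines(sprintf("%.9g %.9g", m[, 1], m[, 2]), con)
  }
  invisible(path)
}

#' Read a profile from a plain-text file
#'
#' Inverse of [save_profile()]. Parse and validation failures report the
#' offending line number.
#'
#' @param path input file.
#' @param name optional label; defaults to the file name.
#' @export
load_profile <- function(path, name = NULL) {
  if (!file.exists(path)) abort(sprintf("cannot read profile file '%s'", path))
  raw <- readLines(path)
  loops <- list()
  cur <- list()
  cur_lines <- integer(0)
  flush_loop <- function() {
    if (length(cur) == 0) return()
    m <- do.call(rbind, cur)
    if (nrow(m) >= 2 && all(abs(m[1, ] - m[nrow(m), ]) < 1e-12))
      m <- m[-nrow(m), , drop = FALSE]
    if (nrow(m) < 3) {
      abort(sprintf("loop ending at line %d has fewer than 3 distinct points",
                    cur_lines[length(cur_lines)]))
    }
    hit <- polygon_self_intersection(m)
    if (hit[1] != 0) {
      abort(sprintf("loop ending at line %d self-intersects (segments %d and %d)",
                    cur_lines[length(cur_lines)], hit[1], hit[2]))
    }
    loops[[length(loops) + 1]] <<- m
    cur <<- list(); cur_lines <<- integer(0)
  }
  for (ln in seq_along(raw)) {
    s <- sub("#.*$", "", raw[ln])
    s <- trimws(s)
    if (s == "") { flush_loop(); next }
    vals <- suppressWarnings(as.numeric(strsplit(s, "[[:space:],]+")[[1]]))
    if (length(vals) != 2 || any(is.na(vals))) {
      abort(sprintf("line %d: expected two numeric columns, got '%s'", ln, raw[ln]))
    }
    cur[[length(cur) + 1]] <- vals
    cur_lines <- c(cur_lines, ln)
  }
  flush_loop()
  if (length(loops) == 0) abort("file contains no profile points")
  wing_profile(loops, name = name %||% basename(path))
}

#' Profile vertices as a tibble
#' @param x a `wing_profile`.
#' @param ... unused.
#' @export
tidy.wing_profile <- function(x, ...) {
  dplyr::bind_rows(lapply(seq_along(x$loops), function(k) {
    lp <- x$loops[[k]]
    tibble(loop = k, x = lp[, 1], y = lp[, 2])
  }))
}

#' @export
autoplot.wing_profile <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y, group = .data$loop)) +
    ggplot2::geom_polygon(fill = "grey70", colour = "grey20", linewidth = 0.3) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = object$name, x = "x (mm)", y = "y (mm)")
}
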