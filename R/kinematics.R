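# Prescribed rigid-body wing kinematics. The three angular amplitudes of the
# 3D wing stroke are reduced to a 2D motion of the cross-section: the pitch
# (incidence) angle stays angular while the other two rotations become x/y
# translations of the section at the span station r0. Convention (fixed so
# every narrated waypoint of the stroke is reproduced): pitch varies as
# sin(omega t), translations as cos(omega t + phi), so translational
# velocity vanishes at stroke reversal (tau = 0, 0.5) and peaks at
# mid-stroke (tau = 0.25).

#' Kinematics specification for a flapping wing section
#'
#' @param f flap frequency in Hz.
#' @param theta1A,theta2A,theta3A angular amplitudes in degrees: stroke
#'   (applied as x-translation), deviation (y-translation) and pitch.
#' @param phi1,phi2 phase shifts in radians for the x and y translations.
#' @param r0 pivot-to-section distance in mm (the span station whose motion
#'   the 2D section follows).
#' @param mode `"forward-flight"` for the bee kinematics (pitch about the
#'   horizontal chord), `"hover-validation"` for the hovering-plate case
#'   (stroke horizontal, plate near-vertical at reversal), or `"tow"` for a
#'   uniform translation at `tow_speed` in +x (used by the solver checks).
#' @param tow_speed constant translation speed in m/s (`"tow"` mode only).
#' @return an object of class `kinematics_spec`.
#' @examples
#' bee_kinematics(V_inf = 3)        # theta2A = 20 degrees at 3 m/s
#' validation_kinematics()
#' @export
kinematics_spec <- function(f, theta1A, theta2A, theta3A,
                            phi1 = 0, phi2 = 0, r0,
                            mode = c("forward-flight", "hover-validation",
                                     "tow"),
                            tow_speed = 0) {
  mode <- match.arg(mode)
  if (!is.numeric(f) || f <= 0) abort("flap frequency f must be positive")
  if (theta1A < 0 || theta2A < 0 || theta3A < 0) abort("amplitudes must be >= 0")
  if (theta1A > 180) abort("theta1A must not exceed 180 degrees")
  if (r0 <= 0) abort("pivot distance r0 must be positive")
  structure(list(f = f, theta1A = theta1A, theta2A = theta2A,
                 theta3A = theta3A, phi1 = phi1, phi2 = phi2,
                 r0 = r0, mode = mode, tow_speed = tow_speed),
            class = "kinematics_spec")
}

#' @export
print.kinematics_spec <- function(x, ...) {
  cat(sprintf("<kinematics_spec> %s: f=%g Hz, amplitudes %g/%g/%g deg, r0=%g mm\n",
              x$mode, x$f, x$theta1A, x$theta2A, x$theta3A, x$r0))
  invisible(x)
}

#' Bee forward-flight kinematics
#'
#' Frequency 150 Hz, stroke amplitude 110 degrees, pitch amplitude
#' 24 degrees, pivot distance 6.61 mm; the deviation amplitude depends on
#' flight speed via [theta2A_for_speed()].
#'
#' @param V_inf flight speed in m/s (1 to 5), used to look up theta2A.
#' @param theta2A override for the deviation amplitude in degrees.
#' @export
bee_kinematics <- function(V_inf = NULL, theta2A = NULL) {
  if (is.null(theta2A)) {
    theta2A <- if (is.null(V_inf)) 0 else theta2A_for_speed(V_inf)
  }
  kinematics_spec(f = 150, theta1A = 110, theta2A = theta2A, theta3A = 24,
                  r0 = 6.61, mode = "forward-flight")
}

#' Hovering-plate validation kinematics
#'
#' f = 0.25 Hz, r = 0.1625 m, theta1a = 23.5 deg, theta2a = 0, theta3a =
#' 45 deg, phi1 = pi/2, phi2 = 0. The pi/2 phase is the 90-degree
#' pitch-translation offset of normal hovering: translation follows
#' cos(omega t) while the pitch from vertical follows sin(omega t).
#' @export
validation_kinematics <- function() {
  kinematics_spec(f = 0.25, theta1A = 23.5, theta2A = 0, theta3A = 45,
                  phi1 = pi / 2, phi2 = 0, r0 = 162.5,
                  mode = "hover-validation")
}

#' Static or uniformly towed wing
#'
#' Zero flapping; optionally a constant translation at `speed` m/s in +x.
#' Used for grid studies and the solver verification cases.
#' @param speed tow speed in m/s (0 = static wing).
#' @export
tow_kinematics <- function(speed = 0) {
  kinematics_spec(f = 1, theta1A = 0, theta2A = 0, theta3A = 0, r0 = 1,
                  mode = "tow", tow_speed = speed)
}

deg2rad <- function(x) x * pi / 180

#' Pitch angle of the wing section
#'
#' `theta3A * sin(omega t)` in degrees: zero incidence at stroke reversal,
#' maximum at mid-stroke. In hover-validation mode this is the plate's
#' inclination from vertical.
#'
#' @param t time in seconds (vectorized).
#' @param spec a [kinematics_spec()].
#' @export
pitch_angle <- function(t, spec) {
  stopifnot(inherits(spec, "kinematics_spec"))
  if (spec$mode == "tow") return(rep(0, length(t)))
  spec$theta3A * sin(2 * pi * spec$f * t)
}

#' Translation of the wing section
#'
#' x = r0 * theta1A\[rad\] * cos(omega t + phi1) and likewise for y with
#' theta2A, phi2 (hover-validation mode keeps the stroke on the x axis and
#' uses phase zero, the pitch already carrying the quarter-period offset).
#'
#' @inheritParams pitch_angle
#' @return tibble with columns `x`, `y` in mm.
#' @export
translation <- function(t, spec) {
  stopifnot(inherits(spec, "kinematics_spec"))
  w <- 2 * pi * spec$f
  if (spec$mode == "tow") {
    tibble(x = spec$tow_speed * t * 1000, y = rep(0, length(t)))
  } else if (spec$mode == "hover-validation") {
    tibble(x = spec$r0 * deg2rad(spec$theta1A) * cos(w * t),
           y = rep(0, length(t)))
  } else {
    # minus-cosine: the first half-stroke (tau 0-0.5, positive pitch) moves
    # the section in +x, pairing positive incidence with forward motion
    tibble(x = -spec$r0 * deg2rad(spec$theta1A) * cos(w * t + spec$phi1),
           y = -spec$r0 * deg2rad(spec$theta2A) * cos(w * t + spec$phi2))
  }
}

#' Analytic body velocities of the wing section
#'
#' Time derivatives of [translation()] and [pitch_angle()].
#'
#' @inheritParams pitch_angle
#' @return tibble with `vx`, `vy` in m/s and `omega3` (pitch rate, rad/s).
#' @export
body_velocity <- function(t, spec) {
  stopifnot(inherits(spec, "kinematics_spec"))
  if (spec$mode == "tow") {
    return(tibble(vx = rep(spec$tow_speed, length(t)),
                  vy = rep(0, length(t)), omega3 = rep(0, length(t))))
  }
  w <- 2 * pi * spec$f
  r0m <- spec$r0 / 1000
  if (spec$mode == "hover-validation") {
    vx <- -r0m * deg2rad(spec$theta1A) * w * sin(w * t)
    vy <- rep(0, length(t))
  } else {
    vx <- r0m * deg2rad(spec$theta1A) * w * sin(w * t + spec$phi1)
    vy <- r0m * deg2rad(spec$theta2A) * w * sin(w * t + spec$phi2)
  }
  tibble(vx = vx, vy = vy,
         omega3 = deg2rad(spec$theta3A) * w * cos(w * t))
}

#' Maximum translational speed of the wing over one flap cycle
#'
#' Closed form when the two translation axes share phase; otherwise a dense
#' sampling of one period (32768 samples). This is the reference speed used
#' to normalize force coefficients and in the Reynolds number.
#'
#' @param spec a [kinematics_spec()].
#' @return speed in m/s.
#' @export
v_kin_max <- function(spec) {
  stopifnot(inherits(spec, "kinematics_spec"))
  if (spec$mode == "tow") return(abs(spec$tow_speed))
  w <- 2 * pi * spec$f
  r0m <- spec$r0 / 1000
  a1 <- r0m * deg2rad(spec$theta1A) * w
  a2 <- if (spec$mode == "hover-validation") 0 else r0m * deg2rad(spec$theta2A) * w
  p1 <- if (spec$mode == "hover-validation") 0 else spec$phi1
  if (a2 == 0 || abs(sin(p1 - spec$phi2)) < 1e-12) {
    return(sqrt(a1^2 + a2^2) * 1)
  }
  tt <- seq(0, 1 / spec$f, length.out = 32768)
  v <- body_velocity(tt, spec)
  max(sqrt(v$vx^2 + v$vy^2))
}

#' Deviation amplitude theta2A as a function of flight speed
#'
#' Exact table values 10, 15, 20, 24, 26 degrees at 1-5 m/s, linearly
#' interpolated in between; speeds outside \[1, 5\] are an error.
#'
#' @param V_inf flight speed in m/s.
#' @export
theta2A_for_speed <- function(V_inf) {
  if (any(V_inf < 1 | V_inf > 5)) {
    abort("flight speed must be between 1 and 5 m/s for the theta2A table")
  }
  approx(1:5, c(10, 15, 20, 24, 26), xout = V_inf)$y
}

#' Reynolds number of a flapping case
#'
#' `rho * (V_kin + V_inf) * c / mu` with `V_kin = v_kin_max(spec)`.
#'
#' @param spec a [kinematics_spec()].
#' @param V_inf freestream speed in m/s.
#' @param rho fluid density in kg/m^3.
#' @param mu dynamic viscosity in Pa s.
#' @param chord chord in mm.
#' @export
reynolds_number <- function(spec, V_inf, rho, mu, chord) {
  if (mu <= 0 || rho <= 0) abort("fluid properties must be positive")
  rho * (v_kin_max(spec) + V_inf) * (chord / 1000) / mu
}

#' Sample the full wing motion at given times
#'
#' @inheritParams pitch_angle
#' @return tibble with `t`, `tau`, `x`, `y` (mm), `theta3` (deg), `vx`, `vy`
#'   (m/s), `omega3` (rad/s).
#' @export
wing_motion <- function(t, spec) {
  tr <- translation(t, spec)
  v <- body_velocity(t, spec)
  tibble(t = t, tau = spec$f * t, x = tr$x, y = tr$y,
         theta3 = pitch_angle(t, spec),
         vx = v$vx, vy = v$vy, omega3 = v$omega3)
}

#' Motion sample for the hovering validation case
#'
#' As [wing_motion()] but only defined for `mode = "hover-validation"`.
#'
#' @inheritParams pitch_angle
#' @export
validation_motion <- function(t, spec) {
  stopifnot(inherits(spec, "kinematics_spec"))
  if (spec$mode != "hover-validation") {
    abort("validation_motion requires a spec with mode 'hover-validation'")
  }
  wing_motion(t, spec)
}

# placement angle of the profile chord measured CCW from +x, degrees.
# Forward flight: the pitch angle itself. Hover validation: plate vertical
# at reversal, inclined by theta3 from vertical at mid-stroke.
placement_angle <- function(t, spec) {
  th <- pitch_angle(t, spec)
  if (spec$mode == "hover-validation") 90 + th else th
}

#' Export a sampled motion trace to CSV
#'
#' @param spec a [kinematics_spec()].
#' @param path output CSV.
#' @param cycles number of flap cycles to sample.
#' @param n samples per cycle.
#' @export
write_motion_trace <- function(spec, path, cycles = 1, n = 400) {
  tt <- seq(0, cycles / spec$f, length.out = cycles * n + 1)
  write.csv(wing_motion(tt, spec), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
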