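# Aerodynamic force extraction and normalization. The penalization term is
# itself the momentum exchanged with the body, so the force on the wing is
# the volume integral rho * chi/eta * (u - u_body) over the domain, per unit
# span. Sign convention: +x is the flight direction (opposite the
# freestream), +y is up.

#' Penalization force on the wing
#'
#' `F = rho * sum(chi/eta * (u - u_body)) * dA` evaluated on the face-centred
#' solid fractions stored in a stepped `flow_state` (the reaction on the
#' body, N per metre span). States that have not been advanced through the
#' penalization (no wing present) give zero force.
#'
#' @param state a `flow_state` returned by [step_flow()].
#' @param case the [flight_case()] that produced it.
#' @return named numeric `c(Fx, Fy)` in N/m.
#' @export
body_force <- function(state, case) {
  if (is.null(state$chiu) || is.null(state$body)) {
    return(c(Fx = 0, Fy = 0))
  }
  b <- state$body
  g <- state$grid
  yu <- matrix((seq_len(g$ny) - 0.5) * g$dy, g$nx + 1, g$ny, byrow = TRUE)
  ubody <- b$vx - b$omega * (yu - b$yc)
  xv <- matrix((seq_len(g$nx) - 0.5) * g$dx, g$nx, g$ny + 1)
  vbody <- b$vy + b$omega * (xv - b$xc)
  rho <- case$fluid$rho
  dA <- g$dx * g$dy
  c(Fx = rho * dA / b$eta * sum(state$chiu * (state$u - ubody)),
    Fy = rho * dA / b$eta * sum(state$chiv * (state$v - vbody)))
}

#' Lift and drag coefficients from forces
#'
#' `CL = Fy / (0.5 rho V_mag^2 A)` and, in the forward-flight convention,
#' `CD = Fx / (0.5 rho V_mag^2 A)` so that positive CD means net thrust and
#' negative CD a drag-dominated horizontal force. The resistive convention
#' (hovering validation) instead reports the force component opposing the
#' instantaneous translation, sign-folded per half-stroke, so cycle-averaged
#' drag is positive.
#'
#' @param Fx,Fy force per unit span in N/m.
#' @param rho fluid density kg/m^3.
#' @param V_mag reference speed in m/s (the wing's maximum translational
#'   speed, or the freestream in the static grid-study mode).
#' @param A reference area per unit span (chord, m).
#' @param convention `"forward"` or `"resistive"`.
#' @param translation_dir direction of the instantaneous wing translation
#'   (any length; normalized internally), required for `"resistive"`.
#' @return tibble with `CL`, `CD`.
#' @export
force_coefficients <- function(Fx, Fy, rho, V_mag, A,
                               convention = c("forward", "resistive"),
                               translation_dir = NULL) {
  convention <- match.arg(convention)
  if (V_mag <= 0) abort("V_mag must be positive")
  if (A <= 0) abort("reference area must be positive")
  q <- 0.5 * rho * V_mag^2 * A
  CL <- Fy / q
  if (convention == "forward") {
    CD <- Fx / q
  } else {
    if (is.null(translation_dir)) {
      abort("resistive convention needs the instantaneous translation direction")
    }
    nrm <- sqrt(sum(translation_dir^2))
    s <- if (nrm > 0) translation_dir / nrm else c(0, 0)
    CD <- -(Fx * s[1] + Fy * s[2]) / q
  }
  tibble(CL = CL, CD = CD)
}

#' Recompute coefficients of a force record under either convention
#'
#' Utility over a force CSV/tibble with columns `Fx`, `Fy` (and `vx`, `vy`
#' or `t` for the resistive convention).
#'
#' @param data tibble or data frame of per-step forces.
#' @param rho,V_mag,A as in [force_coefficients()].
#' @param convention `"forward"` or `"resistive"`.
#' @param kin a [kinematics_spec()], used to reconstruct the translation
#'   direction from `t` when `vx`/`vy` are absent.
#' @return the input with `CL`, `CD` columns replaced.
#' @export
recompute_coefficients <- function(data, rho, V_mag, A,
                                   convention = c("forward", "resistive"),
                                   kin = NULL) {
  convention <- match.arg(convention)
  q <- 0.5 * rho * V_mag^2 * A
  out <- tibble::as_tibble(data)
  out$CL <- out$Fy / q
  if (convention == "forward") {
    out$CD <- out$Fx / q
  } else {
    if (!all(c("vx", "vy") %in% names(out))) {
      if (is.null(kin)) abort("need vx/vy columns or a kinematics spec")
      v <- body_velocity(out$t, kin)
      out$vx <- v$vx; out$vy <- v$vy
    }
    nrm <- sqrt(out$vx^2 + out$vy^2)
    sx <- ifelse(nrm > 0, out$vx / nrm, 0)
    sy <- ifelse(nrm > 0, out$vy / nrm, 0)
    out$CD <- -(out$Fx * sx + out$Fy * sy) / q
  }
  out
}
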