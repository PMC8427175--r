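# Free-floating two-segment dynamics.
#
# The animal is a free-floating pair of rigid bodies (body = torso + legs,
# tail = cone) joined by a 2-degree-of-freedom pin-joint pair at the vent.
# No net external force acts; translation of the system COM is decoupled
# and ignored. The rotational equations are written in the momentum form of
# the Euler-Poincare equations for a shape-changing free body:
#
#   dL/dt      = tau_external            (inertial frame, about system COM)
#   omega_body = Mww(q)^-1 (L_body - Mwq(q) qdot)
#
# so conservation of angular momentum with aerodynamics off is structural,
# and any prescribed (kinematic) tail trajectory needs only the body
# orientation quaternion and L as states. Torque-driven joints add the
# shape momenta p_q with dp_q/dt = dT/dq + tau_joint.
#
# External aerodynamic restoring torques act on body pitch (alpha) and roll
# (beta) as damped torsion springs, -(C1*angle + C2*rate), applied as
# generalized forces conjugate to the Z-Y-X Euler angles so that yaw is
# exactly unconstrained.

JOINT_AXES <- list(roll = c(1, 0, 0), pitch = c(0, 1, 0), yaw = c(0, 0, 1))

#' Aerodynamic restoring-torque parameters
#'
#' Linear torsion spring + damper on body pitch and roll, representing the
#' aerodynamic torques that keep a stable glider at its equilibrium
#' orientation (zero pitch and roll); yaw is left unconstrained. The
#' applied torque opposes displacement and rate: with both angles and rates
#' zero the torque vanishes.
#'
#' @param C1 spring constant, N m / rad (>= 0).
#' @param C2 damping constant, N m s / rad (>= 0).
#' @param enabled logical; `FALSE` turns the external torque off entirely.
#' @return an object of class `aero_spring_params`.
#' @seealso [default_aero_params()]
#' @export
aero_spring_params <- function(C1 = 0, C2 = 0, enabled = TRUE) {
  stopifnot(is.finite(C1), is.finite(C2), C1 >= 0, C2 >= 0)
  structure(list(C1 = C1, C2 = C2, enabled = isTRUE(enabled)),
            class = "aero_spring_params")
}

#' Default aerodynamic spring constants for a morphology
#'
#' Chooses `C1`, `C2` so that the linearized pitch mode of the assembled
#' animal (tail at neutral) is underdamped with the given oscillation
#' period and damping ratio. The defaults (0.5 s, 0.3) give an
#' order-of-magnitude representation of the short-period pitch oscillation
#' of a ~3 g glider.
#'
#' @param morph a `gecko_morphology`.
#' @param period damped oscillation period, s.
#' @param damping_ratio dimensionless damping ratio in (0, 1).
#' @return an `aero_spring_params`.
#' @export
default_aero_params <- function(morph, period = 0.5, damping_ratio = 0.3) {
  par <- dyn_params(morph, c("pitch", "roll"))
  Ip <- dyn_geometry(c(0, 0), par)$Mww[2, 2]
  wd <- 2 * pi / period
  wn <- wd / sqrt(1 - damping_ratio^2)
  aero_spring_params(C1 = Ip * wn^2, C2 = 2 * damping_ratio * wn * Ip)
}

#' Body orientation state
#'
#' @param quat unit quaternion c(w, x, y, z), body -> inertial.
#' @param omega body-frame angular velocity, rad/s.
#' @return object of class `body_state`.
#' @export
body_state <- function(quat = c(1, 0, 0, 0), omega = c(0, 0, 0)) {
  quat <- as.numeric(quat); omega <- as.numeric(omega)
  stopifnot(length(quat) == 4, length(omega) == 3,
            abs(sum(quat^2) - 1) < 1e-6)
  structure(list(quat = quat_normalize(quat), omega = omega),
            class = "body_state")
}

#' Tail joint state
#'
#' @param q 2-vector of joint angles, rad.
#' @param qd 2-vector of joint rates, rad/s.
#' @return object of class `joint_state`.
#' @export
joint_state <- function(q = c(0, 0), qd = c(0, 0)) {
  structure(list(q = as.numeric(q), qd = as.numeric(qd)),
            class = "joint_state")
}

resolve_axes <- function(axes) {
  axes <- match.arg(axes, names(JOINT_AXES), several.ok = TRUE)
  if (length(axes) != 2L || axes[1] == axes[2]) {
    stop("joint axes must be two distinct of 'roll', 'pitch', 'yaw'",
         call. = FALSE)
  }
  axes
}

# Precompute constant dynamic parameters for a morphology + joint axes.
dyn_params <- function(morph, axes = c("yaw", "pitch")) {
  stopifnot(inherits(morph, "gecko_morphology"))
  axes <- resolve_axes(axes)
  is_tail <- vapply(morph$segments, function(s) s$name == "tail", logical(1))
  body <- compose_mass_properties(morph$segments[!is_tail])
  tail_spec <- morph$segments[is_tail][[1]]
  tp <- segment_mass_properties(tail_spec)
  R0 <- tail_spec$orientation      # cone axis (+x, base->tip) -> caudal (-x)
  list(m1 = body$mass, I1 = body$inertia,
       m2 = tp$mass,
       I2 = R0 %*% tp$inertia %*% t(R0),
       d2 = as.numeric(R0 %*% tp$com),   # tail COM in joint frame at q = 0
       pj = -body$com,                   # joint position relative to body COM
       mu = body$mass * tp$mass / (body$mass + tp$mass),
       Mtot = body$mass + tp$mass,
       a1 = JOINT_AXES[[axes[1]]], a2 = JOINT_AXES[[axes[2]]],
       axes = axes)
}

# Configuration-dependent geometry and mass-matrix blocks, body frame.
dyn_geometry <- function(q, par) {
  R1a <- rot_axis_angle(par$a1, q[1])
  R2a <- rot_axis_angle(par$a2, q[2])
  Rj <- R1a %*% R2a
  Rjd2 <- as.numeric(Rj %*% par$d2)
  s <- par$pj + Rjd2
  Jv <- cbind(cross3(par$a1, Rjd2),
              as.numeric(R1a %*% cross3(par$a2, as.numeric(R2a %*% par$d2))))
  Gw <- t(Rj)
  Gq <- cbind(as.numeric(t(R2a) %*% par$a1), par$a2)
  K <- skew3(s)
  I2Gw <- par$I2 %*% Gw
  Mww <- par$I1 + t(Gw) %*% I2Gw + par$mu * crossprod(K)
  Mwq <- par$mu * (K %*% Jv) + t(Gw) %*% (par$I2 %*% Gq)
  Mqq <- par$mu * crossprod(Jv) + t(Gq) %*% (par$I2 %*% Gq)
  list(Rj = Rj, s = s, Jv = Jv, Gw = Gw, Gq = Gq,
       Mww = Mww, Mwq = Mwq, Mqq = Mqq)
}

kinetic_energy <- function(geom, omega, qd) {
  0.5 * (sum(omega * (geom$Mww %*% omega)) +
         2 * sum(omega * (geom$Mwq %*% qd)) +
         sum(qd * (geom$Mqq %*% qd)))
}

#' Total angular momentum about the instantaneous system COM
#'
#' Sums the two segments' momenta (orbital terms about the system COM plus
#' each segment's spin term), expressed in the inertial frame. This is the
#' bookkeeping quantity that a free-floating maneuver with aerodynamics off
#' must conserve.
#'
#' @param morph a `gecko_morphology`.
#' @param state a [body_state()].
#' @param joint a [joint_state()].
#' @param axes joint axis pair, e.g. `c("yaw", "pitch")`.
#' @return 3-vector, kg m^2 / s, inertial frame.
#' @export
angular_momentum <- function(morph, state, joint, axes = c("yaw", "pitch")) {
  par <- dyn_params(morph, axes)
  g <- dyn_geometry(joint$q, par)
  omega <- state$omega
  w <- cross3(omega, g$s) + as.numeric(g$Jv %*% joint$qd)
  omega2 <- as.numeric(g$Gw %*% omega + g$Gq %*% joint$qd)
  Lb <- par$mu * cross3(g$s, w) +
    as.numeric(par$I1 %*% omega) +
    as.numeric(g$Rj %*% (par$I2 %*% omega2))
  as.numeric(quat_to_rot(state$quat) %*% Lb)
}

#' Aerodynamic restoring torque on the body
#'
#' Evaluates the pitch/roll spring-damper torque for a body state. The
#' torque is built as generalized forces `-(C1*alpha + C2*alpha_dot)` on
#' pitch and `-(C1*beta + C2*beta_dot)` on roll (Z-Y-X Euler angles) and
#' mapped to a body-frame torque vector; its component about the inertial
#' yaw (z) axis is identically zero, leaving yaw unconstrained.
#'
#' @param state a [body_state()].
#' @param params an [aero_spring_params()].
#' @return body-frame torque 3-vector, N m.
#' @export
external_torque <- function(state, params) {
  stopifnot(inherits(state, "body_state"),
            inherits(params, "aero_spring_params"))
  if (!params$enabled || (params$C1 == 0 && params$C2 == 0)) {
    return(c(0, 0, 0))
  }
  eul <- quat_to_euler_zyx(state$quat)
  rates <- euler_rates_from_omega(eul[2], eul[3], state$omega)
  Q <- c(0,
         -(params$C1 * eul[2] + params$C2 * rates[2]),
         -(params$C1 * eul[3] + params$C2 * rates[3]))
  E <- euler_rate_matrix(eul[2], eul[3])
  as.numeric(solve(t(E), Q))
}

aero_torque_raw <- function(quat, omega, params) {
  external_torque(structure(list(quat = quat, omega = omega),
                            class = "body_state"), params)
}

spring_potential <- function(quat, params) {
  if (!params$enabled) return(0)
  eul <- quat_to_euler_zyx(quat)
  0.5 * params$C1 * (eul[2]^2 + eul[3]^2)
}

#' Joint drive specifications
#'
#' A kinematic drive prescribes the tail joint trajectory `q(t)`, `qdot(t)`
#' directly (the joint constraint torques are implicit); a torque drive
#' applies a joint torque program and integrates the joint angles as
#' states.
#'
#' @param q_fun function of time returning the 2-vector of joint angles,
#'   rad.
#' @param qd_fun function of time returning joint rates, rad/s (required;
#'   kept explicit so drives are exact, not numerically differentiated).
#' @param axes joint axis pair (two of `"roll"`, `"pitch"`, `"yaw"`); the
#'   first axis rotation is applied outermost.
#' @param spline optional list of natural-spline coefficient tables (one
#'   per axis, from [natural_spline_coefs()]) enabling the compiled
#'   integrator.
#' @return an object of class `joint_drive`.
#' @export
kinematic_drive <- function(q_fun, qd_fun, axes = c("yaw", "pitch"),
                            spline = NULL) {
  structure(list(mode = "kinematic", q_fun = q_fun, qd_fun = qd_fun,
                 axes = resolve_axes(axes), spline = spline),
            class = "joint_drive")
}

#' @rdname kinematic_drive
#' @param tau_fun function of time returning the 2-vector of joint torques,
#'   N m.
#' @param q0,qd0 initial joint angles (rad) and rates (rad/s).
#' @export
torque_drive <- function(tau_fun, axes = c("yaw", "pitch"),
                         q0 = c(0, 0), qd0 = c(0, 0)) {
  structure(list(mode = "torque", tau_fun = tau_fun,
                 axes = resolve_axes(axes),
                 q0 = as.numeric(q0), qd0 = as.numeric(qd0)),
            class = "joint_drive")
}

#' Simulation configuration
#'
#' @param duration simulated time, s.
#' @param dt_out output sampling interval, s.
#' @param rtol,atol integrator tolerances.
#' @param engine `"compiled"` (Dormand-Prince RK45 in C++; used for
#'   kinematic drives that carry spline coefficients) or `"reference"`
#'   (deSolve). Torque drives always use the reference integrator.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(duration = 1, dt_out = 0.002,
                       rtol = 1e-9, atol = 1e-12,
                       engine = c("compiled", "reference")) {
  stopifnot(duration > 0, dt_out > 0)
  structure(list(duration = duration, dt_out = dt_out,
                 rtol = rtol, atol = atol,
                 engine = match.arg(engine)),
            class = "sim_config")
}

#' Simulate a free-floating tail maneuver
#'
#' Integrates the coupled body + tail rotational dynamics. With
#' aerodynamics disabled the total angular momentum about the system COM is
#' conserved; with the pitch/roll springs enabled it evolves by the
#' external torque only.
#'
#' @param morph a `gecko_morphology`.
#' @param drive a [kinematic_drive()] or [torque_drive()].
#' @param config a [sim_config()].
#' @param aero an [aero_spring_params()]; default disabled.
#' @param state0 initial [body_state()].
#' @return a `sim_result` data frame with one row per output time: the body
#'   quaternion, Z-Y-X Euler angles (deg), joint angles (deg) and rates
#'   (rad/s), body angular velocity (rad/s, body frame) and the system
#'   angular momentum (inertial frame) recomputed from the sampled states.
#' @export
#' @examples
#' g <- build_default_gecko()
#' drv <- kinematic_drive(function(t) c(pi * sin(pi * t / 0.5)^2 * (t < 0.5), 0),
#'                        function(t) c(2 * pi^2 / 0.5 * sin(pi * t / 0.5) *
#'                                      cos(pi * t / 0.5) * (t < 0.5), 0))
#' res <- simulate_maneuver(g, drv, sim_config(duration = 0.6, engine = "reference"))
#' res[nrow(res), "yaw_deg"]
simulate_maneuver <- function(morph, drive, config = sim_config(),
                              aero = aero_spring_params(enabled = FALSE),
                              state0 = body_state()) {
  stopifnot(inherits(drive, "joint_drive"), inherits(config, "sim_config"))
  par <- dyn_params(morph, drive$axes)
  times <- seq(0, config$duration, by = config$dt_out)
  if (drive$mode == "kinematic") {
    use_compiled <- config$engine == "compiled" && !is.null(drive$spline)
    raw <- if (use_compiled) {
      sim_kinematic_compiled(par, drive, config, aero, state0, times)
    } else {
      sim_kinematic_reference(par, drive, config, aero, state0, times)
    }
  } else {
    raw <- sim_torque_reference(par, drive, config, aero, state0, times)
  }
  finish_sim_result(morph, drive, par, times, raw)
}

# ---- kinematic drive, reference integrator (deSolve) ----

sim_kinematic_reference <- function(par, drive, config, aero, state0, times) {
  g0 <- dyn_geometry(drive$q_fun(0), par)
  Lb0 <- as.numeric(g0$Mww %*% state0$omega + g0$Mwq %*% drive$qd_fun(0))
  y0 <- c(state0$quat, as.numeric(quat_to_rot(state0$quat) %*% Lb0))
  rhs <- function(t, y, p) {
    quat <- quat_normalize(y[1:4])
    q <- drive$q_fun(t); qd <- drive$qd_fun(t)
    g <- dyn_geometry(q, par)
    R1 <- quat_to_rot(quat)
    Lb <- as.numeric(t(R1) %*% y[5:7])
    omega <- solve(g$Mww, Lb - as.numeric(g$Mwq %*% qd))
    tau <- if (aero$enabled) aero_torque_raw(quat, omega, aero) else c(0, 0, 0)
    list(c(quat_derivative(quat, omega), as.numeric(R1 %*% tau)))
  }
  sol <- deSolve::ode(y0, times, rhs, NULL, method = "lsoda",
                      rtol = config$rtol, atol = config$atol)
  check_integration(sol, times)
  ys <- unname(sol[, -1, drop = FALSE])
  qs <- t(vapply(times, drive$q_fun, numeric(2)))
  qds <- t(vapply(times, drive$qd_fun, numeric(2)))
  omegas <- matrix(0, length(times), 3)
  for (i in seq_along(times)) {
    quat <- quat_normalize(ys[i, 1:4]); ys[i, 1:4] <- quat
    g <- dyn_geometry(qs[i, ], par)
    Lb <- as.numeric(t(quat_to_rot(quat)) %*% ys[i, 5:7])
    omegas[i, ] <- solve(g$Mww, Lb - as.numeric(g$Mwq %*% qds[i, ]))
  }
  list(quat = ys[, 1:4, drop = FALSE], omega = omegas, q = qs, qd = qds)
}

# ---- kinematic drive, compiled integrator ----

sim_kinematic_compiled <- function(par, drive, config, aero, state0, times) {
  g0 <- dyn_geometry(drive$q_fun(0), par)
  Lb0 <- as.numeric(g0$Mww %*% state0$omega + g0$Mwq %*% drive$qd_fun(0))
  Lw0 <- as.numeric(quat_to_rot(state0$quat) %*% Lb0)
  out <- sim_kinematic_cpp(
    par$m1, par$I1, par$m2, par$I2, par$d2, par$pj, par$mu,
    par$a1, par$a2,
    drive$spline[[1]]$knots, drive$spline[[1]]$coef,
    drive$spline[[2]]$knots, drive$spline[[2]]$coef,
    state0$quat, Lw0, times,
    aero$enabled, aero$C1, aero$C2,
    config$rtol, config$atol)
  if (any(!is.finite(out))) {
    stop("integration produced non-finite state", call. = FALSE)
  }
  list(quat = out[, 1:4, drop = FALSE], omega = out[, 5:7, drop = FALSE],
       q = out[, 8:9, drop = FALSE], qd = out[, 10:11, drop = FALSE])
}

# ---- torque drive, reference integrator ----

sim_torque_reference <- function(par, drive, config, aero, state0, times) {
  g0 <- dyn_geometry(drive$q0, par)
  Lb0 <- as.numeric(g0$Mww %*% state0$omega + g0$Mwq %*% drive$qd0)
  pq0 <- as.numeric(t(g0$Mwq) %*% state0$omega + g0$Mqq %*% drive$qd0)
  y0 <- c(state0$quat, drive$q0, Lb0, pq0)
  h <- 1e-6
  rhs <- function(t, y, p) {
    quat <- quat_normalize(y[1:4]); q <- y[5:6]
    Lb <- y[7:9]; pq <- y[10:11]
    g <- dyn_geometry(q, par)
    M <- rbind(cbind(g$Mww, g$Mwq), cbind(t(g$Mwq), g$Mqq))
    u <- solve(M, c(Lb, pq))
    omega <- u[1:3]; qd <- u[4:5]
    dTdq <- numeric(2)
    for (i in 1:2) {
      qp <- q; qp[i] <- qp[i] + h
      qm <- q; qm[i] <- qm[i] - h
      dTdq[i] <- (kinetic_energy(dyn_geometry(qp, par), omega, qd) -
                  kinetic_energy(dyn_geometry(qm, par), omega, qd)) / (2 * h)
    }
    tau_a <- if (aero$enabled) aero_torque_raw(quat, omega, aero) else c(0, 0, 0)
    list(c(quat_derivative(quat, omega),
           qd,
           -cross3(omega, Lb) + tau_a,
           dTdq + drive$tau_fun(t)))
  }
  sol <- deSolve::ode(y0, times, rhs, NULL, method = "lsoda",
                      rtol = config$rtol, atol = config$atol)
  check_integration(sol, times)
  ys <- unname(sol[, -1, drop = FALSE])
  omegas <- matrix(0, length(times), 3)
  qds <- matrix(0, length(times), 2)
  for (i in seq_along(times)) {
    quat <- quat_normalize(ys[i, 1:4]); ys[i, 1:4] <- quat
    g <- dyn_geometry(ys[i, 5:6], par)
    M <- rbind(cbind(g$Mww, g$Mwq), cbind(t(g$Mwq), g$Mqq))
    u <- solve(M, ys[i, 7:11])
    omegas[i, ] <- u[1:3]; qds[i, ] <- u[4:5]
  }
  list(quat = ys[, 1:4, drop = FALSE], omega = omegas,
       q = ys[, 5:6, drop = FALSE], qd = qds)
}

check_integration <- function(sol, times) {
  if (nrow(sol) < length(times) || any(!is.finite(sol))) {
    t_fail <- if (nrow(sol) > 0) sol[nrow(sol), 1] else NA_real_
    stop(sprintf("integrator failed near t = %.4g s", t_fail), call. = FALSE)
  }
}

finish_sim_result <- function(morph, drive, par, times, raw) {
  n <- length(times)
  eul <- t(apply(raw$quat, 1, quat_to_euler_zyx))
  L <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    st <- structure(list(quat = raw$quat[i, ], omega = raw$omega[i, ]),
                    class = "body_state")
    js <- structure(list(q = raw$q[i, ], qd = raw$qd[i, ]),
                    class = "joint_state")
    L[i, ] <- angular_momentum(morph, st, js, drive$axes)
  }
  out <- data.frame(
    time = times,
    qw = raw$quat[, 1], qx = raw$quat[, 2],
    qy = raw$quat[, 3], qz = raw$quat[, 4],
    yaw_deg = rad2deg(unwrap_angle(eul[, 1])),
    pitch_deg = rad2deg(eul[, 2]),
    roll_deg = rad2deg(unwrap_angle(eul[, 3])),
    q1_deg = rad2deg(raw$q[, 1]), q2_deg = rad2deg(raw$q[, 2]),
    qd1 = raw$qd[, 1], qd2 = raw$qd[, 2],
    wx = raw$omega[, 1], wy = raw$omega[, 2], wz = raw$omega[, 3],
    Lx = L[, 1], Ly = L[, 2], Lz = L[, 3])
  attr(out, "axes") <- drive$axes
  attr(out, "mode") <- drive$mode
  class(out) <- c("sim_result", "data.frame")
  out
}

#' Export a simulation result
#'
#' Writes the time series as tidy CSV and a JSON sidecar with metadata
#' (joint axes, drive mode, package version, and any extra fields given).
#'
#' @param result a `sim_result` from [simulate_maneuver()].
#' @param path output CSV path; metadata goes to `<path>.json`.
#' @param meta named list of extra metadata (e.g. seed, config echo).
#' @return invisibly, `path`.
#' @export
export_sim_result <- function(result, path, meta = list()) {
  stopifnot(inherits(result, "sim_result"))
  write.csv(as.data.frame(result), path, row.names = FALSE)
  meta <- c(list(axes = attr(result, "axes"), mode = attr(result, "mode"),
                 package_version = as.character(packageVersion("tailspin"))),
            meta)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
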