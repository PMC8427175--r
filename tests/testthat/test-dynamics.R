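g_default <- build_default_gecko()

test_that("a stationary tail with zero rates leaves the body orientation constant", {
  drv <- kinematic_drive(function(t) c(0.4, -0.2), function(t) c(0, 0))
  res <- simulate_maneuver(g_default, drv,
                           sim_config(duration = 0.5, engine = "reference"))
  expect_close(res$yaw_deg, 0, 1e-9)
  expect_close(res$pitch_deg, 0, 1e-9)
  expect_close(res$roll_deg, 0, 1e-9)
})

test_that("a planar 180-degree tail yaw swing turns the body the opposite way", {
  span <- 0.4
  phi <- function(t) ifelse(t < span, pi * (1 - cos(pi * t / span)) / 2, pi)
  phid <- function(t) ifelse(t < span, pi^2 / (2 * span) * sin(pi * t / span), 0)
  drv <- kinematic_drive(function(t) c(phi(t), 0), function(t) c(phid(t), 0),
                         axes = c("yaw", "pitch"))
  res <- simulate_maneuver(g_default, drv,
                           sim_config(duration = 0.5, engine = "reference"))
  final <- res$yaw_deg[nrow(res)]
  expect_lt(final, -1)                      # opposite sign to the +180 sweep
})

test_that("angular momentum matches a numerical-differentiation oracle", {
  set.seed(3)
  for (rep in 1:4) {
    m <- random_morphology()
    axes <- sample(c("yaw", "pitch", "roll"), 2)
    quat <- quat_normalize_pub(rnorm(4))
    omega <- rnorm(3)
    q <- runif(2, -pi, pi); qd <- rnorm(2)
    L_pkg <- angular_momentum(m, body_state(quat, omega),
                              joint_state(q, qd), axes)
    L_num <- numeric_angular_momentum(m, quat, omega, q, qd, axes)
    expect_close(L_pkg, L_num, 1e-6 * max(abs(L_num), 1e-9),
                 label = "angular momentum vs numeric oracle")
  }
})

test_that("angular momentum is zero at rest and the tail->0 limit is the rigid body", {
  expect_equal(angular_momentum(g_default, body_state(), joint_state()),
               c(0, 0, 0))
  tiny_tail <- gecko_morphology(svl = 0.05, tail_length_ratio = 1e-4,
                                total_mass = 3e-3,
                                tail_mass_fraction = 1e-6)
  omega <- c(0.2, -0.4, 1.1)
  L <- angular_momentum(tiny_tail, body_state(omega = omega), joint_state())
  par <- tailspin:::dyn_params(tiny_tail, c("yaw", "pitch"))
  expect_close(L, as.numeric(par$I1 %*% omega), 1e-4 * max(abs(L)))
})

test_that("momentum is conserved on random maneuvers with aerodynamics off", {
  set.seed(21)
  for (rep in 1:3) {
    m <- random_morphology()
    traj <- random_spline_trajectory()
    drv <- spline_from_points(traj)
    res <- simulate_maneuver(m, drv, sim_config(duration = 0.7))
    L <- as.matrix(res[, c("Lx", "Ly", "Lz")])
    # characteristic scale: whole-animal inertia x peak joint rate
    par <- tailspin:::dyn_params(m, drv$axes)
    scale <- max(abs(tailspin:::dyn_geometry(c(0, 0), par)$Mww)) *
      max(abs(as.matrix(res[, c("qd1", "qd2")])), 1)
    expect_lt(max(abs(L)), 1e-6 * scale)
  }
})

test_that("compiled and reference integrators agree", {
  traj <- collocation_trajectory(c(120, -40, 80), c(-60, 90, -30))
  drv <- spline_from_points(traj)
  for (aero in list(aero_spring_params(enabled = FALSE),
                    default_aero_params(g_default))) {
    r1 <- simulate_maneuver(g_default, drv,
                            sim_config(duration = 1, engine = "compiled"),
                            aero)
    r2 <- simulate_maneuver(g_default, drv,
                            sim_config(duration = 1, engine = "reference"),
                            aero)
    expect_close(r1$yaw_deg, r2$yaw_deg, 1e-5)
    expect_close(r1$pitch_deg, r2$pitch_deg, 1e-5)
  }
})

test_that("yaw-only drives in the 3D engine match the planar oracle to 0.1 degree", {
  span <- 0.35
  phi <- function(t) {
    ifelse(t < span, 2.5 * (1 - cos(pi * t / span)) / 2, 2.5)
  }
  phid <- function(t) {
    ifelse(t < span, 2.5 * pi / (2 * span) * sin(pi * t / span), 0)
  }
  drv <- kinematic_drive(function(t) c(phi(t), 0), function(t) c(phid(t), 0),
                         axes = c("yaw", "pitch"))
  res <- simulate_maneuver(g_default, drv,
                           sim_config(duration = 0.4, engine = "reference"))
  orc <- planar_oracle(g_default, phi, phid, t_end = 0.4)
  expect_lt(abs(res$yaw_deg[nrow(res)] - orc$theta_deg[nrow(orc)]), 0.1)
})

test_that("planar cyclic strokes yield no net rotation; figure-eights do, with odd symmetry", {
  # out-and-back along one axis: conservative, no net reorientation
  planar <- collocation_trajectory(c(0, 150, 0), c(0, 0, 0))
  res <- evaluate_trajectory(planar, g_default,
                             aero_spring_params(enabled = FALSE))
  expect_lt(abs(res$yaw), 0.1)
  expect_lt(abs(res$pitch), 0.1)
  expect_lt(abs(res$roll), 0.1)
  # two-axis stroke: nonzero net yaw (geometric phase); the sagittal mirror
  # (roll reversed, pitch kept) reverses the yaw
  fig8 <- collocation_trajectory(c(110, 0, -110), c(60, -80, 60))
  mirrored <- collocation_trajectory(c(110, 0, -110), -c(60, -80, 60))
  y1 <- evaluate_trajectory(fig8, g_default,
                            aero_spring_params(enabled = FALSE))$yaw
  y2 <- evaluate_trajectory(mirrored, g_default,
                            aero_spring_params(enabled = FALSE))$yaw
  expect_gt(abs(y1), 0.5)
  expect_equal(y2, -y1, tolerance = 1e-6)
})

test_that("the restoring torque vanishes at equilibrium and never acts about world yaw", {
  aero <- aero_spring_params(C1 = 2e-4, C2 = 3e-5)
  expect_equal(external_torque(body_state(), aero), c(0, 0, 0))
  off <- aero_spring_params(C1 = 2e-4, C2 = 3e-5, enabled = FALSE)
  set.seed(5)
  for (rep in 1:10) {
    st <- body_state(quat_normalize_pub(rnorm(4)), rnorm(3))
    expect_equal(external_torque(st, off), c(0, 0, 0))
    tau_b <- external_torque(st, aero)
    tau_w <- as.numeric(tailspin:::quat_to_rot(st$quat) %*% tau_b)
    expect_lt(abs(tau_w[3]), 1e-12 * max(abs(tau_w), 1e-12))
  }
})

test_that("a small pitch release rings down like the linearized damped oscillator", {
  aero <- default_aero_params(g_default, period = 0.5, damping_ratio = 0.3)
  a0 <- 0.05                                 # rad; small-angle regime
  q0 <- c(cos(a0 / 2), 0, sin(a0 / 2), 0)
  drv <- kinematic_drive(function(t) c(0, 0), function(t) c(0, 0),
                         axes = c("pitch", "roll"))
  res <- simulate_maneuver(g_default, drv,
                           sim_config(duration = 1.5, dt_out = 0.001,
                                      engine = "reference"),
                           aero, state0 = body_state(quat = q0))
  wd <- 2 * pi / 0.5
  wn <- wd / sqrt(1 - 0.3^2)
  zeta <- 0.3
  closed <- rad2deg_pub(a0 * exp(-zeta * wn * res$time) *
    (cos(wd * res$time) + zeta * wn / wd * sin(wd * res$time)))
  expect_close(res$pitch_deg, closed, 0.02 * rad2deg_pub(a0),
               label = "pitch ringdown vs damped harmonic oscillator")
})

test_that("energy is conserved with undamped springs and a free, unactuated joint", {
  aero_full <- default_aero_params(g_default)
  aero <- aero_spring_params(C1 = aero_full$C1, C2 = 0)
  a0 <- 0.15
  q0 <- c(cos(a0 / 2), 0, sin(a0 / 2), 0)
  drv <- torque_drive(function(t) c(0, 0), axes = c("pitch", "roll"),
                      qd0 = c(0.5, -0.3))
  res <- simulate_maneuver(g_default, drv, sim_config(duration = 1),
                           aero, state0 = body_state(quat = q0))
  par <- tailspin:::dyn_params(g_default, c("pitch", "roll"))
  E <- vapply(seq_len(nrow(res)), function(i) {
    geom <- tailspin:::dyn_geometry(deg2rad_pub(c(res$q1_deg[i], res$q2_deg[i])),
                                    par)
    quat <- c(res$qw[i], res$qx[i], res$qy[i], res$qz[i])
    tailspin:::kinetic_energy(geom, c(res$wx[i], res$wy[i], res$wz[i]),
                              c(res$qd1[i], res$qd2[i])) +
      tailspin:::spring_potential(quat, aero)
  }, numeric(1))
  expect_lt(max(abs(E - E[1])), 1e-6 * E[1])
})

test_that("torque-driven and kinematic simulations of the same motion agree", {
  # drive the joint with a smooth torque, then replay the resulting joint
  # trajectory kinematically; body yaw must match
  tau <- function(t) c(2e-5 * sin(pi * t / 0.4) * (t < 0.4), 0)
  drv_t <- torque_drive(tau, axes = c("yaw", "pitch"))
  res_t <- simulate_maneuver(g_default, drv_t,
                             sim_config(duration = 0.5, dt_out = 0.001))
  qf <- splinefun(res_t$time, deg2rad_pub(res_t$q1_deg))
  drv_k <- kinematic_drive(function(t) c(qf(t), 0),
                           function(t) c(qf(t, deriv = 1), 0),
                           axes = c("yaw", "pitch"))
  res_k <- simulate_maneuver(g_default, drv_k,
                             sim_config(duration = 0.5, dt_out = 0.001,
                                        engine = "reference"))
  expect_lt(abs(res_t$yaw_deg[nrow(res_t)] - res_k$yaw_deg[nrow(res_k)]),
            0.05)
})

test_that("quaternions stay normalized and results export cleanly", {
  traj <- collocation_trajectory(c(90, 0, -90), c(0, 60, 0))
  res <- simulate_maneuver(g_default, spline_from_points(traj),
                           sim_config(duration = 0.6))
  norms <- sqrt(res$qw^2 + res$qx^2 + res$qy^2 + res$qz^2)
  expect_close(norms, 1, 1e-9)
  path <- withr::local_tempfile(fileext = ".csv")
  export_sim_result(res, path, meta = list(seed = 1))
  back <- read.csv(path)
  expect_equal(nrow(back), nrow(res))
  meta <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(meta$mode, "kinematic")
})
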